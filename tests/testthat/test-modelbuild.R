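# Comparative model construction: threading, minimisers, loop closure,
# side-chain placement, secondary-structure-preserving refinement.

test_that("threading copies, mutates and flags per the alignment", {
  tm_seq <- strsplit("ADKLVESTRQMLNHKYGQIE", "")[[1]]
  tmpl <- generate_toy_structure("ideal_helix", length = 20, seed = 11,
                                 sequence = tm_seq)
  tseq <- paste(tm_seq, collapse = "")
  # identical target: coordinates reproduced exactly
  ss <- sequence_set(c("t", "p"), c(tseq, tseq))
  m <- thread_onto_template(ss[1, ], tmpl, align_progressive(ss),
                            template_id = "p")
  expect_equal(superpose_rmsd(m, tmpl, "all")$rmsd, 0, tolerance = 1e-9)
  # single mutation keeps the backbone and rebuilds the side chain
  ts2 <- tseq
  substr(ts2, 5, 5) <- "A"
  ss2 <- sequence_set(c("t", "p"), c(ts2, tseq))
  m2 <- thread_onto_template(ss2[1, ], tmpl, align_progressive(ss2),
                             template_id = "p")
  expect_equal(superpose_rmsd(m2, tmpl, "backbone")$rmsd, 0,
               tolerance = 1e-9)
  expect_setequal(m2$atoms$atom[m2$atoms$res == 5],
                  c("N", "CA", "C", "O", "CB"))
  # insertion becomes an unbuilt segment read off the alignment gap
  ts3 <- paste0(substr(tseq, 1, 10), "GGG", substr(tseq, 11, 20))
  ss3 <- sequence_set(c("t", "p"), c(ts3, tseq))
  m3 <- thread_onto_template(ss3[1, ], tmpl, align_progressive(ss3),
                             template_id = "p")
  expect_equal(m3$unbuilt, list(c(11, 13)))
  expect_false(any(m3$atoms$res %in% 11:13))
})

test_that("torsion minimisation honours its contracts", {
  # already-minimal ideal dipeptide stays put
  d <- build_backbone(c("A", "A"), phi = c(NA, -70), psi = c(150, 150))
  d2 <- minimize_torsion(d, max_steps = 3)
  expect_lt(max(abs(as.matrix(d$atoms[, c("x", "y", "z")]) -
                    as.matrix(d2$atoms[, c("x", "y", "z")]))), 0.2)
  tr <- attr(d2, "energy_trace")
  expect_true(all(diff(tr) <= 1e-9))
  # eclipsed-chi valine relaxes to within 15 degrees of the 1-D scan minimum
  v <- build_backbone(c("G", "V", "G"), phi = c(NA, -70, -70),
                      psi = c(150, 150, 150))
  v <- build_side_chain(v, 2, chi = 0)
  en <- energy_model()
  vmin <- minimize_torsion(v, en, max_steps = 3)
  # 1-D scan of the energy over chi on the relaxed backbone as oracle
  scan <- sapply(seq(-179, 180, by = 1), function(ch) {
    model_energy(build_side_chain(vmin, 2, chi = ch), en, terms = "all")
  })
  best_chi <- seq(-179, 180, by = 1)[which.min(scan)]
  chi_final <- chi_angles(vmin, 2)
  dist_deg <- abs((chi_final - best_chi + 180) %% 360 - 180)
  expect_lt(dist_deg, 15)
  # hard clash (two helices packed far too tightly): energy strictly
  # decreases and the worst clash distance grows
  cl <- generate_toy_structure("two_domain", length = 8, separation = 4.5,
                               seed = 1)
  worst_gap <- function(m) {
    topo <- paraloop:::model_topology(m)
    rp <- paraloop:::repulsive_pairs(as.matrix(m$atoms[, c("x", "y", "z")]),
                                     topo, 0.85)
    if (is.null(rp)) Inf
    else {
      xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
      min(sqrt(rowSums((xyz[rp[, 1], , drop = FALSE] -
                        xyz[rp[, 2], , drop = FALSE])^2)) / rp[, 3])
    }
  }
  e0 <- model_energy(cl, en, terms = "differentiable")
  expect_gt(e0, 1)  # fixture really clashes
  cl2 <- minimize_torsion(cl, en, max_steps = 2)
  expect_lt(model_energy(cl2, en, terms = "differentiable"), e0)
  expect_gt(worst_gap(cl2), worst_gap(cl))
})

test_that("steepest descent restores a stretched bond (harmonic closed form)", {
  m <- build_backbone(c("A", "A"), phi = c(NA, -70), psi = c(150, 150))
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  i <- which(m$atoms$res == 1 & m$atoms$atom == "C")
  j <- which(m$atoms$res == 2 & m$atoms$atom == "N")
  dirv <- xyz[j, ] - xyz[i, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  xyz[j, ] <- xyz[j, ] + 0.2 * dirv
  m$atoms[, c("x", "y", "z")] <- xyz
  m2 <- minimize_cartesian(m, steps = 500)
  xyz2 <- as.matrix(m2$atoms[, c("x", "y", "z")])
  blen <- sqrt(sum((xyz2[i, ] - xyz2[j, ])^2))
  expect_lt(abs(blen - 1.329), 0.01)
  tr <- attr(m2, "energy_trace")
  expect_true(all(diff(tr) <= 0))
  # minimum-energy fragment unchanged within tolerance
  f <- build_backbone(c("A", "A"), phi = c(NA, -70), psi = c(150, 150))
  f2 <- minimize_cartesian(f, steps = 100)
  expect_lt(max(abs(as.matrix(f$atoms[, c("x", "y", "z")]) -
                    as.matrix(f2$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("loop sampling closes, is seed-deterministic, and checks reach", {
  h <- build_backbone(rep("A", 14), phi = rep(-57, 14), psi = rep(-47, 14))
  cs <- sample_and_close_segment(h, c(6, 9), n_samples = 40, seed = 7)
  expect_gt(length(cs$conformers), 0)
  gaps <- vapply(cs$conformers, `[[`, 0, "gap")
  expect_true(all(gaps <= 0.3))
  ens <- vapply(cs$conformers, `[[`, 0, "energy")
  expect_true(all(diff(ens) >= 0))  # sorted ascending
  cs2 <- sample_and_close_segment(h, c(6, 9), n_samples = 40, seed = 7)
  expect_identical(lapply(cs$conformers, `[[`, "xyz"),
                   lapply(cs2$conformers, `[[`, "xyz"))
  # single-residue span between ideal anchors closes tightly
  cs1 <- sample_and_close_segment(h, c(7, 7), n_samples = 30, seed = 2)
  expect_gt(length(cs1$conformers), 0)
  expect_true(all(vapply(cs1$conformers, `[[`, 0, "gap") <= 0.3))
  # infeasible span: anchors far beyond the chain's maximal reach
  far <- h
  at <- far$atoms
  at[at$res > 9, c("x", "y", "z")] <-
    at[at$res > 9, c("x", "y", "z")] + 60
  far$atoms <- at
  far$breaks <- 9L  # annotate so the stretched gap is legal geometry
  expect_error(sample_and_close_segment(far, c(7, 9), n_samples = 5, seed = 1),
               "reach")
})

test_that("loop modelling improves a strained loop and respects closure", {
  h <- generate_toy_structure("helix_with_loop", length = 16,
                              loop_span = c(7, 10), seed = 3)
  e0 <- model_energy(h, terms = "all")
  out <- model_loop(h, c(7, 10), n_samples = 60, seed = 4)
  expect_lt(attr(out, "loop_energy"), e0)
  expect_lte(attr(out, "loop_energy"), attr(out, "first_round_energy"))
  validate_model(out)
  expect_true(TRUE)
})

test_that("side-chain placement matches an exhaustive library scan", {
  lib <- default_rotamer_library()
  # all-Gly/Ala segment is untouched
  g <- build_backbone(c("G", "A", "G"), phi = c(NA, -57, -57),
                      psi = c(-47, -47, -47))
  g2 <- place_side_chains(g, lib)
  expect_equal(g$atoms, g2$atoms)
  # lone valine in empty space: placement equals the brute-force minimum
  v <- build_backbone(c("G", "V", "G"), phi = c(NA, -70, -70),
                      psi = c(150, 150, 150))
  en <- energy_model()
  v2 <- place_side_chains(v, lib, energy = en)
  rots <- lib$rotamers[["V"]]
  es <- vapply(seq_len(nrow(rots)), function(r) {
    model_energy(build_side_chain(v, 2, chi = rots[r, ]), en,
                 terms = "differentiable")
  }, 0)
  placed_energy <- model_energy(build_side_chain(v, 2, chi_angles(v2, 2)),
                                en, terms = "differentiable")
  expect_equal(placed_energy, min(es), tolerance = 1e-9)
  # valine against a wall of atoms: the chosen rotamer is clash-free while
  # at least one library entry clashes
  w <- build_side_chain(v, 2, chi = 180)
  cg1 <- as.numeric(w$atoms[w$atoms$res == 2 & w$atoms$atom == "CG1",
                            c("x", "y", "z")])
  cb <- as.numeric(w$atoms[w$atoms$res == 2 & w$atoms$atom == "CB",
                           c("x", "y", "z")])
  # a blocking atom on the chi = 180 side-chain axis, far enough from the
  # fixed CB that only the chi = 180 rotamer clashes with it
  bpos <- cb + 3.2 * (cg1 - cb) / sqrt(sum((cg1 - cb)^2))
  blocker <- data.frame(res = 4, resname = "G", atom = "CA",
                        x = bpos[1], y = bpos[2], z = bpos[3],
                        stringsAsFactors = FALSE)
  w$atoms <- rbind(w$atoms, blocker)
  w$sequence <- c(w$sequence, "G")
  w$breaks <- 3L
  clash_of <- function(m) {
    topo <- paraloop:::model_topology(m)
    rp <- paraloop:::repulsive_pairs(as.matrix(m$atoms[, c("x", "y", "z")]),
                                     topo, 0.85)
    if (is.null(rp)) 0L else nrow(rp)
  }
  any_clash <- any(vapply(seq_len(nrow(rots)), function(r) {
    clash_of(build_side_chain(w, 2, chi = rots[r, ])) > 0
  }, TRUE))
  expect_true(any_clash)
  w2 <- place_side_chains(w, lib, span = c(2, 2))
  expect_equal(clash_of(w2), 0L)
  # unknown residue type errors
  bad_lib <- lib
  bad_lib$rotamers[["V"]] <- NULL
  expect_error(place_side_chains(v, bad_lib), "absent")
})

test_that("secondary-structure refinement retains the bond network", {
  h <- build_backbone(rep("A", 12), phi = rep(-57, 12), psi = rep(-47, 12))
  ss <- assign_secondary_structure(h)
  hb0 <- nrow(ss$hbonds)
  r <- refine_secondary_structure(h, ss, hbond_penalty = 10)
  expect_equal(nrow(backbone_hbonds(r)), hb0)
  tr <- attr(r, "penalised_trace")
  expect_true(all(diff(tr) <= 0))
  # a strained residue relaxes while nearly all bonds survive
  hs <- paraloop:::rotate_torsion(h, 6, "phi", 25)
  sss <- assign_secondary_structure(hs)
  rs <- refine_secondary_structure(hs, sss, hbond_penalty = 10)
  e_before <- model_energy(hs, terms = "differentiable")
  e_after <- model_energy(rs, terms = "differentiable")
  expect_lte(e_after, e_before)
  kept <- nrow(backbone_hbonds(rs))
  expect_gte(kept, nrow(sss$hbonds) - 1)
})

test_that("rotamer library records its metadata", {
  lib <- default_rotamer_library()
  expect_gt(lib$size, 100)
  expect_equal(lib$bin_width[["chi1"]], 30)
  for (rt in names(lib$rotamers)) {
    r <- lib$rotamers[[rt]]
    if (ncol(r) > 0) {
      expect_true(all(r > -180 & r <= 180), info = rt)
    }
  }
})
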