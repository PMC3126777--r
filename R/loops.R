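# Loop construction: random-tweak sampling of backbone torsions followed by
# cyclic-coordinate-descent (CCD) closure onto the downstream anchor, and
# the two-round loop modelling driver.

# build span backbone (N, CA, C per residue, plus the rebuilt N', CA', C' of
# the downstream anchor residue) from a torsion vector; returns (3k+3) x 3
# torsions: c(psi_prev, phi_s, psi_s, ..., phi_e, psi_e, phi_next)
span_backbone_from_torsions <- function(anchorN, anchorCA, anchorC, k, tors) {
  out <- matrix(0, 3L * k + 3L, 3L)
  A <- anchorN; B <- anchorCA; C <- anchorC
  t <- 1L
  row <- 1L
  for (i in seq_len(k + 1L)) {
    N <- place_atom(A, B, C, IDEAL$b_C_N, IDEAL$a_CA_C_N, tors[t]); t <- t + 1L
    CA <- place_atom(B, C, N, IDEAL$b_N_CA, IDEAL$a_C_N_CA, 180)
    Cn <- place_atom(C, N, CA, IDEAL$b_CA_C, IDEAL$a_N_CA_C, tors[t]); t <- t + 1L
    out[row, ] <- N; out[row + 1L, ] <- CA; out[row + 2L, ] <- Cn
    row <- row + 3L
    A <- N; B <- CA; C <- Cn
  }
  out
}

# torsion handle table for the CCD core: anchor N/CA/C occupy rows 1-3 of
# the coordinate matrix, the rebuilt chain (k span residues plus the
# downstream anchor backbone) rows 4 onward
ccd_handles <- function(k) {
  h <- list(c(2L, 3L, 4L))  # psi of the upstream anchor residue
  for (j in seq_len(k + 1L)) {
    base <- 3L + 3L * (j - 1L)
    h[[length(h) + 1L]] <- c(base + 1L, base + 2L, base + 3L)  # phi
    if (j <= k) {
      h[[length(h) + 1L]] <- c(base + 2L, base + 3L, base + 4L)  # psi
    }
  }
  do.call(rbind, h)
}

# write closed span coordinates back into the model (backbone + O + default
# side chains for the span residues)
install_span <- function(model, span, xyz, side_chains = TRUE) {
  s <- span[1L]; e <- span[2L]
  k <- e - s + 1L
  keep <- !(model$atoms$res %in% s:e)
  model$atoms <- model$atoms[keep, , drop = FALSE]
  rows <- lapply(seq_len(k), function(j) {
    base <- 3L * (j - 1L)
    i <- s + j - 1L
    N <- xyz[base + 1L, ]; CA <- xyz[base + 2L, ]; C <- xyz[base + 3L, ]
    nextN <- xyz[base + 4L, ]
    psi <- dihedral_angle(N, CA, C, nextN)
    O <- place_atom(N, CA, C, IDEAL$b_C_O, IDEAL$a_CA_C_O, psi + 180)
    data.frame(res = i, resname = model$sequence[i],
               atom = c("N", "CA", "C", "O"),
               x = c(N[1L], CA[1L], C[1L], O[1L]),
               y = c(N[2L], CA[2L], C[2L], O[2L]),
               z = c(N[3L], CA[3L], C[3L], O[3L]),
               stringsAsFactors = FALSE)
  })
  model$atoms <- rbind(model$atoms, do.call(rbind, rows))
  model <- reindex_atoms(model)
  if (side_chains) for (i in s:e) model <- build_side_chain(model, i)
  # span now built: clear any unbuilt annotation and break inside/around it
  model$unbuilt <- Filter(function(u) !(u[1L] >= s && u[2L] <= e), model$unbuilt)
  model$breaks <- setdiff(model$breaks, (s - 1L):e)
  model
}

#' Sample and close a backbone segment (random tweak + CCD)
#'
#' Draws `n_samples` random coil backbone conformations for the span, closes
#' each onto the downstream anchor by cyclic coordinate descent, and returns
#' the closed conformers sorted by energy. Deterministic for a fixed seed.
#'
#' @param model a [protein_model()]; residues `span[1]-1` and `span[2]+1`
#'   must be built (anchors).
#' @param span `c(start, end)` residue range, interior to the chain.
#' @param n_samples number of random conformations (default 200).
#' @param seed RNG seed.
#' @param energy an [energy_model()] used to rank closed conformers.
#' @param tol closure tolerance: RMSD over the downstream anchor N/CA/C
#'   atoms, in Angstroms (default 0.3).
#' @param max_iter CCD iteration cap per sample.
#' @param around optional torsion vector; when given, samples perturb it
#'   within `jitter` degrees instead of drawing fresh coil torsions (the
#'   second "tweak" round of loop modelling).
#' @param jitter perturbation half-width for `around` (degrees).
#' @return Object of class `conformer_set`: list with `conformers` (each
#'   `list(torsions, xyz, gap, energy)`, sorted by energy ascending), `span`,
#'   `seed`, `tol`.
#' @export
sample_and_close_segment <- function(model, span, n_samples = 200L,
                                     seed = 1L, energy = energy_model(),
                                     tol = 0.3, max_iter = 500L,
                                     around = NULL, jitter = 20) {
  s <- span[1L]; e <- span[2L]
  k <- e - s + 1L
  aN <- atom_coord(model, s - 1L, "N")
  aCA <- atom_coord(model, s - 1L, "CA")
  aC <- atom_coord(model, s - 1L, "C")
  tN <- atom_coord(model, e + 1L, "N")
  tCA <- atom_coord(model, e + 1L, "CA")
  tC <- atom_coord(model, e + 1L, "C")
  if (is.null(aN) || is.null(aCA) || is.null(aC) ||
      is.null(tN) || is.null(tCA) || is.null(tC)) {
    stop("anchor residues flanking the span must have built backbones")
  }
  reach <- 3.8 * k + 1.4
  need <- vnorm(tN - aC)
  if (reach < need) {
    stop(sprintf("span of %d residues cannot reach anchor: max reach %.1f A, anchor distance %.1f A",
                 k, reach, need))
  }
  target <- rbind(tN, tCA, tC)
  n_tors <- 2L * (k + 1L) + 1L
  handles <- ccd_handles(k)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  conformers <- list()
  for (it in seq_len(n_samples)) {
    if (is.null(around)) {
      tors <- numeric(n_tors)
      tors[1L] <- runif(1, -75, 175)                      # psi of anchor
      phis <- runif(k + 1L, -155, -45)
      psis <- runif(k, -60, 170)
      tors[seq(2L, by = 2L, length.out = k + 1L)] <- phis
      if (k > 0L) tors[seq(3L, by = 2L, length.out = k)] <- psis
    } else {
      tors <- around + runif(n_tors, -jitter, jitter)
    }
    xyz0 <- rbind(aN, aCA, aC,
                  span_backbone_from_torsions(aN, aCA, aC, k, tors))
    closed <- .ccd_close(xyz0, handles, target, tol, max_iter)
    gap <- closed$gap
    if (gap > tol) next
    xyz <- closed$xyz[-(1:3), , drop = FALSE]
    # rank on the backbone conformer's energy; side chains are modelled
    # after the winning conformer is retained
    m2 <- install_span(model, span, xyz, side_chains = FALSE)
    en <- model_energy(m2, energy, terms = "all")
    conformers[[length(conformers) + 1L]] <-
      list(torsions = tors, xyz = xyz, gap = gap, energy = en)
  }
  ord <- order(vapply(conformers, `[[`, 0, "energy"))
  structure(list(conformers = conformers[ord], span = span, seed = seed,
                 tol = tol),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("conformer_set: %d closed conformer(s) for span %d-%d (tol %.2f A)\n",
              length(x$conformers), x$span[1L], x$span[2L], x$tol))
  invisible(x)
}

#' Model a loop: sample, close, minimise, place side chains, resample
#'
#' Runs the two-round loop protocol: random-tweak sampling with CCD closure,
#' retain the lowest-energy closed conformer, torsion-minimise and build its
#' side chains, then resample locally about the winner and keep the better
#' result. The returned model's span energy is never worse than the best
#' first-round conformer.
#'
#' @param model a [protein_model()].
#' @param span `c(start, end)` residue range.
#' @param library a rotamer library (default [default_rotamer_library()]).
#' @param energy an [energy_model()].
#' @param n_samples samples in round one (round two uses half).
#' @param seed RNG seed.
#' @param tol closure tolerance (Angstroms).
#' @return The model with the span rebuilt; attributes `loop_energy` (final)
#'   and `first_round_energy`.
#' @export
model_loop <- function(model, span, library = default_rotamer_library(),
                       energy = energy_model(), n_samples = 200L, seed = 1L,
                       tol = 0.3) {
  cs <- sample_and_close_segment(model, span, n_samples = n_samples,
                                 seed = seed, energy = energy, tol = tol)
  if (!length(cs$conformers)) stop("no conformer closed within tolerance")
  best <- cs$conformers[[1L]]
  polish <- function(m) {
    m <- minimize_torsion(m, energy, max_steps = 2L, span = span)
    m <- place_side_chains(m, library, span = span, energy = energy)
    # short Cartesian touch-up regularises the closure-junction bond
    minimize_cartesian(m, energy, steps = 60L)
  }
  m1 <- polish(install_span(model, span, best$xyz))
  e1 <- model_energy(m1, energy, terms = "all")
  # round two: local tweak about the winner
  cs2 <- sample_and_close_segment(model, span, n_samples = max(n_samples %/% 2L, 10L),
                                  seed = seed + 1L, energy = energy, tol = tol,
                                  around = best$torsions, jitter = 20)
  m_out <- m1
  e_out <- e1
  if (length(cs2$conformers)) {
    m2 <- polish(install_span(model, span, cs2$conformers[[1L]]$xyz))
    e2 <- model_energy(m2, energy, terms = "all")
    if (e2 < e_out) { m_out <- m2; e_out <- e2 }
  }
  attr(m_out, "loop_energy") <- e_out
  attr(m_out, "first_round_energy") <- best$energy
  m_out
}
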