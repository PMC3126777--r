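#' Backbone-independent rotamer library
#'
#' Built by chi-angle enumeration: chi1 on a 30-degree grid, higher chi
#' angles at the three staggered states (-60, 60, 180), pruned of rotamers
#' whose side-chain atoms clash internally with the residue's own backbone
#' in an ideal dipeptide context. Proline carries a single fixed ring-like
#' entry. Bin widths and total size are recorded as metadata; the library is
#' memoised per session.
#'
#' @param chi1_step chi1 grid spacing in degrees (default 30).
#' @return Object of class `rotamer_library`: list with `rotamers` (per
#'   residue type, a matrix with one row per rotamer), `bin_width`, `size`.
#' @export
default_rotamer_library <- function(chi1_step = 30) {
  key <- paste0("rotlib_", chi1_step)
  if (!is.null(.paraloop_cache[[key]])) return(.paraloop_cache[[key]])
  lib <- list()
  chi1_grid <- seq(-180 + chi1_step, 180, by = chi1_step)
  stag <- c(-60, 60, 180)
  for (rt in names(SIDE_CHAINS)) {
    k <- n_chi(rt)
    if (k == 0L) {
      lib[[rt]] <- matrix(numeric(0), nrow = 1L, ncol = 0L)
      next
    }
    if (rt == "P") {
      lib[[rt]] <- matrix(c(-25, 35)[seq_len(k)], nrow = 1L)
      next
    }
    grids <- c(list(chi1_grid), rep(list(stag), k - 1L))
    combos <- as.matrix(do.call(expand.grid, grids))
    dimnames(combos) <- NULL
    keep <- vapply(seq_len(nrow(combos)), function(r) {
      !rotamer_self_clash(rt, combos[r, ])
    }, TRUE)
    lib[[rt]] <- combos[keep, , drop = FALSE]
  }
  out <- structure(list(rotamers = lib,
                        bin_width = c(chi1 = chi1_step, higher = 120),
                        size = sum(vapply(lib, nrow, 0L))),
                   class = "rotamer_library")
  .paraloop_cache[[key]] <- out
  out
}

#' @export
print.rotamer_library <- function(x, ...) {
  cat(sprintf("rotamer_library: %d rotamers (chi1 bin %g deg, higher chi bin %g deg)\n",
              x$size, x$bin_width[["chi1"]], x$bin_width[["higher"]]))
  invisible(x)
}

# does this rotamer clash with the residue's own backbone / itself in an
# ideal alanine-dipeptide-like context?
rotamer_self_clash <- function(restype, chi) {
  ctx <- .paraloop_cache$rot_ctx
  if (is.null(ctx)) {
    ctx <- build_backbone(c("G", "X", "G"), phi = c(NA, -120, -120),
                          psi = c(140, 140, 140), side_chains = FALSE)
    .paraloop_cache$rot_ctx <- ctx
  }
  N <- atom_coord(ctx, 2L, "N")
  CA <- atom_coord(ctx, 2L, "CA")
  C <- atom_coord(ctx, 2L, "C")
  chain <- SIDE_CHAINS[[restype]]
  pos <- list(cb_position(N, CA, C))
  frame <- list(N, CA, pos[[1L]])
  for (k in seq_along(chi)) {
    pos[[k + 1L]] <- place_atom(frame[[1L]], frame[[2L]], frame[[3L]],
                                side_bond_length(chain[k + 1L]),
                                IDEAL$a_side, chi[k])
    frame <- list(frame[[2L]], frame[[3L]], pos[[k + 1L]])
  }
  sc <- do.call(rbind, pos)
  # clash of atoms >= 3 bonds apart: side atom k vs backbone N/C/O and vs
  # side atoms separated by >= 3 in the chain
  bb <- rbind(N, C, atom_coord(ctx, 2L, "O"),
              atom_coord(ctx, 1L, "C"), atom_coord(ctx, 3L, "N"))
  for (k in seq_len(nrow(sc))) {
    lim <- if (k == 1L) 2.4 else 2.6
    if (k >= 2L) {
      d <- sqrt(rowSums(sweep(bb, 2L, sc[k, ])^2))
      if (any(d < lim)) return(TRUE)
    }
    if (k >= 4L) {
      d <- sqrt(rowSums(sweep(sc[seq_len(k - 3L), , drop = FALSE], 2L, sc[k, ])^2))
      if (any(d < 2.8)) return(TRUE)
    }
  }
  FALSE
}

#' Rotamer-library side-chain placement
#'
#' Each residue in the span is assigned the library rotamer of lowest local
#' energy (soft repulsion against the fixed environment plus the chi torsion
#' term), sweeping residues in order of increasing solvent exposure until no
#' assignment changes or 10 sweeps have run. Ties between equal-energy
#' rotamers go to the lowest library index.
#'
#' @param model a [protein_model()] with complete backbone over the span.
#' @param library a [default_rotamer_library()].
#' @param span optional `c(start, end)` residue range (default whole chain).
#' @param energy an [energy_model()] (supplies the repulsion and chi terms).
#' @return The model with side chains placed.
#' @export
place_side_chains <- function(model, library = default_rotamer_library(),
                              span = NULL, energy = energy_model()) {
  built <- sort(unique(model$atoms$res))
  res_set <- if (is.null(span)) built else intersect(built, span[1L]:span[2L])
  res_set <- res_set[vapply(res_set, function(i) {
    n_chi(model$sequence[i]) > 0L && model$sequence[i] != "P"
  }, TRUE)]
  if (!length(res_set)) return(model)
  for (i in res_set) {
    if (is.null(library$rotamers[[model$sequence[i]]])) {
      stop("residue type absent from rotamer library: ", model$sequence[i])
    }
  }
  # exposure order: buried residues (fewest neighbours ~ most exposed) last
  ca <- do.call(rbind, lapply(res_set, function(i) atom_coord(model, i, "CA")))
  all_ca <- do.call(rbind, lapply(built, function(i) atom_coord(model, i, "CA")))
  ncount <- vapply(seq_len(nrow(ca)), function(k) {
    sum(sqrt(rowSums(sweep(all_ca, 2L, ca[k, ])^2)) < 10) - 1L
  }, 0L)
  res_set <- res_set[order(-ncount, res_set)]  # buried first
  assigned <- rep(NA_integer_, length(res_set))
  names(assigned) <- as.character(res_set)
  for (sweep_i in 1:10) {
    changed <- FALSE
    for (i in res_set) {
      rots <- library$rotamers[[model$sequence[i]]]
      es <- vapply(seq_len(nrow(rots)), function(r) {
        rotamer_local_energy(model, i, rots[r, ], energy)
      }, 0)
      best <- which.min(es)  # which.min takes the first (lowest index) tie
      if (!identical(best, assigned[[as.character(i)]])) {
        model <- build_side_chain(model, i, chi = rots[best, ])
        assigned[[as.character(i)]] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  model
}

# local energy of a candidate rotamer: soft repulsion of its side atoms
# against all other atoms plus the 3-fold chi torsion term
rotamer_local_energy <- function(model, res, chi, energy) {
  restype <- model$sequence[res]
  chain <- SIDE_CHAINS[[restype]]
  N <- atom_coord(model, res, "N")
  CA <- atom_coord(model, res, "CA")
  C <- atom_coord(model, res, "C")
  pos <- list(cb_position(N, CA, C))
  frame <- list(N, CA, pos[[1L]])
  for (k in seq_along(chi)) {
    pos[[k + 1L]] <- place_atom(frame[[1L]], frame[[2L]], frame[[3L]],
                                side_bond_length(chain[k + 1L]),
                                IDEAL$a_side, chi[k])
    frame <- list(frame[[2L]], frame[[3L]], pos[[k + 1L]])
  }
  sc <- do.call(rbind, pos)
  env <- model$atoms[!(model$atoms$res == res &
                       !model$atoms$atom %in% c("N", "CA", "C", "O")), ,
                     drop = FALSE]
  # local neighbourhood only
  exyz <- as.matrix(env[, c("x", "y", "z")])
  near <- sqrt(rowSums(sweep(exyz, 2L, CA)^2)) < 12
  env <- env[near, , drop = FALSE]
  exyz <- exyz[near, , drop = FALSE]
  eradii <- VDW_RADII[atom_element(env$atom)]
  e <- energy$k_chi * sum(1 + cos(3 * chi * DEG))
  for (k in seq_len(nrow(sc))) {
    # skip pairs within 3 bonds, mirroring the global exclusion graph
    skip <- switch(min(k, 4L),
      env$res == res & env$atom %in% c("N", "CA", "C", "O") |
        env$res == res - 1L & env$atom == "C" |
        env$res == res + 1L & env$atom == "N",
      env$res == res & env$atom %in% c("N", "CA", "C"),
      env$res == res & env$atom == "CA",
      rep(FALSE, nrow(env)))
    rk <- VDW_RADII[atom_element(chain[k])]
    thr <- energy$rep_scale * (eradii + rk)
    d <- sqrt(rowSums(sweep(exyz, 2L, sc[k, ])^2))
    viol <- which(d < thr & !skip)
    if (length(viol)) {
      e <- e + energy$k_rep * sum((thr[viol] - d[viol])^2)
    }
    # intra-side-chain pairs four or more bonds apart
    if (k >= 5L) {
      for (l in seq_len(k - 4L)) {
        thr2 <- energy$rep_scale * (VDW_RADII[atom_element(chain[l])] + rk)
        d2 <- sqrt(sum((sc[k, ] - sc[l, ])^2))
        if (d2 < thr2) e <- e + energy$k_rep * (thr2 - d2)^2
      }
    }
  }
  e
}
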