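# Structure assessment: secondary-structure assignment, accessible surface
# area, and least-squares superposition.

#' DSSP-like three-state secondary-structure assignment
#'
#' Backbone hydrogen bonds are computed with the Kabsch-Sander electrostatic
#' formula (bond threshold -0.5 kcal/mol, amide H built geometrically).
#' Helix (`H`) comes from runs of at least two consecutive i -> i+4 turns,
#' strand (`E`) from parallel/antiparallel bridge patterns, everything else
#' is coil (`C`). Residues with incomplete backbones are labelled `C` and
#' flagged.
#'
#' @param model a [protein_model()].
#' @return Object of class `ss_assignment`: list with `labels` (per-residue
#'   `H`/`E`/`C`), `hbonds` (data.frame donor/acceptor/energy), `flagged`
#'   (residues with missing backbone atoms).
#' @export
assign_secondary_structure <- function(model) {
  n <- n_residues(model)
  labels <- rep("C", n)
  complete <- vapply(seq_len(n), function(i) {
    all(vapply(c("N", "CA", "C", "O"),
               function(a) length(atom_row(model, i, a)) > 0L, TRUE))
  }, TRUE)
  flagged <- which(!complete)
  hb <- backbone_hbonds(model)
  BM <- matrix(FALSE, n + 1L, n + 1L)  # +1 guards the j+1/i+1 look-ups
  if (nrow(hb)) BM[cbind(hb$donor, hb$acceptor)] <- TRUE
  has_bond <- function(donor, acceptor) {
    donor >= 1L && acceptor >= 1L && BM[donor, acceptor]
  }
  # 4-turn at i: acceptor i, donor i+4
  turns <- vapply(seq_len(max(n - 4L, 0L)), function(i) {
    has_bond(i + 4L, i)
  }, TRUE)
  if (length(turns) >= 2L) {
    for (i in seq_len(length(turns) - 1L)) {
      if (turns[i] && turns[i + 1L]) labels[(i + 1L):(i + 4L)] <- "H"
    }
  }
  # bridges
  if (nrow(hb)) {
    for (i in 2:(n - 1L)) {
      for (j in 2:(n - 1L)) {
        if (abs(i - j) < 3L) next
        par <- (has_bond(i - 1L, j) && has_bond(j, i + 1L)) ||
               (has_bond(j - 1L, i) && has_bond(i, j + 1L))
        anti <- (has_bond(i, j) && has_bond(j, i)) ||
                (has_bond(i - 1L, j + 1L) && has_bond(j - 1L, i + 1L))
        if (par || anti) {
          if (labels[i] != "H") labels[i] <- "E"
          if (labels[j] != "H") labels[j] <- "E"
        }
      }
    }
  }
  labels[flagged] <- "C"
  structure(list(labels = labels, hbonds = hb, flagged = flagged),
            class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat("ss_assignment:", paste(x$labels, collapse = ""), "\n")
  cat(sprintf("  %d backbone hydrogen bond(s)\n", nrow(x$hbonds)))
  invisible(x)
}

# deterministic sphere point set (golden-spiral), rows are unit vectors
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# canonical principal-axes frame: makes point-sampled ASA exactly invariant
# under rigid-body motion of the model
canonical_frame <- function(xyz) {
  ctr <- colMeans(xyz)
  x <- sweep(xyz, 2L, ctr)
  if (nrow(xyz) < 3L) return(x)
  ev <- eigen(crossprod(x), symmetric = TRUE)
  R <- ev$vectors
  # fix axis signs by statistics intrinsic to the point cloud (third
  # moment, atom-order-weighted first moment as fallback), so the frame is
  # identical for any rigidly moved copy
  for (k in 1:2) {
    pr <- as.numeric(x %*% R[, k])
    s <- sum(pr^3)
    if (abs(s) < 1e-6) s <- sum(pr * seq_along(pr))
    if (s < 0) R[, k] <- -R[, k]
  }
  R[, 3L] <- c(R[2L, 1L] * R[3L, 2L] - R[3L, 1L] * R[2L, 2L],
               R[3L, 1L] * R[1L, 2L] - R[1L, 1L] * R[3L, 2L],
               R[1L, 1L] * R[2L, 2L] - R[2L, 1L] * R[1L, 2L])
  x %*% R
}

#' Rolling-probe accessible surface area (Shrake-Rupley)
#'
#' Sphere-point sampling on each atom's solvent-expanded sphere, with points
#' occluded by any neighbouring atom removed. Coordinates are first put in a
#' canonical principal-axes frame so the sampled area is invariant under
#' rigid-body motion. Per-residue relative areas are normalised by
#' extended Gly-X-Gly reference maxima computed with the same atom model.
#'
#' @param model a [protein_model()].
#' @param probe probe radius in Angstroms (default 1.4).
#' @param points_per_atom sphere points per atom (default 960).
#' @return Object of class `asa_profile`: list with `atom_area` (per atom,
#'   A^2), `residue_area` (named by residue index), `relative` (residue area
#'   over the extended reference maximum), `probe`, `points_per_atom`.
#' @export
accessible_surface <- function(model, probe = 1.4, points_per_atom = 960L) {
  at <- model$atoms
  el <- atom_element(at$atom)
  if (any(!el %in% names(VDW_RADII))) {
    bad <- which(!el %in% names(VDW_RADII))[1L]
    stop(sprintf("unknown element for atom %s (residue %d)",
                 at$atom[bad], at$res[bad]))
  }
  radii <- VDW_RADII[el] + probe
  xyz <- canonical_frame(model_xyz(model))
  n <- nrow(xyz)
  pts <- sphere_points(points_per_atom)
  area <- numeric(n)
  maxr <- max(radii)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (radii[i] + maxr)^2 & d2 > 1e-12)
    surf <- sweep(pts * radii[i], 2L, xyz[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, points_per_atom)
      for (j in nb) {
        if (!any(free)) break
        dj <- rowSums(sweep(surf[free, , drop = FALSE], 2L, xyz[j, ])^2)
        keep <- dj >= radii[j]^2
        free[free] <- keep
      }
      frac <- sum(free) / points_per_atom
    } else frac <- 1
    area[i] <- frac * 4 * pi * radii[i]^2
  }
  res_area <- tapply(area, at$res, sum)
  ref <- residue_reference_areas(probe, points_per_atom)
  rel <- res_area / ref[model$sequence[as.integer(names(res_area))]]
  structure(list(atom_area = area, residue_area = res_area, relative = rel,
                 probe = probe, points_per_atom = points_per_atom),
            class = "asa_profile")
}

# extended Gly-X-Gly maximum accessible areas per residue type, computed
# with the same reduced atom model and memoised
residue_reference_areas <- function(probe = 1.4, points_per_atom = 960L) {
  key <- sprintf("refarea_%g_%d", probe, points_per_atom)
  if (!is.null(.paraloop_cache[[key]])) return(.paraloop_cache[[key]])
  types <- names(SIDE_CHAINS)
  out <- vapply(types, function(rt) {
    m <- build_backbone(c("G", rt, "G"), phi = c(NA, -140, -140),
                        psi = c(140, 140, 140))
    a <- accessible_surface_raw(m, probe, points_per_atom)
    sum(a[m$atoms$res == 2L])
  }, 0)
  names(out) <- types
  .paraloop_cache[[key]] <- out
  out
}

# per-atom areas without the relative normalisation (avoids recursion)
accessible_surface_raw <- function(model, probe, points_per_atom) {
  at <- model$atoms
  radii <- VDW_RADII[atom_element(at$atom)] + probe
  xyz <- model_xyz(model)
  pts <- sphere_points(points_per_atom)
  n <- nrow(xyz)
  area <- numeric(n)
  maxr <- max(radii)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (radii[i] + maxr)^2 & d2 > 1e-12)
    surf <- sweep(pts * radii[i], 2L, xyz[i, ], `+`)
    free <- rep(TRUE, points_per_atom)
    for (j in nb) {
      if (!any(free)) break
      dj <- rowSums(sweep(surf[free, , drop = FALSE], 2L, xyz[j, ])^2)
      free[free] <- dj >= radii[j]^2
    }
    area[i] <- sum(free) / points_per_atom * 4 * pi * radii[i]^2
  }
  area
}

#' Least-squares superposition (Kabsch) and RMSD
#'
#' @param a,b [protein_model()] objects with matching residue numbering.
#' @param selection `"CA"`, `"backbone"` (N/CA/C/O) or `"all"`.
#' @return List with `rmsd` (Angstroms), `rotation` (3x3), `translation`
#'   (length 3; the transform maps `b` onto `a`), and `n_atoms`.
#' @export
superpose_rmsd <- function(a, b, selection = c("CA", "backbone", "all")) {
  selection <- match.arg(selection)
  pick <- function(m) {
    at <- m$atoms
    keep <- switch(selection,
      CA = at$atom == "CA",
      backbone = at$atom %in% c("N", "CA", "C", "O"),
      all = rep(TRUE, nrow(at)))
    at <- at[keep, , drop = FALSE]
    at <- at[order(at$res, at$atom), , drop = FALSE]
    as.matrix(at[, c("x", "y", "z")])
  }
  X <- pick(a)
  Y <- pick(b)
  if (nrow(X) != nrow(Y)) {
    stop(sprintf("selected atom counts differ: %d vs %d", nrow(X), nrow(Y)))
  }
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx)
  Yc <- sweep(Y, 2L, cy)
  S <- crossprod(Yc, Xc)
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Yr <- Yc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Xc - Yr)^2)))
  list(rmsd = rmsd, rotation = R, translation = cx - as.numeric(R %*% cy),
       n_atoms = nrow(X))
}
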