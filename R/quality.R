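# Model quality report: the full metric battery (threading score, molecular
# mechanics energy, RMSD to template, structure Z-scores and RMS Z-scores)
# with reference means/SDs shipped as a versioned data file.

angdiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Load the packaged quality-reference statistics
#'
#' Means and standard deviations used for Z-scoring, computed once from a
#' deterministic synthetic reference ensemble and shipped as JSON.
#'
#' @return Named list of reference statistics.
#' @export
quality_reference_stats <- function() {
  if (!is.null(.paraloop_cache$refstats)) return(.paraloop_cache$refstats)
  path <- system.file("extdata", "reference_stats.json", package = "paraloop")
  if (path == "") stop("reference statistics file not found")
  st <- jsonlite::read_json(path, simplifyVector = TRUE)
  .paraloop_cache$refstats <- st
  st
}

rama_favoured <- function(phi, psi) {
  ok <- !is.na(phi) & !is.na(psi)
  helix <- phi >= -160 & phi <= -20 & psi >= -120 & psi <= 45
  strand <- phi >= -180 & phi <= -20 & (psi >= 45 | psi <= -150)
  lefth <- phi >= 20 & phi <= 100 & psi >= -20 & psi <= 100
  mean((helix | strand | lefth)[ok])
}

backbone_loglik <- function(phi, psi) {
  ok <- !is.na(phi) & !is.na(psi)
  phi <- phi[ok]; psi <- psi[ok]
  dens <- function(mphi, mpsi, s) {
    exp(-(angdiff(phi, mphi)^2 + angdiff(psi, mpsi)^2) / (2 * s^2)) /
      (2 * pi * s^2)
  }
  mean(log(0.5 * dens(-63, -43, 25) + 0.5 * dens(-120, 130, 30) + 1e-12))
}

packing_count <- function(model) {
  cc <- cb_coords(model)
  if (nrow(cc$xyz) < 2L) return(0)
  d <- as.matrix(stats::dist(cc$xyz))
  mean(colSums(d < 8) - 1L)
}

rotamer_deviation <- function(model, library) {
  devs <- numeric(0)
  for (i in sort(unique(model$atoms$res))) {
    rt <- model$sequence[i]
    if (n_chi(rt) == 0L || rt == "P") next
    chi <- chi_angles(model, i)
    if (anyNA(chi)) next
    rots <- library$rotamers[[rt]]
    dd <- apply(rots, 1L, function(r) mean(abs(angdiff(chi, r))))
    devs <- c(devs, min(dd))
  }
  if (!length(devs)) return(0)
  mean(devs)
}

#' Table-style model quality report
#'
#' Computes the full assessment battery: threading (mean-force) score,
#' molecular-mechanics energy, backbone RMSD to the template, structure
#' Z-scores (packing, Ramachandran appearance, chi rotamer quality,
#' backbone conformation; positive is better than the reference average)
#' and RMS Z-scores (bond lengths, bond angles, omega restraints,
#' side-chain planarity, improper dihedrals, inside/outside distribution;
#' near 1 means reference-like spread).
#'
#' @param model a [protein_model()].
#' @param template optional [protein_model()] for the RMSD row.
#' @param energy an [energy_model()].
#' @param library a rotamer library.
#' @param potential a statistical potential (default the packaged one).
#' @param reference_stats reference means/SDs (default the shipped file).
#' @return Object of class `model_quality_report` (named list of metrics).
#' @export
quality_report <- function(model, template = NULL, energy = energy_model(),
                           library = default_rotamer_library(),
                           potential = default_stat_potential(),
                           reference_stats = quality_reference_stats()) {
  st <- reference_stats
  topo <- model_topology(model)
  xyz <- model_xyz(model)
  B <- topo$bonds
  blen <- sqrt(rowSums((xyz[B[, 1L], , drop = FALSE] -
                        xyz[B[, 2L], , drop = FALSE])^2))
  rmsz_bond <- sqrt(mean(((blen - topo$b0) / st$sd_bond)^2))
  A <- topo$angles
  u <- xyz[A[, 1L], , drop = FALSE] - xyz[A[, 2L], , drop = FALSE]
  v <- xyz[A[, 3L], , drop = FALSE] - xyz[A[, 2L], , drop = FALSE]
  ang <- acos(pmin(1, pmax(-1, rowSums(u * v) /
                             sqrt(rowSums(u^2) * rowSums(v^2))))) / DEG
  rmsz_angle <- sqrt(mean(((ang - topo$a0) / st$sd_angle)^2))
  tor <- backbone_torsions(model)
  om <- tor$omega[!is.na(tor$omega)]
  rmsz_omega <- if (length(om)) {
    dev <- pmin(abs(angdiff(om, 180)), abs(angdiff(om, 0)))
    sqrt(mean((dev / st$sd_omega)^2))
  } else 1
  # side-chain planarity: terminal torsion of sp2-terminated chains
  plan_dev <- numeric(0)
  imp_dev <- numeric(0)
  for (i in sort(unique(model$atoms$res))) {
    rt <- model$sequence[i]
    chi <- chi_angles(model, i)
    k <- n_chi(rt)
    if (rt %in% c("R", "D", "N", "E", "Q") && k > 0L && !anyNA(chi)) {
      d <- min(abs(angdiff(chi[k], 0)), abs(angdiff(chi[k], 180)))
      plan_dev <- c(plan_dev, d)
    }
    cb <- atom_coord(model, i, "CB")
    if (!is.null(cb)) {
      N <- atom_coord(model, i, "N")
      C <- atom_coord(model, i, "C")
      CA <- atom_coord(model, i, "CA")
      if (!is.null(N) && !is.null(C) && !is.null(CA)) {
        imp_dev <- c(imp_dev, angdiff(dihedral_angle(N, C, CA, cb),
                                      st$improper_ideal))
      }
    }
  }
  rmsz_planarity <- if (length(plan_dev)) {
    sqrt(mean((plan_dev / st$sd_planarity)^2))
  } else 1
  rmsz_improper <- if (length(imp_dev)) {
    sqrt(mean((imp_dev / st$sd_improper)^2))
  } else 1
  # inside/outside: relative exposure standardised within hydropathy class
  asa <- accessible_surface(model, points_per_atom = 240L)
  hyd <- model$sequence[as.integer(names(asa$residue_area))] %in% HYDROPHOBIC
  zin <- ifelse(hyd, (asa$relative - st$inout_hydro_mean) / st$inout_hydro_sd,
                (asa$relative - st$inout_polar_mean) / st$inout_polar_sd)
  rmsz_inout <- sqrt(mean(zin^2))
  z_pack <- (packing_count(model) - st$packing_mean) / st$packing_sd
  z_rama <- (rama_favoured(tor$phi, tor$psi) - st$rama_mean) / st$rama_sd
  z_rot <- (st$rotamer_mean - rotamer_deviation(model, library)) / st$rotamer_sd
  z_back <- (backbone_loglik(tor$phi, tor$psi) - st$backbone_mean) / st$backbone_sd
  rmsd <- NA_real_
  if (!is.null(template)) {
    common <- intersect(unique(model$atoms$res), unique(template$atoms$res))
    sub <- function(m) {
      m$atoms <- m$atoms[m$atoms$res %in% common &
                           m$atoms$atom %in% c("N", "CA", "C", "O"), ,
                         drop = FALSE]
      m
    }
    rmsd <- superpose_rmsd(sub(model), sub(template), "backbone")$rmsd
  }
  structure(list(
    threading_score = threading_score(model, potential),
    mm_energy = model_energy(model, energy),
    rmsd_to_template = rmsd,
    z_packing = z_pack,
    z_ramachandran = z_rama,
    z_rotamer = z_rot,
    z_backbone = z_back,
    rmsz_bond_lengths = rmsz_bond,
    rmsz_bond_angles = rmsz_angle,
    rmsz_omega = rmsz_omega,
    rmsz_side_chain_planarity = rmsz_planarity,
    rmsz_improper_dihedrals = rmsz_improper,
    rmsz_inside_outside = rmsz_inout),
    class = "model_quality_report")
}

#' @export
print.model_quality_report <- function(x, ...) {
  cat("model_quality_report\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm,
                                   format(x[[nm]], digits = 4)))
  invisible(x)
}

#' Write a quality report as JSON
#' @param report a [quality_report()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quality_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
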