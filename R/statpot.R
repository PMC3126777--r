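# Distance-dependent statistical (mean-force) potential for model
# assessment, compiled from a packaged synthetic mini-reference set of
# compact helix-pair fragments whose sequences follow burial (hydrophobic
# interface, polar surface). Not numerically comparable to potentials
# trained on experimental structures.

STATPOT_BINS <- 3:14  # lower edges; 1 A bins spanning 3-15 A

HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "C")

# interaction centre per residue: CB, or CA for glycine / missing CB
cb_coords <- function(model) {
  built <- sort(unique(model$atoms$res))
  xyz <- matrix(NA_real_, length(built), 3L)
  for (k in seq_along(built)) {
    p <- atom_coord(model, built[k], "CB")
    if (is.null(p)) p <- atom_coord(model, built[k], "CA")
    if (!is.null(p)) xyz[k, ] <- p
  }
  list(res = built, xyz = xyz, type = model$sequence[built])
}

#' Compile a residue-pair statistical potential from reference models
#'
#' Counts CB-CB contacts (CA for glycine) in 1-Angstrom bins over 3-15 A
#' for residue pairs separated by at least 3 in sequence, and converts them
#' to log-odds pseudo-scores against a composition-based reference state.
#'
#' @param models list of [protein_model()] objects.
#' @param pseudo additive smoothing count.
#' @return Object of class `stat_potential`: `score` array
#'   (21 x 21 x bins; positive favours the contact), `bins`, `n_models`.
#' @export
compile_stat_potential <- function(models, pseudo = 1) {
  codes <- c(AA_CODES, "X")
  nb <- length(STATPOT_BINS)
  counts <- array(0, c(21L, 21L, nb), dimnames = list(codes, codes, NULL))
  comp <- setNames(numeric(21L), codes)
  for (m in models) {
    cc <- cb_coords(m)
    comp[names(table(cc$type))] <- comp[names(table(cc$type))] + table(cc$type)
    n <- nrow(cc$xyz)
    if (n < 4L) next
    d <- as.matrix(stats::dist(cc$xyz))
    for (i in seq_len(n - 3L)) {
      for (j in (i + 3L):n) {
        if (abs(cc$res[j] - cc$res[i]) < 3L) next
        dij <- d[i, j]
        if (dij < 3 || dij >= 15) next
        b <- floor(dij - 3) + 1L
        a1 <- cc$type[i]; a2 <- cc$type[j]
        counts[a1, a2, b] <- counts[a1, a2, b] + 1
        counts[a2, a1, b] <- counts[a2, a1, b] + 1
      }
    }
  }
  p <- comp / max(sum(comp), 1)
  score <- array(0, dim(counts), dimnames = dimnames(counts))
  for (b in seq_len(nb)) {
    tot <- sum(counts[, , b]) / 2
    if (tot == 0) next
    exp_pair <- outer(p, p) * tot * 2
    score[, , b] <- log((counts[, , b] / 2 + pseudo) / (exp_pair + pseudo))
  }
  structure(list(score = score, bins = STATPOT_BINS,
                 n_models = length(models), composition = p),
            class = "stat_potential")
}

#' Default packaged statistical potential
#'
#' Compiled once per session from 40 deterministic synthetic helix-pair
#' fragments with burial-correlated sequences (see
#' [generate_toy_structure()] kind `"two_domain"`).
#'
#' @return A [compile_stat_potential()] result.
#' @export
default_stat_potential <- function() {
  if (!is.null(.paraloop_cache$statpot)) return(.paraloop_cache$statpot)
  models <- lapply(1:40, function(s) {
    generate_toy_structure(kind = "two_domain", length = 12L + (s %% 4L),
                           seed = 1000L + s, burial_sequence = TRUE)
  })
  pot <- compile_stat_potential(models)
  .paraloop_cache$statpot <- pot
  pot
}

#' Threading (mean-force) score of a model
#'
#' Sum of binned pair pseudo-scores over residue pairs separated by at
#' least 3 in sequence and within 15 Angstroms in space. Higher is more
#' native-like under this package's sign convention.
#'
#' @param model a [protein_model()].
#' @param potential a [compile_stat_potential()] result (default the
#'   packaged one).
#' @return Numeric score (0 for models with fewer than 4 residues).
#' @export
threading_score <- function(model, potential = default_stat_potential()) {
  cc <- cb_coords(model)
  n <- nrow(cc$xyz)
  if (n < 4L) return(0)
  d <- as.matrix(stats::dist(cc$xyz))
  s <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (abs(cc$res[j] - cc$res[i]) < 3L) next
      dij <- d[i, j]
      if (dij < 3 || dij >= 15) next
      b <- floor(dij - 3) + 1L
      s <- s + potential$score[cc$type[i], cc$type[j], b]
    }
  }
  s
}
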