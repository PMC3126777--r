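# Candidate-site nomination: combine sequence divergence with surface-loop
# structure evidence.

#' Detect solvent-exposed surface loops
#'
#' Maximal runs of coil-labelled residues of at least `min_len` whose mean
#' relative accessible surface area reaches `min_rel_asa`.
#'
#' @param ss an [assign_secondary_structure()] result.
#' @param asa an [accessible_surface()] result on the same model.
#' @param min_len minimum run length (default 6).
#' @param min_rel_asa minimum mean relative area (default 0.25).
#' @return data.frame with columns `start`, `end`, `coil_fraction`,
#'   `mean_rel_asa`, ordered by position.
#' @export
detect_surface_loops <- function(ss, asa, min_len = 6L, min_rel_asa = 0.25) {
  labels <- ss$labels
  rel <- asa$relative
  res_idx <- as.integer(names(asa$residue_area))
  if (length(labels) != length(rel) ||
      !all(res_idx == seq_along(labels))) {
    stop("secondary structure and ASA profiles cover different residues")
  }
  runs <- rle(labels == "C")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] || runs$lengths[k] < min_len) next
    span <- starts[k]:ends[k]
    m <- mean(rel[span])
    if (m < min_rel_asa) next
    out[[length(out) + 1L]] <- data.frame(start = starts[k], end = ends[k],
                                          coil_fraction = 1,
                                          mean_rel_asa = m)
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      coil_fraction = numeric(), mean_rel_asa = numeric()))
  }
  do.call(rbind, out)
}

#' Nominate candidate sites from divergent windows and surface loops
#'
#' A window whose mapped residue span overlaps a surface loop by at least
#' half the window length becomes a candidate site spanning the overlap.
#' Sites are ranked by
#' `cross_divergence_score * mean relative ASA * (1 + Pro/Arg composition)`
#' descending, ties broken by residue start.
#'
#' @param windows a [scan_divergent_windows()] result (mapped spans are
#'   interpreted as residue indices of the modelled chain).
#' @param loops a [detect_surface_loops()] result.
#' @param asa optional [accessible_surface()] result; when given, the mean
#'   relative area is recomputed over each site's own span (otherwise the
#'   loop's mean is used).
#' @param domain_boundary residue index separating the N-lobe from the
#'   C-terminal lobe (default two thirds of the chain when `asa` is given,
#'   otherwise the largest mapped index seen).
#' @return data.frame of class `candidate_sites`: `start`, `end`,
#'   `consensus`, `hexamer`, `divergence`, `rel_asa`, `composition`,
#'   `rank_score`, `domain`.
#' @export
nominate_sites <- function(windows, loops, asa = NULL,
                           domain_boundary = NULL) {
  empty <- data.frame(start = integer(), end = integer(),
                      consensus = character(), hexamer = character(),
                      divergence = numeric(), rel_asa = numeric(),
                      composition = numeric(), rank_score = numeric(),
                      domain = character(), stringsAsFactors = FALSE)
  class(empty) <- c("candidate_sites", "data.frame")
  if (nrow(windows) == 0L || nrow(loops) == 0L) return(empty)
  n_res <- if (!is.null(asa)) length(asa$relative) else max(loops$end, windows$mapped_end)
  if (is.null(domain_boundary)) domain_boundary <- floor(2 * n_res / 3)
  out <- list()
  for (w in seq_len(nrow(windows))) {
    ws <- windows$mapped_start[w]
    we <- windows$mapped_end[w]
    if (is.na(ws) || is.na(we)) next
    wlen <- we - ws + 1L
    for (l in seq_len(nrow(loops))) {
      os <- max(ws, loops$start[l])
      oe <- min(we, loops$end[l])
      if (os > oe) next
      if ((oe - os + 1L) < 0.5 * wlen) next
      rel <- if (!is.null(asa)) mean(asa$relative[os:oe]) else loops$mean_rel_asa[l]
      cons <- windows$consensus_sequence[w]
      comp <- mean(strsplit(cons, "")[[1L]] %in% c("P", "R"))
      hex <- if (nchar(cons) >= 6L) extract_central_hexamer(cons) else NA_character_
      out[[length(out) + 1L]] <- data.frame(
        start = os, end = oe, consensus = cons, hexamer = hex,
        divergence = windows$cross_divergence_score[w],
        rel_asa = rel, composition = comp,
        rank_score = windows$cross_divergence_score[w] * rel * (1 + comp),
        domain = if (os > domain_boundary) "C-lobe" else "N-lobe",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$rank_score, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("candidate_sites", "data.frame")
  res
}
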