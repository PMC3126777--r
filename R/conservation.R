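#' Per-column conservation profile for a labelled group
#'
#' Conservation at a column is the mean pairwise identity among the group's
#' rows: a gap paired with anything scores 0, gap-gap pairs are excluded, and
#' a column whose group rows are all gaps scores 0 and is flagged. The raw
#' per-column scores are then moving-average smoothed.
#'
#' @param aln a [multiple_alignment()].
#' @param group group label; rows with `seqs$group == group` are used.
#' @param window smoothing window width in columns (odd; default 5).
#' @param rows optional explicit row indices, overriding `group`.
#' @return Object of class `conservation_profile`: list with `score`
#'   (smoothed, in \[0,1\]), `raw`, `all_gap` (logical flags), `group`,
#'   `window`.
#' @export
conservation_profile <- function(aln, group = NULL, window = 5L, rows = NULL) {
  if (is.null(rows)) {
    rows <- which(aln$seqs$group == group)
    if (length(rows) < 2L) stop("fewer than 2 rows carry group label: ", group)
  }
  m <- alignment_matrix(aln)[rows, , drop = FALSE]
  raw <- column_identity(m)
  allgap <- colSums(m != "-") == 0L
  k <- max(1L, as.integer(window))
  half <- k %/% 2L
  nc <- length(raw)
  sm <- vapply(seq_len(nc), function(j) {
    mean(raw[max(1L, j - half):min(nc, j + half)])
  }, 0)
  structure(list(score = sm, raw = raw, all_gap = allgap,
                 group = if (is.null(group)) NA_character_ else group,
                 window = k),
            class = "conservation_profile")
}

# mean pairwise identity per column of a character matrix over residue rows;
# gap-residue pairs score 0, gap-gap pairs are excluded; all-gap column -> 0
column_identity <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- numeric(nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    res <- col[col != "-"]
    ngap <- nr - length(res)
    n_pairs <- choose(nr, 2L) - choose(ngap, 2L)  # excludes gap-gap
    if (n_pairs == 0L) { out[j] <- 0; next }
    tab <- table(res)
    matches <- sum(choose(tab, 2L))
    out[j] <- matches / n_pairs
  }
  out
}

# majority-consensus residues of a character matrix, per column; ties broken
# alphabetically; all-gap columns yield "-"
column_consensus <- function(m) {
  apply(m, 2L, function(col) {
    res <- col[col != "-"]
    if (!length(res)) return("-")
    tab <- sort(table(res), decreasing = TRUE)
    names(tab)[tab == tab[1L]][order(names(tab)[tab == tab[1L]])][1L]
  })
}

#' Scan for windows conserved in-group but divergent elsewhere
#'
#' For each alignment column the scan computes `d = c_in - c_cross`, where
#' `c_in` is the in-group conservation ([conservation_profile()] raw score,
#' in-group rows = rows carrying both `target_paralog` and `in_group` labels)
#' and `c_cross` is the mean identity between the in-group consensus and each
#' contrast row (all remaining rows), gaps scoring 0. Every window of
#' `window_len` columns is scored by the mean of `d`; windows at or above
#' `min_score` are merged into maximal runs and each run is trimmed to the
#' outermost columns whose own `d` meets `min_score`, so a reported window is
#' the divergent core rather than a smeared union.
#'
#' @param aln a [multiple_alignment()].
#' @param target_paralog paralog label of the in-group.
#' @param in_group group label of the in-group.
#' @param window_len window length in columns (default 12).
#' @param min_score minimum mean divergence to report (default 0.5).
#' @param reference id of the row used to map columns to residue indices
#'   (default: first in-group row).
#' @return data.frame of class `divergent_windows`, ordered by score
#'   (descending) then start column, with columns `start_col`, `end_col`,
#'   `in_group_conservation`, `cross_divergence_score`, `consensus_sequence`,
#'   `mapped_start`, `mapped_end`.
#' @export
scan_divergent_windows <- function(aln, target_paralog, in_group,
                                   window_len = 12L, min_score = 0.5,
                                   reference = NULL) {
  nc <- aln$n_columns
  if (window_len > nc) stop("window_len exceeds alignment columns")
  in_rows <- which(aln$seqs$paralog == target_paralog &
                   aln$seqs$group == in_group)
  if (length(in_rows) < 2L) {
    stop("need >= 2 in-group rows for ", target_paralog, "/", in_group)
  }
  contrast <- setdiff(seq_len(nrow(aln$seqs)), in_rows)
  if (!length(contrast)) stop("no contrast rows in alignment")
  m <- alignment_matrix(aln)
  c_in <- column_identity(m[in_rows, , drop = FALSE])
  cons <- column_consensus(m[in_rows, , drop = FALSE])
  cm <- m[contrast, , drop = FALSE]
  match_mat <- sweep(cm, 2L, cons, function(a, b) a == b & a != "-" & b != "-")
  c_cross <- colMeans(match_mat)
  d <- c_in - c_cross

  win_scores <- vapply(seq_len(nc - window_len + 1L), function(s) {
    mean(d[s:(s + window_len - 1L)])
  }, 0)
  hits <- which(win_scores >= min_score)
  empty <- data.frame(start_col = integer(), end_col = integer(),
                      in_group_conservation = numeric(),
                      cross_divergence_score = numeric(),
                      consensus_sequence = character(),
                      mapped_start = integer(), mapped_end = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("divergent_windows", "data.frame")
  if (!length(hits)) return(empty)

  if (is.null(reference)) reference <- aln$seqs$id[in_rows[1L]]
  res_map <- alignment_to_residue_map(aln, reference)

  # merge overlapping hit windows into runs, then trim to the divergent core
  runs <- list()
  cur <- c(hits[1L], hits[1L] + window_len - 1L)
  for (s in hits[-1L]) {
    if (s <= cur[2L] + 1L) cur[2L] <- s + window_len - 1L
    else { runs[[length(runs) + 1L]] <- cur; cur <- c(s, s + window_len - 1L) }
  }
  runs[[length(runs) + 1L]] <- cur

  rows <- lapply(runs, function(r) {
    a <- r[1L]; b <- r[2L]
    while (a < b && d[a] < min_score) a <- a + 1L
    while (b > a && d[b] < min_score) b <- b - 1L
    span <- a:b
    mapped <- res_map[span]
    mapped <- mapped[!is.na(mapped)]
    data.frame(start_col = a, end_col = b,
               in_group_conservation = mean(c_in[span]),
               cross_divergence_score = mean(d[span]),
               consensus_sequence = paste(cons[span][cons[span] != "-"],
                                          collapse = ""),
               mapped_start = if (length(mapped)) min(mapped) else NA_integer_,
               mapped_end = if (length(mapped)) max(mapped) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$cross_divergence_score, out$start_col), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("divergent_windows", "data.frame")
  out
}

#' Extract the proline/arginine-richest central hexamer of a consensus
#'
#' Returns the length-6 subsequence maximising the Pro+Arg composition
#' fraction; ties are broken by the most central start position, then by the
#' leftmost.
#'
#' @param window one row of [scan_divergent_windows()] output, or a plain
#'   consensus string.
#' @return The hexamer as a character scalar.
#' @export
extract_central_hexamer <- function(window) {
  s <- if (is.character(window)) window else window$consensus_sequence[1L]
  L <- nchar(s)
  if (L < 6L) stop("consensus shorter than 6 residues")
  starts <- seq_len(L - 5L)
  frac <- vapply(starts, function(i) {
    ch <- strsplit(substr(s, i, i + 5L), "")[[1L]]
    mean(ch %in% c("P", "R"))
  }, 0)
  centre <- (L - 6L) / 2 + 1
  ord <- order(-frac, abs(starts - centre), starts)
  substr(s, starts[ord[1L]], starts[ord[1L]] + 5L)
}
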