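#' Multiple alignment container
#'
#' A `multiple_alignment` ties gapped rows (strings over residues plus `-`)
#' back to their [sequence_set()] records. Degapping any row reproduces the
#' record's residues exactly; all rows have equal length.
#'
#' @param seqs a [sequence_set()].
#' @param aligned character vector of gapped rows, parallel to `seqs`.
#' @param score optional alignment score (recorded for two-row alignments).
#' @return Object of class `multiple_alignment` with elements `seqs`,
#'   `aligned`, `n_columns`, `score`.
#' @export
multiple_alignment <- function(seqs, aligned, score = NA_real_) {
  stopifnot(nrow(seqs) == length(aligned))
  aligned <- toupper(aligned)
  w <- unique(nchar(aligned))
  if (length(w) > 1L) stop("aligned rows have unequal lengths")
  degapped <- gsub("-", "", aligned, fixed = TRUE)
  bad <- which(degapped != seqs$residues)
  if (length(bad)) {
    stop("row ", seqs$id[bad[1L]], ": degapped row does not match its record")
  }
  structure(list(seqs = seqs, aligned = aligned,
                 n_columns = if (length(w)) w else 0L, score = score),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("multiple_alignment: %d rows x %d columns\n",
              nrow(x$seqs), x$n_columns))
  invisible(x)
}

# rows as a character matrix (rows x columns)
alignment_matrix <- function(aln) {
  if (nrow(aln$seqs) == 0L) return(matrix(character(), 0, 0))
  do.call(rbind, strsplit(aln$aligned, ""))
}

#' Map alignment columns to residue indices of one row
#'
#' @param aln a [multiple_alignment()].
#' @param id row id (default: first row).
#' @return Integer vector of length `n_columns`; `NA` at columns where the
#'   row has a gap, otherwise the 1-based residue index in that row.
#' @export
alignment_to_residue_map <- function(aln, id = aln$seqs$id[1L]) {
  i <- match(id, aln$seqs$id)
  if (is.na(i)) stop("row not found: ", id)
  ch <- strsplit(aln$aligned[i], "")[[1L]]
  idx <- cumsum(ch != "-")
  idx[ch == "-"] <- NA_integer_
  idx
}

#' Read an existing alignment (FASTA or Clustal dialect)
#'
#' @inheritParams read_sequences
#' @return A [multiple_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"), labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               set.attributes = FALSE)
    ids <- names(seqs)
    rows <- toupper(unlist(seqs, use.names = FALSE))
  } else {
    a <- parse_clustal(path)
    ids <- a$ids
    rows <- a$rows
  }
  lab <- parse_labelled_id(ids)
  if (!is.null(labels)) {
    m <- match(lab$id, labels$id)
    lab$paralog <- ifelse(!is.na(m), labels$paralog[m], lab$paralog)
    lab$group <- ifelse(!is.na(m), labels$group[m], lab$group)
  }
  ss <- sequence_set(lab$id, gsub("-", "", rows, fixed = TRUE),
                     lab$paralog, lab$group)
  multiple_alignment(ss, rows)
}

#' Write an alignment to FASTA or a Clustal-like file
#'
#' @param aln a [multiple_alignment()].
#' @param path output path.
#' @param format `"fasta"` or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  labelled <- function(i) {
    s <- aln$seqs
    hdr <- s$id[i]
    if (!is.na(s$paralog[i]) || !is.na(s$group[i])) {
      hdr <- paste(hdr, ifelse(is.na(s$paralog[i]), "", s$paralog[i]), sep = "|")
      if (!is.na(s$group[i])) hdr <- paste(hdr, s$group[i], sep = "|")
    }
    hdr
  }
  n <- nrow(aln$seqs)
  if (format == "fasta") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(n)) {
      writeLines(paste0(">", labelled(i)), con)
      s <- aln$aligned[i]
      starts <- seq(1L, max(nchar(s), 1L), by = 60L)
      writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("CLUSTAL W multiple sequence alignment", con)
    writeLines("", con)
    nm <- vapply(seq_len(n), labelled, "")
    wid <- max(nchar(nm)) + 3L
    for (start in seq(1L, max(aln$n_columns, 1L), by = 60L)) {
      for (i in seq_len(n)) {
        chunk <- substr(aln$aligned[i], start,
                        min(start + 59L, aln$n_columns))
        writeLines(sprintf("%-*s%s", wid, nm[i], chunk), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}

# minimal Clustal-dialect parser: header line, then blocks of
# "name  chunk" rows; conservation lines (leading whitespace) and blank
# lines are skipped; chunks accumulate per name in first-seen order
parse_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(toupper(lines[1L]), "CLUSTAL")) {
    stop("not a CLUSTAL file (missing header): ", path)
  }
  lines <- lines[-1L]
  acc <- list()
  order_seen <- character(0)
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(trimws(ln)) || grepl("^\\s", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) < 2L) {
      stop(sprintf("malformed CLUSTAL row at line %d", k + 1L))
    }
    nm <- parts[1L]
    chunk <- gsub("[0-9]", "", paste(parts[-1L], collapse = ""))
    if (!nm %in% order_seen) order_seen <- c(order_seen, nm)
    acc[[nm]] <- paste0(acc[[nm]] %||% "", chunk)
  }
  list(ids = order_seen,
       rows = toupper(unname(unlist(acc[order_seen]))))
}

# k-mer (default k = 3) fractional distance between ungapped sequences
kmer_distance <- function(residues, k = 3L) {
  n <- length(residues)
  km <- lapply(residues, function(s) {
    L <- nchar(s)
    if (L < k) return(table(s))
    table(substring(s, 1:(L - k + 1L), k:L))
  })
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      a <- km[[i]]; b <- km[[j]]
      common <- intersect(names(a), names(b))
      shared <- sum(pmin(a[common], b[common]))
      denom <- min(sum(a), sum(b))
      d[i, j] <- d[j, i] <- 1 - shared / max(denom, 1)
    }
  }
  d
}

# profile of a set of gapped rows: (columns x 21) residue frequency matrix,
# frequencies normalised over non-gap characters; plus per-column gap fraction
row_profile <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  codes <- c(AA_CODES, "X")
  nc <- ncol(m)
  prof <- matrix(0, nc, 21L, dimnames = list(NULL, codes))
  for (a in seq_along(codes)) prof[, a] <- colSums(m == codes[a])
  tot <- rowSums(prof)
  prof <- prof / pmax(tot, 1)
  prof
}

# insert gap columns per DP traceback (0 entries are gaps)
apply_trace <- function(rows, idx) {
  m <- do.call(rbind, strsplit(rows, ""))
  out <- matrix("-", nrow(m), length(idx))
  out[, idx != 0L] <- m[, idx[idx != 0L], drop = FALSE]
  apply(out, 1L, paste, collapse = "")
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree from k-mer (k = 3) distances with average-linkage
#' clustering, then progressively aligns profiles with a global affine-gap
#' dynamic program. Deterministic given the inputs; ties in tree joins are
#' broken by input order (via the stable distance ordering of `hclust`).
#'
#' @param seqs a [sequence_set()] with at least one record.
#' @param substitution_matrix matrix name (`"BLOSUM62"`) or a matrix.
#' @param gap_open,gap_extend gap scores (negative; a gap run of length L
#'   scores `gap_open + gap_extend * L`).
#' @return A [multiple_alignment()] in input row order. For exactly two
#'   sequences the optimal pairwise score is recorded in `$score`.
#' @export
align_progressive <- function(seqs, substitution_matrix = "BLOSUM62",
                              gap_open = -10, gap_extend = -0.5) {
  S <- resolve_substitution_matrix(substitution_matrix)
  n <- nrow(seqs)
  if (n == 0L) stop("no sequences to align")
  if (n == 1L) {
    message("single sequence: returning a 1-row alignment")
    return(multiple_alignment(seqs, seqs$residues))
  }
  go <- -gap_open
  ge <- -gap_extend
  align_two <- function(rowsA, rowsB) {
    pa <- row_profile(rowsA)
    pb <- row_profile(rowsB)
    colscore <- pa %*% S[colnames(pa), colnames(pb)] %*% t(pb)
    r <- .affine_profile_align(colscore, go, ge)
    list(rows = c(apply_trace(rowsA, r$a), apply_trace(rowsB, r$b)),
         score = r$score)
  }
  if (n == 2L) {
    r <- align_two(seqs$residues[1L], seqs$residues[2L])
    return(multiple_alignment(seqs, r$rows, score = r$score))
  }
  d <- kmer_distance(seqs$residues)
  tree <- hclust(as.dist(d), method = "average")
  clusters <- lapply(seq_len(n), function(i) {
    list(members = i, rows = seqs$residues[i])
  })
  merged <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    pick <- function(k) if (k < 0L) clusters[[-k]] else merged[[k]]
    a <- pick(tree$merge[step, 1L])
    b <- pick(tree$merge[step, 2L])
    r <- align_two(a$rows, b$rows)
    merged[[step]] <- list(members = c(a$members, b$members), rows = r$rows)
  }
  final <- merged[[n - 1L]]
  ord <- order(final$members)
  multiple_alignment(seqs, final$rows[ord])
}
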