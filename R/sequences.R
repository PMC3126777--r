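#' Sequence sets with paralog and group labels
#'
#' A `sequence_set` holds protein sequences together with two categorical
#' tags per record: a paralog label (e.g. `"CDK4"`, `"CDK6"`, `"CDK2"`) and a
#' group label (e.g. `"mammal"`, `"nonmammal"`). Records are kept in input
#' order; ids must be unique and residues are restricted to the 20 standard
#' one-letter codes plus `X`.
#'
#' @param id character vector of record identifiers.
#' @param residues character vector of sequences (one string per record).
#' @param paralog character vector of paralog labels (recycled if length 1).
#' @param group character vector of group labels (recycled if length 1).
#' @return An object of class `sequence_set`: a data.frame with columns
#'   `id`, `residues`, `paralog`, `group`.
#' @export
sequence_set <- function(id, residues, paralog = NA_character_,
                         group = NA_character_) {
  n <- length(id)
  stopifnot(length(residues) == n)
  if (n > 0 && any(id == "" | is.na(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1L])
  }
  residues <- toupper(gsub("[ \t]", "", residues))
  ok <- c(AA_CODES, "X")
  for (i in seq_len(n)) {
    ch <- strsplit(residues[i], "")[[1L]]
    bad <- which(!ch %in% ok)
    if (length(bad)) {
      stop(sprintf("record '%s': invalid residue '%s' at position %d",
                   id[i], ch[bad[1L]], bad[1L]))
    }
  }
  out <- data.frame(id = as.character(id), residues = residues,
                    paralog = rep_len(as.character(paralog), n),
                    group = rep_len(as.character(group), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("sequence_set", "data.frame")
  out
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set: %d record(s)\n", nrow(x)))
  for (i in seq_len(min(nrow(x), 10L))) {
    cat(sprintf("  %s [%s/%s] %d aa\n", x$id[i], x$paralog[i], x$group[i],
                nchar(x$residues[i])))
  }
  if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

# split "id|paralog|group" headers; missing fields become NA
parse_labelled_id <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  get <- function(p, i) if (length(p) >= i) p[i] else NA_character_
  data.frame(id = vapply(parts, get, "", 1L),
             paralog = vapply(parts, get, "", 2L),
             group = vapply(parts, get, "", 3L),
             stringsAsFactors = FALSE)
}

#' Read sequences from FASTA or Clustal files
#'
#' Headers may carry paralog/group labels with the convention
#' `id|paralog|group`; alternatively a sidecar table (`labels`) with columns
#' `id`, `paralog`, `group` can supply them.
#'
#' @param path file path.
#' @param format `"fasta"` or `"clustal"`.
#' @param labels optional data.frame with columns `id`, `paralog`, `group`.
#' @return A [sequence_set()]. For Clustal input the gapped rows are degapped;
#'   use [read_alignment()] to keep the alignment.
#' @export
read_sequences <- function(path, format = c("fasta", "clustal"), labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (all(!nzchar(trimws(raw)))) {
    warning("empty sequence file: ", path)
    return(sequence_set(character(), character()))
  }
  if (format == "fasta") {
    first <- which(nzchar(trimws(raw)))[1L]
    if (!startsWith(trimws(raw[first]), ">")) {
      stop(sprintf("malformed FASTA at line %d: expected '>' header", first))
    }
    seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               set.attributes = FALSE)
    ids <- names(seqs)
    res <- unlist(seqs, use.names = FALSE)
  } else {
    aln <- parse_clustal(path)
    ids <- aln$ids
    res <- gsub("-", "", aln$rows, fixed = TRUE)
  }
  lab <- parse_labelled_id(ids)
  if (!is.null(labels)) {
    m <- match(lab$id, labels$id)
    lab$paralog <- ifelse(!is.na(m), labels$paralog[m], lab$paralog)
    lab$group <- ifelse(!is.na(m), labels$group[m], lab$group)
  }
  sequence_set(lab$id, res, lab$paralog, lab$group)
}

#' Write a sequence set to FASTA
#'
#' Labels are encoded in headers as `id|paralog|group` (omitted when NA), so a
#' write/read cycle round-trips records and labels.
#'
#' @param seqs a [sequence_set()].
#' @param path output path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    p <- seqs$paralog[i]
    g <- seqs$group[i]
    hdr <- seqs$id[i]
    if (!is.na(p) || !is.na(g)) {
      hdr <- paste(hdr, ifelse(is.na(p), "", p), sep = "|")
      if (!is.na(g)) hdr <- paste(hdr, g, sep = "|")
    }
    writeLines(paste0(">", hdr), con)
    s <- seqs$residues[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
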