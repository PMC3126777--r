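# Sequence ingestion, progressive alignment and the paralog-divergence scan.

test_that("FASTA reading round-trips records and labels", {
  p <- tempfile(fileext = ".fasta")
  make_labelled_fasta(p, c("hs1|CDK4|mammal", "gg1|CDK4|nonmammal"),
                      c("ACDEFGHIKL", "ACDEFGHIKV"))
  ss <- read_sequences(p)
  expect_equal(nrow(ss), 2L)
  expect_equal(ss$residues, c("ACDEFGHIKL", "ACDEFGHIKV"))
  expect_equal(ss$paralog, c("CDK4", "CDK4"))
  expect_equal(ss$group, c("mammal", "nonmammal"))
  p2 <- tempfile(fileext = ".fasta")
  write_sequences(ss, p2)
  ss2 <- read_sequences(p2)
  expect_equal(ss, ss2)
})

test_that("malformed and invalid records are rejected with positions", {
  p <- tempfile()
  writeLines(c("not a header", "ACDE"), p)
  expect_error(read_sequences(p), "line 1")
  p3 <- tempfile()
  make_labelled_fasta(p3, "x", "ACBDE")
  expect_error(read_sequences(p3), "position 3")
  expect_error(sequence_set(c("a", "a"), c("AC", "AC")), "duplicate")
})

test_that("empty input yields an empty set with a warning", {
  p <- tempfile()
  writeLines("", p)
  expect_warning(ss <- read_sequences(p), "empty")
  expect_equal(nrow(ss), 0L)
})

test_that("clustal writing/reading preserves the alignment", {
  ss <- sequence_set(c("a", "b"), c("ACDE", "ACE"),
                     paralog = c("CDK4", "CDK6"),
                     group = c("mammal", "mammal"))
  aln <- align_progressive(ss)
  p <- tempfile(fileext = ".aln")
  write_alignment(aln, p, format = "clustal")
  aln2 <- read_alignment(p, format = "clustal")
  expect_equal(aln2$aligned, aln$aligned)
  expect_equal(aln2$seqs$paralog, c("CDK4", "CDK6"))
})

test_that("identical sequences align without gaps", {
  ss <- sequence_set(c("a", "b"), c("ACDE", "ACDE"))
  aln <- align_progressive(ss)
  expect_equal(aln$aligned, c("ACDE", "ACDE"))
})

test_that("pairwise alignment score matches a brute-force affine NW oracle", {
  S <- blosum62()
  cases <- list(c("ACDE", "ACE"), c("WKLY", "WY"), c("PRGPRP", "PRRPGP"),
                c("MKV", "MKVLL"))
  for (cs in cases) {
    ss <- sequence_set(c("a", "b"), cs)
    aln <- align_progressive(ss)
    expect_equal(aln$score, nw_affine_score(cs[1], cs[2], S),
                 info = paste(cs, collapse = " vs "))
    # degapping invariant
    expect_equal(gsub("-", "", aln$aligned), cs)
  }
})

test_that("mutation-free ortholog family aligns gap-free to its inputs", {
  fam <- generate_protein_family(n_ingroup = 5, n_outgroup = 0,
                                 n_paralog = 0, length = 60,
                                 window_start = 20, background_rate = 0,
                                 seed = 2)
  aln <- align_progressive(fam$seqs)
  expect_equal(aln$aligned, fam$seqs$residues)
})

test_that("single sequence returns a one-row alignment with a notice", {
  ss <- sequence_set("a", "ACDE")
  expect_message(aln <- align_progressive(ss), "single")
  expect_equal(aln$n_columns, 4L)
})

test_that("conservation scores match hand-derived column values", {
  ss <- sequence_set(c("a", "b", "c"), c("AAC", "AAC", "AVC"),
                     group = "g")
  aln <- multiple_alignment(ss, ss$residues)
  cp <- conservation_profile(aln, "g", window = 1)
  expect_equal(cp$raw, c(1, 1 / 3, 1))
  # all-gap column flagged and scored 0
  ss2 <- sequence_set(c("a", "b"), c("AC", "AC"), group = "g")
  aln2 <- multiple_alignment(ss2, c("A-C", "A-C"))
  cp2 <- conservation_profile(aln2, "g", window = 1)
  expect_equal(cp2$raw[2], 0)
  expect_true(cp2$all_gap[2])
  expect_error(conservation_profile(aln, "missing"), "group")
})

test_that("conservation is bounded and invariant to row order", {
  fam <- generate_protein_family(length = 80, window_start = 30, seed = 9)
  aln <- fam$alignment
  cp <- conservation_profile(aln, "mammal")
  expect_true(all(cp$score >= 0 & cp$score <= 1))
  set.seed(1)
  perm <- sample(nrow(aln$seqs))
  ss2 <- aln$seqs[perm, ]
  class(ss2) <- class(aln$seqs)
  aln2 <- multiple_alignment(ss2, aln$aligned[perm])
  cp2 <- conservation_profile(aln2, "mammal")
  expect_equal(cp2$score, cp$score)
})

test_that("scan returns nothing when all rows are identical", {
  ss <- sequence_set(sprintf("s%d", 1:6), rep("ACDEFGHIKLMNPQRS", 6),
                     paralog = c("CDK4", "CDK4", "CDK4", "CDK6", "CDK6", "CDK2"),
                     group = "mammal")
  aln <- multiple_alignment(ss, ss$residues)
  w <- scan_divergent_windows(aln, "CDK4", "mammal", window_len = 8)
  expect_equal(nrow(w), 0L)
})

test_that("scan scores equal a brute-force recomputation on short alignments", {
  fam <- generate_protein_family(n_ingroup = 4, n_outgroup = 4, n_paralog = 0,
                                 length = 20, window_start = 8,
                                 window_seq = "FPPRGP", seed = 5,
                                 background_rate = 0.08)
  aln <- fam$alignment
  mat <- do.call(rbind, strsplit(aln$aligned, ""))
  in_rows <- which(aln$seqs$paralog == "CDK4" & aln$seqs$group == "mammal")
  oracle <- brute_scan_score(mat, in_rows, 6)
  w <- scan_divergent_windows(aln, "CDK4", "mammal", window_len = 6,
                              min_score = 0.3)
  expect_gt(nrow(w), 0L)
  # the top reported run must contain the best brute-force window score
  expect_equal(max(oracle), max(w$cross_divergence_score), tolerance = 1e-9)
  expect_error(scan_divergent_windows(aln, "CDK4", "mammal",
                                      window_len = 50), "window_len")
})

test_that("implanted divergent window is recovered and mapped correctly", {
  fam <- generate_protein_family(seed = 31)
  w <- scan_divergent_windows(fam$alignment, "CDK4", "mammal")
  expect_equal(w$start_col[1], fam$truth$start)
  expect_equal(w$end_col[1], fam$truth$end)
  expect_equal(w$consensus_sequence[1], fam$truth$sequence)
  expect_equal(w$mapped_start[1], 249L)
  expect_equal(w$mapped_end[1], 260L)
})

test_that("central hexamer extraction follows the composition/tie rules", {
  expect_equal(extract_central_hexamer("FPPRGPRPVQSV"), "PRGPRP")
  expect_equal(extract_central_hexamer("AAAAAA"), "AAAAAA")
  # brute-force oracle over all windows with the stated tie rules
  s <- "PRPRPRGG"
  L <- nchar(s)
  frac <- sapply(1:(L - 5), function(i) {
    mean(strsplit(substr(s, i, i + 5), "")[[1]] %in% c("P", "R"))
  })
  centre <- (L - 6) / 2 + 1
  best <- order(-frac, abs(seq_along(frac) - centre), seq_along(frac))[1]
  expect_equal(extract_central_hexamer(s), substr(s, best, best + 5))
  expect_error(extract_central_hexamer("PRGP"), "shorter")
})
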