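# Surface-loop detection and candidate-site nomination.

test_that("an all-helix model yields no surface loops", {
  h <- generate_toy_structure("ideal_helix", length = 20)
  ss <- assign_secondary_structure(h)
  asa <- accessible_surface(h, points_per_atom = 240)
  loops <- detect_surface_loops(ss, asa)
  expect_equal(nrow(loops), 0L)
})

test_that("an embedded exposed coil is found exactly; thresholds exclude", {
  m <- generate_toy_structure("helix_with_loop", length = 24,
                              loop_span = c(10, 15), seed = 2)
  ss <- assign_secondary_structure(m)
  asa <- accessible_surface(m, points_per_atom = 240)
  loops <- detect_surface_loops(ss, asa)
  expect_equal(nrow(loops), 1L)
  expect_lte(abs(loops$start[1] - 10), 1)
  expect_gte(loops$end[1], 14)
  # same span is excluded when the exposure threshold is unattainable
  none <- detect_surface_loops(ss, asa, min_rel_asa = 1.5)
  expect_equal(nrow(none), 0L)
  # mismatched profiles are rejected
  short <- asa
  short$relative <- asa$relative[-1]
  short$residue_area <- asa$residue_area[-1]
  expect_error(detect_surface_loops(ss, short), "different residues")
})

test_that("nomination requires overlap and ranks the implanted site first", {
  loops <- data.frame(start = c(5L, 40L), end = c(12L, 52L),
                      coil_fraction = 1, mean_rel_asa = c(0.4, 0.6))
  win <- data.frame(start_col = 40L, end_col = 51L,
                    in_group_conservation = 1,
                    cross_divergence_score = 0.9,
                    consensus_sequence = "FPPRGPRPVQSV",
                    mapped_start = 40L, mapped_end = 51L,
                    stringsAsFactors = FALSE)
  sites <- nominate_sites(win, loops)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start[1], 40L)
  expect_equal(sites$end[1], 51L)
  expect_equal(sites$hexamer[1], "PRGPRP")
  expect_equal(sites$rank_score[1],
               0.9 * 0.6 * (1 + mean(strsplit("FPPRGPRPVQSV", "")[[1]] %in%
                                       c("P", "R"))))
  # no overlap -> empty
  far <- win
  far$mapped_start <- 100L
  far$mapped_end <- 111L
  expect_equal(nrow(nominate_sites(far, loops)), 0L)
  # under 50 percent overlap -> rejected
  part <- win
  part$mapped_start <- 48L
  part$mapped_end <- 59L  # only 5 of 12 columns overlap the 40-52 loop
  expect_equal(nrow(nominate_sites(part, loops)), 0L)
})

test_that("rank score is monotone in divergence and exposure", {
  loops <- data.frame(start = 10L, end = 21L, coil_fraction = 1,
                      mean_rel_asa = 0.5)
  base <- data.frame(start_col = 10L, end_col = 21L,
                     in_group_conservation = 1,
                     cross_divergence_score = 0.5,
                     consensus_sequence = "AAAAAAAAAAAA",
                     mapped_start = 10L, mapped_end = 21L,
                     stringsAsFactors = FALSE)
  s0 <- nominate_sites(base, loops)$rank_score
  hi_div <- base
  hi_div$cross_divergence_score <- 0.8
  expect_gt(nominate_sites(hi_div, loops)$rank_score, s0)
  hi_exp <- loops
  hi_exp$mean_rel_asa <- 0.9
  expect_gt(nominate_sites(base, hi_exp)$rank_score, s0)
})

test_that("nominated spans always lie inside window and loop extents", {
  set.seed(7)
  for (rep in 1:20) {
    ws <- sample(5:40, 1)
    we <- ws + sample(6:14, 1)
    ls <- sample(5:40, 1)
    le <- ls + sample(6:20, 1)
    win <- data.frame(start_col = ws, end_col = we,
                      in_group_conservation = 1,
                      cross_divergence_score = runif(1, 0.3, 1),
                      consensus_sequence = paste(rep("P", we - ws + 1),
                                                 collapse = ""),
                      mapped_start = ws, mapped_end = we,
                      stringsAsFactors = FALSE)
    loops <- data.frame(start = ls, end = le, coil_fraction = 1,
                        mean_rel_asa = runif(1, 0.3, 1))
    sites <- nominate_sites(win, loops)
    if (nrow(sites)) {
      expect_gte(sites$start[1], max(ws, ls))
      expect_lte(sites$end[1], min(we, le))
    }
  }
})
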