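# Co-expression regression, ratio-shift biomarker and the compound-response
# table analyses.

test_that("least squares matches closed-form and limiting cases", {
  x <- 1:5
  f <- fit_least_squares(x, 2 * x)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$r, 1)
  expect_lt(f$p, 1e-6)
  # independent response: slope and r near zero under a fixed seed
  set.seed(11)
  y <- rnorm(40)
  x2 <- rnorm(40)
  f2 <- fit_least_squares(x2, y)
  expect_lt(abs(f2$r), 0.35)
  # 4-point set against the standard linear-model fit as oracle
  x3 <- c(1, 2, 4, 7)
  y3 <- c(2.3, 2.9, 5.4, 8.8)
  f3 <- fit_least_squares(x3, y3)
  lmfit <- lm(y3 ~ x3)
  expect_equal(f3$slope, unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(f3$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
  expect_equal(f3$p, cor.test(x3, y3)$p.value, tolerance = 1e-10)
  expect_error(fit_least_squares(rep(1, 5), 1:5), "constant")
})

test_that("co-expression screen flags the correlated partner only", {
  hits <- 0
  clean <- 0
  for (s in 1:30) {
    panel <- generate_expression_panel(seed = s)
    sc <- coexpression_screen(panel, "CDK1")
    if ("CDK4" %in% sc$flagged) hits <- hits + 1
    if (!any(c("CDK2", "CDK6") %in% sc$flagged)) clean <- clean + 1
  }
  expect_gte(hits, 27)   # r = 0.9 partner found in >= 90 percent
  expect_gte(clean, 25)  # independent partners stay unflagged
  # single-partner panel: Bonferroni factor 1
  p1 <- generate_expression_panel(r = c(CDK4 = 0.9), seed = 1)
  sc1 <- coexpression_screen(p1, "CDK1")
  expect_equal(sc1$bonferroni_factor, 1L)
  expect_equal(names(sc1$fits), "CDK4")
})

test_that("permuting line labels holds the flag rate near nominal", {
  set.seed(21)
  false_flags <- 0
  n_tests <- 0
  for (s in 1:150) {
    panel <- generate_expression_panel(r = c(CDK4 = 0, CDK6 = 0, CDK2 = 0),
                                       seed = 4000 + s)
    sc <- coexpression_screen(panel, "CDK1")
    false_flags <- false_flags + length(sc$flagged)
    n_tests <- n_tests + 3
  }
  # Bonferroni-corrected family-wise rate: expected <= alpha per family
  expect_lte(false_flags / 150, 1.5 * 0.05)
})

test_that("expression ratio shift follows its definition", {
  expect_equal(expression_ratio_shift(c(1, 1), c(1, 1))$fold, 1)
  expect_false(expression_ratio_shift(c(1, 1), c(1, 1))$disrupted)
  r <- expression_ratio_shift(c(2, 4), c(6, 0))
  expect_equal(r$fold, Inf)
  expect_true(r$disrupted)
  expect_equal(expression_ratio_shift(c(1, 1), c(4, 1))$fold, 4)
  expect_error(expression_ratio_shift(c(-1, 1), c(1, 1)), "non-negative")
})

test_that("response tables load, normalise doses and validate codes", {
  fx <- package_fixtures()
  t2 <- load_response_table(fx$path[fx$fixture == "table2"])
  expect_equal(nrow(t2), 9L)
  expect_equal(t2$peptide[t2$compound_id == "THR1" & !is.na(t2$compound_id)],
               "PRGPRP")
  expect_equal(t2$dose_uM[2], 5000)
  expect_equal(t2$dose_uM[1], 1000)
  # dose round-trips exactly through the unit conversion
  expect_equal(t2$dose_uM / 1000 * 1000, t2$dose_uM)
  # empty table -> 0 rows
  p <- tempfile()
  writeLines(paste("peptide", "dose", "cancer_viability",
                   "fibroblast_viability", sep = "\t"), p)
  expect_equal(nrow(load_response_table(p)), 0L)
  # unitless dose rejected
  p2 <- tempfile()
  writeLines(c(paste("peptide", "dose", "cancer_viability",
                     "fibroblast_viability", sep = "\t"),
               paste("PRGPRP", "5.0", "- - -", "+ + +", sep = "\t")), p2)
  expect_error(load_response_table(p2), "unit")
  # unknown viability code rejected
  p3 <- tempfile()
  writeLines(c(paste("peptide", "dose", "cancer_viability",
                     "fibroblast_viability", sep = "\t"),
               paste("PRGPRP", "5.0 mM", "??", "+ + +", sep = "\t")), p3)
  expect_error(load_response_table(p3), "viability")
})

test_that("complete-responder counting matches the fixture and edits", {
  fx <- package_fixtures()
  t5 <- utils::read.delim(fx$path[fx$fixture == "table5"])
  expect_equal(count_complete_responders(t5, 200), 11L)
  expect_equal(count_complete_responders(t5[0, ], 200), 0L)
  t5b <- t5
  t5b$complete_response[3] <- FALSE
  expect_equal(count_complete_responders(t5b, 200), 10L)
})

test_that("minimal active concentration and fold improvements line up", {
  fx <- package_fixtures()
  t3 <- load_response_table(fx$path[fx$fixture == "table3"])
  t4 <- load_response_table(fx$path[fx$fixture == "table4"])
  mac <- minimal_active_concentration(t4,
                                      function(t) t$topology == "cyclic")
  expect_true(mac$active)
  expect_equal(mac$dose_uM, 50)
  expect_equal(mac$compound, "THR79")
  none <- minimal_active_concentration(t3)
  expect_false(none$active)
  expect_true(is.na(none$dose_uM))
  single <- t4[t4$compound_id %in% "THR53", , drop = FALSE]
  expect_equal(minimal_active_concentration(single)$dose_uM, 200)
  expect_equal(fold_improvement(5000, 50), 100)
  expect_equal(fold_improvement(5000, 100), 50)
  expect_equal(fold_improvement(70, 70), 1)
  expect_error(fold_improvement(0, 10), "positive")
})

test_that("structure-activity rules pass on the fixtures and detect edits", {
  fx <- package_fixtures()
  tabs <- do.call(rbind, lapply(fx$path[fx$fixture != "table5"],
                                load_response_table))
  rep0 <- sar_consistency(tabs)
  expect_true(all(rep0$status == "pass"))
  # recoding the transposed-arginine compound as lethal breaks that rule
  t2b <- tabs
  t2b$cancer_viability[t2b$peptide == "PRRPGP"] <- "- - -"
  repb <- sar_consistency(t2b)
  expect_equal(repb$status[repb$rule == "arginine_transposition_inactive"],
               "fail")
  # dropping the referenced compounds makes the rule non-evaluable
  t2c <- tabs[!grepl("PRRPGP", tabs$peptide), ]
  repc <- sar_consistency(t2c)
  expect_equal(repc$status[repc$rule == "arginine_transposition_inactive"],
               "not evaluable")
})
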