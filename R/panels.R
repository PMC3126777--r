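# Co-expression statistics: closed-form least squares, the anchored
# co-expression screen, and the expression ratio-shift biomarker.

#' Closed-form ordinary least squares with Pearson r and two-sided p
#'
#' Normal-equation fit of `y ~ x` (no iterative fitting), with the Pearson
#' correlation and the t-based two-sided p-value (requires n >= 3).
#'
#' @param x,y numeric vectors of equal length (n >= 2); `x` must vary.
#' @return Object of class `regression_fit`: list with `slope`,
#'   `intercept`, `r`, `p`, `n`.
#' @export
fit_least_squares <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 2L) stop("need at least 2 points")
  if (stats::sd(x) == 0) stop("x is constant; slope undefined")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  intercept <- my - slope * mx
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  p <- NA_real_
  if (n >= 3L && abs(r) < 1) {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  } else if (n >= 3L) {
    p <- 0
  }
  structure(list(slope = slope, intercept = intercept, r = r, p = p, n = n),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit: slope %.4g, intercept %.4g, r %.3f, p %.3g, n %d\n",
              x$slope, x$intercept, x$r, x$p, x$n))
  invisible(x)
}

#' Anchored co-expression screen across a panel
#'
#' Fits the anchor protein against every other protein in the panel and
#' flags partners significant at `alpha` after Bonferroni correction over
#' the number of partners tested.
#'
#' @param panel an [generate_expression_panel()]-style data.frame:
#'   `cell_line` plus one numeric column per protein.
#' @param anchor anchor protein column name.
#' @param alpha nominal significance level (default 0.05).
#' @return List with `fits` (named list of [fit_least_squares()] results),
#'   `flagged` (partner names significant after correction),
#'   `bonferroni_factor`.
#' @export
coexpression_screen <- function(panel, anchor, alpha = 0.05) {
  proteins <- setdiff(names(panel), "cell_line")
  if (!anchor %in% proteins) stop("anchor not in panel: ", anchor)
  if (sum(!is.na(panel[[anchor]])) < 3L) stop("anchor needs >= 3 lines")
  partners <- setdiff(proteins, anchor)
  k <- length(partners)
  fits <- lapply(partners, function(p) {
    fit_least_squares(panel[[anchor]], panel[[p]])
  })
  names(fits) <- partners
  pvals <- vapply(fits, `[[`, 0, "p")
  flagged <- partners[!is.na(pvals) & pvals * k < alpha]
  list(fits = fits, flagged = flagged, bonferroni_factor = k)
}

#' Expression ratio shift (anchor/target before vs after treatment)
#'
#' Computes `(cdk1/cdk4)_after / (cdk1/cdk4)_before`. A vanished target
#' after treatment gives `Inf` and is always flagged disrupted.
#'
#' @param before,after length-2 numeric vectors `c(cdk1, cdk4)`; values
#'   must be non-negative and the `before` pair strictly positive.
#' @param threshold fold-change at or above which co-expression is called
#'   disrupted (default 2).
#' @return List with `fold` and `disrupted`.
#' @export
expression_ratio_shift <- function(before, after, threshold = 2) {
  if (any(c(before, after) < 0)) stop("expression values must be non-negative")
  if (any(before == 0)) stop("baseline expression must be positive")
  fold <- if (after[2L] == 0) Inf
          else (after[1L] / after[2L]) / (before[1L] / before[2L])
  list(fold = fold, disrupted = fold >= threshold)
}
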