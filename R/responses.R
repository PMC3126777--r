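# Compound-response tables: the packaged in-study fixtures, the reader with
# dose normalisation, and the dose / structure-activity analyses.

VIABILITY_CODES <- c("- - -", "+/-", "+ +/-", "+ + +", "+ + + + +",
                     "_ _ _", "++ +", "N/D")
LETHAL_CODES <- c("- - -", "_ _ _")
PARTIAL_CODES <- c("+/-", "+ +/-")

viability_class <- function(code) {
  ifelse(code %in% LETHAL_CODES, "lethal",
         ifelse(code %in% PARTIAL_CODES, "partial",
                ifelse(code == "N/D", NA_character_, "viable")))
}

# in-code single source for the packaged response-table fixtures
response_fixture_data <- function(which) {
  t2 <- data.frame(
    compound_number = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX"),
    compound_id = c(NA, "THR1", NA, NA, NA, NA, NA, NA, NA),
    peptide = c("FPPRGPRPVQ", "PRGPRP", "PRGPR", "RGPRP", "RGPR",
                "PRRPGP", "PEGPRP", "PRGPEP", "PEGPEP"),
    topology = "linear",
    dose = c("1.0 mM", rep("5.0 mM", 8)),
    cancer_viability = c("+/-", "- - -", "- - -", "+/-", "+ + +",
                         "+ + +", "+ + +", "+ + +", "+ + +"),
    fibroblast_viability = c("+ +/-", "+ + + + +", "+ + +", "+ + +",
                             "+ + +", "+ + +", "+ + +", "+ + +", "+ + +"),
    cell_line = "RT112",
    stringsAsFactors = FALSE)
  t3 <- data.frame(
    compound_number = c("X", "XI", "XII", "XIII", "XIV", "XV"),
    compound_id = NA_character_,
    peptide = c("Cyc-[AAAGGGPRGPRPGGGAAA]", "Cyc-[GGGGGGPRGPRPGGGGGG]",
                "Cyc-[GGGGGGPRGPRPGGGGGG]", "Cyc-[AAGPGGPRGPRPGGPGAA]",
                "FPPRGPRPVKLALKLALK", "PRGPRPVALKLALKLAL"),
    topology = c(rep("cyclic", 4), "linear", "linear"),
    dose = "200 uM",
    cancer_viability = "+ + +",
    fibroblast_viability = "+ + +",
    cell_line = "H460",
    stringsAsFactors = FALSE)
  t4 <- data.frame(
    compound_number = c("XVI", "XVII", "XVIII", "XIX", "XX", "XXI", "XXII"),
    compound_id = c("THR53", "THR53C", "THR54", "THR79", NA, NA, NA),
    peptide = c("Cyc-[FPPRGPRPVKLALKLALK]", "Cyc-[FPPRRPGPVKLALKLALK]",
                "Cyc-[PRGPRPVALKLALKLAL]", "Cyc-[PRGPRPvalklalklal]",
                "Cyc-[PR(Me)GPRPVALKLALKLAL]", "Cyc-[PRGPR(Me)PVALKLALKLAL]",
                "Cyc-[PR(Me)GPR(Me)PVALKLALKLAL]"),
    topology = "cyclic",
    dose = c("200 uM", "200 uM", "100 uM", "50 uM", "200 uM", "200 uM",
             "200 uM"),
    cancer_viability = c("_ _ _", "+ + +", "_ _ _", "_ _ _", "+ +/-",
                         "++ +", "+ + +"),
    fibroblast_viability = c("+ + +", "+ + +", "+ + +", "+ + +", "N/D",
                             "N/D", "N/D"),
    cell_line = "H460",
    stringsAsFactors = FALSE)
  t5 <- data.frame(
    cell_line = c("MGHU-1", "H460", "SW620", "G361", "MCF7", "H1299",
                  "SK-BR-3", "A375", "U2OS", "SW480", "RT112"),
    histology = c("Carcinoma Bladder", "Non-Small Cell Lung Carcinoma",
                  "Adenocarcinoma Colon", "Melanoma",
                  "Adenocarcinoma Breast", "Non-Small Cell Lung Carcinoma",
                  "Adenocarcinoma Breast", "Melanoma", "Osteosarcoma",
                  "Adenocarcinoma Colon", "Carcinoma Bladder"),
    dose = "200 uM",
    complete_response = TRUE,
    stringsAsFactors = FALSE)
  switch(which, table2 = t2, table3 = t3, table4 = t4, table5 = t5,
         stop("unknown fixture: ", which))
}

#' Write the packaged tabular fixtures to a directory
#'
#' Writes the four compound-response/cell-line fixtures as TSV files and
#' returns their paths with MD5 checksums.
#'
#' @param dir output directory (created if needed).
#' @return data.frame with columns `fixture`, `path`, `md5`.
#' @export
package_fixtures <- function(dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names <- c("table2", "table3", "table4", "table5")
  paths <- file.path(dir, paste0(names, ".tsv"))
  for (k in seq_along(names)) {
    utils::write.table(response_fixture_data(names[k]), paths[k],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  data.frame(fixture = names, path = paths,
             md5 = tools::md5sum(paths), row.names = NULL,
             stringsAsFactors = FALSE)
}

parse_dose <- function(dose) {
  m <- regmatches(dose, regexec("^\\s*([0-9.]+)\\s*(mM|uM|µM|nM)\\s*$", dose))
  vapply(seq_along(dose), function(i) {
    p <- m[[i]]
    if (length(p) < 3L || p[2L] == "") {
      stop("dose '", dose[i], "' lacks a recognised unit (uM/mM/nM)")
    }
    v <- as.numeric(p[2L])
    switch(p[3L], mM = v * 1000, uM = v, "µM" = v, nM = v / 1000)
  }, 0)
}

#' Load a compound-response table
#'
#' Reads a tab-delimited response table, normalises doses to micromolar
#' (`dose_uM`), and validates the viability codes against the fixed symbol
#' set. Doses must carry a unit.
#'
#' @param path TSV file with a header; columns `peptide`, `dose`,
#'   `cancer_viability`, `fibroblast_viability` are required.
#' @return The table (class `response_table`) with `dose_uM` plus
#'   `cancer_class` / `fibroblast_class` ordinal classes.
#' @export
load_response_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  if (nrow(tab) == 0L) {
    class(tab) <- c("response_table", "data.frame")
    return(tab)
  }
  need <- c("peptide", "dose", "cancer_viability", "fibroblast_viability")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (col in c("cancer_viability", "fibroblast_viability")) {
    bad <- which(!tab[[col]] %in% VIABILITY_CODES)
    if (length(bad)) {
      stop(sprintf("unknown viability code '%s' in %s (row %d)",
                   tab[[col]][bad[1L]], col, bad[1L]))
    }
  }
  tab$dose_uM <- parse_dose(tab$dose)
  if (any(tab$dose_uM <= 0)) stop("doses must be positive")
  tab$cancer_class <- viability_class(tab$cancer_viability)
  tab$fibroblast_class <- viability_class(tab$fibroblast_viability)
  class(tab) <- c("response_table", "data.frame")
  tab
}

#' Count cell lines with a complete response at a given dose
#'
#' @param lines a cell-line response table (e.g. the packaged `table5`
#'   fixture) with columns `dose` (or `dose_uM`) and `complete_response`.
#' @param dose dose in micromolar.
#' @return Integer count.
#' @export
count_complete_responders <- function(lines, dose = 200) {
  if (nrow(lines) == 0L) return(0L)
  duM <- if ("dose_uM" %in% names(lines)) lines$dose_uM else parse_dose(lines$dose)
  sum(duM == dose & lines$complete_response)
}

#' Minimal fully lethal dose in a response table
#'
#' The smallest dose among rows whose cancer-cell viability code is fully
#' lethal, after applying an optional row filter.
#'
#' @param table a [load_response_table()] result.
#' @param filter optional predicate taking the table and returning a logical
#'   row mask (e.g. `function(t) t$topology == "cyclic"`).
#' @return List with `dose_uM` (NA when nothing is lethal), `active`
#'   (logical), and `compound` (row label of the minimal lethal dose).
#' @export
minimal_active_concentration <- function(table, filter = NULL) {
  rows <- if (is.null(filter)) rep(TRUE, nrow(table)) else filter(table)
  t2 <- table[rows, , drop = FALSE]
  if (nrow(t2) == 0L) stop("no rows pass the compound filter")
  lethal <- t2$cancer_viability %in% LETHAL_CODES
  if (!any(lethal)) {
    return(list(dose_uM = NA_real_, active = FALSE, compound = NA_character_))
  }
  t3 <- t2[lethal, , drop = FALSE]
  k <- which.min(t3$dose_uM)
  lab <- if (!is.null(t3$compound_id) && !is.na(t3$compound_id[k])) {
    t3$compound_id[k]
  } else t3$compound_number[k]
  list(dose_uM = t3$dose_uM[k], active = TRUE, compound = lab)
}

#' Fold improvement between two active doses
#'
#' @param dose_reference,dose_new doses in the same unit (micromolar).
#' @return `dose_reference / dose_new`.
#' @export
fold_improvement <- function(dose_reference, dose_new) {
  if (dose_reference <= 0 || dose_new <= 0) stop("doses must be positive")
  dose_reference / dose_new
}

#' Structure-activity consistency rules over the response tables
#'
#' Evaluates the coded structure-activity relationships: at least one
#' motif-bearing (PRGPRP) compound is fully lethal to cancer cells while
#' sparing fibroblasts; every arginine-transposed (PRRPGP) compound is
#' non-lethal; every glutamate-substituted variant is non-lethal; every
#' N-methyl-arginine variant is non-lethal. A rule whose referenced
#' compounds are absent is reported `not evaluable`.
#'
#' @param table a response table (typically `rbind` of the packaged
#'   fixtures).
#' @return data.frame with columns `rule`, `status`
#'   (`"pass"`/`"fail"`/`"not evaluable"`), `n_rows`.
#' @export
sar_consistency <- function(table) {
  lethal <- table$cancer_viability %in% LETHAL_CODES
  fibro_ok <- !table$fibroblast_viability %in% LETHAL_CODES
  eval_rule <- function(mask, want_all_inactive) {
    if (!any(mask)) return(c("not evaluable", 0L))
    ok <- if (want_all_inactive) all(!lethal[mask])
          else any(lethal[mask] & fibro_ok[mask])
    c(if (ok) "pass" else "fail", sum(mask))
  }
  has <- function(pat) grepl(pat, table$peptide, fixed = TRUE)
  rules <- list(
    motif_active = eval_rule(has("PRGPRP"), FALSE),
    arginine_transposition_inactive = eval_rule(has("PRRPGP"), TRUE),
    glutamate_substitution_inactive =
      eval_rule(has("PEGPRP") | has("PRGPEP") | has("PEGPEP"), TRUE),
    n_methyl_arginine_inactive = eval_rule(has("R(Me)"), TRUE))
  data.frame(rule = names(rules),
             status = vapply(rules, `[`, "", 1L),
             n_rows = as.integer(vapply(rules, `[`, "", 2L)),
             row.names = NULL, stringsAsFactors = FALSE)
}
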