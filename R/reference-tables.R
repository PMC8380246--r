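#' Published demographic comparison table (CAN-BIND-1 escitalopram cohort)
#'
#' Group-by-characteristic counts and summaries for the N = 153 trajectory
#' cohort (nonresponders N = 69, later responders N = 49, early responders
#' N = 35), as published: the categorical rows carry yes/no counts per
#' response group plus the published chi-square p-value; age is carried as
#' per-group (n, mean, sd) triples.  These printed values are inputs for
#' re-deriving the table's test statistics with [chi2_independence()] and
#' [anova_oneway()].
#'
#' @return A list: `categorical` (tibble: `characteristic`, `yes_nr`,
#'   `yes_lr`, `yes_er`, `no_nr`, `no_lr`, `no_er`, `published_p`), `age`
#'   (tibble: `group`, `n`, `mean`, `sd`, plus attribute `published_p`),
#'   `group_n` (named vector).
#' @export
cohort_demographics <- function() {
  categorical <- tibble::tribble(
    ~characteristic,   ~yes_nr, ~yes_lr, ~yes_er, ~published_p,
    "female_sex",           41,      29,      26,        0.274,
    "anxiety_history",      30,      28,      18,        0.334,
    "gad",                  19,       8,       8,        0.360,
    "social_phobia",        10,      19,       5,        0.003,
    "suicidality",          47,      41,      27,        0.149)
  n <- c(nr = 69L, lr = 49L, er = 35L)
  categorical$no_nr <- n[["nr"]] - categorical$yes_nr
  categorical$no_lr <- n[["lr"]] - categorical$yes_lr
  categorical$no_er <- n[["er"]] - categorical$yes_er
  age <- tibble::tibble(group = c("nr", "lr", "er"),
                        n = c(69L, 49L, 35L),
                        mean = c(36.12, 36.55, 34.57),
                        sd = c(13.05, 11.90, 12.39))
  attr(age, "published_p") <- 0.762
  list(categorical = categorical, age = age, group_n = n)
}

#' Contingency table for one demographic characteristic
#'
#' @param characteristic Row name from
#'   `cohort_demographics()$categorical$characteristic`.
#' @return A 2 x 3 integer matrix (yes/no by NR, LR, ER).
#' @export
#' @examples
#' chi2_independence(demographic_table("social_phobia"))
demographic_table <- function(characteristic) {
  cat_tab <- cohort_demographics()$categorical
  row <- cat_tab[cat_tab$characteristic == characteristic, ]
  if (nrow(row) != 1L) {
    stop("unknown characteristic: ", characteristic, call. = FALSE)
  }
  matrix(c(row$yes_nr, row$no_nr, row$yes_lr, row$no_lr, row$yes_er, row$no_er),
         2L, 3L, dimnames = list(c("yes", "no"), c("nr", "lr", "er")))
}

#' Published slope-response association table (CAN-BIND-1 escitalopram cohort)
#'
#' The published multivariable slope-association estimates for the eight RNAs
#' that advanced past the per-RNA screen: per RNA and contrast, the log risk
#' ratio, its standard error, the Wald p-value, the published FDR and the
#' published RR with 95% CI (all as printed, 3 decimals).  Used as input for
#' internal-consistency checks: [wald_rr()] on `log_rr` and `se` reproduces
#' `rr`/`ci`/`p`, and [bh_adjust()] at family size 24 reproduces the FDR
#' column up to the rounding of the printed p-values.
#'
#' @return A tibble with 24 rows: `rna`, `contrast`, `log_rr`, `se`, `p`,
#'   `fdr`, `rr`, `ci_low`, `ci_high`.
#' @export
published_associations <- function() {
  tibble::tribble(
    ~rna,       ~contrast,                     ~log_rr,  ~se,    ~p,     ~fdr,   ~rr,   ~ci_low, ~ci_high,
    "BET1",     "responders_vs_nonresponders",  0.776,   0.471,  0.100,  0.159,  2.17,  0.86,    5.47,
    "CERCAM",   "responders_vs_nonresponders",  1.064,   0.323,  0.001,  0.023,  2.90,  1.54,    5.46,
    "DARS-AS1", "responders_vs_nonresponders", -0.817,   0.387,  0.035,  0.076,  0.44,  0.21,    0.94,
    "FAM228B",  "responders_vs_nonresponders",  1.079,   0.430,  0.012,  0.041,  2.94,  1.27,    6.83,
    "HBEGF",    "responders_vs_nonresponders",  0.748,   0.340,  0.028,  0.066,  2.11,  1.09,    4.11,
    "MCM8",     "responders_vs_nonresponders",  0.563,   0.303,  0.063,  0.116,  1.76,  0.97,    3.18,
    "NME7",     "responders_vs_nonresponders",  0.259,   0.302,  0.392,  0.450,  1.30,  0.72,    2.34,
    "TERF1",    "responders_vs_nonresponders",  0.095,   0.382,  0.803,  0.803,  1.10,  0.52,    2.32,
    "BET1",     "early_vs_nonresponders",       0.659,   0.368,  0.073,  0.125,  1.93,  0.94,    3.97,
    "CERCAM",   "early_vs_nonresponders",       0.794,   0.260,  0.002,  0.023,  2.21,  1.33,    3.68,
    "DARS-AS1", "early_vs_nonresponders",      -0.879,   0.309,  0.004,  0.023,  0.42,  0.23,    0.76,
    "FAM228B",  "early_vs_nonresponders",       0.814,   0.340,  0.017,  0.050,  2.26,  1.16,    4.40,
    "HBEGF",    "early_vs_nonresponders",       0.799,   0.282,  0.005,  0.023,  2.22,  1.28,    3.87,
    "MCM8",     "early_vs_nonresponders",       0.333,   0.244,  0.173,  0.244,  1.40,  0.86,    2.25,
    "NME7",     "early_vs_nonresponders",       0.297,   0.240,  0.217,  0.289,  1.35,  0.84,    2.15,
    "TERF1",    "early_vs_nonresponders",       0.211,   0.296,  0.476,  0.497,  1.24,  0.69,    2.21,
    "BET1",     "later_vs_nonresponders",       0.632,   0.396,  0.110,  0.165,  1.88,  0.87,    4.09,
    "CERCAM",   "later_vs_nonresponders",       0.647,   0.287,  0.024,  0.065,  1.91,  1.09,    3.35,
    "DARS-AS1", "later_vs_nonresponders",      -0.920,   0.342,  0.007,  0.028,  0.40,  0.20,    0.78,
    "FAM228B",  "later_vs_nonresponders",       0.695,   0.371,  0.061,  0.116,  2.00,  0.97,    4.15,
    "HBEGF",    "later_vs_nonresponders",       0.888,   0.315,  0.005,  0.023,  2.43,  1.31,    4.51,
    "MCM8",     "later_vs_nonresponders",       0.228,   0.267,  0.394,  0.450,  1.26,  0.74,    2.12,
    "NME7",     "later_vs_nonresponders",       0.296,   0.266,  0.265,  0.335,  1.34,  0.80,    2.26,
    "TERF1",    "later_vs_nonresponders",       0.244,   0.328,  0.456,  0.497,  1.28,  0.67,    2.43)
}
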