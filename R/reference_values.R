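#' Published reference summaries for immunocastrated lambs
#'
#' Group summary statistics (mean ± SD for parametric variables, median
#' ± interquartile range for non-parametric ones) from a published
#' anti-GnRH immunocastration trial in crossbred Santa Inês lambs:
#' three groups of ten animals (saline control, 1.0 mL vaccine, 0.5 mL
#' vaccine) slaughtered 90 days after the first dose. These summaries
#' calibrate the synthetic-cohort generator ([default_generator_params()])
#' and drive the worked examples ([worked_examples()]); the package does
#' not have access to the underlying per-animal data.
#'
#' @return A data.frame with columns `table` (1–6), `variable`, `group`,
#'   `location` (mean or median), `dispersion` (SD or IQR) and `branch`
#'   (`"parametric"` or `"nonparametric"`, the branch reported for that
#'   variable).
#' @export
published_summaries <- function() {
  groups <- c("control", "vaccine_1.0mL", "vaccine_0.5mL")
  row <- function(table, variable, branch, loc, disp) {
    data.frame(
      table = table, variable = variable, group = groups,
      location = loc, dispersion = disp, branch = branch,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    # Testis weight and morphometry
    row(1L, "TW",         "parametric",    c(109.78, 22.18, 20.15),    c(36.99, 11.30, 6.71)),
    row(1L, "GSI",        "parametric",    c(0.66, 0.13, 0.13),        c(0.17, 0.48, 0.03)),
    row(1L, "STD",        "parametric",    c(204.60, 91.59, 87.94),    c(14.75, 24.57, 19.19)),
    row(1L, "GEH",        "parametric",    c(46.71, 11.21, 10.13),     c(4.15, 2.22, 2.11)),
    row(1L, "LSI",        "nonparametric", c(0.0036, 0.0013, 0.0014),  c(0.0046, 0.0013, 0.0008)),
    row(1L, "TSI",        "parametric",    c(0.28, 0.26, 0.31),        c(0.58, 0.45, 0.78)),
    row(1L, "TLST",       "parametric",    c(3835.7, 15042.2, 14796.4), c(3122.3, 8633.8, 5925.2)),
    row(1L, "TLST_per_g", "nonparametric", c(11.06, 264.92, 335.49),   c(9.85, 662.84, 431.63)),
    # Volumetric proportions of the parenchyma
    row(2L, "lumen",                  "parametric",    c(32.77, 38.34, 42.35), c(9.57, 11.05, 16.19)),
    row(2L, "germinative_epithelium", "nonparametric", c(54.77, 40.87, 47.42), c(12.43, 22.85, 19.11)),
    row(2L, "tunica_propria",         "parametric",    c(4.64, 6.42, 5.26),    c(1.53, 1.14, 0.43)),
    row(2L, "leydig",                 "nonparametric", c(1.96, 3.43, 2.69),    c(1.22, 1.96, 0.73)),
    row(2L, "blood_vessels",          "parametric",    c(0.77, 0.93, 0.94),    c(0.39, 0.16, 0.19)),
    row(2L, "connective_tissue",      "parametric",    c(7.03, 12.31, 10.38),  c(2.89, 3.92, 5.11)),
    # Corrected stage-1 cell populations
    row(3L, "A",  "parametric", c(0.95, 2.29, 2.54),   c(0.12, 0.20, 0.53)),
    row(3L, "PL", "parametric", c(11.46, 1.34, 1.14),  c(3.03, 1.23, 1.24)),
    row(3L, "PQ", "parametric", c(15.44, 0.00, 0.00),  c(3.12, 0.00, 0.00)),
    row(3L, "Ar", "parametric", c(50.29, 0.02, 0.00),  c(5.82, 0.06, 0.00)),
    row(3L, "S",  "parametric", c(5.27, 10.67, 13.25), c(0.79, 1.73, 2.64)),
    # Intrinsic spermatogenic yield
    row(4L, "A_PL",  "parametric",    c(12.37, 0.59, 0.51), c(3.92, 0.54, 0.55)),
    row(4L, "PL_PQ", "parametric",    c(1.37, 0.00, 0.00),  c(0.25, 0.00, 0.00)),
    row(4L, "PQ_Ar", "nonparametric", c(3.16, 0.00, 0.00),  c(0.33, 0.00, 0.00)),
    row(4L, "A_Ar",  "parametric",    c(53.79, 0.01, 0.00), c(9.91, 0.03, 0.00)),
    # Sertoli cell indices
    row(5L, "S_A",  "parametric", c(0.18, 0.21, 0.19),  c(0.03, 0.03, 0.04)),
    row(5L, "S_PL", "parametric", c(2.27, 0.13, 0.09),  c(0.93, 0.14, 0.10)),
    row(5L, "S_PQ", "parametric", c(3.05, 0.00, 0.00),  c(1.00, 0.00, 0.00)),
    row(5L, "S_Ar", "parametric", c(9.84, 0.00, 0.00),  c(2.49, 0.00, 0.00)),
    row(5L, "S_CG", "parametric", c(15.36, 0.36, 0.29), c(4.40, 0.16, 0.10)),
    # Production estimates (absolute counts; per-gram in counts/g)
    row(6L, "NSCT",       "parametric",    c(7.05e9, 55.23e9, 66.72e9), c(6.47e9, 33.80e9, 30.18e9)),
    row(6L, "NSCT_per_g", "nonparametric", c(0.03e9, 1.94e9, 4.04e9),   c(0.049e9, 6.15e9, 7.61e9)),
    row(6L, "DSP",        "nonparametric", c(4.52e9, 0, 0),             c(0.97e9, 0, 0)),
    row(6L, "DSP_per_g",  "nonparametric", c(35.88e6, 0, 0),            c(8.99e6, 0, 0)),
    row(6L, "TSR",        "nonparametric", c(47.53e9, 0, 0),            c(10.25e9, 0, 0)),
    row(6L, "TSR_per_g",  "nonparametric", c(376.75e6, 0, 0),           c(250.19e6, 0, 0))
  )
}

ref_value <- function(summaries, variable, group) {
  v <- summaries$location[summaries$variable == variable &
                            summaries$group == group]
  if (length(v) != 1L) stop("no unique reference value for ", variable)
  v
}

ref_dispersion <- function(summaries, variable, group) {
  v <- summaries$dispersion[summaries$variable == variable &
                              summaries$group == group]
  if (length(v) != 1L) stop("no unique reference dispersion for ", variable)
  v
}

#' Worked examples: derived effect percentages from published summaries
#'
#' Recomputes, from the published group summaries alone, the headline
#' effect sizes of the immunocastration trial: STD and GSI percent
#' reductions under each vaccine dose, mean GEH reduction, the minimum
#' reduction across the regressing morphometric variables, the general
#' spermatogenic yield as a percentage of the theoretical 256-fold
#' expansion, and the meiotic loss percentage.
#'
#' @param config A [stereology_config()] supplying the theoretical
#'   yield constants.
#' @return Named numeric vector of percentages.
#' @examples
#' round(worked_examples()[c("std_reduction_1.0mL", "gsi_reduction")], 2)
#' @export
worked_examples <- function(config = stereology_config()) {
  s <- published_summaries()
  ctrl <- function(v) ref_value(s, v, "control")
  v10 <- function(v) ref_value(s, v, "vaccine_1.0mL")
  v05 <- function(v) ref_value(s, v, "vaccine_0.5mL")

  regressing <- c("TW", "GSI", "STD", "GEH", "LSI")
  red10 <- vapply(regressing, function(v) percent_reduction(ctrl(v), v10(v)),
                  numeric(1))
  red05 <- vapply(regressing, function(v) percent_reduction(ctrl(v), v05(v)),
                  numeric(1))

  c(
    "std_reduction_1.0mL" = percent_reduction(ctrl("STD"), v10("STD")),
    "std_reduction_0.5mL" = percent_reduction(ctrl("STD"), v05("STD")),
    "gsi_reduction" = percent_reduction(ctrl("GSI"), v10("GSI")),
    "geh_mean_reduction" = mean(c(
      percent_reduction(ctrl("GEH"), v10("GEH")),
      percent_reduction(ctrl("GEH"), v05("GEH"))
    )),
    "min_reduction_both_doses" = min(red10, red05),
    "general_yield_pct" = general_yield_percent(ctrl("A_Ar"), config),
    "meiotic_loss_pct" = meiotic_loss_percent(ctrl("PQ_Ar"), config)
  )
}

#' Calibration targets for the synthetic-cohort generator
#'
#' The published group means the generator is calibrated to reproduce
#' through the analysis pipeline: seminiferous tubule diameter,
#' germinative epithelium height, and the five corrected stage-1 cell
#' populations, per group. The `sd` column is the published
#' between-animal dispersion (used to size Monte-Carlo standard
#' errors).
#'
#' @return Data.frame with columns `variable`, `group`, `target`, `sd`.
#' @export
calibration_targets <- function() {
  s <- published_summaries()
  keep <- s$variable %in% c("STD", "GEH", CELL_CLASSES) & s$table %in% c(1L, 3L)
  out <- s[keep, c("variable", "group", "location", "dispersion")]
  names(out) <- c("variable", "group", "target", "sd")
  rownames(out) <- NULL
  out
}
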