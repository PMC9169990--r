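# Ratio convention for cell-class quotients: 0/0 is a structural zero
# (the printed convention for fully regressed tubules), x/0 with x > 0
# is undefined and excluded from group summaries.
safe_ratio <- function(numerator, denominator, label = "ratio") {
  if (any(numerator < 0, na.rm = TRUE) || any(denominator < 0, na.rm = TRUE)) {
    stop("cell populations must be non-negative")
  }
  out <- numerator / denominator
  zero_zero <- denominator == 0 & numerator == 0
  out[zero_zero] <- 0
  undef <- denominator == 0 & numerator > 0
  if (any(undef, na.rm = TRUE)) {
    warning(sprintf(
      "%s undefined (zero denominator with positive numerator) for %d value(s); set to NA",
      label, sum(undef, na.rm = TRUE)
    ))
    out[undef] <- NA_real_
  }
  out
}

# Look up per-class nuclear diameters (nucleolar for S) and the section
# thickness from a nuclear_geometry table (cell_class, mean_diameter_um,
# section_thickness_um).
geometry_lookup <- function(geometry) {
  required <- c("cell_class", "mean_diameter_um", "section_thickness_um")
  if (!is.data.frame(geometry) || !all(required %in% names(geometry))) {
    stop("`geometry` must have columns ", paste(required, collapse = ", "))
  }
  missing <- setdiff(CELL_CLASSES, geometry$cell_class)
  if (length(missing)) {
    stop("`geometry` lacks cell class(es): ", paste(missing, collapse = ", "))
  }
  idx <- match(CELL_CLASSES, geometry$cell_class)
  thickness <- unique(geometry$section_thickness_um)
  if (length(thickness) != 1L || thickness <= 0) {
    stop("`geometry` must carry a single positive section thickness")
  }
  list(
    diameters = stats::setNames(geometry$mean_diameter_um[idx], CELL_CLASSES),
    thickness = thickness
  )
}

#' Abercrombie-corrected cell populations per cross-section
#'
#' Per cell class, the mean raw stage-1 count over the evaluated tubule
#' cross-sections is corrected for section geometry with
#' [abercrombie_correct()], using the class's mean nuclear diameter
#' (nucleolar diameter for Sertoli cells) and the section thickness.
#'
#' @param counts A data.frame with one row per evaluated stage-1 tubule
#'   cross-section and non-negative integer columns `A`, `PL`, `PQ`,
#'   `Ar`, `S` (see [CELL_CLASSES]).
#' @param geometry A nuclear-geometry data.frame with columns
#'   `cell_class`, `mean_diameter_um`, `section_thickness_um`.
#' @return Named numeric vector of corrected mean counts per
#'   cross-section, one per cell class.
#' @export
corrected_populations <- function(counts, geometry) {
  if (!is.data.frame(counts) || !all(CELL_CLASSES %in% names(counts))) {
    stop("`counts` must have columns ", paste(CELL_CLASSES, collapse = ", "))
  }
  if (nrow(counts) == 0L) stop("at least one tubule cross-section is required")
  geo <- geometry_lookup(geometry)
  raw_means <- vapply(CELL_CLASSES, function(cl) {
    x <- counts[[cl]]
    if (any(x < 0) || any(x != round(x))) {
      stop("raw counts must be non-negative integers (class ", cl, ")")
    }
    mean(x)
  }, numeric(1))
  abercrombie_correct(raw_means, geo$thickness, geo$diameters)
}

#' Intrinsic spermatogenic yield ratios
#'
#' Cell-class quotients along spermatogenesis: A:PL (= PL/A, the
#' spermatogonial mitosis coefficient), PL:PQ (meiotic prophase),
#' PQ:Ar (meiotic yield) and A:Ar (general yield). When a denominator
#' and numerator are both 0 the ratio is a structural 0 (the fully
#' regressed-tubule convention); a positive numerator over a zero
#' denominator is undefined (`NA`) and excluded from group summaries.
#'
#' @param populations Named numeric vector of corrected populations as
#'   returned by [corrected_populations()].
#' @return Named numeric vector `c(A_PL, PL_PQ, PQ_Ar, A_Ar)`.
#' @export
intrinsic_yields <- function(populations) {
  p <- check_populations(populations)
  c(
    A_PL  = safe_ratio(p[["PL"]], p[["A"]], "A:PL"),
    PL_PQ = safe_ratio(p[["PQ"]], p[["PL"]], "PL:PQ"),
    PQ_Ar = safe_ratio(p[["Ar"]], p[["PQ"]], "PQ:Ar"),
    A_Ar  = safe_ratio(p[["Ar"]], p[["A"]], "A:Ar")
  )
}

#' Sertoli cell indices
#'
#' Germ cells supported per Sertoli cell: S:X = X/S for each germ cell
#' class X, and S:CG = (A + PL + PQ + Ar)/S for all germ cells. By
#' construction S:CG is the sum of the four class indices.
#'
#' @inheritParams intrinsic_yields
#' @return Named numeric vector `c(S_A, S_PL, S_PQ, S_Ar, S_CG)`.
#' @export
sertoli_indices <- function(populations) {
  p <- check_populations(populations)
  s <- p[["S"]]
  c(
    S_A  = safe_ratio(p[["A"]], s, "S:A"),
    S_PL = safe_ratio(p[["PL"]], s, "S:PL"),
    S_PQ = safe_ratio(p[["PQ"]], s, "S:PQ"),
    S_Ar = safe_ratio(p[["Ar"]], s, "S:Ar"),
    S_CG = safe_ratio(p[["A"]] + p[["PL"]] + p[["PQ"]] + p[["Ar"]], s, "S:CG")
  )
}

check_populations <- function(populations) {
  if (!all(CELL_CLASSES %in% names(populations))) {
    stop("`populations` must be named with ",
         paste(CELL_CLASSES, collapse = ", "))
  }
  p <- populations[CELL_CLASSES]
  if (any(p < 0, na.rm = TRUE)) stop("populations must be non-negative")
  p
}

#' General yield of spermatogenesis as a percentage of theory
#'
#' Expresses the observed general yield (round spermatids per type-A
#' spermatogonium, A:Ar) as a percentage of the theoretical expansion
#' (256 for domestic mammals).
#'
#' @param A_to_Ar Observed A:Ar ratio.
#' @param config A [stereology_config()].
#' @return Percentage of the theoretical yield realized.
#' @examples
#' general_yield_percent(53.79)  # ~21.01
#' @export
general_yield_percent <- function(A_to_Ar, config = stereology_config()) {
  if (any(A_to_Ar < 0)) stop("`A_to_Ar` must be >= 0")
  100 * A_to_Ar / config$theoretical_Ar_per_A
}

#' Meiotic loss percentage
#'
#' Cell loss across the meiotic divisions, relative to the theoretical
#' four round spermatids per pachytene spermatocyte; clamped at 0 when
#' the observed yield exceeds theory.
#'
#' @param PQ_to_Ar Observed PQ:Ar ratio.
#' @param config A [stereology_config()].
#' @return Loss in percent, >= 0.
#' @examples
#' meiotic_loss_percent(3.16)  # 21
#' @export
meiotic_loss_percent <- function(PQ_to_Ar, config = stereology_config()) {
  if (any(PQ_to_Ar < 0)) stop("`PQ_to_Ar` must be >= 0")
  k <- config$theoretical_Ar_per_PQ
  pmax(0, 100 * (k - PQ_to_Ar) / k)
}

#' Whole-testis population from a per-section corrected count
#'
#' Scales a corrected per-cross-section count to the whole organ by the
#' number of sections the seminiferous tubules would span: total tubule
#' length divided by section thickness. Used with the Sertoli class for
#' the total Sertoli cell number (NSCT) and with round spermatids for
#' the testicular sperm reserve (TSR).
#'
#' @param corrected_per_section Corrected mean count per tubule
#'   cross-section.
#' @param tlst_m Total seminiferous tubule length in metres.
#' @param section_thickness_um Section thickness in µm.
#' @return Estimated whole-testis cell number.
#' @examples
#' total_population(1, 3, 3)  # 3 m / 3 µm = 1e6
#' @export
total_population <- function(corrected_per_section, tlst_m,
                             section_thickness_um) {
  if (any(section_thickness_um <= 0)) {
    stop("`section_thickness_um` must be > 0")
  }
  if (any(corrected_per_section < 0, na.rm = TRUE) || any(tlst_m < 0)) {
    stop("counts and lengths must be non-negative")
  }
  corrected_per_section * (tlst_m * 1e6 / section_thickness_um)
}

#' Daily sperm production from the testicular sperm reserve
#'
#' Divides the stage-1 testicular sperm reserve by the time (in days)
#' that one reserve turnover represents.
#'
#' @param tsr Testicular sperm reserve (cells).
#' @param config A [stereology_config()]; `sec_duration_days` is the
#'   divisor.
#' @return Daily sperm production (cells/day).
#' @export
daily_sperm_production <- function(tsr, config = stereology_config()) {
  if (any(tsr < 0, na.rm = TRUE)) stop("`tsr` must be >= 0")
  tsr / config$sec_duration_days
}
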