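#' Abercrombie section-geometry correction
#'
#' Profile counts in a histological section overestimate the true number
#' of particles per section volume, because any particle whose centre
#' lies within one radius of either slab face still leaves a visible
#' profile. For spherical particles of mean diameter `D` cut by sections
#' of thickness `T`, the expected overcount factor is `(T + D) / T`, so
#' the corrected count is the raw count times `T / (T + D)`.
#'
#' `abercrombie_factor()` returns the multiplicative factor
#' `T / (T + D)`, `abercrombie_correct()` applies it, and
#' `inverse_abercrombie()` undoes it (used to back-solve raw count means
#' from published corrected means).
#'
#' @param raw_count Raw profile count(s), >= 0.
#' @param corrected_count Corrected count(s), >= 0.
#' @param section_thickness Section thickness in µm, > 0.
#' @param nuclear_diameter Mean nuclear (or nucleolar, for Sertoli
#'   cells) diameter in µm, >= 0.
#' @return Numeric vector: the correction factor in `(0, 1]`, the
#'   corrected count, or the raw count.
#' @examples
#' abercrombie_correct(10, section_thickness = 3, nuclear_diameter = 7)  # 3
#' inverse_abercrombie(3, section_thickness = 3, nuclear_diameter = 7)   # 10
#' @export
abercrombie_factor <- function(section_thickness, nuclear_diameter) {
  if (any(!is.finite(section_thickness)) || any(section_thickness <= 0)) {
    stop("`section_thickness` must be positive and finite")
  }
  if (any(!is.finite(nuclear_diameter)) || any(nuclear_diameter < 0)) {
    stop("`nuclear_diameter` must be non-negative and finite")
  }
  section_thickness / (section_thickness + nuclear_diameter)
}

#' @rdname abercrombie_factor
#' @export
abercrombie_correct <- function(raw_count, section_thickness,
                                nuclear_diameter) {
  if (any(raw_count < 0, na.rm = TRUE)) stop("`raw_count` must be >= 0")
  raw_count * abercrombie_factor(section_thickness, nuclear_diameter)
}

#' @rdname abercrombie_factor
#' @export
inverse_abercrombie <- function(corrected_count, section_thickness,
                                nuclear_diameter) {
  if (any(corrected_count < 0, na.rm = TRUE)) {
    stop("`corrected_count` must be >= 0")
  }
  corrected_count / abercrombie_factor(section_thickness, nuclear_diameter)
}
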