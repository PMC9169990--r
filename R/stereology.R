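#' Summarize seminiferous tubule profiles
#'
#' Mean seminiferous tubule diameter (STD) and germinative epithelium
#' height (GEH) over the measured circular cross-sections of one animal.
#'
#' @param profiles A data.frame with numeric columns `diameter_um` and
#'   `epithelium_height_um`, one row per measured tubule profile.
#' @return Named numeric vector `c(STD = ..., GEH = ...)` in µm.
#' @examples
#' p <- data.frame(diameter_um = c(100, 300), epithelium_height_um = c(20, 40))
#' summarize_tubule_profiles(p)  # STD 200, GEH 30
#' @export
summarize_tubule_profiles <- function(profiles) {
  required <- c("diameter_um", "epithelium_height_um")
  if (!is.data.frame(profiles) || !all(required %in% names(profiles))) {
    stop("`profiles` must have columns diameter_um and epithelium_height_um")
  }
  if (nrow(profiles) == 0L) stop("at least one tubule profile is required")
  d <- profiles$diameter_um
  h <- profiles$epithelium_height_um
  if (any(!is.finite(d)) || any(!is.finite(h))) {
    stop("tubule profile measurements must be finite")
  }
  if (any(d <= 0) || any(h <= 0)) {
    stop("tubule diameters and epithelium heights must be > 0")
  }
  if (any(2 * h > d + 1e-9)) {
    stop("epithelium height exceeds tubule radius (2*GEH must be <= diameter)")
  }
  c(STD = mean(d), GEH = mean(h))
}

#' Point-count volumetric proportions
#'
#' Pools point-count fields and converts them to percentage volume
#' densities per tissue compartment (point fractions estimate volume
#' fractions under uniform random sampling).
#'
#' @param fields A data.frame with one row per field and the six
#'   non-negative integer count columns named as in
#'   [TESTIS_COMPARTMENTS].
#' @return Named numeric vector of six percentages summing to 100.
#' @examples
#' f <- data.frame(lumen = c(10, 0), germinative_epithelium = c(10, 10),
#'                 tunica_propria = c(0, 10), leydig = 0,
#'                 blood_vessels = 0, connective_tissue = 0)
#' volumetric_proportions(f)
#' @export
volumetric_proportions <- function(fields) {
  if (!is.data.frame(fields) || !all(TESTIS_COMPARTMENTS %in% names(fields))) {
    stop("`fields` must have the six compartment count columns: ",
         paste(TESTIS_COMPARTMENTS, collapse = ", "))
  }
  counts <- vapply(TESTIS_COMPARTMENTS,
                   function(cl) sum(fields[[cl]]), numeric(1))
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("point counts must be finite and non-negative")
  }
  total <- sum(counts)
  if (total <= 0) stop("pooled point count total must be > 0")
  100 * counts / total
}

#' Gonadosomatic index
#'
#' Percentage of body mass allocated to the paired testes.
#'
#' @param paired_testis_mass Combined mass of both testes, g.
#' @param body_mass Body mass, g.
#' @return GSI in percent.
#' @examples
#' gonadosomatic_index(1, 100)  # 1
#' @export
gonadosomatic_index <- function(paired_testis_mass, body_mass) {
  if (any(paired_testis_mass <= 0) || any(body_mass <= 0)) {
    stop("masses must be > 0")
  }
  100 * paired_testis_mass / body_mass
}

#' Testis parenchyma volume
#'
#' Converts testis mass to parenchyma volume, discounting the
#' non-parenchymal share (albuginea + mediastinum) and dividing by
#' tissue density.
#'
#' @param testis_mass Testis mass in g (single or paired, depending on
#'   what the downstream length estimate should refer to).
#' @param config A [stereology_config()].
#' @return Volume in mL.
#' @export
parenchyma_volume <- function(testis_mass, config = stereology_config()) {
  if (any(testis_mass <= 0)) stop("`testis_mass` must be > 0")
  testis_mass * (1 - config$nonparenchyma_fraction) / config$tissue_density
}

#' Tubular volume fraction from compartment proportions
#'
#' The seminiferous (tubular) compartment is lumen + germinative
#' epithelium + tunica propria; the remainder is intertubular.
#'
#' @param proportions Named percentages as returned by
#'   [volumetric_proportions()].
#' @return Unitless fraction in `[0, 1]`.
#' @export
tubular_fraction <- function(proportions) {
  if (!all(TUBULAR_COMPARTMENTS %in% names(proportions))) {
    stop("`proportions` must be named with the compartment classes")
  }
  sum(proportions[TUBULAR_COMPARTMENTS]) / 100
}

#' Total length of seminiferous tubules
#'
#' Treats the tubular compartment as a cylinder of diameter STD: the
#' total length is the tubular volume divided by the tubule
#' cross-sectional area.
#'
#' @param parenchyma_volume_ml Parenchyma volume in mL.
#' @param tubular_frac Tubular volume fraction in `[0, 1]`.
#' @param std_um Mean seminiferous tubule diameter in µm.
#' @return Total tubule length in metres.
#' @examples
#' # one metre of 200-µm tubule occupies pi * 100^2 * 1e6 µm^3
#' v_ml <- pi * 100^2 * 1e6 / 1e12
#' total_tubule_length(v_ml, 1, 200)  # 1
#' @export
total_tubule_length <- function(parenchyma_volume_ml, tubular_frac, std_um) {
  if (any(std_um <= 0)) stop("`std_um` must be > 0")
  if (any(tubular_frac < 0) || any(tubular_frac > 1)) {
    stop("`tubular_frac` must be in [0, 1]")
  }
  if (any(parenchyma_volume_ml < 0)) {
    stop("`parenchyma_volume_ml` must be >= 0")
  }
  volume_um3 <- parenchyma_volume_ml * 1e12
  area_um2 <- pi * (std_um / 2)^2
  (volume_um3 * tubular_frac / area_um2) / 1e6
}

#' Somatic indices (LSI, TSI)
#'
#' Percentage of body mass allocated to a testicular parenchyma
#' component: the Leydig-cell fraction gives the leydigosomatic index,
#' the tubular fraction the tubulosomal index.
#'
#' @param component_fraction Volume fraction of the component in the
#'   parenchyma, `[0, 1]`.
#' @param paired_testis_mass Combined testis mass, g.
#' @param body_mass Body mass, g.
#' @param config A [stereology_config()] (supplies the non-parenchyma
#'   discount; with density 1 g/mL component volume and mass coincide).
#' @return Index in percent.
#' @export
somatic_index <- function(component_fraction, paired_testis_mass, body_mass,
                          config = stereology_config()) {
  if (any(component_fraction < 0) || any(component_fraction > 1)) {
    stop("`component_fraction` must be in [0, 1]")
  }
  if (any(paired_testis_mass <= 0) || any(body_mass <= 0)) {
    stop("masses must be > 0")
  }
  parenchyma_mass <- paired_testis_mass * (1 - config$nonparenchyma_fraction)
  100 * parenchyma_mass * component_fraction / body_mass
}

#' Percent reduction relative to control
#'
#' @param control_value Control group value, > 0.
#' @param treated_value Treated group value.
#' @return `100 * (control - treated) / control`.
#' @examples
#' percent_reduction(204.60, 91.59)  # 55.23
#' @export
percent_reduction <- function(control_value, treated_value) {
  if (any(control_value <= 0)) stop("`control_value` must be > 0")
  100 * (control_value - treated_value) / control_value
}
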