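#' Per-group generator settings
#'
#' Describes one treatment group for the synthetic-cohort generator.
#' Masses are drawn lognormally (strictly positive, right-skewed),
#' lengths from zero-truncated normals with a between-animal and a
#' within-animal (profile-to-profile) level, point-count fields from a
#' Dirichlet-multinomial (the Dirichlet draw gives each animal its own
#' compartment composition), and stage-1 raw counts from a
#' gamma-Poisson mixture (animal-level mean from a gamma with the given
#' coefficient of variation, tubule counts Poisson around it).
#'
#' @param body_mass_mean_g,body_mass_sd_g Body mass mean and SD, g.
#' @param testis_mass_mean_g,testis_mass_sd_g Mass of one testis, g
#'   (left and right are drawn independently).
#' @param std_mean_um,std_between_sd_um,std_within_sd_um Seminiferous
#'   tubule diameter: group mean, between-animal SD, and
#'   profile-to-profile SD within an animal (µm).
#' @param geh_mean_um,geh_between_sd_um,geh_within_sd_um Germinative
#'   epithelium height, same structure (µm).
#' @param compartment_weights Named positive Dirichlet concentration
#'   weights for the six compartments in [TESTIS_COMPARTMENTS]; the
#'   normalized weights are the expected volumetric proportions and the
#'   total concentration sets the between-animal spread.
#' @param stage1_raw_means Named non-negative mean RAW counts per
#'   stage-1 cross-section for the classes in [CELL_CLASSES]. A mean of
#'   0 yields structural zeros (fully regressed classes).
#' @param stage1_cv Named non-negative between-animal coefficients of
#'   variation for the stage-1 count means (0 = no animal-level
#'   overdispersion beyond Poisson).
#' @return A list of class `group_params`.
#' @export
group_params <- function(body_mass_mean_g, body_mass_sd_g,
                         testis_mass_mean_g, testis_mass_sd_g,
                         std_mean_um, std_between_sd_um, std_within_sd_um,
                         geh_mean_um, geh_between_sd_um, geh_within_sd_um,
                         compartment_weights,
                         stage1_raw_means,
                         stage1_cv) {
  means <- c(body_mass_mean_g, testis_mass_mean_g, std_mean_um, geh_mean_um)
  if (any(!is.finite(means)) || any(means <= 0)) {
    stop("generator means (masses, lengths) must be positive")
  }
  sds <- c(body_mass_sd_g, testis_mass_sd_g, std_between_sd_um,
           std_within_sd_um, geh_between_sd_um, geh_within_sd_um)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("generator SDs must be non-negative")
  }
  if (!all(TESTIS_COMPARTMENTS %in% names(compartment_weights))) {
    stop("`compartment_weights` must be named with the six compartments")
  }
  w <- compartment_weights[TESTIS_COMPARTMENTS]
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("compartment weights must be strictly positive")
  }
  if (!all(CELL_CLASSES %in% names(stage1_raw_means))) {
    stop("`stage1_raw_means` must be named with the five cell classes")
  }
  m <- stage1_raw_means[CELL_CLASSES]
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("stage-1 raw count means must be non-negative")
  }
  if (length(stage1_cv) == 1L && is.null(names(stage1_cv))) {
    stage1_cv <- stats::setNames(rep(stage1_cv, 5), CELL_CLASSES)
  }
  if (!all(CELL_CLASSES %in% names(stage1_cv))) {
    stop("`stage1_cv` must be named with the five cell classes")
  }
  cv <- stage1_cv[CELL_CLASSES]
  if (any(!is.finite(cv)) || any(cv < 0)) {
    stop("stage-1 CVs must be non-negative")
  }
  structure(
    list(
      body_mass_mean_g = body_mass_mean_g, body_mass_sd_g = body_mass_sd_g,
      testis_mass_mean_g = testis_mass_mean_g,
      testis_mass_sd_g = testis_mass_sd_g,
      std_mean_um = std_mean_um, std_between_sd_um = std_between_sd_um,
      std_within_sd_um = std_within_sd_um,
      geh_mean_um = geh_mean_um, geh_between_sd_um = geh_between_sd_um,
      geh_within_sd_um = geh_within_sd_um,
      compartment_weights = w,
      stage1_raw_means = m,
      stage1_cv = cv
    ),
    class = "group_params"
  )
}

#' Cohort-level generator settings
#'
#' @param groups Named list of [group_params()], one per treatment
#'   group; names are the group labels.
#' @param nuclear_diameters Named mean nuclear diameters per cell class
#'   (nucleolar diameter for S), µm.
#' @param section_thickness_um Histological section thickness, µm.
#' @param points_per_field Points in the counting reticle per field.
#' @param n_fields Point-count fields per animal.
#' @param n_profiles Tubule profiles measured per animal.
#' @param n_stage1_tubules Stage-1 cross-sections counted per animal.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(groups,
                             nuclear_diameters,
                             section_thickness_um = 3,
                             points_per_field = 400,
                             n_fields = 10,
                             n_profiles = 30,
                             n_stage1_tubules = 10) {
  if (!is.list(groups) || length(groups) == 0L || is.null(names(groups)) ||
      any(names(groups) == "")) {
    stop("`groups` must be a non-empty named list of group_params")
  }
  ok <- vapply(groups, inherits, logical(1), what = "group_params")
  if (!all(ok)) stop("every element of `groups` must be a group_params object")
  if (!all(CELL_CLASSES %in% names(nuclear_diameters))) {
    stop("`nuclear_diameters` must be named with the five cell classes")
  }
  d <- nuclear_diameters[CELL_CLASSES]
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("nuclear diameters must be non-negative")
  }
  if (section_thickness_um <= 0) stop("`section_thickness_um` must be > 0")
  counts <- c(points_per_field, n_fields, n_profiles, n_stage1_tubules)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("points per field and per-animal sampling counts must be positive integers")
  }
  structure(
    list(
      groups = groups,
      nuclear_diameters = d,
      section_thickness_um = section_thickness_um,
      points_per_field = as.integer(points_per_field),
      n_fields = as.integer(n_fields),
      n_profiles = as.integer(n_profiles),
      n_stage1_tubules = as.integer(n_stage1_tubules)
    ),
    class = "generator_params"
  )
}

#' Cohort design
#'
#' @param labels Unique group labels.
#' @param n_per_group Animals per group (>= 2; the group statistics
#'   need at least two). A single integer is recycled over groups.
#' @param seed Integer seed; the whole cohort is drawn from a single
#'   RNG stream, group by group and animal by animal in label order, so
#'   the same seed reproduces the same dataset bit for bit.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(labels = c("control", "vaccine_1.0mL",
                                     "vaccine_0.5mL"),
                          n_per_group = 10,
                          seed = 1L) {
  if (anyDuplicated(labels)) stop("group labels must be unique")
  if (length(n_per_group) == 1L) {
    n_per_group <- rep(n_per_group, length(labels))
  }
  if (length(n_per_group) != length(labels)) {
    stop("`n_per_group` must have one entry per group label")
  }
  if (any(n_per_group < 2) || any(n_per_group != round(n_per_group))) {
    stop("`n_per_group` must be integers >= 2")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer")
  }
  structure(
    list(labels = as.character(labels),
         n_per_group = as.integer(n_per_group),
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' Default generator parameters
#'
#' Generator settings calibrated so that the analysis pipeline applied
#' to a large simulated cohort reproduces the published group summaries
#' for anti-GnRH-immunocastrated Santa Inês lambs
#' ([published_summaries()]): three groups (saline control, 1.0 mL and
#' 0.5 mL vaccine), ten animals each.
#'
#' Body masses are back-solved from published testis weight and
#' gonadosomatic index (15% CV); per-testis masses are half the
#' published paired weight with the paired SD split over two
#' independent testes; compartment weights are the normalized published
#' proportions at a total Dirichlet concentration matching the
#' published between-animal spread; stage-1 raw count means are the
#' published corrected means pushed back through
#' [inverse_abercrombie()], so generator and correction are mutually
#' consistent by construction. Nuclear diameters are typical values for
#' lamb testis histology (not reported with the summaries).
#'
#' @param section_thickness_um Section thickness, µm.
#' @param points_per_field Reticle points per field.
#' @param compartment_concentration Total Dirichlet concentration
#'   governing between-animal variability of the compartment
#'   composition.
#' @return A [generator_params()] object with groups `control`,
#'   `vaccine_1.0mL`, `vaccine_0.5mL`.
#' @export
default_generator_params <- function(section_thickness_um = 3,
                                     points_per_field = 400,
                                     compartment_concentration = 15) {
  s <- published_summaries()
  nuclear <- c(A = 6.9, PL = 6.2, PQ = 9.5, Ar = 5.3, S = 3.0)
  body_mass <- c(control = 16633, "vaccine_1.0mL" = 17062,
                 "vaccine_0.5mL" = 15500)

  make_group <- function(g) {
    loc <- function(v) ref_value(s, v, g)
    disp <- function(v) ref_dispersion(s, v, g)

    props <- vapply(TESTIS_COMPARTMENTS, loc, numeric(1))
    weights <- compartment_concentration * props / sum(props)

    corrected <- vapply(CELL_CLASSES, loc, numeric(1))
    raw_means <- inverse_abercrombie(corrected, section_thickness_um, nuclear)
    cvs <- vapply(CELL_CLASSES, function(cl) {
      m <- loc(cl)
      if (m > 0) disp(cl) / m else 0
    }, numeric(1))

    group_params(
      body_mass_mean_g = body_mass[[g]],
      body_mass_sd_g = 0.15 * body_mass[[g]],
      testis_mass_mean_g = loc("TW") / 2,
      testis_mass_sd_g = disp("TW") / sqrt(2),
      std_mean_um = loc("STD"),
      std_between_sd_um = disp("STD"),
      std_within_sd_um = 0.08 * loc("STD"),
      geh_mean_um = loc("GEH"),
      geh_between_sd_um = disp("GEH"),
      geh_within_sd_um = 0.10 * loc("GEH"),
      compartment_weights = weights,
      stage1_raw_means = raw_means,
      stage1_cv = cvs
    )
  }

  labels <- c("control", "vaccine_1.0mL", "vaccine_0.5mL")
  generator_params(
    groups = stats::setNames(lapply(labels, make_group), labels),
    nuclear_diameters = nuclear,
    section_thickness_um = section_thickness_um,
    points_per_field = points_per_field
  )
}

# Lognormal parameterization from arithmetic mean and SD.
lnorm_pars <- function(mean, sd) {
  s2 <- log1p((sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

rlnorm_ms <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p <- lnorm_pars(mean, sd)
  stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]])
}

# Normal truncated at > 0 by resampling.
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  tries <- 0L
  while (length(bad) > 0L && tries < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
    tries <- tries + 1L
  }
  if (length(bad) > 0L) x[bad] <- mean  # pathological mean/SD; keep positive
  x
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha  # numerically degenerate draw
  g / sum(g)
}

#' Generate a synthetic raw-measurement cohort
#'
#' Draws a full raw dataset — animal records, tubule profiles,
#' point-count fields, stage-1 cell counts and the nuclear-geometry
#' table — for each group in the design, from a single seeded RNG
#' stream. The same seed and parameters reproduce the dataset exactly.
#'
#' @param design A [cohort_design()]; its labels must all be present in
#'   `params$groups`.
#' @param params A [generator_params()] object.
#' @return A `raw_dataset`: a list of data.frames `animals`,
#'   `tubule_profiles`, `point_fields`, `stage1_counts`,
#'   `nuclear_geometry` with the column schemas used by
#'   [write_raw_dataset()].
#' @examples
#' ds <- generate_cohort(cohort_design(n_per_group = 3, seed = 7),
#'                       default_generator_params())
#' head(ds$animals)
#' @export
generate_cohort <- function(design, params) {
  if (!inherits(design, "cohort_design")) {
    stop("`design` must be a cohort_design")
  }
  if (!inherits(params, "generator_params")) {
    stop("`params` must be a generator_params")
  }
  missing <- setdiff(design$labels, names(params$groups))
  if (length(missing)) {
    stop("no generator parameters for group(s): ",
         paste(missing, collapse = ", "))
  }

  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(design$seed)

  animals <- list()
  profiles <- list()
  fields <- list()
  stage1 <- list()

  for (gi in seq_along(design$labels)) {
    label <- design$labels[gi]
    gp <- params$groups[[label]]
    n <- design$n_per_group[gi]
    for (ai in seq_len(n)) {
      id <- sprintf("%s-%02d", label, ai)

      body <- rlnorm_ms(1, gp$body_mass_mean_g, gp$body_mass_sd_g)
      testes <- rlnorm_ms(2, gp$testis_mass_mean_g, gp$testis_mass_sd_g)
      animals[[id]] <- data.frame(
        animal_id = id, group = label,
        body_mass_g = body,
        testis_mass_left_g = testes[1], testis_mass_right_g = testes[2],
        age_months = 7.2,  # slaughter age: vaccinated at ~4.2 mo + 90 d
        stringsAsFactors = FALSE
      )

      d_animal <- rnorm_pos(1, gp$std_mean_um, gp$std_between_sd_um)
      h_animal <- rnorm_pos(1, gp$geh_mean_um, gp$geh_between_sd_um)
      d <- rnorm_pos(params$n_profiles, d_animal, gp$std_within_sd_um)
      h <- rnorm_pos(params$n_profiles, h_animal, gp$geh_within_sd_um)
      # the epithelium must fit inside the tubule radius
      h <- pmin(h, d / 2)
      profiles[[id]] <- data.frame(
        animal_id = id, profile_idx = seq_len(params$n_profiles),
        diameter_um = d, epithelium_height_um = h,
        stringsAsFactors = FALSE
      )

      p <- rdirichlet1(gp$compartment_weights)
      draws <- stats::rmultinom(params$n_fields, params$points_per_field, p)
      fld <- as.data.frame(t(draws))
      names(fld) <- TESTIS_COMPARTMENTS
      fields[[id]] <- cbind(
        data.frame(animal_id = id, field_idx = seq_len(params$n_fields),
                   stringsAsFactors = FALSE),
        fld
      )

      cnt <- lapply(CELL_CLASSES, function(cl) {
        m <- gp$stage1_raw_means[[cl]]
        if (m == 0) return(rep(0L, params$n_stage1_tubules))
        cv <- gp$stage1_cv[[cl]]
        lambda <- if (cv > 0) {
          shape <- 1 / cv^2
          stats::rgamma(1, shape = shape, rate = shape / m)
        } else m
        stats::rpois(params$n_stage1_tubules, lambda)
      })
      names(cnt) <- CELL_CLASSES
      stage1[[id]] <- cbind(
        data.frame(animal_id = id,
                   tubule_idx = seq_len(params$n_stage1_tubules),
                   stringsAsFactors = FALSE),
        as.data.frame(cnt)
      )
    }
  }

  geometry <- data.frame(
    cell_class = CELL_CLASSES,
    mean_diameter_um = as.numeric(params$nuclear_diameters),
    section_thickness_um = params$section_thickness_um,
    stringsAsFactors = FALSE
  )

  structure(
    list(
      animals = do.call(rbind, c(animals, list(make.row.names = FALSE))),
      tubule_profiles = do.call(rbind, c(profiles, list(make.row.names = FALSE))),
      point_fields = do.call(rbind, c(fields, list(make.row.names = FALSE))),
      stage1_counts = do.call(rbind, c(stage1, list(make.row.names = FALSE))),
      nuclear_geometry = geometry
    ),
    class = "raw_dataset"
  )
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat("Raw histomorphometry dataset\n")
  cat(sprintf("  animals: %d (%s)\n", nrow(x$animals),
              paste(sprintf("%s n=%d", names(table(x$animals$group)),
                            as.integer(table(x$animals$group))),
                    collapse = ", ")))
  cat(sprintf("  tubule profiles: %d rows\n", nrow(x$tubule_profiles)))
  cat(sprintf("  point-count fields: %d rows\n", nrow(x$point_fields)))
  cat(sprintf("  stage-1 counts: %d rows\n", nrow(x$stage1_counts)))
  invisible(x)
}
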