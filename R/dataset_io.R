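# CSV schemas of the raw dataset (column name -> expected type).
RAW_SCHEMAS <- list(
  animals = c(animal_id = "character", group = "character",
              body_mass_g = "numeric", testis_mass_left_g = "numeric",
              testis_mass_right_g = "numeric", age_months = "numeric"),
  tubule_profiles = c(animal_id = "character", profile_idx = "numeric",
                      diameter_um = "numeric",
                      epithelium_height_um = "numeric"),
  point_fields = c(animal_id = "character", field_idx = "numeric",
                   lumen = "numeric", germinative_epithelium = "numeric",
                   tunica_propria = "numeric", leydig = "numeric",
                   blood_vessels = "numeric", connective_tissue = "numeric"),
  stage1_counts = c(animal_id = "character", tubule_idx = "numeric",
                    A = "numeric", PL = "numeric", PQ = "numeric",
                    Ar = "numeric", S = "numeric"),
  nuclear_geometry = c(cell_class = "character",
                       mean_diameter_um = "numeric",
                       section_thickness_um = "numeric")
)

#' Write a raw dataset to CSV files
#'
#' Writes the five linked tables (`animals.csv`, `tubule_profiles.csv`,
#' `point_fields.csv`, `stage1_counts.csv`, `nuclear_geometry.csv`)
#' into a directory, UTF-8, comma-separated, with a header row.
#'
#' @param dataset A `raw_dataset` (see [generate_cohort()]).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_raw_dataset <- function(dataset, dir) {
  validate_raw_dataset(dataset)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tbl in names(RAW_SCHEMAS)) {
    utils::write.csv(dataset[[tbl]], file.path(dir, paste0(tbl, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' Read and validate a raw dataset from CSV files
#'
#' Reads the five tables written by [write_raw_dataset()] and runs the
#' full schema and referential validation; any violation is a hard
#' error with row-level diagnostics.
#'
#' @param dir Directory containing the five CSV files.
#' @return A validated `raw_dataset`.
#' @export
read_raw_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("dataset directory does not exist: ", dir)
  dataset <- lapply(names(RAW_SCHEMAS), function(tbl) {
    path <- file.path(dir, paste0(tbl, ".csv"))
    if (!file.exists(path)) stop("missing dataset file: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  })
  names(dataset) <- names(RAW_SCHEMAS)
  dataset <- structure(dataset, class = "raw_dataset")
  validate_raw_dataset(dataset)
  dataset
}

#' Validate a raw dataset
#'
#' Checks column schemas, numeric types, referential integrity (every
#' measurement row must reference an existing animal), duplicate animal
#' ids, uniform per-animal row counts, positivity of masses and
#' lengths, integrality of counts, and the epithelium-fits-inside-the-
#' tubule constraint.
#'
#' @param dataset A `raw_dataset`.
#' @return The dataset, invisibly, if valid; otherwise an error.
#' @export
validate_raw_dataset <- function(dataset) {
  if (!is.list(dataset) || !all(names(RAW_SCHEMAS) %in% names(dataset))) {
    stop("dataset must contain tables: ",
         paste(names(RAW_SCHEMAS), collapse = ", "))
  }
  for (tbl in names(RAW_SCHEMAS)) {
    df <- dataset[[tbl]]
    if (!is.data.frame(df)) stop("table `", tbl, "` must be a data.frame")
    schema <- RAW_SCHEMAS[[tbl]]
    missing <- setdiff(names(schema), names(df))
    if (length(missing)) {
      stop("table `", tbl, "` is missing column(s): ",
           paste(missing, collapse = ", "))
    }
    for (col in names(schema)) {
      if (schema[[col]] == "numeric" && !is.numeric(df[[col]])) {
        stop("table `", tbl, "`, column `", col, "` must be numeric ",
             "(found ", class(df[[col]])[1], ")")
      }
      bad <- which(is.na(df[[col]]))
      if (length(bad)) {
        stop("table `", tbl, "`, column `", col, "` has missing values ",
             "at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
      }
    }
  }

  animals <- dataset$animals
  if (nrow(animals) == 0L) stop("no animals in dataset")
  dup <- animals$animal_id[duplicated(animals$animal_id)]
  if (length(dup)) {
    stop("duplicate animal_id(s) in animals table: ",
         paste(unique(dup), collapse = ", "))
  }
  masses <- c(animals$body_mass_g, animals$testis_mass_left_g,
              animals$testis_mass_right_g)
  if (any(masses <= 0)) stop("animal masses must be > 0")

  for (tbl in c("tubule_profiles", "point_fields", "stage1_counts")) {
    df <- dataset[[tbl]]
    orphan <- which(!(df$animal_id %in% animals$animal_id))
    if (length(orphan)) {
      stop("table `", tbl, "` references unknown animal_id `",
           df$animal_id[orphan[1]], "` at row(s) ",
           paste(utils::head(orphan, 5), collapse = ", "))
    }
    counts <- table(df$animal_id)
    if (length(counts) != nrow(animals)) {
      missing <- setdiff(animals$animal_id, names(counts))
      stop("table `", tbl, "` has no rows for animal(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    if (length(unique(as.integer(counts))) != 1L) {
      stop("table `", tbl, "` has unequal per-animal row counts (",
           paste(range(counts), collapse = "-"), ")")
    }
  }

  prof <- dataset$tubule_profiles
  if (any(prof$diameter_um <= 0) || any(prof$epithelium_height_um <= 0)) {
    stop("tubule diameters and epithelium heights must be > 0")
  }
  bad <- which(2 * prof$epithelium_height_um > prof$diameter_um + 1e-9)
  if (length(bad)) {
    stop("epithelium height exceeds tubule radius in tubule_profiles at ",
         "row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }

  pf <- dataset$point_fields
  pts <- as.matrix(pf[, TESTIS_COMPARTMENTS])
  if (any(pts < 0) || any(pts != round(pts))) {
    stop("point counts must be non-negative integers")
  }
  if (any(rowSums(pts) <= 0)) {
    stop("every point-count field must contain at least one point")
  }

  sc <- dataset$stage1_counts
  cc <- as.matrix(sc[, CELL_CLASSES])
  if (any(cc < 0) || any(cc != round(cc))) {
    stop("stage-1 cell counts must be non-negative integers")
  }

  geo <- dataset$nuclear_geometry
  geometry_lookup(geo)  # reuses the class/thickness checks

  invisible(dataset)
}
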