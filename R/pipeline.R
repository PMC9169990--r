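# Variables rendered in each of the six results tables.
TABLE_VARIABLES <- list(
  table1 = c("TW", "GSI", "STD", "GEH", "LSI", "TSI", "TLST", "TLST_per_g"),
  table2 = TESTIS_COMPARTMENTS,
  table3 = CELL_CLASSES,
  table4 = c("A_PL", "PL_PQ", "PQ_Ar", "A_Ar"),
  table5 = c("S_A", "S_PL", "S_PQ", "S_Ar", "S_CG"),
  table6 = c("NSCT", "NSCT_per_g", "DSP", "DSP_per_g", "TSR", "TSR_per_g")
)

# Display scaling used when rendering table 6 (counts are huge).
TABLE6_SCALE <- c(NSCT = 1e9, NSCT_per_g = 1e9, DSP = 1e9, DSP_per_g = 1e6,
                  TSR = 1e9, TSR_per_g = 1e6)

#' Per-animal morphometry and stereology
#'
#' Computes, for each animal, the testis-weight and morphometric
#' variables: paired testis weight (TW), gonadosomatic index (GSI),
#' mean seminiferous tubule diameter (STD) and germinative epithelium
#' height (GEH), the six volumetric proportions, leydigosomatic (LSI)
#' and tubulosomal (TSI) indices, and the total seminiferous tubule
#' length per testis pair (TLST) and per testis gram.
#'
#' @param dataset A validated `raw_dataset`.
#' @param config A [stereology_config()].
#' @return Data.frame, one row per animal.
#' @export
animal_morphometry <- function(dataset, config = stereology_config()) {
  validate_raw_dataset(dataset)
  animals <- dataset$animals
  rows <- lapply(seq_len(nrow(animals)), function(i) {
    a <- animals[i, ]
    tw <- a$testis_mass_left_g + a$testis_mass_right_g
    prof <- dataset$tubule_profiles[
      dataset$tubule_profiles$animal_id == a$animal_id, , drop = FALSE]
    flds <- dataset$point_fields[
      dataset$point_fields$animal_id == a$animal_id, , drop = FALSE]

    tub <- summarize_tubule_profiles(prof)
    props <- volumetric_proportions(flds)
    tf <- tubular_fraction(props)
    vol <- parenchyma_volume(tw, config)
    tlst <- total_tubule_length(vol, tf, tub[["STD"]])

    out <- data.frame(
      animal_id = a$animal_id, group = a$group,
      TW = tw,
      GSI = gonadosomatic_index(tw, a$body_mass_g),
      STD = tub[["STD"]], GEH = tub[["GEH"]],
      LSI = somatic_index(props[["leydig"]] / 100, tw, a$body_mass_g, config),
      TSI = somatic_index(tf, tw, a$body_mass_g, config),
      TLST = tlst, TLST_per_g = tlst / tw,
      stringsAsFactors = FALSE
    )
    for (cl in TESTIS_COMPARTMENTS) out[[cl]] <- props[[cl]]
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-animal cytometry and production estimates
#'
#' Computes, for each animal, the Abercrombie-corrected stage-1 cell
#' populations, intrinsic spermatogenic yields, Sertoli cell indices,
#' and the whole-testis production estimates: total Sertoli cell
#' number (NSCT), testicular sperm reserve (TSR) and daily sperm
#' production (DSP), each in absolute terms and per testis gram.
#'
#' @param dataset A validated `raw_dataset`.
#' @param morphometry The output of [animal_morphometry()] (supplies
#'   TLST and TW); computed on the fly if `NULL`.
#' @param config A [stereology_config()].
#' @return Data.frame, one row per animal.
#' @export
animal_cytometry <- function(dataset, morphometry = NULL,
                             config = stereology_config()) {
  validate_raw_dataset(dataset)
  if (is.null(morphometry)) morphometry <- animal_morphometry(dataset, config)
  geo <- dataset$nuclear_geometry
  thickness <- geometry_lookup(geo)$thickness

  rows <- lapply(seq_len(nrow(morphometry)), function(i) {
    m <- morphometry[i, ]
    counts <- dataset$stage1_counts[
      dataset$stage1_counts$animal_id == m$animal_id, , drop = FALSE]
    pop <- corrected_populations(counts, geo)
    yields <- intrinsic_yields(pop)
    sertoli <- sertoli_indices(pop)

    nsct <- total_population(pop[["S"]], m$TLST, thickness)
    tsr <- total_population(pop[["Ar"]], m$TLST, thickness)
    dsp <- daily_sperm_production(tsr, config)

    out <- data.frame(animal_id = m$animal_id, group = m$group,
                      stringsAsFactors = FALSE)
    for (cl in CELL_CLASSES) out[[cl]] <- pop[[cl]]
    for (nm in names(yields)) out[[nm]] <- yields[[nm]]
    for (nm in names(sertoli)) out[[nm]] <- sertoli[[nm]]
    out$NSCT <- nsct
    out$NSCT_per_g <- nsct / m$TW
    out$DSP <- dsp
    out$DSP_per_g <- dsp / m$TW
    out$TSR <- tsr
    out$TSR_per_g <- tsr / m$TW
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the full analysis pipeline
#'
#' Per-animal morphometry and cytometry, group comparisons for every
#' variable of the six results tables, and the rendered tables
#' themselves (group summary ± dispersion with compact superscript
#' letters and the omnibus P value; SD for parametric variables, IQR
#' for nonparametric ones).
#'
#' @param dataset A validated `raw_dataset`.
#' @param config A [stereology_config()]; its `alpha` drives both the
#'   branch choice and the letters.
#' @param decimals Decimal places used when rendering tables.
#' @return A list of class `pipeline_result` with elements
#'   `morphometry`, `cytometry`, `comparisons` (one `group_comparison`
#'   per variable), `comparison_table` (flat data.frame), and `tables`
#'   (list of six rendered data.frames).
#' @export
run_pipeline <- function(dataset, config = stereology_config(),
                         decimals = 2) {
  morpho <- animal_morphometry(dataset, config)
  cyto <- animal_cytometry(dataset, morpho, config)
  merged <- merge(morpho, cyto[, setdiff(names(cyto), "group")],
                  by = "animal_id", sort = FALSE)
  merged <- merged[match(morpho$animal_id, merged$animal_id), ]

  all_vars <- unlist(TABLE_VARIABLES, use.names = FALSE)
  comparisons <- lapply(all_vars, function(v) {
    compare_groups(merged[[v]], merged$group, alpha = config$alpha,
                   variable = v)
  })
  names(comparisons) <- all_vars

  tables <- lapply(names(TABLE_VARIABLES), function(tbl) {
    vars <- TABLE_VARIABLES[[tbl]]
    scale <- if (tbl == "table6") TABLE6_SCALE else NULL
    render_comparison_table(comparisons[vars], decimals = decimals,
                            scale = scale)
  })
  names(tables) <- names(TABLE_VARIABLES)

  structure(
    list(
      morphometry = morpho,
      cytometry = cyto,
      comparisons = comparisons,
      comparison_table = comparison_table(comparisons),
      tables = tables
    ),
    class = "pipeline_result"
  )
}

#' Flatten group comparisons to a single table
#'
#' @param comparisons A list of `group_comparison` objects.
#' @return Data.frame with one row per variable: branch, omnibus
#'   statistic and p-value, and per-group location/dispersion/letters
#'   columns.
#' @export
comparison_table <- function(comparisons) {
  rows <- lapply(comparisons, function(cmp) {
    s <- cmp$summaries
    out <- data.frame(
      variable = cmp$variable, branch = cmp$branch,
      statistic = cmp$statistic, p_value = cmp$p_value,
      stringsAsFactors = FALSE
    )
    for (i in seq_len(nrow(s))) {
      g <- s$group[i]
      out[[paste0(g, "_location")]] <- s$location[i]
      out[[paste0(g, "_dispersion")]] <- s$dispersion[i]
      out[[paste0(g, "_letters")]] <- s$letters[i]
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Round-half-even to `decimals` places and format with fixed digits.
format_value <- function(x, decimals) {
  formatC(round(x, decimals), format = "f", digits = decimals)
}

#' Render a results table from group comparisons
#'
#' @param comparisons List of `group_comparison` objects (one table's
#'   variables, in row order).
#' @param decimals Decimal places.
#' @param scale Optional named display divisors (e.g. 1e9 for absolute
#'   cell counts).
#' @return Data.frame: `variable`, one "location ± dispersion letters"
#'   column per group, `P_value`.
#' @export
render_comparison_table <- function(comparisons, decimals = 2,
                                    scale = NULL) {
  groups <- comparisons[[1]]$summaries$group
  rows <- lapply(comparisons, function(cmp) {
    s <- cmp$summaries
    div <- if (!is.null(scale) && cmp$variable %in% names(scale)) {
      scale[[cmp$variable]]
    } else 1
    cells <- vapply(seq_len(nrow(s)), function(i) {
      cell <- sprintf("%s ± %s", format_value(s$location[i] / div, decimals),
                      format_value(s$dispersion[i] / div, decimals))
      if (nzchar(s$letters[i]) && nrow(s) > 1 &&
          length(unique(s$letters)) > 1) {
        cell <- paste(cell, s$letters[i])
      }
      cell
    }, character(1))
    out <- data.frame(variable = cmp$variable, stringsAsFactors = FALSE)
    for (i in seq_along(groups)) out[[groups[i]]] <- cells[i]
    out$P_value <- if (is.na(cmp$p_value)) "-" else {
      format_value(cmp$p_value, 3)
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Testicular stereology pipeline result\n")
  cat(sprintf("  %d animals, %d variables compared\n",
              nrow(x$morphometry), length(x$comparisons)))
  for (tbl in names(x$tables)) {
    cat("\n--", tbl, "--\n")
    print(x$tables[[tbl]], row.names = FALSE)
  }
  invisible(x)
}
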