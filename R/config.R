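#' Stereological configuration
#'
#' Bundles the geometric and physiological constants shared by the
#' stereology and cytometry computations.
#'
#' @param tissue_density Testis parenchyma density in g/mL. 1.0 is the
#'   conventional assumption for fresh testicular tissue.
#' @param nonparenchyma_fraction Fraction of testis mass taken by the
#'   tunica albuginea and mediastinum, in `[0, 1)`. 0 means the whole
#'   testis mass is treated as parenchyma.
#' @param alpha Significance level for group comparisons.
#' @param sec_duration_days Divisor converting the testicular sperm
#'   reserve at stage 1 into a daily production rate, in days. The
#'   default 10.5 is the time-equivalent of one reserve turnover implied
#'   by published control-group reserve/production ratios in lambs.
#' @param theoretical_Ar_per_A Theoretical number of round spermatids
#'   produced per type-A spermatogonium over a full spermatogenic wave
#'   (256 = four mitotic doublings to 16 spermatocytes, each yielding 4
#'   spermatids... the classical expansion for domestic mammals).
#' @param theoretical_Ar_per_PQ Theoretical round spermatids per
#'   pachytene spermatocyte (4: two meiotic divisions).
#' @param theoretical_PQ_per_PL Theoretical pachytene spermatocytes per
#'   pre-leptotene spermatocyte (1: no expansion during meiotic
#'   prophase).
#'
#' @return An object of class `stereology_config` (a named list).
#' @examples
#' cfg <- stereology_config()
#' cfg$sec_duration_days
#' @export
stereology_config <- function(tissue_density = 1.0,
                              nonparenchyma_fraction = 0,
                              alpha = 0.05,
                              sec_duration_days = 10.5,
                              theoretical_Ar_per_A = 256,
                              theoretical_Ar_per_PQ = 4,
                              theoretical_PQ_per_PL = 1) {
  if (!is.numeric(tissue_density) || length(tissue_density) != 1L ||
      tissue_density <= 0) {
    stop("`tissue_density` must be a single positive number (g/mL)")
  }
  if (!is.numeric(nonparenchyma_fraction) ||
      length(nonparenchyma_fraction) != 1L ||
      nonparenchyma_fraction < 0 || nonparenchyma_fraction >= 1) {
    stop("`nonparenchyma_fraction` must be in [0, 1)")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)")
  }
  if (!is.numeric(sec_duration_days) || sec_duration_days <= 0) {
    stop("`sec_duration_days` must be > 0")
  }
  if (theoretical_Ar_per_A <= 0 || theoretical_Ar_per_PQ <= 0 ||
      theoretical_PQ_per_PL <= 0) {
    stop("theoretical yield constants must be > 0")
  }
  structure(
    list(
      tissue_density = tissue_density,
      nonparenchyma_fraction = nonparenchyma_fraction,
      alpha = alpha,
      sec_duration_days = sec_duration_days,
      theoretical_Ar_per_A = theoretical_Ar_per_A,
      theoretical_Ar_per_PQ = theoretical_Ar_per_PQ,
      theoretical_PQ_per_PL = theoretical_PQ_per_PL
    ),
    class = "stereology_config"
  )
}

#' @export
print.stereology_config <- function(x, ...) {
  cat("Stereological configuration\n")
  cat(sprintf("  tissue density:          %g g/mL\n", x$tissue_density))
  cat(sprintf("  non-parenchyma fraction: %g\n", x$nonparenchyma_fraction))
  cat(sprintf("  alpha:                   %g\n", x$alpha))
  cat(sprintf("  SEC duration equivalent: %g d\n", x$sec_duration_days))
  cat(sprintf("  theoretical Ar per A:    %g\n", x$theoretical_Ar_per_A))
  cat(sprintf("  theoretical Ar per PQ:   %g\n", x$theoretical_Ar_per_PQ))
  invisible(x)
}
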