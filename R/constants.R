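#' Tissue compartment classes used in point counting
#'
#' Order matters: the first three classes (lumen, germinative
#' epithelium, tunica propria) make up the tubular compartment, the
#' last three the intertubular compartment.
#'
#' @format Character vector of length 6.
#' @export
TESTIS_COMPARTMENTS <- c(
  "lumen", "germinative_epithelium", "tunica_propria",
  "leydig", "blood_vessels", "connective_tissue"
)

#' Cell classes counted in stage-1 tubule cross-sections
#'
#' Type-A spermatogonia (A), pre-leptotene/leptotene spermatocytes
#' (PL), pachytene spermatocytes (PQ), round spermatids (Ar), and
#' Sertoli cells (S, counted by nucleolus).
#'
#' @format Character vector of length 5.
#' @export
CELL_CLASSES <- c("A", "PL", "PQ", "Ar", "S")

# Compartments belonging to the seminiferous (tubular) compartment.
TUBULAR_COMPARTMENTS <- TESTIS_COMPARTMENTS[1:3]
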