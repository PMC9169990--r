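# Small hand-built fixtures used across test files.

tiny_geometry <- function(thickness = 3,
                          diameters = c(A = 6.9, PL = 6.2, PQ = 9.5,
                                        Ar = 5.3, S = 3.0)) {
  data.frame(
    cell_class = names(diameters),
    mean_diameter_um = as.numeric(diameters),
    section_thickness_um = thickness,
    stringsAsFactors = FALSE
  )
}

# A deterministic two-animal dataset with round numbers, for exact
# arithmetic checks of the per-animal pipeline.
tiny_dataset <- function() {
  animals <- data.frame(
    animal_id = c("a1", "a2"), group = c("g1", "g2"),
    body_mass_g = c(10000, 20000),
    testis_mass_left_g = c(50, 10), testis_mass_right_g = c(50, 10),
    age_months = 7, stringsAsFactors = FALSE
  )
  profiles <- do.call(rbind, lapply(c("a1", "a2"), function(id) {
    data.frame(animal_id = id, profile_idx = 1:4,
               diameter_um = if (id == "a1") c(100, 300, 200, 200) else 100,
               epithelium_height_um = if (id == "a1") c(20, 40, 30, 30) else 10,
               stringsAsFactors = FALSE)
  }))
  fields <- do.call(rbind, lapply(c("a1", "a2"), function(id) {
    data.frame(animal_id = id, field_idx = 1:2,
               lumen = c(10, 0), germinative_epithelium = c(10, 10),
               tunica_propria = c(0, 10), leydig = c(0, 0),
               blood_vessels = c(0, 0), connective_tissue = c(0, 0),
               stringsAsFactors = FALSE)
  }))
  counts <- do.call(rbind, lapply(c("a1", "a2"), function(id) {
    data.frame(animal_id = id, tubule_idx = 1:2,
               A = c(1, 3), PL = c(4, 4), PQ = c(4, 4), Ar = c(10, 14),
               S = c(10, 10), stringsAsFactors = FALSE)
  }))
  structure(
    list(animals = animals, tubule_profiles = profiles,
         point_fields = fields, stage1_counts = counts,
         nuclear_geometry = tiny_geometry(
           thickness = 3, diameters = c(A = 0, PL = 0, PQ = 0, Ar = 0, S = 3)
         )),
    class = "raw_dataset"
  )
}

small_cohort <- function(seed = 11, n = 4) {
  generate_cohort(cohort_design(n_per_group = n, seed = seed),
                  default_generator_params())
}
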