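test_that("generation is deterministic under a fixed seed", {
  a <- small_cohort(seed = 5)
  b <- small_cohort(seed = 5)
  expect_identical(a, b)
  c <- small_cohort(seed = 6)
  expect_false(identical(a$animals, c$animals))

  # identical seed gives byte-identical CSV output
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_raw_dataset(a, d1)
  write_raw_dataset(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(small_cohort(seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("zero within-animal SD collapses profiles onto the animal mean", {
  params <- default_generator_params()
  g <- params$groups$control
  g$std_within_sd_um <- 0
  g$geh_within_sd_um <- 0
  params$groups <- list(control = g)
  ds <- generate_cohort(cohort_design(labels = "control", n_per_group = 3,
                                      seed = 2), params)
  per_animal <- split(ds$tubule_profiles$diameter_um,
                      ds$tubule_profiles$animal_id)
  for (d in per_animal) expect_equal(length(unique(d)), 1L)
  # between-animal variation is still there
  expect_gt(length(unique(ds$tubule_profiles$diameter_um)), 1L)
})

test_that("generated datasets satisfy the measurement invariants", {
  ds <- small_cohort(seed = 8)
  expect_silent(validate_raw_dataset(ds))
  expect_true(all(ds$tubule_profiles$diameter_um > 0))
  expect_true(all(2 * ds$tubule_profiles$epithelium_height_um <=
                    ds$tubule_profiles$diameter_um + 1e-9))
  cc <- as.matrix(ds$stage1_counts[, CELL_CLASSES])
  expect_true(all(cc >= 0 & cc == round(cc)))
  pts <- as.matrix(ds$point_fields[, TESTIS_COMPARTMENTS])
  expect_true(all(rowSums(pts) == 400))
  # fully regressed classes are structural zeros
  v05 <- ds$stage1_counts[grepl("0.5mL", ds$stage1_counts$animal_id), ]
  expect_true(all(v05$PQ == 0) && all(v05$Ar == 0))
})

test_that("invalid designs and parameters are rejected", {
  expect_error(cohort_design(n_per_group = 1), ">= 2")
  expect_error(cohort_design(labels = c("a", "a")), "unique")
  expect_error(
    group_params(1, -1, 1, 0, 1, 0, 0, 1, 0, 0,
                 setNames(rep(1, 6), TESTIS_COMPARTMENTS),
                 setNames(rep(1, 5), CELL_CLASSES), 0),
    "SDs"
  )
  expect_error(
    group_params(1, 0, 1, 0, 1, 0, 0, 1, 0, 0,
                 setNames(c(0, rep(1, 5)), TESTIS_COMPARTMENTS),
                 setNames(rep(1, 5), CELL_CLASSES), 0),
    "positive"
  )
  expect_error(
    generator_params(list(x = default_generator_params()$groups$control),
                     c(A = 1, PL = 1, PQ = 1, Ar = 1, S = 1),
                     points_per_field = 0),
    "positive integers"
  )
  des <- cohort_design(labels = "nosuch")
  expect_error(generate_cohort(des, default_generator_params()), "nosuch")
})

test_that("default parameters are self-consistent with the correction", {
  params <- default_generator_params()
  s <- published_summaries()
  for (g in names(params$groups)) {
    raw <- params$groups[[g]]$stage1_raw_means
    corrected <- abercrombie_correct(raw, params$section_thickness_um,
                                     params$nuclear_diameters)
    targets <- vapply(CELL_CLASSES, function(cl) {
      s$location[s$variable == cl & s$group == g]
    }, numeric(1))
    expect_equal(unname(corrected), unname(targets))
  }
  # compartment weights are the normalized published proportions
  w <- params$groups$control$compartment_weights
  props <- vapply(TESTIS_COMPARTMENTS, function(v) {
    s$location[s$table == 2 & s$variable == v & s$group == "control"]
  }, numeric(1))
  expect_equal(unname(w / sum(w)), unname(props / sum(props)))
})

test_that("a calibrated control cohort recovers its input diameter mean", {
  # Monte-Carlo self-check: 200 control animals, compare the mean of
  # per-animal STD with the generator's configured mean within 2 SE
  params <- default_generator_params()
  params$groups <- params$groups["control"]
  ds <- generate_cohort(
    cohort_design(labels = "control", n_per_group = 200, seed = 31), params
  )
  per_animal <- tapply(ds$tubule_profiles$diameter_um,
                       ds$tubule_profiles$animal_id, mean)
  se <- sd(per_animal) / sqrt(length(per_animal))
  expect_lt(abs(mean(per_animal) - params$groups$control$std_mean_um), 2 * se)
})
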