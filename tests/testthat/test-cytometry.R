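test_that("corrected populations average then shrink raw counts", {
  zero <- data.frame(animal_id = "x", tubule_idx = 1:3,
                     A = 0, PL = 0, PQ = 0, Ar = 0, S = 0)
  pop <- corrected_populations(zero, tiny_geometry())
  expect_equal(unname(pop), rep(0, 5))

  # single cross-section, zero diameters except Sertoli nucleolus 3 µm:
  # only S shrinks, by 3/(3+3)
  one <- data.frame(A = 4L, PL = 8L, PQ = 2L, Ar = 10L, S = 11L)
  geo <- tiny_geometry(thickness = 3,
                       diameters = c(A = 0, PL = 0, PQ = 0, Ar = 0, S = 3))
  pop <- corrected_populations(one, geo)
  expect_equal(pop, c(A = 4, PL = 8, PQ = 2, Ar = 10, S = 5.5))

  # correcting the mean equals averaging corrected per-tubule counts
  set.seed(3)
  counts <- as.data.frame(matrix(rpois(50, 8), 10, 5))
  names(counts) <- CELL_CLASSES
  geo <- tiny_geometry()
  pop <- corrected_populations(counts, geo)
  manual <- vapply(CELL_CLASSES, function(cl) {
    d <- geo$mean_diameter_um[geo$cell_class == cl]
    mean(counts[[cl]] * 3 / (3 + d))
  }, numeric(1))
  expect_equal(pop, manual)

  expect_error(corrected_populations(counts[0, ], geo), "at least one")
  expect_error(corrected_populations(counts, geo[-2, ]), "lacks cell class")
})

test_that("intrinsic yields follow the ratio conventions", {
  p <- c(A = 2, PL = 4, PQ = 4, Ar = 12, S = 5)
  y <- intrinsic_yields(p)
  expect_equal(y, c(A_PL = 2, PL_PQ = 1, PQ_Ar = 3, A_Ar = 6))
  # chain identity: A:Ar is the product of the step yields
  expect_equal(y[["A_Ar"]], y[["A_PL"]] * y[["PL_PQ"]] * y[["PQ_Ar"]])

  zero <- c(A = 0, PL = 0, PQ = 0, Ar = 0, S = 5)
  expect_equal(unname(intrinsic_yields(zero)), rep(0, 4))

  undef <- c(A = 0, PL = 3, PQ = 0, Ar = 0, S = 5)
  expect_warning(y2 <- intrinsic_yields(undef), "A:PL undefined")
  expect_true(is.na(y2[["A_PL"]]))
  expect_equal(y2[["PL_PQ"]], 0)
  expect_error(intrinsic_yields(c(A = -1, PL = 0, PQ = 0, Ar = 0, S = 1)))
})

test_that("Sertoli indices are additive", {
  p <- c(A = 0.95, PL = 11.46, PQ = 15.44, Ar = 50.29, S = 5.27)
  s <- sertoli_indices(p)
  expect_equal(s[["S_CG"]], sum(s[c("S_A", "S_PL", "S_PQ", "S_Ar")]))
  # plug-in of published control populations: S:CG near the published
  # per-animal mean 15.36 (averaging-order difference, so only 10%)
  expect_equal(s[["S_CG"]], 15.36, tolerance = 0.10)

  none <- sertoli_indices(c(A = 0, PL = 0, PQ = 0, Ar = 0, S = 1))
  expect_equal(unname(none), rep(0, 5))

  set.seed(9)
  for (i in 1:20) {
    q <- setNames(runif(5, 0, 30), CELL_CLASSES)
    si <- sertoli_indices(q)
    expect_equal(si[["S_CG"]], sum(si[c("S_A", "S_PL", "S_PQ", "S_Ar")]))
  }
})

test_that("yield percentages use the theoretical expansions", {
  expect_equal(general_yield_percent(256), 100)
  expect_equal(general_yield_percent(0), 0)
  expect_equal(round(general_yield_percent(53.79), 2), 21.01)
  expect_equal(meiotic_loss_percent(4), 0)
  expect_equal(meiotic_loss_percent(0), 100)
  expect_equal(meiotic_loss_percent(3.16), 21)
  expect_equal(meiotic_loss_percent(5), 0)  # above-theory yield clamps at 0
})

test_that("whole-testis scaling converts units correctly", {
  expect_equal(total_population(1, 3, 3), 1e6)
  expect_equal(total_population(0, 5000, 3), 0)
  expect_equal(total_population(2, 1, 2), 1e6)
  expect_error(total_population(1, 3, 0), "section_thickness")
})

test_that("daily production divides the reserve by the SEC equivalent", {
  expect_equal(daily_sperm_production(0), 0)
  expect_equal(daily_sperm_production(21, stereology_config()), 2)
  one_day <- stereology_config(sec_duration_days = 1)
  expect_equal(daily_sperm_production(47.53e9, one_day), 47.53e9)
})
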