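test_that("tubule profile summaries are plain means", {
  const <- data.frame(diameter_um = rep(200, 30),
                      epithelium_height_um = rep(45, 30))
  expect_equal(summarize_tubule_profiles(const), c(STD = 200, GEH = 45))
  two <- data.frame(diameter_um = c(100, 300),
                    epithelium_height_um = c(20, 40))
  expect_equal(summarize_tubule_profiles(two), c(STD = 200, GEH = 30))
  expect_error(summarize_tubule_profiles(two[0, ]), "at least one")
  bad <- data.frame(diameter_um = 100, epithelium_height_um = 60)
  expect_error(summarize_tubule_profiles(bad), "radius")
})

test_that("volumetric proportions pool fields and sum to 100", {
  lumen_only <- data.frame(lumen = 10, germinative_epithelium = 0,
                           tunica_propria = 0, leydig = 0,
                           blood_vessels = 0, connective_tissue = 0)
  expect_equal(unname(volumetric_proportions(lumen_only)),
               c(100, 0, 0, 0, 0, 0))
  two <- data.frame(lumen = c(10, 0), germinative_epithelium = c(10, 10),
                    tunica_propria = c(0, 10), leydig = 0,
                    blood_vessels = 0, connective_tissue = 0)
  expect_equal(unname(volumetric_proportions(two)), c(25, 50, 25, 0, 0, 0))
  expect_error(volumetric_proportions(two * 0), "total")

  set.seed(21)
  for (i in 1:20) {
    f <- as.data.frame(matrix(rpois(30, 20), 5, 6))
    names(f) <- TESTIS_COMPARTMENTS
    expect_equal(sum(volumetric_proportions(f)), 100)
  }
})

test_that("gonadosomatic index matches direct division", {
  expect_equal(gonadosomatic_index(1, 100), 1)
  # body masses back-solved from published paired weight and GSI
  expect_equal(round(gonadosomatic_index(109.78, 16633), 2), 0.66)
  expect_equal(round(gonadosomatic_index(22.18, 17061), 2), 0.13)
  expect_error(gonadosomatic_index(0, 100), "> 0")
})

test_that("parenchyma volume applies density and discount", {
  expect_equal(parenchyma_volume(100), 100)
  cfg <- stereology_config(nonparenchyma_fraction = 0.1)
  expect_equal(parenchyma_volume(100, cfg), 90)
  expect_equal(parenchyma_volume(109.78), 109.78)
  cfg2 <- stereology_config(tissue_density = 1.1)
  expect_equal(parenchyma_volume(110, cfg2), 100)
})

test_that("tubule length inverts the cylinder volume", {
  # one metre of 200-µm tubule
  v_ml <- pi * 100^2 * 1e6 / 1e12
  expect_equal(total_tubule_length(v_ml, 1, 200), 1)
  # plug-in of published control means: frozen from direct arithmetic
  # 109.78e12 * 0.9218 / (pi * 102.3^2) / 1e6
  plug <- total_tubule_length(109.78, 0.9218, 204.60)
  expect_equal(plug, 3077.93, tolerance = 1e-4)
  # strictly decreasing in diameter at fixed volume and fraction
  d <- seq(50, 400, by = 25)
  l <- total_tubule_length(100, 0.8, d)
  expect_true(all(diff(l) < 0))
})

test_that("cylinder phantom length is recovered exactly", {
  set.seed(12)
  for (i in 1:25) {
    len <- runif(1, 100, 5000)
    dia <- runif(1, 60, 350)
    fill <- runif(1, 0.1, 0.9)
    ph <- cylinder_phantom(total_length_m = len, diameter_um = dia,
                           volume_ml = pi * (dia / 2)^2 * len * 1e6 /
                             (fill * 1e12))
    est <- total_tubule_length(ph$volume_ml, ph$fraction, ph$diameter_um)
    expect_equal(est, ph$length_m, tolerance = 1e-12)
  }
})

test_that("somatic indices scale parenchyma mass by body mass", {
  expect_equal(somatic_index(0, 100, 1000), 0)
  expect_equal(somatic_index(1, 1, 100), 1)
  expect_equal(round(somatic_index(0.0196, 109.78, 16633), 4), 0.0129)
  cfg <- stereology_config(nonparenchyma_fraction = 0.5)
  expect_equal(somatic_index(1, 2, 100, cfg), 1)
  expect_error(somatic_index(1.2, 1, 100), "\\[0, 1\\]")
})

test_that("percent reduction is exact and behaves at the limits", {
  expect_equal(percent_reduction(5, 5), 0)
  expect_equal(percent_reduction(5, 0), 100)
  expect_equal(round(percent_reduction(204.60, 91.59), 2), 55.23)
  # antisymmetry around equality: going up mirrors going down
  expect_equal(percent_reduction(10, 12), -percent_reduction(10, 8))
  expect_error(percent_reduction(0, 1), "control")
})
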