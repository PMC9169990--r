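test_that("normality branch choice is calibrated and deterministic", {
  set.seed(15)
  g <- rep(c("a", "b", "c"), each = 10)
  picks <- replicate(500, {
    choose_branch(rnorm(30, 50, 5), g)$branch == "parametric"
  })
  # Shapiro on pooled residuals of truly normal data keeps the
  # parametric branch about 95% of the time at alpha 0.05
  expect_gt(mean(picks), 0.90)
  expect_lt(mean(picks), 0.99)

  # gross outliers push the choice to the nonparametric branch
  set.seed(16)
  flips <- replicate(100, {
    x <- rnorm(30, 50, 5)
    x[c(3, 14, 25)] <- x[c(3, 14, 25)] + 50  # 10-SD outliers
    choose_branch(x, g)$branch == "nonparametric"
  })
  expect_gt(mean(flips), 0.95)

  x <- rnorm(30)
  expect_identical(choose_branch(x, g), choose_branch(x, g))
  const <- choose_branch(rep(1, 30), g)
  expect_true(const$degenerate)
  expect_equal(const$branch, "nonparametric")
  expect_error(choose_branch(1:4, c("a", "a", "b", "b")), "at least 3")
})

test_that("parametric comparison separates well-separated groups", {
  g <- rep(c("a", "b", "c"), each = 10)
  set.seed(2)
  x <- c(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01), rnorm(10, 10, 0.01))
  cmp <- parametric_compare(x, g)
  expect_lt(cmp$p_value, 1e-10)
  expect_lt(cmp$pairwise["a", "b"], 1e-6)
  expect_gt(cmp$pairwise["b", "c"], 0.05)
  expect_equal(cmp$pairwise, t(cmp$pairwise))
  expect_error(parametric_compare(x, rep("a", 30)), "2 groups")
})

test_that("Dunn z agrees with Kruskal-Wallis in the two-group case", {
  set.seed(33)
  for (i in 1:10) {
    x <- c(rnorm(8), rnorm(9, 1))
    g <- rep(c("a", "b"), c(8, 9))
    d <- dunn_test(x, g)
    kw <- kruskal.test(x, factor(g))
    # H equals z^2 when k = 2 (same rank variance, same tie correction)
    expect_equal(d$z^2, unname(kw$statistic), tolerance = 1e-10)
  }
  # tie-heavy data keep the statistic finite and the p in [0, 1]
  d <- dunn_test(c(1, 1, 1, 2, 2, 1, 1, 2), rep(c("a", "b"), each = 4))
  expect_true(is.finite(d$z) && d$p >= 0 && d$p <= 1)
})

test_that("nonparametric comparison separates disjoint-range groups", {
  g <- rep(c("a", "b", "c"), each = 10)
  x <- c(runif(10, 0, 1), runif(10, 10, 11), runif(10, 20, 21))
  cmp <- nonparametric_compare(x, g)
  expect_lt(cmp$p_value, 1e-4)
  expect_true(all(cmp$pairwise[upper.tri(cmp$pairwise)] < 0.05))
  expect_equal(unname(compact_letters(cmp$pairwise, 0.05)),
               c("a", "b", "c"))
})

test_that("letters and pairwise significance are biconditional", {
  set.seed(27)
  g <- rep(c("g1", "g2", "g3"), each = 10)
  for (i in 1:30) {
    shift <- sample(c(0, 0, 2, 5), 3, replace = TRUE)
    x <- rnorm(30, rep(shift, each = 10))
    cmp <- compare_groups(x, g, alpha = 0.05)
    lv <- cmp$summaries$group
    for (a in seq_along(lv)) {
      for (b in seq_along(lv)) {
        if (a >= b) next
        share <- any(strsplit(cmp$letters[[a]], "")[[1]] %in%
                       strsplit(cmp$letters[[b]], "")[[1]])
        signif <- !is.na(cmp$pairwise[a, b]) && cmp$pairwise[a, b] < 0.05
        expect_equal(share, !signif)
      }
    }
  }
})

test_that("summaries match the selected branch", {
  set.seed(5)
  g <- rep(c("a", "b"), each = 12)
  x <- c(rnorm(12, 10), rnorm(12, 30))
  cmp_p <- compare_groups(x, g, branch = "parametric")
  expect_equal(cmp_p$summaries$location,
               as.numeric(tapply(x, g, mean)))
  expect_equal(cmp_p$summaries$dispersion,
               as.numeric(tapply(x, g, sd)))
  cmp_n <- compare_groups(x, g, branch = "nonparametric")
  expect_equal(cmp_n$summaries$location,
               as.numeric(tapply(x, g, median)))
  expect_equal(cmp_n$summaries$dispersion,
               as.numeric(tapply(x, g, IQR)))
})

test_that("constant data fall back to the exact-tie convention", {
  g <- rep(c("a", "b", "c"), each = 5)
  cmp <- compare_groups(rep(3.2, 15), g)
  expect_true(cmp$degenerate)
  expect_true(is.na(cmp$p_value))
  expect_equal(unname(cmp$letters), c("a", "a", "a"))
})

test_that("undefined values are dropped with a warning", {
  g <- rep(c("a", "b", "c"), each = 5)
  x <- c(rnorm(5), rnorm(5, 5), rnorm(5, 10))
  x[4] <- NA
  expect_warning(cmp <- compare_groups(x, g, variable = "PQ_Ar"),
                 "undefined")
  expect_equal(cmp$summaries$n, c(4L, 5L, 5L))
})
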