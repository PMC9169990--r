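# Coerce a grouping vector to a factor with levels in order of first
# appearance (the tables list control first, then the doses).
as_group_factor <- function(groups) {
  if (is.factor(groups)) groups else factor(groups, levels = unique(groups))
}

#' Choose the statistical branch by a normality check
#'
#' Applies the Shapiro–Wilk test to the pooled within-group residuals
#' (each value minus its group mean); `p >= alpha` selects the
#' parametric branch (ANOVA + Tukey), otherwise the nonparametric
#' branch (Kruskal–Wallis + Dunn). Residual-based (rather than
#' per-group) testing is used because small groups leave per-group
#' tests underpowered; set `method = "per_group"` to require every
#' group to pass instead.
#'
#' Constant data cannot be tested; the branch falls back to
#' nonparametric with `degenerate = TRUE`.
#'
#' @param values Numeric response values.
#' @param groups Group labels, same length.
#' @param alpha Significance level for the normality decision.
#' @param method `"pooled_residuals"` (default) or `"per_group"`.
#' @return List with `branch` (`"parametric"`/`"nonparametric"`),
#'   `normality_p`, and `degenerate`.
#' @export
choose_branch <- function(values, groups, alpha = 0.05,
                          method = c("pooled_residuals", "per_group")) {
  method <- match.arg(method)
  g <- as_group_factor(groups)
  if (length(values) != length(g)) {
    stop("`values` and `groups` must have the same length")
  }
  if (any(table(g) < 3L)) {
    stop("each group needs at least 3 values for the normality check")
  }
  sw_p <- function(x) {
    if (length(unique(x)) < 3L || stats::sd(x) == 0) return(NA_real_)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  p <- if (method == "pooled_residuals") {
    sw_p(values - stats::ave(values, g))
  } else {
    min(vapply(split(values, g), sw_p, numeric(1)))
  }
  if (is.na(p)) {
    list(branch = "nonparametric", normality_p = NA_real_, degenerate = TRUE)
  } else {
    list(branch = if (p >= alpha) "parametric" else "nonparametric",
         normality_p = p, degenerate = FALSE)
  }
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param values Numeric response values.
#' @param groups Group labels, same length.
#' @param alpha Significance level (recorded; letters are derived
#'   downstream).
#' @return List with `statistic` (F), `p_value`, `pairwise` (symmetric
#'   matrix of Tukey-adjusted p-values, groups in factor order), and
#'   `method = "anova_tukey"`.
#' @export
parametric_compare <- function(values, groups, alpha = 0.05) {
  g <- as_group_factor(groups)
  if (nlevels(g) < 2L) stop("at least 2 groups are required")
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  tukey <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pmat <- pairwise_matrix(levels(g))
  for (row in rownames(tukey)) {
    pair <- strsplit(row, "-", fixed = TRUE)[[1]]
    pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tukey[row, "p adj"]
  }
  list(
    statistic = tab[["F value"]][1],
    p_value = tab[["Pr(>F)"]][1],
    pairwise = pmat,
    method = "anova_tukey"
  )
}

#' Kruskal–Wallis test with Dunn pairwise comparisons
#'
#' The omnibus test is [stats::kruskal.test()]; pairwise comparisons
#' use Dunn's rank-based z statistic with the tie correction, and Holm
#' adjustment across the pairs.
#'
#' @inheritParams parametric_compare
#' @return List with `statistic` (H), `p_value`, `pairwise` (symmetric
#'   matrix of Holm-adjusted Dunn p-values), and
#'   `method = "kruskal_dunn"`.
#' @export
nonparametric_compare <- function(values, groups, alpha = 0.05) {
  g <- as_group_factor(groups)
  if (nlevels(g) < 2L) stop("at least 2 groups are required")
  kw <- stats::kruskal.test(values, g)
  dunn <- dunn_test(values, g)
  pmat <- pairwise_matrix(levels(g))
  for (i in seq_len(nrow(dunn))) {
    pmat[dunn$group1[i], dunn$group2[i]] <-
      pmat[dunn$group2[i], dunn$group1[i]] <- dunn$p_adj[i]
  }
  list(
    statistic = unname(kw$statistic),
    p_value = kw$p.value,
    pairwise = pmat,
    method = "kruskal_dunn"
  )
}

pairwise_matrix <- function(levels) {
  k <- length(levels)
  matrix(NA_real_, k, k, dimnames = list(levels, levels))
}

#' Dunn's pairwise rank comparisons
#'
#' Pairwise z-tests on mean ranks after a Kruskal–Wallis analysis, with
#' the standard tie correction; two-sided p-values are Holm-adjusted
#' across the pairs.
#'
#' @inheritParams parametric_compare
#' @return Data.frame with columns `group1`, `group2`, `z`, `p`,
#'   `p_adj`.
#' @export
dunn_test <- function(values, groups) {
  g <- as_group_factor(groups)
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  var_base <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))

  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  out <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE
  )
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se2 <- var_base * (1 / sizes[[a]] + 1 / sizes[[b]])
    z <- if (se2 <= 0) 0 else (mean_ranks[[a]] - mean_ranks[[b]]) / sqrt(se2)
    out$z[i] <- z
    out$p[i] <- 2 * stats::pnorm(-abs(z))
  }
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Compare one variable across treatment groups
#'
#' The full group-comparison workflow for a single variable:
#' Shapiro–Wilk branch choice ([choose_branch()]), the omnibus and
#' pairwise tests of the selected branch, branch-matched group
#' summaries (mean ± SD or median ± IQR), and the compact letter
#' display. `NA` values (undefined ratios) are dropped with a warning.
#' Constant data are reported untested with every group lettered "a".
#'
#' @param values Numeric response values (one per animal).
#' @param groups Group labels, same length.
#' @param alpha Significance level.
#' @param variable Optional variable name carried into the result.
#' @param branch Force `"parametric"` or `"nonparametric"` instead of
#'   the normality-based choice (`"auto"`).
#' @return A `group_comparison` list: `variable`, `branch`,
#'   `normality_p`, `statistic`, `p_value`, `pairwise`, `summaries`
#'   (data.frame group/location/dispersion/n/letters), `letters`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05, variable = NA_character_,
                           branch = c("auto", "parametric", "nonparametric")) {
  branch <- match.arg(branch)
  g <- as_group_factor(groups)
  keep <- !is.na(values)
  if (!all(keep)) {
    warning(sprintf("%d undefined value(s) dropped for %s",
                    sum(!keep), variable))
    values <- values[keep]
    g <- droplevels(g[keep])
  }
  lv <- levels(g)

  degenerate <- length(unique(values)) == 1L
  if (degenerate) {
    # exact-tie convention: nothing to test, every group shares "a"
    summ <- summarize_by_group(values, g, "nonparametric")
    summ$letters <- rep("a", nrow(summ))
    return(structure(
      list(variable = variable, branch = "nonparametric",
           normality_p = NA_real_, statistic = NA_real_, p_value = NA_real_,
           pairwise = pairwise_matrix(lv), summaries = summ,
           letters = stats::setNames(summ$letters, summ$group),
           degenerate = TRUE),
      class = "group_comparison"
    ))
  }

  if (branch == "auto") {
    ch <- choose_branch(values, g, alpha)
    use_branch <- ch$branch
    normality_p <- ch$normality_p
  } else {
    use_branch <- branch
    normality_p <- NA_real_
  }

  cmp <- if (use_branch == "parametric") {
    parametric_compare(values, g, alpha)
  } else {
    nonparametric_compare(values, g, alpha)
  }
  letters <- compact_letters(cmp$pairwise, alpha)
  summ <- summarize_by_group(values, g, use_branch)
  summ$letters <- letters[summ$group]

  structure(
    list(variable = variable, branch = use_branch,
         normality_p = normality_p,
         statistic = cmp$statistic, p_value = cmp$p_value,
         pairwise = cmp$pairwise, summaries = summ, letters = letters,
         degenerate = FALSE),
    class = "group_comparison"
  )
}

summarize_by_group <- function(values, g, branch) {
  loc_fun <- if (branch == "parametric") mean else stats::median
  disp_fun <- if (branch == "parametric") stats::sd else stats::IQR
  data.frame(
    group = levels(g),
    location = as.numeric(tapply(values, g, loc_fun)),
    dispersion = as.numeric(tapply(values, g, disp_fun)),
    n = as.integer(tapply(values, g, length)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison%s [%s]\n",
              if (is.na(x$variable)) "" else paste0(": ", x$variable),
              x$branch))
  if (!is.na(x$p_value)) {
    cat(sprintf("  omnibus statistic = %.4g, p = %.4g\n",
                x$statistic, x$p_value))
  } else {
    cat("  untested (constant data)\n")
  }
  s <- x$summaries
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.4g ± %.4g %s (n=%d)\n", s$group[i],
                s$location[i], s$dispersion[i], s$letters[i], s$n[i]))
  }
  invisible(x)
}
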