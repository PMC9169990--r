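#' Compact letter display from a pairwise p-value matrix
#'
#' Assigns lowercase letters to groups with the insert-and-absorb
#' algorithm: starting from one set holding every group, each
#' significant pair splits every set containing both members into two
#' (dropping one member each), and sets contained in another set are
#' absorbed. Letters are then assigned in group order starting at "a".
#' Two groups share at least one letter if and only if their pairwise
#' p-value is not below `alpha`; `NA` p-values are treated as
#' not-significant.
#'
#' @param pairwise Square symmetric matrix of pairwise p-values with
#'   group names as dimnames (diagonal ignored).
#' @param alpha Significance level.
#' @return Named character vector: one letter string per group.
#' @examples
#' p <- matrix(c(NA, 0.001, 0.001, 0.001, NA, 0.8, 0.001, 0.8, NA), 3,
#'             dimnames = list(c("c", "t1", "t2"), c("c", "t1", "t2")))
#' compact_letters(p, 0.05)  # c = "a", t1 = t2 = "b"
#' @export
compact_letters <- function(pairwise, alpha = 0.05) {
  if (!is.matrix(pairwise) || nrow(pairwise) != ncol(pairwise)) {
    stop("`pairwise` must be a square matrix")
  }
  lv <- rownames(pairwise)
  if (is.null(lv) || !identical(lv, colnames(pairwise))) {
    stop("`pairwise` must have matching row/column group names")
  }
  k <- length(lv)
  if (k > 26L) stop("more than 26 groups are not supported")

  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      p <- pairwise[i, j]
      if (is.na(p) || p >= alpha) next
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb: drop sets fully contained in another set
      new_sets <- unique(lapply(new_sets, sort))
      keep <- vapply(seq_along(new_sets), function(a) {
        !any(vapply(seq_along(new_sets), function(b) {
          b != a && length(new_sets[[b]]) > length(new_sets[[a]]) &&
            all(new_sets[[a]] %in% new_sets[[b]])
        }, logical(1)))
      }, logical(1))
      sets <- new_sets[keep]
    }
  }

  sets <- sets[order(vapply(sets, min, numeric(1)))]
  out <- stats::setNames(rep("", k), lv)
  for (si in seq_along(sets)) {
    letter <- letters[si]
    for (m in sets[[si]]) out[m] <- paste0(out[m], letter)
  }
  out
}
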