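#' Rank PCA coefficients by Fisher Discriminant Ratio
#'
#' Scores each coefficient (column) by its univariate class separability
#' `FDR = (mu1 - mu2)^2 / (s1^2 + s2^2)`, where `mu_i` and `s_i^2` are the
#' mean and sample variance of class i's coefficients, and orders
#' components by descending FDR (ties broken by ascending component index,
#' for reproducibility). Class 1 is label `-1`, class 2 is label `+1`; the
#' score is symmetric in the two classes.
#'
#' Degenerate columns: if both class variances are zero but the means
#' differ, the column separates the classes perfectly and receives `Inf`
#' (ranked first); if the means are also equal the score is 0.
#'
#' @param coefficients n_samples x n_components numeric matrix of PCA
#'   coefficients (or any feature columns).
#' @param labels Vector of class labels in `{-1, +1}`, one per row. Both
#'   classes need at least 2 samples for the variances to be defined.
#' @return An object of class `fdr_ranking`: list with `fdr_scores`,
#'   `order` (permutation sorting scores nonincreasing), and `class_stats`
#'   (tibble of per-class per-component means and variances).
#' @export
#' @examples
#' set.seed(1)
#' co <- cbind(c(rnorm(5, 0), rnorm(5, 2)), rnorm(10))
#' r <- fdr_rank(co, rep(c(-1, 1), each = 5))
#' r$order[1]  # the shifted column ranks first
fdr_rank <- function(coefficients, labels) {
  co <- as.matrix(coefficients)
  labels <- as.numeric(labels)
  if (length(labels) != nrow(co))
    stopf("labels length (%d) != number of rows (%d)", length(labels), nrow(co))
  i1 <- labels < 0
  i2 <- labels > 0
  if (sum(i1) < 2L || sum(i2) < 2L)
    stopf("each class needs >= 2 samples (got %d and %d)", sum(i1), sum(i2))

  mu1 <- colMeans(co[i1, , drop = FALSE])
  mu2 <- colMeans(co[i2, , drop = FALSE])
  v1 <- apply(co[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(co[i2, , drop = FALSE], 2L, stats::var)

  num <- (mu1 - mu2)^2
  den <- v1 + v2
  fdr <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))

  structure(
    list(
      fdr_scores = fdr,
      order = order(-fdr, seq_along(fdr)),
      class_stats = tibble::tibble(
        component = rep(seq_along(fdr), 2L),
        class = rep(c("1 (-1)", "2 (+1)"), each = length(fdr)),
        mean = c(mu1, mu2),
        variance = c(v1, v2)
      )
    ),
    class = "fdr_ranking"
  )
}

#' @export
print.fdr_ranking <- function(x, ...) {
  cat(sprintf("<fdr_ranking> %d components; top: %s\n",
              length(x$fdr_scores),
              paste(utils::head(x$order, 4L), collapse = ", ")))
  invisible(x)
}

#' Tidy an FDR ranking
#'
#' @param x An `fdr_ranking`.
#' @param ... Unused.
#' @return A tibble with `component`, `fdr` and `rank` (1 = most
#'   discriminative), sorted by rank.
#' @export
tidy.fdr_ranking <- function(x, ...) {
  tibble::tibble(
    component = x$order,
    fdr = x$fdr_scores[x$order],
    rank = seq_along(x$order)
  )
}
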