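#' Stratified partition of subjects into cross-validation subsets
#'
#' Randomly divides subjects into `n_subsets` folds preserving class
#' proportions: within each class subjects are shuffled (seeded) and dealt
#' round-robin, the second class continuing where the first stopped so
#' that no fold is left empty even when `n_subsets` exceeds a class size
#' (e.g. 17 + 17 subjects into 20 folds). Per-class fold sizes differ by
#' at most one.
#'
#' @param labels Vector of labels in `{-1, +1}`.
#' @param n_subsets Number of folds (at most the number of subjects).
#' @param seed Integer seed; the plan is a pure function of
#'   `(labels, n_subsets, seed)`.
#' @return An object of class `fold_plan`: tibble with `subject` (row
#'   index), `label` and `fold`, plus attributes `n_subsets` and `seed`.
#' @export
stratified_partition <- function(labels, n_subsets, seed = 1L) {
  labels <- as.numeric(labels)
  n <- length(labels)
  if (n_subsets > n)
    stopf("n_subsets (%d) exceeds number of subjects (%d)", n_subsets, n)
  if (n_subsets < 2L) stopf("need at least 2 subsets")
  if (!all(c(-1, 1) %in% labels)) stopf("both classes must be present")

  fold <- integer(n)
  offset <- 0L
  with_seed(seed, {
    for (cls in c(-1, 1)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% n_subsets) + 1L
      offset <- offset + length(idx)
    }
  })
  plan <- tibble::tibble(subject = seq_len(n), label = labels, fold = fold)
  attr(plan, "n_subsets") <- as.integer(n_subsets)
  attr(plan, "seed") <- as.integer(seed)
  class(plan) <- c("fold_plan", class(plan))
  plan
}

#' Run one cross-validation fold across a range of coefficient counts
#'
#' The leakage-free fold protocol: PCA is fitted on the training rows
#' only; training and test rows are projected into that subspace; the
#' Fisher-ratio ranking is computed from training coefficients only; for
#' each requested `k` an SVM is trained on the first `k` ranked training
#' coefficients and applied to the test rows. If `k` exceeds the
#' components available in this fold, all available components are used
#' and the substitution is recorded in `k_used`.
#'
#' @param train_x,test_x Numeric matrices (subjects x voxels).
#' @param train_labels,test_labels Labels in `{-1, +1}`.
#' @param k_values Integer vector of coefficient counts to evaluate.
#' @param cost SVM soft-margin cost.
#' @return List with `predictions` (tibble: `k`, `k_used`, `test_row`,
#'   `truth`, `prediction`, `decision_value`) and `artifacts` (fitted PCA,
#'   ranking, and per-k SVMs) for audit.
#' @export
run_fold <- function(train_x, train_labels, test_x, test_labels,
                     k_values, cost = 1) {
  pca <- fit_pca(train_x)
  train_co <- project(pca, train_x)
  test_co <- project(pca, test_x)
  ranking <- fdr_rank(train_co, train_labels)
  n_avail <- ncol(train_co)

  rows <- vector("list", length(k_values))
  svms <- vector("list", length(k_values))
  for (i in seq_along(k_values)) {
    k <- k_values[i]
    k_used <- min(k, n_avail)
    sel <- ranking$order[seq_len(k_used)]
    m <- svm_train(train_co[, sel, drop = FALSE], train_labels, cost = cost)
    dv <- decision_value(m, test_co[, sel, drop = FALSE])
    rows[[i]] <- tibble::tibble(
      k = k,
      k_used = k_used,
      test_row = seq_along(test_labels),
      truth = as.integer(test_labels),
      prediction = ifelse(dv >= 0, 1L, -1L),
      decision_value = dv
    )
    svms[[i]] <- m
  }
  list(
    predictions = dplyr::bind_rows(rows),
    artifacts = list(pca = pca, ranking = ranking, svms = svms,
                     n_available = n_avail)
  )
}

#' Classification metrics from pooled confusion counts
#'
#' Computes Accuracy, Specificity and Sensitivity from the counts of
#' correctly/incorrectly classified images of the first group (A, label
#' `-1`, the control-like group) and the second group (B, label `+1`, the
#' patient-like group). Accuracy is always `N_CC / N`. Two conventions are
#' offered for the class-wise rates:
#' \describe{
#'   \item{`"standard"`}{textbook definitions with same-group
#'     denominators: Specificity `= A_CC / (A_CC + A_IC)`,
#'     Sensitivity `= B_CC / (B_CC + B_IC)`.}
#'   \item{`"as-printed"`}{cross-group denominators,
#'     Specificity `= A_CC / (A_CC + B_IC)`,
#'     Sensitivity `= B_CC / (B_CC + A_IC)`, retained because some
#'     published formulations typeset the rates this way.}
#' }
#' A zero denominator yields `NA` (an undefined metric is never reported
#' as 0).
#'
#' @param counts List or one-row data frame with `A_CC`, `A_IC`, `B_CC`,
#'   `B_IC`.
#' @param convention `"standard"` (default) or `"as-printed"`.
#' @return A one-row tibble: `n`, `n_correct`, `accuracy`, `specificity`,
#'   `sensitivity`, `convention`.
#' @export
#' @examples
#' compute_metrics(list(A_CC = 10, A_IC = 7, B_CC = 15, B_IC = 2))
compute_metrics <- function(counts, convention = c("standard", "as-printed")) {
  convention <- match.arg(convention)
  a_cc <- counts$A_CC; a_ic <- counts$A_IC
  b_cc <- counts$B_CC; b_ic <- counts$B_IC
  n <- a_cc + a_ic + b_cc + b_ic
  if (n <= 0) stopf("no images classified")
  n_cc <- a_cc + b_cc
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  if (convention == "standard") {
    spec <- safe_div(a_cc, a_cc + a_ic)
    sens <- safe_div(b_cc, b_cc + b_ic)
  } else {
    spec <- safe_div(a_cc, a_cc + b_ic)
    sens <- safe_div(b_cc, b_cc + a_ic)
  }
  tibble::tibble(
    n = n, n_correct = n_cc,
    accuracy = n_cc / n,
    specificity = spec,
    sensitivity = sens,
    convention = convention
  )
}

pool_counts <- function(truth, prediction) {
  list(
    A_CC = sum(truth < 0 & prediction < 0),
    A_IC = sum(truth < 0 & prediction > 0),
    B_CC = sum(truth > 0 & prediction > 0),
    B_IC = sum(truth > 0 & prediction < 0)
  )
}

#' Stratified k-fold cross-validation of the PCA + FDR + SVM pipeline
#'
#' Evaluates the full decoding pipeline on a vectorized cohort: for each
#' fold, PCA and the Fisher-ratio ranking are fitted on the training
#' subjects alone, test subjects are projected into the training subspace,
#' and a linear SVM trained on the first `k` ranked coefficients predicts
#' them. Test predictions are pooled across folds into one confusion table
#' per `k` (metrics count images, so pooling — not per-fold averaging —
#' gives a single coherent `N`), and metric curves as a function of `k`
#' are returned together with the best operating point (highest accuracy;
#' ties go to the smallest `k`).
#'
#' @param fm A `feature_matrix` from [vectorize()] (carries the labels),
#'   or a bare matrix if `labels` is given.
#' @param n_folds Number of folds (20 and 10 are typical choices).
#' @param k_range Coefficient counts to evaluate; default `1:k_max` where
#'   `k_max` is the largest training-fold size minus 1.
#' @param cost SVM soft-margin cost (default 1).
#' @param seed Seed for the fold assignment.
#' @param convention Metric convention, see [compute_metrics()].
#' @param labels Optional labels when `fm` is a bare matrix.
#' @return An object of class `cv_result`: list with `metrics` (tibble of
#'   per-k pooled Accuracy/Specificity/Sensitivity), `best` (one-row
#'   tibble at the best k), `predictions` (per fold/subject/k),
#'   `fold_plan`, `fold_log` (folds where `k` was capped), `n_folds`,
#'   `cost`, `seed`, `convention`.
#' @export
run_cv <- function(fm, n_folds = 20, k_range = NULL, cost = 1, seed = 1L,
                   convention = c("standard", "as-printed"), labels = NULL) {
  convention <- match.arg(convention)
  if (inherits(fm, "feature_matrix")) {
    X <- fm$values
    labels <- labels %||% fm$labels
  } else {
    X <- as.matrix(fm)
    if (is.null(labels)) stopf("labels must be supplied with a bare matrix")
  }
  labels <- as.numeric(labels)
  n <- nrow(X)

  plan <- stratified_partition(labels, n_folds, seed = seed)
  fold_sizes <- table(plan$fold)
  k_max_global <- (n - max(fold_sizes)) - 1L
  if (is.null(k_range)) k_range <- seq_len(k_max_global)

  preds <- vector("list", n_folds)
  log_rows <- list()
  for (f in seq_len(n_folds)) {
    te <- plan$subject[plan$fold == f]
    tr <- plan$subject[plan$fold != f]
    res <- run_fold(X[tr, , drop = FALSE], labels[tr],
                    X[te, , drop = FALSE], labels[te],
                    k_values = k_range, cost = cost)
    p <- res$predictions
    p$fold <- f
    p$subject <- te[p$test_row]
    preds[[f]] <- p
    capped <- unique(p$k[p$k_used < p$k])
    if (length(capped) > 0L) {
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        fold = f, k_requested = capped,
        k_used = res$artifacts$n_available
      )
    }
  }
  preds <- dplyr::bind_rows(preds)

  metrics <- dplyr::bind_rows(lapply(k_range, function(k) {
    pk <- preds[preds$k == k, ]
    m <- compute_metrics(pool_counts(pk$truth, pk$prediction), convention)
    dplyr::bind_cols(tibble::tibble(k = k), m)
  }))

  best_i <- which.max(metrics$accuracy)  # first max = smallest k on ties
  structure(
    list(
      metrics = metrics,
      best = metrics[best_i, ],
      predictions = preds,
      fold_plan = plan,
      fold_log = if (length(log_rows)) dplyr::bind_rows(log_rows)
                 else tibble::tibble(fold = integer(), k_requested = integer(),
                                     k_used = integer()),
      n_folds = as.integer(n_folds),
      cost = cost,
      seed = as.integer(seed),
      convention = convention
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<cv_result> %d-fold CV over k = %d..%d\n  best: k = %d, accuracy %.3f, specificity %.3f, sensitivity %.3f\n",
    x$n_folds, min(x$metrics$k), max(x$metrics$k),
    b$k, b$accuracy, b$specificity, b$sensitivity
  ))
  invisible(x)
}

#' Tidy a cross-validation result: the per-k metric curves
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with one row per evaluated k: `k`, `n`, `n_correct`,
#'   `accuracy`, `specificity`, `sensitivity`.
#' @export
tidy.cv_result <- function(x, ...) x$metrics

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble: `n_folds`, `best_k`, `accuracy`, `specificity`,
#'   `sensitivity`, `cost`, `seed`.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    n_folds = x$n_folds,
    best_k = x$best$k,
    accuracy = x$best$accuracy,
    specificity = x$best$specificity,
    sensitivity = x$best$sensitivity,
    cost = x$cost,
    seed = x$seed
  )
}

#' Plot cross-validated metrics against the number of PCA coefficients
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot with one line per metric.
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics[, c("k", "accuracy", "specificity", "sensitivity")],
    -"k", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Number of PCA coefficients (FDR-ranked)",
      y = "Pooled cross-validated value",
      colour = NULL,
      title = sprintf("%d-fold cross-validation", object$n_folds)
    ) +
    ggplot2::theme_minimal()
}
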