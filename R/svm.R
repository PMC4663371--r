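#' Train a linear soft-margin support vector machine
#'
#' Fits the maximal-margin separating hyperplane with soft-margin cost `C`
#' on labelled coefficient vectors. The decision function is the standard
#' kernel expansion `y(x) = sum_n a_n t_n <x, x_n> + b` over the support
#' samples, with `a_n` in `[0, C]` and `sum a_n t_n = 0`; predictions are
#' `sign(y(x))`, with the `y(x) = 0` tie resolved to class `+1`.
#'
#' Training is delegated to the libsvm solver (via \pkg{e1071}) with
#' feature scaling disabled; the returned model stores the dual weights,
#' support samples, bias and the equivalent primal weight vector
#' `w = sum a_n t_n x_n`, sign-canonicalized so that positive decision
#' values always mean class `+1`. Only the linear kernel is supported:
#' weight maps require the primal weight vector, which other kernels do
#' not provide.
#'
#' @param coefficients n_samples x n_features numeric matrix.
#' @param labels Class labels in `{-1, +1}`, both present.
#' @param cost Soft-margin cost `C` (positive; default 1). Large values
#'   approach the hard-margin solution on separable data.
#' @param kernel Must be `"linear"`; anything else is an error.
#' @return An object of class `linear_svm`: list with `dual_weights`
#'   (`a_n`, nonnegative, one per support sample), `support_labels`,
#'   `support_samples`, `support_index` (rows of the training matrix),
#'   `bias`, `weights` (primal `w`), `cost`, `n_features`.
#' @export
svm_train <- function(coefficients, labels, cost = 1, kernel = "linear") {
  if (!identical(kernel, "linear"))
    stopf("only the linear kernel is supported, got '%s'", kernel)
  X <- as.matrix(coefficients)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) stopf("labels must be in {-1, +1}")
  if (length(unique(labels)) < 2L) stopf("training data contain a single class")
  if (any(!is.finite(X))) stopf("coefficients contain non-finite values")
  if (cost <= 0) stopf("cost must be positive")

  fit <- e1071::svm(X, factor(labels, levels = c(-1, 1)),
                    type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE, tolerance = 1e-8)
  at <- as.numeric(fit$coefs)          # a_n * t_n in libsvm's internal sign
  sv <- as.matrix(fit$SV)
  b <- -fit$rho
  # libsvm's positive decision side is the class of the first training
  # sample; canonicalize so positive always means +1.
  if (labels[1] < 0) {
    at <- -at
    b <- -b
  }
  tn <- labels[fit$index]
  structure(
    list(
      dual_weights = at * tn,          # a_n >= 0
      support_labels = tn,
      support_samples = sv,
      support_index = fit$index,
      bias = b,
      weights = drop(crossprod(sv, at)),
      cost = cost,
      n_features = ncol(X)
    ),
    class = "linear_svm"
  )
}

#' Decision values of a linear SVM
#'
#' Evaluates `y(x) = sum_n a_n t_n <x, x_n> + b` through the stored dual
#' expansion. `sign(y)` is the predicted class; positive means `+1`.
#'
#' @param model A `linear_svm`.
#' @param x Numeric matrix (or single vector) of samples.
#' @return Numeric vector of decision values.
#' @export
decision_value <- function(model, x) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != model$n_features)
    stopf("sample has %d features, model expects %d", ncol(X), model$n_features)
  drop(X %*% crossprod(model$support_samples,
                       model$dual_weights * model$support_labels)) + model$bias
}

#' Predict class labels with a linear SVM
#'
#' @param object A `linear_svm`.
#' @param newdata Numeric matrix of samples.
#' @param ... Unused.
#' @return Integer vector of predicted labels in `{-1, +1}`; a decision
#'   value of exactly zero predicts `+1`.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  ifelse(decision_value(object, newdata) >= 0, 1L, -1L)
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> %d support vectors in %d features, C = %g, b = %.4g\n",
              length(x$dual_weights), x$n_features, x$cost, x$bias))
  invisible(x)
}

#' Tidy a linear SVM: one row per support sample
#'
#' @param x A `linear_svm`.
#' @param ... Unused.
#' @return Tibble with `sample` (training row index), `label` and
#'   `dual_weight`.
#' @export
tidy.linear_svm <- function(x, ...) {
  tibble::tibble(
    sample = x$support_index,
    label = x$support_labels,
    dual_weight = x$dual_weights
  )
}

#' @export
glance.linear_svm <- function(x, ...) {
  tibble::tibble(
    n_support = length(x$dual_weights),
    n_features = x$n_features,
    cost = x$cost,
    bias = x$bias,
    weight_norm = sqrt(sum(x$weights^2))
  )
}
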