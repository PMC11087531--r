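#' Kernel and penalty parameters of the lambda-scaled RBF SVM
#'
#' The classifier's kernel is `k(a, b) = exp(-||a - b||^2 / sigma^2) *
#' lambda`: a Gaussian similarity of width `sigma`, rescaled by `lambda`
#' (`lambda = 1` recovers the standard Gaussian kernel).  `cost` is the
#' soft-margin error penalty C.
#'
#' @param sigma Positive kernel width.
#' @param lambda Positive kernel multiplier (default 1).
#' @param cost Positive error penalty (default 1).
#' @return A `kernel_params` list.
#' @export
kernel_params <- function(sigma, lambda = 1, cost = 1) {
  stopifnot(is_scalar_number(sigma), sigma > 0,
            is_scalar_number(lambda), lambda > 0,
            is_scalar_number(cost), cost > 0)
  structure(list(sigma = sigma, lambda = lambda, cost = cost),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("RBF kernel: sigma = %.6g, lambda = %.6g, cost = %.6g\n",
              x$sigma, x$lambda, x$cost))
  invisible(x)
}

#' Lambda-scaled radial basis function kernel
#'
#' `k(a, b) = exp(-||a - b||^2 / sigma^2) * lambda`; symmetric in its two
#' arguments, equal to `lambda` at zero distance.
#'
#' @param a,b Numeric vectors of equal length.
#' @param params A [kernel_params()].
#' @return The scalar kernel value.
#' @export
rbf_kernel <- function(a, b, params) {
  if (length(a) != length(b)) stop_dim("rbf_kernel", length(a), length(b))
  exp(-sum((a - b)^2) / params$sigma^2) * params$lambda
}

# Squared Euclidean distance matrix between the rows of x (and optionally
# y); computed once per dataset and reused across kernel widths.
sq_dist <- function(x, y = NULL) {
  x <- as.matrix(x)
  if (is.null(y)) {
    s <- rowSums(x^2)
    d <- outer(s, s, "+") - 2 * tcrossprod(x)
  } else {
    y <- as.matrix(y)
    d <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  }
  pmax(d, 0)
}

#' Gram matrix of the lambda-scaled RBF kernel
#'
#' @param x Feature matrix (samples x features).
#' @param params A [kernel_params()].
#' @param y Optional second feature matrix for a rectangular Gram block.
#' @return The kernel matrix.
#' @export
rbf_gram <- function(x, params, y = NULL) {
  exp(-sq_dist(x, y) / params$sigma^2) * params$lambda
}

# Fit one binary soft-margin classifier (target class vs rest) and return
# a closure producing decision values oriented so larger = target.
fit_binary <- function(x, y01, params) {
  if (params$lambda == 1) {
    # Eq-28 kernel with lambda = 1 is exactly libsvm's radial kernel with
    # gamma = 1 / sigma^2.
    m <- e1071::svm(x, factor(y01, levels = c(0, 1)), kernel = "radial",
                    gamma = 1 / params$sigma^2, cost = params$cost,
                    scale = FALSE)
    dv_train <- attr(stats::predict(m, x, decision.values = TRUE),
                     "decision.values")[, 1]
    flip <- mean(dv_train[y01 == 1]) < mean(dv_train[y01 == 0])
    function(newx) {
      dv <- attr(stats::predict(m, newx, decision.values = TRUE),
                 "decision.values")[, 1]
      if (flip) -dv else dv
    }
  } else {
    K <- kernlab::as.kernelMatrix(rbf_gram(x, params))
    m <- kernlab::ksvm(K, factor(y01, levels = c(0, 1)), type = "C-svc",
                       C = params$cost)
    sv <- kernlab::SVindex(m)
    dv_train <- kernlab::predict(
      m, kernlab::as.kernelMatrix(K[, sv, drop = FALSE]), type = "decision")[, 1]
    flip <- mean(dv_train[y01 == 1]) < mean(dv_train[y01 == 0])
    function(newx) {
      Kt <- rbf_gram(newx, params, x)[, sv, drop = FALSE]
      dv <- kernlab::predict(m, kernlab::as.kernelMatrix(Kt),
                             type = "decision")[, 1]
      if (flip) -dv else dv
    }
  }
}

#' Train a one-vs-all multiclass RBF SVM
#'
#' Fits one binary soft-margin classifier per class (the class's samples
#' labelled 1, the rest 0) with the lambda-scaled RBF kernel; prediction
#' assigns the class whose classifier yields the largest decision value.
#' The margin solver is delegated to libsvm (via e1071) when `lambda = 1`
#' and to kernlab with the lambda-scaled precomputed Gram matrix
#' otherwise.
#'
#' @param x Feature matrix (samples x features).
#' @param y Class labels (factor or coercible); at least two classes.
#' @param params A [kernel_params()].
#' @return An `ovr_svm` model with a [predict.ovr_svm()] method.
#' @export
train_one_vs_all <- function(x, y, params) {
  x <- as.matrix(x)
  y <- as.factor(y)
  classes <- levels(droplevels(y))
  if (length(classes) < 2) {
    stop("one-vs-all training needs at least two classes", call. = FALSE)
  }
  deciders <- lapply(classes, function(cl) {
    fit_binary(x, as.integer(y == cl), params)
  })
  names(deciders) <- classes
  structure(list(classes = classes, deciders = deciders, params = params,
                 n_train = nrow(x),
                 support = as.vector(table(droplevels(y)))),
            class = "ovr_svm")
}

#' Predict classes or decision values from a one-vs-all RBF SVM
#'
#' @param object An `ovr_svm` model.
#' @param newdata Feature matrix.
#' @param type `"class"` (default) or `"decision"` for the per-class
#'   decision-value matrix.
#' @param ... Unused.
#' @return A factor of predicted classes, or a numeric matrix of decision
#'   values with one column per class.
#' @export
predict.ovr_svm <- function(object, newdata, type = c("class", "decision"),
                            ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  dv <- vapply(object$deciders, function(f) f(newdata),
               numeric(nrow(newdata)))
  if (!is.matrix(dv)) dv <- matrix(dv, nrow = 1)
  colnames(dv) <- object$classes
  if (type == "decision") return(dv)
  factor(object$classes[max.col(dv, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.ovr_svm <- function(x, ...) {
  cat(sprintf("One-vs-all RBF SVM: %d classes (%s), %d training samples\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$n_train))
  print(x$params)
  invisible(x)
}

#' Stratified cross-validated accuracy of the one-vs-all RBF SVM
#'
#' @param x Feature matrix.
#' @param y Class labels; every class needs at least `k` members.
#' @param params A [kernel_params()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return Mean held-out accuracy over the `k` folds, in `[0, 1]`.
#' @export
cv_accuracy <- function(x, y, params, k = 10, seed = 1) {
  x <- as.matrix(x)
  y <- as.factor(y)
  fold <- stratified_kfold(y, k, seed)
  acc <- vapply(seq_len(k), function(i) {
    tr <- fold != i
    m <- train_one_vs_all(x[tr, , drop = FALSE], droplevels(y[tr]), params)
    mean(as.character(predict(m, x[!tr, , drop = FALSE])) ==
           as.character(y[!tr]))
  }, numeric(1))
  mean(acc)
}
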