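#' Hyperparameter search space
#'
#' Declares the box searched by [optimize_hyperparams()]: per parameter a
#' `(low, high)` range on a linear or log scale, plus the number of bits
#' used by binary optimizers to encode each parameter.  The defaults
#' follow the standard RBF grid conventions: penalty in `[2^-5, 2^15]` and
#' width in `[2^-8, 2^8]`, both log-scaled.
#'
#' @param parameters Named list; each element is
#'   `list(low =, high =, scale = "linear"|"log")`.
#' @param bits_per_parameter Bits per parameter for binary optimizers
#'   (`>= 2`).
#' @return A `search_space` object.
#' @export
search_space <- function(parameters = list(
                           cost = list(low = 2^-5, high = 2^15,
                                       scale = "log"),
                           sigma = list(low = 2^-8, high = 2^8,
                                        scale = "log")),
                         bits_per_parameter = 16) {
  stopifnot(bits_per_parameter >= 2)
  for (p in parameters) {
    stopifnot(p$low < p$high)
    if (identical(p$scale, "log")) stopifnot(p$low > 0)
  }
  structure(list(parameters = parameters,
                 bits_per_parameter = as.integer(bits_per_parameter)),
            class = "search_space")
}

# Map a unit-box point (one coordinate per parameter) to parameter values
# on the declared scales.
unit_to_params <- function(u, space) {
  vals <- mapply(function(ui, p) {
    if (identical(p$scale, "log")) {
      exp(log(p$low) + ui * (log(p$high) - log(p$low)))
    } else {
      p$low + ui * (p$high - p$low)
    }
  }, u, space$parameters)
  stats::setNames(as.list(vals), names(space$parameters))
}

#' Decode a bit vector into kernel parameters
#'
#' Fixed-point decoding: each parameter's bit block maps its integer value
#' `v` to `low + v / (2^bits - 1) * (high - low)` on the declared scale
#' (log scale interpolates the logarithms).  All-zero bits give the lower
#' bound, all-one bits the upper bound.
#'
#' @param bits 0/1 vector of length `n_parameters * bits_per_parameter`.
#' @param space A [search_space()].
#' @return Named list of decoded parameter values.
#' @export
decode_params <- function(bits, space) {
  stopifnot(inherits(space, "search_space"))
  np <- length(space$parameters)
  bpp <- space$bits_per_parameter
  if (length(bits) != np * bpp) {
    stop_dim("decode_params", length(bits), np * bpp)
  }
  u <- vapply(seq_len(np), function(j) {
    b <- bits[((j - 1) * bpp + 1):(j * bpp)]
    sum(b * 2^((bpp - 1):0)) / (2^bpp - 1)
  }, numeric(1))
  unit_to_params(u, space)
}

#' Optimizer-driven hyperparameter search for the RBF SVM
#'
#' Minimizes `1 - cv_accuracy` over the declared search space with one of
#' the pack optimizers: the continuous GWO searches the (scaled)
#' parameters directly; the binary optimizers drive them through the
#' fixed-point decoding of [decode_params()].  The returned model is
#' retrained on the full data with the best parameters.
#'
#' @param x Feature matrix.
#' @param y Class labels.
#' @param optimizer `"gwo"`, `"bgwo"` or `"iqi"`.
#' @param space A [search_space()] over `cost` and `sigma` (and optionally
#'   `lambda`).
#' @param cv_k Cross-validation folds for the fitness (default 10).
#' @param population_size,max_iterations Pack settings.
#' @param seed Seed for both the optimizer stream and the fold assignment.
#' @param lambda Fixed kernel multiplier used when `lambda` is not part of
#'   the search space (default 1).
#' @return An `svm_tune` object: `params` (the best [kernel_params()]),
#'   `model` (retrained `ovr_svm`), `cv_accuracy`, and `result` (the
#'   optimizer's `gwo_result` trace).
#' @export
optimize_hyperparams <- function(x, y, optimizer = c("gwo", "bgwo", "iqi"),
                                 space = search_space(), cv_k = 10,
                                 population_size = 8, max_iterations = 20,
                                 seed = 1, lambda = 1) {
  optimizer <- match.arg(optimizer)
  x <- as.matrix(x)
  y <- as.factor(y)
  np <- length(space$parameters)

  as_kp <- function(vals) {
    kernel_params(sigma = vals$sigma,
                  lambda = vals$lambda %||% lambda,
                  cost = vals$cost)
  }
  fitness_from_vals <- function(vals) {
    1 - cv_accuracy(x, y, as_kp(vals), k = cv_k, seed = seed)
  }

  if (optimizer == "gwo") {
    cfg <- gwo_config(np, population_size, max_iterations, c(0, 1), seed)
    res <- gwo(function(u) fitness_from_vals(unit_to_params(u, space)), cfg)
    best_vals <- unit_to_params(res$best_position, space)
  } else {
    d <- np * space$bits_per_parameter
    obj <- function(bits) fitness_from_vals(decode_params(bits, space))
    res <- if (optimizer == "bgwo") {
      bgwo(obj, gwo_config(d, population_size, max_iterations, c(0, 1),
                           seed))
    } else {
      iqi_bgwo(obj, iqi_config(d, population_size, max_iterations, c(0, 1),
                               seed))
    }
    best_vals <- decode_params(res$best_position, space)
  }
  params <- as_kp(best_vals)
  structure(list(params = params,
                 model = train_one_vs_all(x, y, params),
                 cv_accuracy = 1 - res$best_fitness,
                 result = res,
                 optimizer = optimizer),
            class = "svm_tune")
}

#' @export
print.svm_tune <- function(x, ...) {
  cat(sprintf("SVM hyperparameter search (%s): cv accuracy %.4f\n",
              x$optimizer, x$cv_accuracy))
  print(x$params)
  invisible(x)
}

#' @export
predict.svm_tune <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
coef.svm_tune <- function(object, ...) {
  unlist(object$params[c("sigma", "lambda", "cost")])
}
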