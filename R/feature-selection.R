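#' Fitness specification for wrapper feature selection
#'
#' The wrapper fitness trades the classifier's cross-validated error rate
#' against the relative subset size:
#' `fitness = q * error_rate + e * |R| / |C|` with `e = 1 - q`.  The
#' defaults `q = 0.99`, `e = 0.01` weight accuracy heavily while still
#' rewarding smaller subsets.
#'
#' @param q Error-rate weight in `[0, 1]` (default 0.99); `e = 1 - q`.
#' @param classifier_cv Cross-validation folds of the wrapper classifier.
#' @param classifier_params A [kernel_params()] for the wrapper
#'   classifier, or `NULL` (default) for mid-range parameters with the
#'   kernel width scaled to the masked subset size
#'   (`sigma = sqrt(subset_size)`, `cost = 10`): the wrapper deliberately
#'   avoids nested hyperparameter optimization so each fitness evaluation
#'   costs one cross-validation.
#' @return An `fs_spec` list with `q`, `e`, `classifier_cv`,
#'   `classifier_params`.
#' @export
fs_spec <- function(q = 0.99, classifier_cv = 10, classifier_params = NULL) {
  stopifnot(is_scalar_number(q), q >= 0, q <= 1)
  structure(list(q = q, e = 1 - q, classifier_cv = classifier_cv,
                 classifier_params = classifier_params),
            class = "fs_spec")
}

#' Wrapper feature-selection fitness
#'
#' `q * error_rate + e * subset_size / total_features`; monotone
#' increasing in both the error rate and the subset size.  An empty
#' subset is rejected here — the optimizer assigns it the sentinel value
#' `1 + e`, worse than any feasible fitness.
#'
#' @param error_rate Classifier error in `[0, 1]`.
#' @param subset_size Number of selected features, `>= 1`.
#' @param total_features Total number of features, `>= 1`.
#' @param spec An [fs_spec()].
#' @return The scalar fitness.
#' @export
fs_fitness <- function(error_rate, subset_size, total_features, spec) {
  stopifnot(inherits(spec, "fs_spec"),
            error_rate >= 0, error_rate <= 1,
            total_features >= 1, subset_size <= total_features)
  if (subset_size < 1) {
    stop("empty feature subsets are handled upstream (sentinel 1 + e)",
         call. = FALSE)
  }
  spec$q * error_rate + spec$e * subset_size / total_features
}

#' Wrapper feature selection with a binary pack optimizer
#'
#' Optimizes a binary feature mask against [fs_fitness()], where the
#' error rate is `1 - cv_accuracy` of the lambda-scaled RBF SVM restricted
#' to the masked features.  Empty masks receive the sentinel fitness
#' `1 + e` and are never returned.  Fitness values are memoized per mask,
#' so repeated visits to a mask cost nothing.
#'
#' @param x Feature matrix (samples x features).
#' @param y Class labels.
#' @param optimizer `"iqi"` (default) or `"bgwo"`.
#' @param spec An [fs_spec()].
#' @param population_size,max_iterations Pack settings.
#' @param seed Seed for the optimizer and fold assignment.
#' @return A `feature_selection` object: `selected` (logical mask),
#'   `fitness`, `error_rate`, `subset_size`, `eliminated_count`,
#'   `optimal_iteration`, `trajectory` and the full optimizer `result`.
#' @export
select_features <- function(x, y, optimizer = c("iqi", "bgwo"),
                            spec = fs_spec(), population_size = 8,
                            max_iterations = 100, seed = 1) {
  optimizer <- match.arg(optimizer)
  x <- as.matrix(x)
  y <- as.factor(y)
  p <- ncol(x)
  # Default wrapper kernel: width scaled to the masked subset size
  # (sigma = sqrt(k)), so sparse masks get a properly calibrated kernel.
  params_for <- function(k) {
    spec$classifier_params %||% kernel_params(sigma = sqrt(k), cost = 10)
  }
  cache <- new.env(parent = emptyenv())
  eval_mask <- function(bits) {
    if (sum(bits) == 0) return(1 + spec$e)
    key <- paste(bits, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    err <- 1 - cv_accuracy(x[, bits == 1, drop = FALSE], y,
                           params_for(sum(bits)),
                           k = spec$classifier_cv, seed = seed)
    f <- fs_fitness(err, sum(bits), p, spec)
    cache[[key]] <- f
    f
  }
  res <- if (optimizer == "bgwo") {
    bgwo(eval_mask, gwo_config(p, population_size, max_iterations, c(0, 1),
                               seed))
  } else {
    iqi_bgwo(eval_mask, iqi_config(p, population_size, max_iterations,
                                   c(0, 1), seed))
  }
  mask <- res$best_position == 1
  params <- params_for(sum(mask))
  err <- 1 - cv_accuracy(x[, mask, drop = FALSE], y, params,
                         k = spec$classifier_cv, seed = seed)
  structure(list(selected = mask,
                 fitness = res$best_fitness,
                 error_rate = err,
                 subset_size = sum(mask),
                 eliminated_count = p - sum(mask),
                 optimal_iteration = res$optimal_iteration,
                 trajectory = res$trajectory,
                 spec = spec, params = params,
                 optimizer = optimizer, result = res),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("Wrapper feature selection (%s): %d of %d features kept\n",
              x$optimizer, x$subset_size,
              x$subset_size + x$eliminated_count))
  cat(sprintf("  fitness %.4f (error rate %.4f), optimum at iteration %d\n",
              x$fitness, x$error_rate, x$optimal_iteration))
  cat("  mask:", paste(as.integer(x$selected), collapse = ""), "\n")
  invisible(x)
}

#' @export
summary.feature_selection <- function(object, ...) {
  cat(sprintf("Selected features: %s\n",
              paste(which(object$selected), collapse = ", ")))
  print(object)
  invisible(object)
}

#' Summarize repeated feature-selection trials
#'
#' Collects per-trial rows (hyperparameters plus outcome) and appends the
#' exact arithmetic mean of every numeric column; rounding happens only
#' when the summary is printed.
#'
#' @param trials A data frame with one row per trial; numeric columns are
#'   averaged, other columns report `"varied"` unless constant.
#' @return A `trial_summary` object: the `trials` and the `means` row.
#' @export
summarize_trials <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1)
  means <- lapply(trials, function(col) {
    if (is.numeric(col)) {
      mean(col)
    } else if (length(unique(col)) == 1) {
      col[1]
    } else {
      "varied"
    }
  })
  structure(list(trials = trials, means = as.data.frame(means)),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, digits = 4, ...) {
  print(x$trials, row.names = FALSE)
  cat("--\nColumn means:\n")
  m <- x$means
  num <- vapply(m, is.numeric, logical(1))
  m[num] <- lapply(m[num], signif, digits = digits)
  print(m, row.names = FALSE)
  invisible(x)
}
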