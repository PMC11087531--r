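# The ten classical test functions of the original grey-wolf benchmark set:
# five unimodal (F1-F5) and five multimodal (F6-F10), with their canonical
# boxes and known optima.

benchmark_defs <- function() {
  u <- function(x, a, k, m) {
    ifelse(x > a, k * (x - a)^m, ifelse(x < -a, k * (-x - a)^m, 0))
  }
  list(
    F1 = list(name = "Sphere", box = 100,
              fn = function(x) sum(x^2),
              opt_at = function(d) rep(0, d), opt = function(d) 0),
    F2 = list(name = "Schwefel 2.22", box = 10,
              fn = function(x) sum(abs(x)) + prod(abs(x)),
              opt_at = function(d) rep(0, d), opt = function(d) 0),
    F3 = list(name = "Schwefel 1.2", box = 100,
              fn = function(x) sum(cumsum(x)^2),
              opt_at = function(d) rep(0, d), opt = function(d) 0),
    F4 = list(name = "Schwefel 2.21", box = 100,
              fn = function(x) max(abs(x)),
              opt_at = function(d) rep(0, d), opt = function(d) 0),
    F5 = list(name = "Generalized Rosenbrock", box = 30,
              fn = function(x) {
                n <- length(x)
                sum(100 * (x[-1] - x[-n]^2)^2 + (x[-n] - 1)^2)
              },
              opt_at = function(d) rep(1, d), opt = function(d) 0),
    F6 = list(name = "Generalized Schwefel", box = 500,
              fn = function(x) -sum(x * sin(sqrt(abs(x)))),
              opt_at = function(d) rep(420.968746, d),
              opt = function(d) -418.9828872724339 * d),
    F7 = list(name = "Rastrigin", box = 5.12,
              fn = function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10),
              opt_at = function(d) rep(0, d), opt = function(d) 0),
    F8 = list(name = "Ackley", box = 32,
              fn = function(x) {
                n <- length(x)
                -20 * exp(-0.2 * sqrt(sum(x^2) / n)) -
                  exp(sum(cos(2 * pi * x)) / n) + 20 + exp(1)
              },
              opt_at = function(d) rep(0, d), opt = function(d) 0),
    F9 = list(name = "Griewank", box = 600,
              fn = function(x) {
                sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
              },
              opt_at = function(d) rep(0, d), opt = function(d) 0),
    F10 = list(name = "Generalized Penalized", box = 50,
               fn = function(x) {
                 n <- length(x)
                 y <- 1 + (x + 1) / 4
                 pi / n * (10 * sin(pi * y[1])^2 +
                             sum((y[-n] - 1)^2 * (1 + 10 * sin(pi * y[-1])^2)) +
                             (y[n] - 1)^2) +
                   sum(u(x, 10, 100, 4))
               },
               opt_at = function(d) rep(-1, d), opt = function(d) 0)
  )
}

#' Benchmark test functions F1-F10
#'
#' `benchmark_function()` returns the definition of one of the ten
#' classical test functions (F1 Sphere, F2 Schwefel 2.22, F3 Schwefel 1.2,
#' F4 Schwefel 2.21, F5 Rosenbrock, F6 Schwefel, F7 Rastrigin, F8 Ackley,
#' F9 Griewank, F10 Penalized) with its canonical symmetric box and known
#' optimum; `evaluate_benchmark()` evaluates one of them at a point inside
#' its box.
#'
#' @param id One of `"F1"` ... `"F10"`.
#' @param dimension Problem dimension (default 30).
#' @return For `benchmark_function()`: a list of class
#'   `benchmark_function` with `id`, `name`, `dimension`, `lower`,
#'   `upper`, `fn`, `known_optimum` and `optimum_location`.
#' @export
benchmark_function <- function(id, dimension = 30) {
  defs <- benchmark_defs()
  id <- match.arg(id, names(defs))
  def <- defs[[id]]
  d <- as.integer(dimension)
  structure(list(id = id, name = def$name, dimension = d,
                 lower = rep(-def$box, d), upper = rep(def$box, d),
                 fn = def$fn,
                 known_optimum = def$opt(d),
                 optimum_location = def$opt_at(d)),
            class = "benchmark_function")
}

#' @rdname benchmark_function
#' @param x Numeric vector inside the function's box.
#' @export
evaluate_benchmark <- function(id, x) {
  bf <- benchmark_function(id, length(x))
  if (any(x < bf$lower - 1e-12) || any(x > bf$upper + 1e-12)) {
    stop(sprintf("point outside the %s box [%g, %g]", id,
                 bf$lower[1], bf$upper[1]), call. = FALSE)
  }
  bf$fn(x)
}

#' @export
print.benchmark_function <- function(x, ...) {
  cat(sprintf("%s: %s, dimension %d, box [%g, %g], optimum %.6g\n",
              x$id, x$name, x$dimension, x$lower[1], x$upper[1],
              x$known_optimum))
  invisible(x)
}

# Map a bit vector to a continuous point in the box: `bits_per_dim` bits
# per coordinate, fixed-point scaling (all-zero bits -> lower bound,
# all-one bits -> upper bound).  Shared with the hyperparameter decoder.
bits_to_box <- function(bits, lower, upper, bits_per_dim = 16) {
  d <- length(lower)
  stopifnot(length(bits) == d * bits_per_dim)
  vapply(seq_len(d), function(j) {
    b <- bits[((j - 1) * bits_per_dim + 1):(j * bits_per_dim)]
    v <- sum(b * 2^((bits_per_dim - 1):0))
    lower[j] + v / (2^bits_per_dim - 1) * (upper[j] - lower[j])
  }, numeric(1))
}

# Pure random search inside the box with the same evaluation budget as a
# pack run; baseline for the benchmark sanity properties.
random_search <- function(objective, config) {
  with_seed(config$seed, {
    n_eval <- config$population_size * (config$max_iterations + 1)
    best <- Inf; best_x <- NULL
    traj <- numeric(config$max_iterations + 1)
    k <- 0
    for (t in 0:config$max_iterations) {
      for (i in seq_len(config$population_size)) {
        x <- stats::runif(config$dimension, config$lower, config$upper)
        f <- objective(x)
        if (f < best) { best <- f; best_x <- x }
      }
      traj[t + 1] <- best
    }
    structure(list(best_position = best_x, best_fitness = best,
                   trajectory = traj,
                   optimal_iteration = NA_integer_,
                   algorithm = "random", config = config),
              class = "gwo_result")
  })
}

run_one_algorithm <- function(algorithm, bf, config) {
  switch(algorithm,
    gwo = {
      cfg <- gwo_config(bf$dimension, config$population_size,
                        config$max_iterations,
                        cbind(bf$lower, bf$upper), config$seed)
      gwo(bf$fn, cfg)
    },
    random = {
      cfg <- gwo_config(bf$dimension, config$population_size,
                        config$max_iterations,
                        cbind(bf$lower, bf$upper), config$seed)
      random_search(bf$fn, cfg)
    },
    bgwo = {
      bpd <- config$bits_per_dim %||% 16
      cfg <- gwo_config(bf$dimension * bpd, config$population_size,
                        config$max_iterations, c(0, 1), config$seed)
      obj <- function(bits) bf$fn(bits_to_box(bits, bf$lower, bf$upper, bpd))
      bgwo(obj, cfg)
    },
    iqi = {
      bpd <- config$bits_per_dim %||% 16
      cfg <- iqi_config(bf$dimension * bpd, config$population_size,
                        config$max_iterations, c(0, 1), config$seed,
                        s_threshold = config$s_threshold %||% 0.4)
      obj <- function(bits) bf$fn(bits_to_box(bits, bf$lower, bf$upper, bpd))
      iqi_bgwo(obj, cfg)
    },
    stop(sprintf("unknown algorithm '%s'", algorithm), call. = FALSE)
  )
}

#' Repeated optimizer trials on one benchmark function
#'
#' Runs `repetitions` independent trials (seed of repetition `r` is
#' `base_seed + r`), collecting the final best fitness of each and the
#' best/worst/mean/std/variance summary.  Binary optimizers (`"bgwo"`,
#' `"iqi"`) evaluate the continuous function through a fixed-point bit
#' encoding (default 16 bits per coordinate).
#'
#' @param algorithm `"gwo"`, `"bgwo"`, `"iqi"` or `"random"`.
#' @param id Benchmark id `"F1"` ... `"F10"`.
#' @param repetitions Number of independent trials.
#' @param population_size,max_iterations Pack settings per trial.
#' @param dimension Problem dimension (default 30).
#' @param base_seed Base of the per-repetition seed.
#' @param bits_per_dim Bits per coordinate for binary optimizers.
#' @return A `benchmark_trials` object: the summary row plus the vector of
#'   final fitness values and the per-trial convergence trajectories.
#' @export
run_trials <- function(algorithm, id, repetitions = 10,
                       population_size = 10, max_iterations = 200,
                       dimension = 30, base_seed = 1, bits_per_dim = 16) {
  stopifnot(repetitions >= 1)
  bf <- benchmark_function(id, dimension)
  finals <- numeric(repetitions)
  trajs <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    cfg <- list(population_size = population_size,
                max_iterations = max_iterations,
                seed = derive_seed(base_seed, r),
                bits_per_dim = bits_per_dim)
    res <- run_one_algorithm(algorithm, bf, cfg)
    finals[r] <- res$best_fitness
    trajs[[r]] <- res$trajectory
  }
  s <- stats::sd(finals)
  if (repetitions == 1) s <- 0
  structure(list(algorithm = algorithm, fn_id = id,
                 best = min(finals), worst = max(finals),
                 mean = mean(finals), std = s, variance = s^2,
                 finals = finals, trajectories = trajs,
                 repetitions = repetitions),
            class = "benchmark_trials")
}

#' @export
print.benchmark_trials <- function(x, ...) {
  cat(sprintf("%s on %s (%d repetitions)\n", x$algorithm, x$fn_id,
              x$repetitions))
  print(data.frame(best = x$best, worst = x$worst, mean = x$mean,
                   std = x$std, variance = x$variance, row.names = ""))
  invisible(x)
}

#' Statistical comparison of optimizer result samples
#'
#' For every pair of algorithms: the paired Wilcoxon signed-rank test and
#' Cohen's d (mean difference over the pooled standard deviation); across
#' all algorithms: a one-way ANOVA, followed by Tukey's HSD when the
#' omnibus test is significant at `alpha`.
#'
#' @param samples Named list of equal-length numeric vectors, one per
#'   algorithm (final fitness over paired repetitions).
#' @param alpha Omnibus significance level gating the post-hoc test.
#' @return An `algo_comparison` object with elements `pairwise` (data frame
#'   with Wilcoxon statistic/p-value, Cohen's d and a `degenerate` flag for
#'   all-zero difference vectors), `anova` (F statistic and p-value) and
#'   `tukey` (the `TukeyHSD` table, or `NULL` when the omnibus test is not
#'   significant).
#' @export
compare_algorithms <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2,
            !is.null(names(samples)))
  n <- unique(lengths(samples))
  if (length(n) != 1) {
    stop("paired tests need equal repetition counts", call. = FALSE)
  }
  combos <- utils::combn(names(samples), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    d <- samples[[a]] - samples[[b]]
    degenerate <- all(d == 0)
    if (degenerate) {
      w <- NA_real_; p <- NA_real_
    } else {
      wt <- suppressWarnings(stats::wilcox.test(samples[[a]], samples[[b]],
                                                paired = TRUE))
      w <- unname(wt$statistic); p <- wt$p.value
    }
    pooled <- sqrt((stats::var(samples[[a]]) + stats::var(samples[[b]])) / 2)
    cd <- if (pooled == 0) 0 else (mean(samples[[a]]) - mean(samples[[b]])) / pooled
    data.frame(algorithm_1 = a, algorithm_2 = b, wilcoxon_V = w,
               p_value = p, cohens_d = cd, degenerate = degenerate)
  }))
  values <- unlist(samples, use.names = FALSE)
  group <- factor(rep(names(samples), each = n))
  fit <- stats::aov(values ~ group)
  an <- summary(fit)[[1]]
  omnibus <- list(F = an[1, "F value"], p_value = an[1, "Pr(>F)"])
  tukey <- if (is.finite(omnibus$p_value) && omnibus$p_value < alpha) {
    stats::TukeyHSD(fit)$group
  } else {
    NULL
  }
  structure(list(pairwise = pairwise, anova = omnibus, tukey = tukey),
            class = "algo_comparison")
}

#' @export
print.algo_comparison <- function(x, ...) {
  cat("Pairwise Wilcoxon signed-rank / Cohen's d:\n")
  print(x$pairwise, row.names = FALSE)
  cat(sprintf("\nOne-way ANOVA: F = %.4g, p = %.4g\n",
              x$anova$F, x$anova$p_value))
  if (!is.null(x$tukey)) {
    cat("Tukey HSD:\n")
    print(round(x$tukey, 6))
  } else {
    cat("Omnibus not significant; Tukey HSD skipped.\n")
  }
  invisible(x)
}

#' Benchmark report grid over functions and algorithms
#'
#' Runs [run_trials()] for every combination and assembles the long-format
#' grid (rows: function x metric, columns: algorithms).
#'
#' @param algorithms Character vector of algorithm ids.
#' @param functions Character vector of benchmark ids.
#' @param ... Passed to [run_trials()].
#' @return A data frame with columns `fn_id`, `metric` and one column per
#'   algorithm.
#' @export
benchmark_report <- function(algorithms = c("gwo", "bgwo", "iqi"),
                             functions = paste0("F", 1:10), ...) {
  metrics <- c("best", "worst", "mean", "std", "variance")
  rows <- list()
  for (f in functions) {
    per_algo <- lapply(algorithms, function(a) run_trials(a, f, ...))
    names(per_algo) <- algorithms
    for (m in metrics) {
      row <- data.frame(fn_id = f, metric = m)
      for (a in algorithms) row[[a]] <- per_algo[[a]][[m]]
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
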