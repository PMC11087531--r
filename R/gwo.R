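#' Configure a grey wolf optimizer run
#'
#' Collects the population machinery shared by [gwo()], [bgwo()] and
#' [iqi_bgwo()]: population size, iteration budget, the per-dimension search
#' box and the seed of the pseudo-random stream.
#'
#' @param dimension Number of decision variables.
#' @param population_size Number of wolves; at least 3, so that the three
#'   pack leaders (alpha, beta, delta) exist.  Default 10.
#' @param max_iterations Number of position-update iterations after the
#'   initial evaluation.  Default 200.
#' @param bounds Either a length-2 numeric `c(lower, upper)` recycled over
#'   dimensions, or a `dimension x 2` matrix of per-dimension bounds.
#'   Binary optimizers use the unit box `c(0, 1)`.
#' @param seed Integer seed; identical seed + config + objective gives a
#'   bit-identical run.
#' @return An object of class `gwo_config`.
#' @seealso [iqi_config()] for the quantum-inspired extension.
#' @export
gwo_config <- function(dimension, population_size = 10, max_iterations = 200,
                       bounds = c(0, 1), seed = 1) {
  if (!is_scalar_number(dimension) || dimension < 1) {
    stop("`dimension` must be a positive integer", call. = FALSE)
  }
  if (!is_scalar_number(population_size) || population_size < 3) {
    stop("`population_size` must be >= 3 (three leaders must exist)",
         call. = FALSE)
  }
  if (!is_scalar_number(max_iterations) || max_iterations < 1) {
    stop("`max_iterations` must be a positive integer", call. = FALSE)
  }
  d <- as.integer(dimension)
  if (is.matrix(bounds)) {
    if (ncol(bounds) != 2 || nrow(bounds) != d) {
      stop("`bounds` matrix must be dimension x 2", call. = FALSE)
    }
    lb <- bounds[, 1]; ub <- bounds[, 2]
  } else if (length(bounds) == 2) {
    lb <- rep(bounds[1], d); ub <- rep(bounds[2], d)
  } else {
    stop("`bounds` must be c(lower, upper) or a dimension x 2 matrix",
         call. = FALSE)
  }
  if (any(!is.finite(lb)) || any(!is.finite(ub)) || any(lb >= ub)) {
    stop("bounds must satisfy lower < upper in every dimension",
         call. = FALSE)
  }
  structure(list(dimension = d,
                 population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 lower = lb, upper = ub, seed = as.integer(seed)),
            class = "gwo_config")
}

#' Linear coefficient schedule of the encircling equations
#'
#' The exploration coefficient `a` decays linearly from 2 at the start of
#' the run to 0 at the last iteration: `a = 2 * (1 - t / T)`.
#'
#' @param t Iteration index, `0 <= t <= T`.
#' @param T_max Total number of iterations, `>= 1`.
#' @return The scalar coefficient `a` in `[0, 2]`.
#' @export
coefficient_schedule <- function(t, T_max) {
  if (!is_scalar_number(T_max) || T_max < 1) {
    stop("`T_max` must be >= 1", call. = FALSE)
  }
  if (!is_scalar_number(t) || t < 0 || t > T_max) {
    stop("`t` must lie in [0, T_max]", call. = FALSE)
  }
  2 * (1 - t / T_max)
}

#' Sample the stochastic coefficient set of one encircling step
#'
#' Draws the random pair `(r1, r2)` uniformly on `[0, 1]` per dimension and
#' forms `A = 2 a r1 - a` (in `[-a, a]`) and `C = 2 r2` (in `[0, 2]`).
#'
#' @param a Current schedule value from [coefficient_schedule()].
#' @param dimension Number of components to draw.
#' @return A list with components `A`, `C`, `r1`, `r2`.
#' @export
sample_coefficients <- function(a, dimension) {
  r1 <- stats::runif(dimension)
  r2 <- stats::runif(dimension)
  list(A = 2 * a * r1 - a, C = 2 * r2, r1 = r1, r2 = r2)
}

#' One encircling update of a single wolf
#'
#' Moves a wolf to the mean of the three leader-guided candidate positions:
#' for each leader `L` in (alpha, beta, delta), `K_L = |C_L * X_L - X|` and
#' `X_i = X_L - A_L * K_L`, with fresh `(r1, r2)` draws per leader.  The
#' result is clamped to the search box.
#'
#' @param position Numeric vector, the wolf's current position.
#' @param leaders 3-row matrix of the alpha, beta and delta positions.
#' @param a Coefficient schedule value.
#' @param lower,upper Per-dimension clamp bounds (default: no clamping).
#' @param draws Optional list of three lists with components `r1`, `r2`
#'   (one per leader) overriding the random draws; used for deterministic
#'   verification.
#' @return The updated, clamped position vector.
#' @export
encircle_update <- function(position, leaders, a,
                            lower = -Inf, upper = Inf, draws = NULL) {
  d <- length(position)
  stopifnot(is.matrix(leaders), nrow(leaders) == 3, ncol(leaders) == d)
  acc <- numeric(d)
  for (j in 1:3) {
    r <- if (is.null(draws)) {
      list(r1 = stats::runif(d), r2 = stats::runif(d))
    } else {
      draws[[j]]
    }
    A <- 2 * a * r$r1 - a
    C <- 2 * r$r2
    K <- abs(C * leaders[j, ] - position)
    acc <- acc + (leaders[j, ] - A * K)
  }
  pmin(pmax(acc / 3, lower), upper)
}

#' Decode a continuous position to a bit vector by the flag rule
#'
#' A component maps to 1 when it exceeds 0.5 strictly, else to 0.
#'
#' @param position Numeric vector.
#' @return Integer 0/1 vector of the same length.
#' @export
flag_binarize <- function(position) {
  as.integer(position > 0.5)
}

# Rank the pack: indices of the three lowest fitness values, ties broken by
# lower wolf index (order() is stable on the index for equal keys).
rank_leaders <- function(fitness) {
  order(fitness)[1:3]
}

# Shared optimizer loop.  `decode` maps a continuous position (and wolf
# index) to the vector handed to the objective; `extra_candidates` lets the
# quantum variant evaluate consensus solutions under the same elitism.
gwo_engine <- function(objective, config, decode, algorithm,
                       step = NULL, extra_candidates = NULL) {
  n <- config$population_size
  d <- config$dimension
  T_max <- config$max_iterations
  with_seed(config$seed, {
    pos <- matrix(stats::runif(n * d, rep(config$lower, each = n),
                               rep(config$upper, each = n)), n, d)
    state <- list()
    if (!is.null(step)) state <- attr(step, "init")(n, d, config)

    eval_one <- function(x_dec) {
      f <- objective(x_dec)
      if (!is_scalar_number(f)) {
        stop(sprintf(
          "objective returned a non-finite value at position (%s)",
          paste(signif(x_dec, 6), collapse = ", ")), call. = FALSE)
      }
      f
    }

    decoded <- lapply(seq_len(n), function(i) decode(pos[i, ], i, state))
    fitness <- vapply(decoded, eval_one, numeric(1))

    best_i <- which.min(fitness)
    best <- list(position = decoded[[best_i]], fitness = fitness[best_i],
                 iteration = 0L)
    trajectory <- numeric(T_max + 1)
    trajectory[1] <- best$fitness

    consider <- function(x_dec, f, t) {
      if (f < best$fitness) {
        best <<- list(position = x_dec, fitness = f, iteration = as.integer(t))
      }
    }

    for (t in seq_len(T_max)) {
      leaders <- rank_leaders(fitness)
      a <- coefficient_schedule(t, T_max)
      if (is.null(step)) {
        lead_pos <- pos[leaders, , drop = FALSE]
        for (i in seq_len(n)) {
          pos[i, ] <- encircle_update(pos[i, ], lead_pos, a,
                                      config$lower, config$upper)
        }
      } else {
        upd <- step(pos, leaders, t, state, config)
        pos <- upd$pos
        state <- upd$state
      }
      decoded <- lapply(seq_len(n), function(i) decode(pos[i, ], i, state))
      fitness <- vapply(decoded, eval_one, numeric(1))
      for (i in seq_len(n)) consider(decoded[[i]], fitness[i], t)
      if (!is.null(extra_candidates)) {
        leaders_now <- rank_leaders(fitness)
        for (cand in extra_candidates(pos, leaders_now, state, config)) {
          consider(cand, eval_one(cand), t)
        }
      }
      trajectory[t + 1] <- best$fitness
    }

    structure(list(best_position = best$position,
                   best_fitness = best$fitness,
                   trajectory = trajectory,
                   optimal_iteration = best$iteration,
                   algorithm = algorithm,
                   config = config),
              class = "gwo_result")
  })
}

#' Grey wolf optimizer (continuous)
#'
#' Minimizes a real-valued objective over the configured box with the
#' pack-based encircling dynamics: the three best wolves (alpha, beta,
#' delta) steer the rest, the exploration coefficient decays linearly from
#' 2 to 0, and out-of-box positions are clamped.
#'
#' @param objective Function taking one numeric position vector and
#'   returning one finite number (minimization convention).
#' @param config A [gwo_config()].
#' @return A `gwo_result` with elements `best_position`, `best_fitness`,
#'   `trajectory` (best-so-far fitness per iteration, length
#'   `max_iterations + 1` with the initial evaluation first),
#'   `optimal_iteration` (first iteration attaining the best fitness,
#'   0 = initial evaluation), `algorithm` and `config`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- gwo(sphere, gwo_config(2, population_size = 20,
#'                               max_iterations = 100,
#'                               bounds = c(-100, 100), seed = 1))
#' res$best_fitness
#' @export
gwo <- function(objective, config) {
  stopifnot(inherits(config, "gwo_config"))
  gwo_engine(objective, config, decode = function(x, i, s) x,
             algorithm = "gwo")
}

#' Binary grey wolf optimizer (flag decoding)
#'
#' Runs the continuous encircling dynamics on the unit box and hands the
#' objective the flag decoding of each position (component > 0.5 reads 1).
#' The reported best position is binary.
#'
#' On the closed unit box the origin is an absorbing state of the
#' encircling equations: once a leader and a wolf both sit at exactly 0 in
#' some component, `K = |C * 0 - 0| = 0` freezes that component at bit 0
#' for the rest of the run.  As in [iqi_bgwo()], any component collapsed
#' below 1e-6 after clamping is therefore re-seeded uniformly on `[0, 1]`,
#' which keeps per-bit exploration alive.
#'
#' @inheritParams gwo
#' @param objective Function of one 0/1 integer vector returning one
#'   finite number.
#' @return A `gwo_result`; `best_position` is an integer 0/1 vector.
#' @export
bgwo <- function(objective, config) {
  stopifnot(inherits(config, "gwo_config"))
  config$lower <- rep(0, config$dimension)
  config$upper <- rep(1, config$dimension)
  step <- function(pos, leaders, t, state, cfg) {
    a <- coefficient_schedule(t, cfg$max_iterations)
    lead_pos <- pos[leaders, , drop = FALSE]
    for (i in seq_len(nrow(pos))) {
      x <- encircle_update(pos[i, ], lead_pos, a, cfg$lower, cfg$upper)
      dead <- x < 1e-6
      if (any(dead)) x[dead] <- stats::runif(sum(dead))
      pos[i, ] <- x
    }
    list(pos = pos, state = state)
  }
  attr(step, "init") <- function(n, d, cfg) list()
  gwo_engine(objective, config, decode = function(x, i, s) flag_binarize(x),
             algorithm = "bgwo", step = step)
}

#' @export
print.gwo_result <- function(x, ...) {
  cat(sprintf("<%s> %d-dimensional run, %d wolves, %d iterations\n",
              toupper(x$algorithm), x$config$dimension,
              x$config$population_size, x$config$max_iterations))
  cat(sprintf("  best fitness %.6g at iteration %d\n",
              x$best_fitness, x$optimal_iteration))
  invisible(x)
}

#' @export
summary.gwo_result <- function(object, ...) {
  tr <- object$trajectory
  structure(list(algorithm = object$algorithm,
                 best_fitness = object$best_fitness,
                 optimal_iteration = object$optimal_iteration,
                 initial_fitness = tr[1],
                 iterations = length(tr) - 1L,
                 improvement = tr[1] - object$best_fitness),
            class = "summary.gwo_result")
}

#' @export
print.summary.gwo_result <- function(x, ...) {
  cat(sprintf("%s: initial %.6g -> best %.6g (improvement %.6g) after %d iterations; first optimum at iteration %d\n",
              toupper(x$algorithm), x$initial_fitness, x$best_fitness,
              x$improvement, x$iterations, x$optimal_iteration))
  invisible(x)
}

#' Plot the convergence trajectory of an optimizer run
#'
#' @param x A `gwo_result`.
#' @param log Axis spec passed to [graphics::plot()] (default `"y"` when
#'   all trajectory values are positive).
#' @param ... Further plot arguments.
#' @export
plot.gwo_result <- function(x, log = if (all(x$trajectory > 0)) "y" else "",
                            ...) {
  graphics::plot(seq_along(x$trajectory) - 1L, x$trajectory, type = "s",
                 xlab = "iteration", ylab = "best fitness", log = log,
                 main = sprintf("%s convergence", toupper(x$algorithm)), ...)
  invisible(x)
}

#' @export
coef.gwo_result <- function(object, ...) object$best_position

#' Read an optimizer configuration from a key-value file
#'
#' The file is YAML-style `key: value` text with keys `dimension`,
#' `population_size`, `max_iterations`, `lower`, `upper`, `seed`, and (for
#' the quantum variant) `s_threshold` and `amplitude_init`.
#'
#' @param path File path.
#' @param quantum Return an [iqi_config()] instead of a [gwo_config()].
#' @return A `gwo_config` or `iqi_config`.
#' @export
read_optimizer_config <- function(path, quantum = FALSE) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  }
  v <- yaml::read_yaml(path)
  bounds <- c(v$lower %||% 0, v$upper %||% 1)
  base <- list(dimension = v$dimension,
               population_size = v$population_size %||% 10,
               max_iterations = v$max_iterations %||% 200,
               bounds = bounds, seed = v$seed %||% 1)
  if (quantum) {
    do.call(iqi_config, c(base, list(
      s_threshold = v$s_threshold %||% 0.4,
      amplitude_init = v$amplitude_init %||% "equal")))
  } else {
    do.call(gwo_config, base)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
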