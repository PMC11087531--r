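#' Configure an improved quantum-inspired binary grey wolf run
#'
#' Extends [gwo_config()] with the quantum-specific knobs: the sigmoid
#' threshold `s` used for the consensus binarization rule and the initial
#' qubit amplitude pair.
#'
#' @inheritParams gwo_config
#' @param s_threshold Sigmoid cut in `[0, 1]` applied to the leaders'
#'   continuous consensus (see [sigmoid_binarize()]); `NULL` disables the
#'   sigmoid consensus candidate.  Default 0.4.
#' @param amplitude_init Either `"equal"` (equal superposition,
#'   amplitudes `1/sqrt(2)` so that `y^2 = 0.5`) or a numeric pair
#'   `c(x, y)`, which is normalised to unit length so the qubit invariant
#'   `x^2 + y^2 = 1` always holds.
#' @param zeta_scale Multiplier on every rotation magnitude `zeta`
#'   (default 1).  Setting it to 0 freezes all rotation gates; useful for
#'   diagnosing the qubit dynamics.
#' @return An object of classes `iqi_config` and `gwo_config`.
#' @export
iqi_config <- function(dimension, population_size = 10, max_iterations = 200,
                       bounds = c(0, 1), seed = 1, s_threshold = 0.4,
                       amplitude_init = "equal", zeta_scale = 1) {
  cfg <- gwo_config(dimension, population_size, max_iterations, bounds, seed)
  if (!is.null(s_threshold)) {
    if (!is_scalar_number(s_threshold) || s_threshold < 0 || s_threshold > 1) {
      stop("`s_threshold` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (identical(amplitude_init, "equal")) {
    amp <- c(1, 1) / sqrt(2)
  } else {
    if (!is.numeric(amplitude_init) || length(amplitude_init) != 2 ||
        all(amplitude_init == 0)) {
      stop("`amplitude_init` must be \"equal\" or a non-zero numeric pair",
           call. = FALSE)
    }
    amp <- amplitude_init / sqrt(sum(amplitude_init^2))
  }
  cfg$s_threshold <- s_threshold
  cfg$amplitude_init <- amp
  cfg$zeta_scale <- zeta_scale
  class(cfg) <- c("iqi_config", "gwo_config")
  cfg
}

#' Rotation gate matrices
#'
#' `y_rotation_matrix()` is the real rotation used by the optimizer's qubit
#' updates; `x_rotation_matrix()` and `z_rotation_matrix()` are the complex
#' companions, provided for completeness but unused by the search dynamics.
#'
#' @param theta Rotation angle in radians.
#' @return A 2x2 (complex for x/z) matrix.  The y gate is orthonormal and
#'   preserves the Euclidean norm of any amplitude pair.
#' @export
y_rotation_matrix <- function(theta) {
  stopifnot(is_scalar_number(theta))
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' @rdname y_rotation_matrix
#' @export
x_rotation_matrix <- function(theta) {
  stopifnot(is_scalar_number(theta))
  matrix(c(cos(theta), -1i * sin(theta), -1i * sin(theta), cos(theta)),
         2, 2)
}

#' @rdname y_rotation_matrix
#' @export
z_rotation_matrix <- function(theta) {
  stopifnot(is_scalar_number(theta))
  diag(c(exp(-1i * theta), exp(1i * theta)))
}

#' Rotation angle contributed by one leader
#'
#' `theta = zeta * gamma * sum(leader - wolf) * 2 * pi`: the angle grows
#' with the (signed, summed) displacement of the wolf from the leader, and
#' is modulated by the two stochastic factors `zeta = lambda * pi` and
#' `gamma`, both refreshed once per leader per iteration.
#'
#' @param leader_position,wolf_position Numeric vectors of equal length.
#' @param zeta,gamma Stochastic scalars (`zeta` in `[0, pi]`, `gamma` in
#'   `[0, 1]`).
#' @return The rotation angle in radians.
#' @export
leader_theta <- function(leader_position, wolf_position, zeta, gamma) {
  if (length(leader_position) != length(wolf_position)) {
    stop_dim("leader_theta", length(leader_position), length(wolf_position))
  }
  zeta * gamma * sum(leader_position - wolf_position) * 2 * pi
}

#' Rotate a qubit amplitude pair
#'
#' Applies the y-axis rotation gate to a unit-norm `(x, y)` amplitude pair.
#'
#' @param qubit Numeric pair with `x^2 + y^2 = 1` (within 1e-9).
#' @param theta Rotation angle in radians.
#' @return The rotated unit-norm pair.
#' @export
rotate_leader_qubit <- function(qubit, theta) {
  stopifnot(length(qubit) == 2)
  if (abs(sum(qubit^2) - 1) > 1e-9) {
    stop("qubit amplitudes are not unit-norm", call. = FALSE)
  }
  drop(y_rotation_matrix(theta) %*% qubit)
}

#' Multiplicative position update from the qubit's |1> probability
#'
#' Each component is scaled by the squared y amplitude of the wolf's qubit:
#' `X(t+1) = X(t) * y^2(t+1)`.
#'
#' @param position Numeric vector.
#' @param y_amplitude Per-dimension y amplitude (not squared).
#' @return The updated position vector.
#' @export
position_update <- function(position, y_amplitude) {
  if (length(position) != length(y_amplitude)) {
    stop_dim("position_update", length(position), length(y_amplitude))
  }
  position * y_amplitude^2
}

#' Threshold a position component against its qubit |1> probability
#'
#' Reads 1 when the component is at least `y^2` (inclusive), else 0.
#'
#' @param position_component Numeric vector (or scalar).
#' @param y_amplitude Matching y amplitude(s), not squared.
#' @return Integer 0/1 vector.
#' @export
threshold_binary <- function(position_component, y_amplitude) {
  as.integer(position_component >= y_amplitude^2)
}

#' Per-position majority vote over the three leader bit vectors
#'
#' @param alpha_bits,beta_bits,delta_bits Equal-length 0/1 vectors.
#' @return Integer 0/1 vector: 1 where at least two of the three inputs
#'   are 1.  Invariant to the order of the three arguments.
#' @export
majority_vote <- function(alpha_bits, beta_bits, delta_bits) {
  n <- length(alpha_bits)
  if (length(beta_bits) != n) stop_dim("majority_vote", n, length(beta_bits))
  if (length(delta_bits) != n) stop_dim("majority_vote", n, length(delta_bits))
  as.integer(alpha_bits + beta_bits + delta_bits >= 2)
}

#' Sigmoid binarization rule
#'
#' Maps each component through the logistic function
#' `sigm(p) = 1 / (1 + exp(-p))` and reads 1 where `sigm(p) >= s`.
#'
#' @param position Numeric vector.
#' @param s Threshold in `[0, 1]`.
#' @return Integer 0/1 vector.
#' @export
sigmoid_binarize <- function(position, s) {
  stopifnot(is_scalar_number(s), s >= 0, s <= 1)
  as.integer(stats::plogis(position) >= s)
}

#' Improved quantum-inspired binary grey wolf optimizer
#'
#' Every wolf carries a per-dimension qubit register initialised in the
#' configured superposition.  Each iteration draws, per leader, a rotation
#' magnitude `zeta = lambda * pi` and a modulation `gamma` (both uniform),
#' turns the wolf's displacement from each leader into a rotation angle via
#' [leader_theta()], applies the three y-gates in alpha, beta, delta order,
#' scales the position by the refreshed `y^2` ([position_update()]), and
#' decodes bits by [threshold_binary()].  Components collapsed below 1e-6
#' by the multiplicative update are re-seeded uniformly on `[0, 1]` to keep
#' exploration alive.  After each iteration the leaders' bit vectors are
#' combined by [majority_vote()] and, when `s_threshold` is set, the
#' leaders' continuous consensus is also binarized by [sigmoid_binarize()];
#' both consensus candidates are evaluated under the same elitism as the
#' pack, so the reported best is the best solution ever evaluated.
#'
#' @param objective Function of one 0/1 integer vector returning one
#'   finite number (minimization).
#' @param config An [iqi_config()].
#' @return A `gwo_result`; `best_position` is an integer 0/1 vector.
#' @export
iqi_bgwo <- function(objective, config) {
  stopifnot(inherits(config, "iqi_config"))
  config$lower <- rep(0, config$dimension)
  config$upper <- rep(1, config$dimension)

  step <- function(pos, leaders, t, state, cfg) {
    n <- nrow(pos); d <- ncol(pos)
    lambda <- stats::runif(3)
    zeta <- lambda * pi * cfg$zeta_scale
    gamma <- stats::runif(3)
    lead_pos <- pos[leaders, , drop = FALSE]
    new_pos <- pos
    for (i in seq_len(n)) {
      theta <- 0
      for (j in 1:3) {
        theta <- theta + leader_theta(lead_pos[j, ], pos[i, ],
                                      zeta[j], gamma[j])
      }
      # One y-rotation by the summed angle == the three gates in sequence.
      ang <- atan2(state$y[i, ], state$x[i, ]) + theta
      state$x[i, ] <- cos(ang)
      state$y[i, ] <- sin(ang)
      xi <- position_update(pos[i, ], state$y[i, ])
      dead <- abs(xi) < 1e-6
      if (any(dead)) xi[dead] <- stats::runif(sum(dead))
      new_pos[i, ] <- xi
    }
    list(pos = new_pos, state = state)
  }
  attr(step, "init") <- function(n, d, cfg) {
    list(x = matrix(cfg$amplitude_init[1], n, d),
         y = matrix(cfg$amplitude_init[2], n, d))
  }

  decode <- function(x, i, state) threshold_binary(x, state$y[i, ])

  extra <- function(pos, leaders, state, cfg) {
    bits <- lapply(leaders, function(i) decode(pos[i, ], i, state))
    out <- list(majority_vote(bits[[1]], bits[[2]], bits[[3]]))
    if (!is.null(cfg$s_threshold)) {
      consensus <- colMeans(pos[leaders, , drop = FALSE])
      out <- c(out, list(sigmoid_binarize(consensus, cfg$s_threshold)))
    }
    out
  }

  gwo_engine(objective, config, decode = decode, algorithm = "iqi_bgwo",
             step = step, extra_candidates = extra)
}
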