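test_that("rotation gate matrices match their closed forms", {
  expect_equal(y_rotation_matrix(0), diag(2))
  expect_equal(drop(y_rotation_matrix(pi / 2) %*% c(1, 0)), c(0, 1))
  # norm preservation for random angles
  set.seed(4)
  for (k in 1:20) {
    th <- stats::runif(1, -10, 10)
    v <- stats::rnorm(2)
    expect_equal(sum((y_rotation_matrix(th) %*% v)^2), sum(v^2),
                 tolerance = 1e-12)
  }
  # companions: x/z gates are unitary
  for (th in c(0.3, 1.2)) {
    for (M in list(x_rotation_matrix(th), z_rotation_matrix(th))) {
      expect_equal(Conj(t(M)) %*% M, diag(2) + 0i, tolerance = 1e-12)
    }
  }
})

test_that("y rotations compose additively (rotation-group property)", {
  set.seed(5)
  for (k in 1:25) {
    t1 <- stats::runif(1, -5, 5); t2 <- stats::runif(1, -5, 5)
    expect_equal(y_rotation_matrix(t1) %*% y_rotation_matrix(t2),
                 y_rotation_matrix(t1 + t2), tolerance = 1e-12)
  }
})

test_that("leader angle follows the displacement-sum formula", {
  w <- c(0.2, 0.4, 0.1)
  expect_equal(leader_theta(w, w, zeta = 1.3, gamma = 0.7), 0)
  expect_equal(leader_theta(c(1, 2), c(0, 0), zeta = 0, gamma = 0.9), 0)
  # displacement sum 0.5, zeta = pi/2, gamma = 0.5 -> pi^2 / 4
  expect_equal(leader_theta(c(0.5, 0.25), c(0.1, 0.15), pi / 2, 0.5),
               (pi / 2) * 0.5 * 0.5 * 2 * pi)
  expect_equal(leader_theta(c(0.5, 0.25), c(0.1, 0.15), pi / 2, 0.5),
               pi^2 / 4, tolerance = 1e-12)
  expect_error(leader_theta(c(1, 2), c(1, 2, 3), 1, 1), "lengths differ")
})

test_that("qubit rotation preserves the unit norm without drift", {
  q <- c(1, 1) / sqrt(2)
  expect_equal(rotate_leader_qubit(q, 0), q)
  expect_equal(rotate_leader_qubit(q, pi / 4), c(0, 1), tolerance = 1e-12)
  expect_error(rotate_leader_qubit(c(0.5, 0.5), 1), "unit-norm")
  # 1000 composed random rotations
  set.seed(6)
  for (k in 1:1000) q <- rotate_leader_qubit(q, stats::runif(1, -pi, pi))
  expect_equal(sum(q^2), 1, tolerance = 1e-9)
})

test_that("multiplicative position update and threshold decode", {
  expect_equal(position_update(c(0.3, 0.9), c(0, 1)), c(0, 0.9))
  expect_equal(position_update(0.8, sqrt(0.5)), 0.4)
  expect_equal(position_update(c(1, 2), c(1, 1)), c(1, 2))
  expect_error(position_update(c(1, 2), 1), "lengths differ")
  expect_equal(threshold_binary(0.5, sqrt(0.25)), 1L)
  expect_equal(threshold_binary(0, 0), 1L)   # inclusive boundary
  expect_equal(threshold_binary(0.1, sqrt(0.5)), 0L)
})

test_that("majority vote needs two of three and ignores leader order", {
  expect_equal(majority_vote(1, 1, 0), 1L)
  expect_equal(majority_vote(0, 0, 1), 0L)
  expect_equal(majority_vote(c(1, 0), c(1, 0), c(1, 0)), c(1L, 0L))
  set.seed(7)
  for (k in 1:20) {
    a <- sample(0:1, 8, TRUE); b <- sample(0:1, 8, TRUE)
    d <- sample(0:1, 8, TRUE)
    v <- majority_vote(a, b, d)
    expect_identical(v, majority_vote(d, a, b))
    expect_identical(v, majority_vote(b, d, a))
  }
  expect_error(majority_vote(c(1, 0), c(1, 0, 1), c(0, 0)),
               "lengths differ")
})

test_that("sigmoid binarization matches the logistic closed form", {
  expect_equal(stats::plogis(0), 0.5)
  expect_equal(stats::plogis(1), 1 / (1 + exp(-1)))
  expect_equal(sigmoid_binarize(0, 0.4), 1L)    # 0.5 >= 0.4
  expect_equal(sigmoid_binarize(0, 0.6), 0L)
  expect_equal(sigmoid_binarize(c(-3, 0, 3), 0.5), c(0L, 1L, 1L))
})

test_that("iqi config validates the quantum knobs", {
  expect_error(iqi_config(4, s_threshold = 1.5), "s_threshold")
  expect_error(iqi_config(4, amplitude_init = c(0, 0)), "amplitude_init")
  cfg <- iqi_config(4, amplitude_init = c(0.5, 0.5))
  expect_equal(sum(cfg$amplitude_init^2), 1)
  expect_equal(iqi_config(4)$amplitude_init, c(1, 1) / sqrt(2))
})

test_that("iqi optimizer finds OneMax optima at the stated budget", {
  hits <- sum(vapply(1:10, function(s) {
    iqi_bgwo(onemax, iqi_config(20, 10, 200, seed = s))$best_fitness == 0
  }, logical(1)))
  expect_gte(hits, 8)
})

test_that("iqi handles dimension 1 and constant objectives exactly", {
  for (s in 1:5) {
    tab <- qibgwo:::with_seed(s, stats::runif(2))
    r <- iqi_bgwo(function(b) tab[b + 1], iqi_config(1, 3, 20, seed = s))
    expect_equal(r$best_fitness, min(tab))
  }
  r <- iqi_bgwo(function(b) 2.25, iqi_config(5, 4, 10, seed = 1))
  expect_equal(r$best_fitness, 2.25)
  expect_equal(r$optimal_iteration, 0L)
  expect_true(all(r$best_position %in% c(0L, 1L)))
})

test_that("iqi is deterministic and its trajectory monotone", {
  obj <- random_table_objective(4, 11)
  cfg <- iqi_config(4, 6, 50, seed = 11)
  r1 <- iqi_bgwo(obj$fn, cfg)
  r2 <- iqi_bgwo(obj$fn, cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_true(all(diff(r1$trajectory) <= 0))
})

test_that("the best solution ever evaluated is the one reported", {
  # exhaustive-oracle equivalence at small dimension
  for (s in 1:10) {
    d <- 3
    seen <- new.env(); seen$best <- Inf
    obj <- random_table_objective(d, 100 + s)
    wrapped <- function(bits) {
      f <- obj$fn(bits)
      seen$best <- min(seen$best, f)
      f
    }
    r <- iqi_bgwo(wrapped, iqi_config(d, 6, 60, seed = s))
    expect_equal(r$best_fitness, seen$best)
  }
})

test_that("frozen rotations leave the qubit stationary and decode constant", {
  # zeta_scale = 0 disables every rotation; with y^2 = 1 the
  # multiplicative update is the identity, so the decode cannot move.
  masks <- new.env(); masks$seen <- character(0)
  obj <- function(bits) {
    masks$seen <- c(masks$seen, paste(bits, collapse = ""))
    sum(bits)
  }
  cfg <- iqi_config(6, 4, 25, seed = 3, zeta_scale = 0,
                    amplitude_init = c(0, 1), s_threshold = NULL)
  r <- iqi_bgwo(obj, cfg)
  # evaluation order: 4 initial decodes, then per iteration 4 wolf decodes
  # plus the majority-vote consensus; every iteration block must repeat
  blocks <- matrix(masks$seen[-(1:4)], nrow = 5)
  for (i in 1:5) expect_length(unique(blocks[i, ]), 1L)
  expect_identical(blocks[1:4, 1], masks$seen[1:4])
})
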