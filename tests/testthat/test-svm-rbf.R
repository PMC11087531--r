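test_that("the lambda-scaled kernel matches direct evaluation", {
  kp <- kernel_params(sigma = 1, lambda = 1)
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), kernel_params(2, lambda = 3)), 3)
  a <- c(0, 0); b <- c(1, 0)   # unit distance
  expect_equal(rbf_kernel(a, b, kp), exp(-1))
  set.seed(14)
  for (k in 1:30) {
    u <- stats::rnorm(4); v <- stats::rnorm(4)
    p <- kernel_params(sigma = stats::runif(1, 0.5, 3),
                       lambda = stats::runif(1, 0.5, 3))
    expect_equal(rbf_kernel(u, v, p), rbf_kernel(v, u, p))
    expect_equal(rbf_kernel(u, v, p),
                 exp(-sum((u - v)^2) / p$sigma^2) * p$lambda,
                 tolerance = 1e-12)
  }
  expect_error(rbf_kernel(1:2, 1:3, kp), "lengths differ")
})

test_that("gram matrices are symmetric PSD and scale linearly in lambda", {
  set.seed(15)
  x <- matrix(stats::rnorm(40), 20, 2)
  K1 <- rbf_gram(x, kernel_params(sigma = 1.5, lambda = 1))
  expect_equal(K1, t(K1), tolerance = 1e-12)
  expect_gte(min(eigen(K1, symmetric = TRUE, only.values = TRUE)$values),
             -1e-9)
  K3 <- rbf_gram(x, kernel_params(sigma = 1.5, lambda = 3))
  expect_equal(K3, 3 * K1, tolerance = 1e-12)
})

test_that("one-vs-all builds one classifier per class and separates blobs", {
  blobs <- make_blobs(30, sep = 6, seed = 16)
  kp <- kernel_params(sigma = 2, cost = 10)
  m <- train_one_vs_all(blobs$x, blobs$y, kp)
  expect_length(m$deciders, 2)
  expect_equal(mean(as.character(predict(m, blobs$x)) ==
                      as.character(blobs$y)), 1)
  # duplicated training point predicts its own label
  expect_equal(as.character(predict(m, blobs$x[1, , drop = FALSE])),
               as.character(blobs$y[1]))
  # three classes -> three classifiers
  x3 <- rbind(blobs$x, matrix(stats::rnorm(60, -6), ncol = 2))
  y3 <- factor(c(as.character(blobs$y), rep("c", 30)))
  m3 <- train_one_vs_all(x3, y3, kp)
  expect_length(m3$deciders, 3)
  expect_equal(mean(as.character(predict(m3, x3)) == as.character(y3)), 1)
  expect_error(train_one_vs_all(blobs$x, rep("a", 60), kp),
               "at least two classes")
})

test_that("libsvm and precomputed-Gram engines agree when lambda is 1", {
  blobs <- make_blobs(20, sep = 4, seed = 17)
  p1 <- kernel_params(sigma = 2, lambda = 1, cost = 5)
  m1 <- train_one_vs_all(blobs$x, blobs$y, p1)
  # the kernlab path is selected by lambda != 1; an infinitesimal lambda
  # perturbation keeps the same decision problem
  p2 <- kernel_params(sigma = 2, lambda = 1 + 1e-12, cost = 5)
  m2 <- train_one_vs_all(blobs$x, blobs$y, p2)
  grid <- as.matrix(expand.grid(seq(-2, 6, length = 7),
                                seq(-2, 6, length = 7)))
  expect_equal(as.character(predict(m1, grid)),
               as.character(predict(m2, grid)))
})

test_that("cross-validated accuracy behaves at its extremes", {
  blobs <- make_blobs(30, sep = 8, seed = 18)
  kp <- kernel_params(sigma = 2, cost = 10)
  expect_equal(cv_accuracy(blobs$x, blobs$y, kp, k = 5, seed = 1), 1)
  # permuted labels: chance level
  null <- qibgwo:::with_seed(19, {
    x <- matrix(stats::rnorm(400), 200, 2)
    y <- factor(rep(c("a", "b"), 100))
    cv_accuracy(x, y, kp, k = 5, seed = 1)
  })
  expect_lt(abs(null - 0.5), 0.1)
  # seed-reproducible
  expect_identical(cv_accuracy(blobs$x, blobs$y, kp, k = 5, seed = 2),
                   cv_accuracy(blobs$x, blobs$y, kp, k = 5, seed = 2))
})

test_that("bit decoding maps patterns onto the declared scales", {
  sp <- search_space(list(a = list(low = 0, high = 255, scale = "linear"),
                          b = list(low = 1e-2, high = 1e2, scale = "log")),
                     bits_per_parameter = 8)
  lo <- decode_params(rep(0, 16), sp)
  hi <- decode_params(rep(1, 16), sp)
  expect_equal(lo$a, 0);   expect_equal(lo$b, 1e-2)
  expect_equal(hi$a, 255); expect_equal(hi$b, 1e2)
  mid <- decode_params(c(1, rep(0, 7), rep(0, 8)), sp)
  expect_equal(mid$a, 128)
  expect_error(decode_params(rep(0, 15), sp), "lengths differ")
})

test_that("hyperparameter search stays inside the space and helps on XOR", {
  xor <- make_xor_data(120, seed = 20)
  sp <- search_space()
  tune <- optimize_hyperparams(xor$x, xor$y, "gwo", sp, cv_k = 5,
                               population_size = 5, max_iterations = 8,
                               seed = 20)
  expect_gte(tune$params$cost, 2^-5); expect_lte(tune$params$cost, 2^15)
  expect_gte(tune$params$sigma, 2^-8); expect_lte(tune$params$sigma, 2^8)
  expect_gte(tune$cv_accuracy, 0.9)
  expect_s3_class(tune$model, "ovr_svm")
  expect_true(all(as.character(predict(tune, xor$x)) %in%
                    levels(xor$y)))
})

test_that("a collapsed search space returns its single point", {
  blobs <- make_blobs(15, sep = 6, seed = 21)
  sp <- search_space(list(cost = list(low = 1, high = 1 + 1e-9,
                                      scale = "linear"),
                          sigma = list(low = 2, high = 2 + 1e-9,
                                       scale = "linear")))
  tune <- optimize_hyperparams(blobs$x, blobs$y, "bgwo", sp, cv_k = 3,
                               population_size = 4, max_iterations = 5,
                               seed = 1)
  expect_equal(tune$params$cost, 1, tolerance = 1e-6)
  expect_equal(tune$params$sigma, 2, tolerance = 1e-6)
  expect_gte(tune$cv_accuracy, 0.95)   # separable blobs
})
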