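test_that("activation values and analytic derivatives are consistent", {
  expect_equal(activation("sigmoid", 0), 0.5)
  expect_equal(activation("gaussian", 0), 1)
  expect_equal(activation("linear", 3.7), 3.7)
  expect_equal(activation("sin", pi / 2), 1)
  expect_equal(activation("cos", 0), 1)
  expect_error(activation("tanh", 0), "unknown")

  set.seed(1)
  pts <- stats::runif(20, -3, 3)
  h <- 1e-6
  for (kind in c("sigmoid", "linear", "gaussian", "sin", "cos")) {
    fd <- (activation(kind, pts + h) - activation(kind, pts - h)) / (2 * h)
    expect_equal(activation(kind, pts, deriv = TRUE), fd, tolerance = 1e-6)
  }
})

test_that("forward pass reduces to explicit linear algebra for linear nets", {
  set.seed(2)
  x <- matrix(rnorm(6 * 4), 6, 4)
  y <- rnorm(6)
  cfg <- ann_config("batch", hidden1_size = 3,
                    hidden1_activation = "linear",
                    output_activation = "linear", max_epochs = 1, seed = 9)
  fit <- ann_train(x, y, cfg)

  # all-zero weights: raw output 0, prediction = inverse-scale of 0
  zero <- ann_set_weights(fit, rep(0, length(coef(fit))))
  rng <- c(0, 1)  # linear target range
  expected0 <- fit$y_min + (0 - rng[1]) / diff(rng) * fit$y_span
  expect_equal(unname(predict(zero, x)), rep(expected0, 6))

  # explicit matrix-product oracle for the linear-linear composition
  W1 <- fit$net$W[[1]]; b1 <- fit$net$b[[1]]
  W2 <- fit$net$W[[2]]; b2 <- fit$net$b[[2]]
  xs <- sweep(sweep(x, 2, fit$x_center), 2, fit$x_scale, "/")
  raw <- xs %*% t(W1) %*% t(W2) + as.numeric(W2 %*% b1 + b2)
  oracle <- fit$y_min + (as.numeric(raw) - rng[1]) / diff(rng) * fit$y_span
  expect_equal(unname(predict(fit, x)), oracle, tolerance = 1e-10)

  expect_error(predict(fit, matrix(NA_real_, 1, 4)), "finite")
})

test_that("sigmoid-output predictions stay inside the inverse-scaled band", {
  set.seed(3)
  x <- matrix(rnorm(10 * 5), 10, 5)
  y <- stats::runif(10, 50, 150)
  cfg <- ann_config("rprop", hidden1_size = 4,
                    output_activation = "sigmoid", max_epochs = 50, seed = 2)
  fit <- ann_train(x, y, cfg)
  probe <- matrix(rnorm(2000 * 5, sd = 5), 2000, 5)
  pred <- predict(fit, probe)
  # raw sigmoid output lies in (0,1), i.e. prediction within +-12.5% margin
  lo <- fit$y_min - 0.125 * fit$y_span
  hi <- fit$y_max + 0.125 * fit$y_span
  expect_true(all(pred > lo & pred < hi))
})

test_that("back-propagated gradients match finite differences on a deep net", {
  set.seed(4)
  x <- matrix(rnorm(8 * 24), 8, 24)
  y <- rnorm(8, 100, 20)
  cfg <- ann_config("batch", hidden1_size = 9, hidden2_size = 11,
                    hidden1_activation = "sigmoid",
                    hidden2_activation = "gaussian",
                    output_activation = "sin", max_epochs = 1, seed = 7)
  fit <- ann_train(x, y, cfg)
  g <- ann_gradient(fit, x, y)
  idx <- sample(length(g), 30)
  expect_equal(g[idx], fd_gradient(fit, x, y, idx), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("the batch gradient is the sum of per-sample gradients", {
  set.seed(5)
  x <- matrix(rnorm(4 * 6), 4, 6)
  y <- rnorm(4)
  cfg <- ann_config("batch", hidden1_size = 5, hidden2_size = 3,
                    output_activation = "linear", max_epochs = 1, seed = 3)
  fit <- ann_train(x, y, cfg)
  g_batch <- ann_gradient(fit, x, y)
  g_sum <- Reduce(`+`, lapply(1:4, function(i)
    ann_gradient(fit, x[i, , drop = FALSE], y[i])))
  expect_equal(g_batch, g_sum, tolerance = 1e-10)
})

test_that("training is deterministic given the seed and records an MSE trace", {
  d <- xor_data()
  cfg <- ann_config("rprop", hidden1_size = 4,
                    hidden1_activation = "sigmoid",
                    output_activation = "sigmoid",
                    max_epochs = 300, seed = 5)
  f1 <- ann_train(d$x, d$y, cfg)
  f2 <- ann_train(d$x, d$y, cfg)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$trace, f2$trace)
  expect_length(f1$trace, 300)
  expect_true(all(is.finite(coef(f1))))
  # learning happened
  expect_lt(utils::tail(f1$trace, 1), f1$trace[1])
})

test_that("each training algorithm solves XOR from most initialisations", {
  d <- xor_data()
  for (alg in c("incremental", "batch", "rprop", "quickprop")) {
    ok <- 0
    for (s in 1:3) {
      cfg <- ann_config(alg, learning_rate = 0.9, hidden1_size = 4,
                        hidden1_activation = "sigmoid",
                        output_activation = "sigmoid",
                        max_epochs = 5000, seed = s, target_mse = 0.009)
      fit <- ann_train(d$x, d$y, cfg)
      if (utils::tail(fit$trace, 1) < 0.01) ok <- ok + 1
    }
    expect_gte(ok, 2)
  }
})

test_that("a linear net recovers a noiseless linear map almost perfectly", {
  set.seed(6)
  x <- matrix(rnorm(40 * 6), 40, 6)
  beta <- rnorm(6)
  y <- as.numeric(x %*% beta) + 3
  cfg <- ann_config("rprop", hidden1_size = 4,
                    hidden1_activation = "linear",
                    output_activation = "linear", max_epochs = 2000, seed = 8)
  fit <- ann_train(x, y, cfg)
  expect_gt(as.numeric(r_squared(predict(fit, x), y)), 0.999)
})

test_that("divergent training aborts with a diagnostic", {
  set.seed(7)
  x <- matrix(rnorm(10 * 3, sd = 10), 10, 3)
  y <- rnorm(10)
  cfg <- ann_config("batch", learning_rate = 1e8, hidden1_size = 4,
                    hidden1_activation = "linear",
                    output_activation = "linear", max_epochs = 100, seed = 1)
  expect_error(ann_train(x, y, cfg), "diverged")
})

test_that("early stopping keeps the best validation weights", {
  set.seed(8)
  x <- matrix(rnorm(30 * 5), 30, 5)
  y <- as.numeric(x %*% rnorm(5)) + rnorm(30, sd = 0.2)
  cfg <- ann_config("rprop", hidden1_size = 8, output_activation = "linear",
                    max_epochs = 3000, patience = 25, seed = 2)
  fit <- ann_train(x[1:20, ], y[1:20], cfg,
                   x_val = x[21:30, ], y_val = y[21:30])
  expect_lt(length(fit$trace), 3000)  # stopped early
  expect_true(all(is.finite(coef(fit))))
})

test_that("fitted models expose the standard modelling verbs", {
  set.seed(9)
  x <- matrix(rnorm(15 * 4), 15, 4)
  y <- rnorm(15, 10)
  fit <- ann_train(x, y, ann_config("rprop", hidden1_size = 3,
                                    output_activation = "linear",
                                    max_epochs = 200, seed = 1))
  expect_equal(fitted(fit), predict(fit, x))
  expect_equal(residuals(fit), y - fitted(fit))
  expect_named(coef(fit))
  expect_output(print(fit), "taste network")
  expect_output(print(summary(fit)), "Training RMSEP")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_ann(fit, f)
  expect_true(file.exists(f))
  obj <- yaml::read_yaml(f)
  expect_equal(unlist(obj$weights), unname(coef(fit)), tolerance = 1e-10)
})
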