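test_that("input scaler maps training values onto [0,1] with degenerate rule", {
  sc <- affinet:::fit_scaler(matrix(c(2, 4, 6), ncol = 1))
  expect_equal(as.vector(affinet:::scale_features(matrix(c(2, 4, 6)), sc)),
               c(0, 0.5, 1))

  const <- affinet:::fit_scaler(matrix(c(5, 5, 5), ncol = 1))
  expect_equal(as.vector(affinet:::scale_features(matrix(c(5, 5, 5)), const)),
               c(0, 0, 0))

  x <- withr::with_seed(3, matrix(rnorm(40), ncol = 1))
  sc <- affinet:::fit_scaler(x)
  xs <- as.vector(affinet:::scale_features(x, sc))
  expect_equal(xs[which.min(x)], 0)
  expect_equal(xs[which.max(x)], 1)
  expect_identical(order(xs), order(as.vector(x)))
  expect_true(all(xs >= 0 & xs <= 1))
})

test_that("forward pass equals the closed-form network output", {
  feats <- c("X.1", "X.2")
  # all weights zero -> 0
  net0 <- manual_net(matrix(0, 3, 2), c(0, 0, 0), feats)
  x <- tibble::tibble(X.1 = 0.3, X.2 = -0.4)
  expect_equal(predict(net0, x), 0)

  # only the output bias set: passes through via the S(.) = 1 convention
  netb <- manual_net(matrix(0, 3, 2), c(4.2, 0, 0), feats)
  expect_equal(predict(netb, x), 4.2)

  # H = 2 sigmoid units, |p| = 2, hand-set weights vs symbolic evaluation
  W1 <- matrix(c(0.1, -0.2, 0.3,
                 -0.5, 0.4, 0.2), nrow = 3)
  w2 <- c(0.7, 1.5, -2.0)
  net <- manual_net(W1, w2, feats)
  xv <- c(0.25, 0.8)
  sig <- function(u) exp(u) / (1 + exp(u))
  expected <- w2[1] +
    w2[2] * sig(W1[1, 1] + W1[2, 1] * xv[1] + W1[3, 1] * xv[2]) +
    w2[3] * sig(W1[1, 2] + W1[2, 2] * xv[1] + W1[3, 2] * xv[2])
  expect_equal(predict(net, tibble::tibble(X.1 = xv[1], X.2 = xv[2])),
               expected, tolerance = 1e-12)

  expect_error(predict(net, tibble::tibble(X.1 = 1)),
               class = "affinet_data_error")
})

test_that("forward pass agrees with an independently implemented network", {
  skip_if_not_installed("nnet")
  ds <- toy_table(n = 25, seed = 7)
  net <- train_network(ds, hidden = 5, config = quick_cfg(epochs = 40))
  # install our weights into an nnet object of the same topology and
  # compare outputs on the scaled inputs
  xs <- affinet:::scale_features(as.matrix(ds[net$features]), net$scaler)
  ref <- nnet::nnet(xs, ds$affinity, size = 4, linout = TRUE, maxit = 1,
                    trace = FALSE)
  ref$wts <- c(as.vector(net$input_weights),
               net$output_weights)
  expect_equal(as.vector(predict(ref, xs)), predict(net, ds),
               tolerance = 1e-10)
})

test_that("objective is squared error plus decay over all weights", {
  ds <- toy_table(n = 15, seed = 2)
  net <- train_network(ds, hidden = 4, config = quick_cfg(epochs = 30,
                                                          lambda = 0.01))
  # brute-force recomputation
  res <- ds$affinity - predict(net, ds)
  wsum <- sum(net$input_weights^2) + sum(net$output_weights^2)
  expect_equal(network_objective(net, ds), sum(res^2) + 0.01 * wsum,
               tolerance = 1e-10)

  # perfect predictions at lambda = 0 -> E = 0
  perfect <- constant_net(3, feature_cols(ds))
  perfect$config <- quick_cfg(lambda = 0)
  ds3 <- dplyr::mutate(ds, affinity = 3)
  expect_equal(network_objective(perfect, ds3), 0)

  # zero-weight net with lambda > 0 -> penalty term vanishes
  zero <- manual_net(matrix(0, length(feature_cols(ds)) + 1, 3),
                     rep(0, 4), feature_cols(ds))
  zero$config <- quick_cfg(lambda = 0.5)
  expect_equal(network_objective(zero, ds), sum(ds$affinity^2))
})

test_that("analytic gradient matches finite differences and the R reference", {
  withr::with_seed(5, {
    p <- 3; H <- 4; n <- 12
    x1 <- cbind(1, matrix(runif(n * p), n))
    y <- rnorm(n)
    par <- runif((p + 1) * H + H + 1, -0.5, 0.5)
    ga <- affinet:::nn_gr_cpp(par, x1, y, 0.01, p, H)
    gr_ref <- affinet:::nn_gradient_fn(par, x1, y, 0.01, p, H)
    expect_equal(as.vector(ga), as.vector(gr_ref), tolerance = 1e-10)
    expect_equal(affinet:::nn_fn_cpp(par, x1, y, 0.01, p, H),
                 affinet:::nn_objective_fn(par, x1, y, 0.01, p, H),
                 tolerance = 1e-12)
    num <- vapply(seq_along(par), function(i) {
      h <- 1e-6
      pp <- par; pp[i] <- pp[i] + h
      pm <- par; pm[i] <- pm[i] - h
      (affinet:::nn_fn_cpp(pp, x1, y, 0.01, p, H) -
         affinet:::nn_fn_cpp(pm, x1, y, 0.01, p, H)) / (2 * h)
    }, numeric(1))
    expect_equal(as.vector(ga), num, tolerance = 1e-5)
  })
})

test_that("training reduces the criterion and is reproducible from the seed", {
  ds <- withr::with_seed(11, {
    x <- runif(50, -1, 1)
    tibble::tibble(complex_id = sprintf("r%02d", 1:50), affinity = x,
                   X.1 = x)
  })
  cfg <- quick_cfg(epochs = 80, seed = 3)
  net <- train_network(ds, hidden = 5, config = cfg)
  par0 <- withr::with_seed(3, runif(2 * 4 + 5, -0.7, 0.7))
  x1 <- cbind(1, affinet:::scale_features(as.matrix(ds["X.1"]), net$scaler))
  e0 <- affinet:::nn_fn_cpp(par0, x1, ds$affinity, cfg$lambda, 1, 4)
  expect_lt(net$objective, e0)

  net2 <- train_network(ds, hidden = 5, config = cfg)
  expect_identical(net$input_weights, net2$input_weights)
  expect_identical(net$output_weights, net2$output_weights)
})

test_that("zero-target fit early-stops below the criterion threshold", {
  ds <- toy_table(n = 20, seed = 4)
  ds$affinity <- 0
  net <- train_network(ds, hidden = 4,
                       config = quick_cfg(epochs = 3000, lambda = 0))
  expect_lt(net$objective, 1e-4)
  expect_true(net$converged)
})

test_that("a trained net beats the best constant predictor on smooth data", {
  ds <- withr::with_seed(21, {
    x <- runif(200, -1.5, 1.5)
    tibble::tibble(complex_id = sprintf("s%03d", 1:200),
                   affinity = sin(3 * x) + x^2, X.1 = x)
  })
  net <- train_network(ds, hidden = 10,
                       config = quick_cfg(epochs = 400, lambda = 1e-4))
  train_rmse <- rmse(ds$affinity, predict(net, ds))
  expect_lt(train_rmse, 0.5 * sd(ds$affinity))
})
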