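test_that("analytic parameter counts reproduce the canonical architecture", {
  cu <- count_parameters(build_ulstm(846))
  expect_equal(cu$table$params, c(378800, 0, 80400, 85446))
  expect_equal(cu$total, 544646)
  expect_equal(cu$non_trainable, 0)
  # first layer follows the LSTM formula 4((d+u)u+u)
  expect_equal(cu$table$params[1], 4 * ((846 + 100) * 100 + 100))

  cc <- count_parameters(build_cnn_lstm(846))
  expect_equal(cc$table$params,
               c(487360, 0, 0, 73856, 0, 0, 512, 0, 0, 142800, 85446))
  expect_equal(cc$table$params[1], (9 * 846 + 1) * 64)
  expect_equal(cc$table$params[4], (9 * 64 + 1) * 128)
  expect_equal(cc$total, 789974)
  expect_equal(cc$trainable, 789718)
  expect_equal(cc$non_trainable, 256)
  # time-dimension chain 5 -> 5 -> 3 -> 3 -> 2 and flatten width 256
  expect_equal(cc$table$output_shape[1:2],
               c("(None, 5, 64)", "(None, 3, 64)"))
  expect_equal(cc$table$output_shape[4:5],
               c("(None, 3, 128)", "(None, 2, 128)"))
  expect_equal(cc$table$output_shape[8], "(None, 256)")

  expect_equal(count_parameters(build_ulstm(3))$total,
               4 * ((3 + 100) * 100 + 100) +
                 4 * ((100 + 100) * 100 + 100) + (100 * 3 + 3))
})

test_that("the bidirectional spec honours the merged width 100", {
  cb <- count_parameters(build_blstm(846))
  expect_equal(cb$table$output_shape[1], "(None, 100)")
  expect_equal(cb$table$output_shape[3], "(None, 1, 100)")
  # two directions of 50 units each, distinct from a forward-only LSTM(100)
  expect_equal(cb$table$params[1], 2 * 4 * ((846 + 50) * 50 + 50))
  expect_false(cb$table$params[1] ==
                 count_parameters(build_ulstm(846))$table$params[1])
})

test_that("analytic counts agree with backend weight-array introspection", {
  ns <- asNamespace("gpcrforecast")
  for (spec in list(build_ulstm(9, 5), build_blstm(9, 5),
                    build_cnn_lstm(9, 5))) {
    m <- ns$nn_build(spec, seed = 1)
    np <- ns$nn_num_params(m)
    cp <- count_parameters(spec)
    expect_equal(np$total, cp$total, info = spec$model)
    expect_equal(np$trainable, cp$trainable, info = spec$model)
    expect_equal(np$non_trainable, cp$non_trainable, info = spec$model)
  }
})

test_that("unchainable specs are rejected", {
  bad <- gpcrforecast:::new_forecaster_spec
  expect_error(bad("x", 6, 2, list(
    list(kind = "maxpool1d", width = 5),
    list(kind = "flatten"),
    list(kind = "repeat-vector"),
    list(kind = "time-distributed-affine", units = 6))),
    "pool width")
})

test_that("layer gradients match finite differences", {
  ns <- asNamespace("gpcrforecast")
  set.seed(42)
  spec <- build_cnn_lstm(6, 5, kernel = 3, dropout = 0)
  m <- ns$nn_build(spec, seed = 3)
  B <- 4
  X <- array(rnorm(B * 5 * 6), c(B, 5, 6))
  y <- matrix(rnorm(B * 6), B, 6)
  lossfun <- function(model) {
    mean((ns$nn_forward(model, X, training = TRUE)$out - y)^2)
  }
  fwd <- ns$nn_forward(m, X, training = TRUE)
  bwd <- ns$nn_backward(fwd$model, fwd$caches,
                        2 * (fwd$out - y) / length(y))
  checks <- list(list(1, "W", 5), list(1, "b", 2), list(4, "W", 10),
                 list(7, "gamma", 3), list(7, "beta", 2),
                 list(10, "W", 4), list(10, "b", 12), list(11, "W", 3))
  for (ck in checks) {
    li <- ck[[1]]; nm <- ck[[2]]; idx <- ck[[3]]
    g <- bwd$grads[[li]][[nm]][idx]
    v <- m$layers[[li]]$weights[[nm]][idx]
    eps <- 1e-5
    perturb <- function(val) {
      mm <- m; mm$layers[[li]]$weights[[nm]][idx] <- val; mm
    }
    num <- (lossfun(perturb(v + eps)) - lossfun(perturb(v - eps))) /
      (2 * eps)
    expect_equal(g, num, tolerance = 1e-5,
                 info = sprintf("layer %d %s[%d]", li, nm, idx))
  }
})

test_that("bidirectional gradients match finite differences", {
  ns <- asNamespace("gpcrforecast")
  set.seed(7)
  m <- ns$nn_build(build_blstm(4, 5, units = 3), seed = 9)
  X <- array(rnorm(4 * 5 * 4), c(4, 5, 4))
  y <- matrix(rnorm(16), 4, 4)
  fwd <- ns$nn_forward(m, X, training = TRUE)
  bwd <- ns$nn_backward(fwd$model, fwd$caches,
                        2 * (fwd$out - y) / length(y))
  for (ck in list(list(1, "fwd", "W", 2), list(1, "bwd", "R", 5),
                  list(1, "fwd", "b", 1), list(3, "bwd", "W", 6))) {
    li <- ck[[1]]; dir <- ck[[2]]; nm <- ck[[3]]; idx <- ck[[4]]
    g <- bwd$grads[[li]][[dir]][[nm]][idx]
    v <- m$layers[[li]]$weights[[dir]][[nm]][idx]
    eps <- 1e-6
    lf <- function(val) {
      mm <- m; mm$layers[[li]]$weights[[dir]][[nm]][idx] <- val
      mean((ns$nn_forward(mm, X, training = TRUE)$out - y)^2)
    }
    expect_equal(g, (lf(v + eps) - lf(v - eps)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("persistence returns the last input frame unchanged", {
  f <- ramp_features(10, 6)
  ws <- make_windows(f, 5)
  pred <- persistence_forecast(ws)
  for (s in seq_len(nrow(pred))) expect_equal(pred[s, ], f[s + 4, ])
  # static trajectory: zero error
  ws0 <- make_windows(matrix(3, 10, 6), 5)
  expect_equal(persistence_forecast(ws0), ws0$y)
  m <- fit_forecaster(persistence_spec(), ws)
  expect_equal(predict(m, ws), pred)
})

test_that("random forest config encodes depth 3N and is reproducible", {
  expect_equal(build_rf(282)$max_depth, 846)
  expect_equal(build_rf(1)$max_depth, 3)
  set.seed(31)
  f <- matrix(rnorm(40 * 6), 40, 6)
  ws <- make_windows(f, 5)
  m1 <- fit_forecaster(build_rf(2), ws)
  m2 <- fit_forecaster(build_rf(2), ws)
  expect_equal(dim(predict(m1, ws)), dim(ws$y))
  expect_identical(predict(m1, ws), predict(m2, ws))
})

test_that("neural training drives a constant target to the constant", {
  # constant trajectory through the normalisation pipeline: degenerate
  # features normalise to 0, and the trained model must reproduce the
  # constant within 1e-2 in normalised space
  set.seed(5)
  f <- matrix(rep(c(0.3, 0.7, 0.5), each = 30), 30, 3)
  mm <- fit_minmax(f)
  ws <- make_windows(apply_minmax(mm, f), 5)
  m <- fit_forecaster(build_ulstm(3, units = 8),
                      ws, fit_config(epochs = 100, seed = 2))
  pred <- predict(m, ws)
  expect_lt(max(abs(pred - ws$y)), 1e-2)
  # inverted back to Angstrom, the constant is recovered
  back <- invert_minmax(mm, pred)
  expect_lt(max(abs(sweep(back, 2, c(0.3, 0.7, 0.5)))), 1e-2)
})

test_that("neural fits are deterministic given the seed", {
  set.seed(6)
  f <- matrix(runif(60), 20, 3)
  ws <- make_windows(f, 5)
  m1 <- fit_forecaster(build_ulstm(3, units = 4), ws,
                       fit_config(epochs = 3, seed = 11))
  m2 <- fit_forecaster(build_ulstm(3, units = 4), ws,
                       fit_config(epochs = 3, seed = 11))
  expect_identical(predict(m1, ws), predict(m2, ws))
})

test_that("training aborts with a diagnostic when the loss is not finite", {
  set.seed(8)
  f <- matrix(runif(30), 10, 3)
  f[7, 2] <- NaN  # poisoned frame surfaces as a non-finite loss
  ws <- make_windows(f, 5)
  expect_error(
    fit_forecaster(build_ulstm(3, units = 4), ws,
                   fit_config(epochs = 5, seed = 1)),
    "non-finite loss")
})

test_that("non-canonical CNN windows re-derive the pooling chain", {
  expect_warning(spec <- build_cnn_lstm(9, n_steps_in = 3, kernel = 3),
                 "non-canonical")
  expect_equal(count_parameters(spec)$table$output_shape[11],
               "(None, 9)")
})
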