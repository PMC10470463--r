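test_that("model building is seeded, shape-checked and orderly", {
  m1 <- build_model(stock_architecture("relu-compact"), 2, c(8, 128), seed = 7)
  m2 <- build_model(stock_architecture("relu-compact"), 2, c(8, 128), seed = 7)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_model(stock_architecture("relu-compact"), 2, c(8, 128), seed = 8)
  expect_false(identical(m1$layers, m3$layers))

  sc <- forward_scores(m1, matrix(0, 8, 128))
  expect_length(sc$activations, 2)
  expect_true(all(is.finite(sc$activations)))

  # dense before flatten is an invalid ordering
  expect_error(build_model(list(layer_dense(2L), layer_flatten()),
                           2, c(4, 16)),
               "configuration error")
  # kernel longer than the time axis
  expect_error(build_model(list(layer_conv_time(2, 64), layer_flatten(),
                                layer_dense()), 2, c(4, 16)),
               "configuration error")
})

test_that("forward pass matches direct matrix arithmetic on a linear model", {
  set.seed(11)
  W <- matrix(rnorm(3 * 40), 3, 40)
  b <- rnorm(3)
  m <- make_linear_model(W, b, input_shape = c(4, 10))
  for (s in 1:3) {
    x <- rand_input(4, 10, seed = s)
    sc <- forward_scores(m, x)
    expect_equal(sc$activations, drop(W %*% as.vector(x)) + b,
                 tolerance = 1e-12)
    expect_equal(sum(sc$probabilities), 1, tolerance = 1e-9)
    expect_true(all(sc$probabilities >= 0 & sc$probabilities <= 1))
    expect_identical(which.max(sc$activations), which.max(sc$probabilities))
  }
})

test_that("softmax probabilities always sum to one on stock models", {
  m <- frozen_stock("elu-compact")
  batch <- lapply(1:5, function(i) rand_input(8, 128, seed = i, sd = 10))
  for (sc in forward_scores(m, batch)) {
    expect_equal(sum(sc$probabilities), 1, tolerance = 1e-9)
  }
  # duplicated sample in one batch (frozen stats) gives identical scores
  dup <- forward_scores(m, list(batch[[1]], batch[[1]]))
  expect_identical(dup[[1]], dup[[2]])
})

test_that("freeze_batch_stats is a no-op without batchnorm and idempotent with it", {
  W <- matrix(rnorm(2 * 20, 1), 2, 20)
  lin <- make_linear_model(W, input_shape = c(2, 10))
  x <- rand_input(2, 10, seed = 4)
  lin2 <- freeze_batch_stats(lin, list(x))
  expect_equal(forward_scores(lin2, x)$activations,
               forward_scores(lin, x)$activations)

  m <- build_model(stock_architecture("relu-compact"), 2, c(8, 64), seed = 2)
  ref <- lapply(1:3, function(i) rand_input(8, 64, seed = i, sd = 10))
  f1 <- freeze_batch_stats(m, ref)
  f2 <- freeze_batch_stats(f1, ref)
  expect_identical(f1$layers, f2$layers)
  expect_error(freeze_batch_stats(m, list()), "input error")
})

test_that("with frozen statistics attribution is independent of batch companions", {
  m <- build_model(stock_architecture("elu-compact"), 2, c(6, 64), seed = 5)
  s <- rand_input(6, 64, seed = 21, sd = 10)
  others <- lapply(1:6, function(i) rand_input(6, 64, seed = 30 + i, sd = 10))
  f <- freeze_batch_stats(m, others[1:3])
  g_alone <- compute_contribution(f, s, 1, attribution_config("gradient_x_input"))
  # process s "inside a batch": batch forward must give the same scores,
  # hence the same map, because frozen stats are constants
  batch_scores <- forward_scores(f, c(list(s), others))
  expect_identical(batch_scores[[1]]$activations,
                   forward_scores(f, s)$activations)
  g_again <- compute_contribution(f, s, 1, attribution_config("gradient_x_input"))
  expect_identical(g_alone$scores, g_again$scores)
})

test_that("modified plain gradient matches finite differences on a deep model", {
  m <- frozen_stock("elu-compact", N = 6, T = 64, seed = 9)
  x <- rand_input(6, 64, seed = 13, sd = 10)
  g <- modified_gradient(m, x, 2, "plain")
  h <- 1e-4
  for (pt in list(c(1, 1), c(3, 17), c(6, 64), c(2, 40))) {
    xp <- x; xp[pt[1], pt[2]] <- xp[pt[1], pt[2]] + h
    xm <- x; xm[pt[1], pt[2]] <- xm[pt[1], pt[2]] - h
    num <- (forward_scores(m, xp)$activations[2] -
            forward_scores(m, xm)$activations[2]) / (2 * h)
    expect_equal(g[pt[1], pt[2]], num, tolerance = 1e-6)
  }
})

test_that("training is seeded, respects zero learning rate, rejects one class", {
  spec <- synthetic_spec(n_channels = 4, n_timepoints = 64,
                         feature_channels = list(1L, 3L),
                         seed = 5L)
  ds <- generate_dataset(spec, 20)
  m <- build_model(stock_architecture("relu-compact", filters = 4, kernel = 9,
                                      pool = 4),
                   2, c(4, 64), seed = 1)

  cfg0 <- train_config(learning_rate = 0, epochs = 2, batch_size = 10, seed = 3)
  t0 <- train(m, ds$samples, cfg0, labels = ds$labels)
  for (i in seq_along(m$layers)) {
    for (f in c("W", "b", "gamma", "beta")) {
      if (!is.null(m$layers[[i]][[f]])) {
        expect_equal(t0$layers[[i]][[f]], m$layers[[i]][[f]], tolerance = 0)
      }
    }
  }

  cfg <- train_config(epochs = 2, batch_size = 10, seed = 3)
  ta <- train(m, ds$samples, cfg, labels = ds$labels)
  tb <- train(m, ds$samples, cfg, labels = ds$labels)
  expect_identical(ta$layers, tb$layers)
  expect_s3_class(attr(ta, "history"), "data.frame")
  expect_equal(nrow(attr(ta, "history")), 2)

  expect_error(train(m, ds$samples, cfg, labels = rep(1L, 20)),
               "configuration error")
})

test_that("a compact CNN learns the synthetic task to high held-out accuracy", {
  # independent separability oracle first: logistic regression on alpha/EMG
  # bandpower features must already separate the classes
  fit <- trained_fixture()
  bandpow <- function(x, fs, lo, hi) {
    T <- ncol(x); f <- (0:(T - 1)) * fs / T
    sel <- f >= lo & f <= hi & f <= fs / 2
    sum(Mod(t(apply(x, 1, fft)))[, sel]^2)
  }
  feats <- t(vapply(fit$data$samples, function(s)
    c(a = bandpow(s$values, 128, 8, 13), e = bandpow(s$values, 128, 25, 45)),
    numeric(2)))
  df <- data.frame(scale(feats), y = fit$data$labels == 2)
  glmfit <- suppressWarnings(stats::glm(y ~ ., data = df, family = binomial))
  oracle_acc <- mean((stats::predict(glmfit, type = "response") > 0.5) == df$y)
  expect_gt(oracle_acc, 0.9)

  preds <- vapply(fit$heldout$samples, function(s) predict_class(fit$model, s),
                  integer(1))
  expect_gt(mean(preds == fit$heldout$labels), 0.9)
})

test_that("frozen batchnorm acts as a fixed affine map", {
  m <- frozen_stock("relu-compact", N = 4, T = 32, seed = 6)
  bn <- which(vapply(m$layers, function(l) l$kind == "batchnorm", logical(1)))[1]
  l <- m$layers[[bn]]
  st <- list(mean = l$frozen_mean, var = l$frozen_var)
  a <- array(rnorm(4 * 4 * 16), dim = c(4, 4, 16))
  y1 <- eegattr:::.fwd_batchnorm(l, a, st)$out
  y2 <- eegattr:::.fwd_batchnorm(l, 2 * a, st)$out
  # affine: y(2a) - y(a) = slope * a, with slope = gamma / sd
  slope <- l$gamma / sqrt(st$var + 1e-5)
  expect_equal(y2 - y1, array(a * slope, dim = dim(a)), tolerance = 1e-6)
})
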