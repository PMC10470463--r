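test_that("patch perturbation zeroes exactly one in-channel patch", {
  z <- matrix(0, 2, 10)
  spec <- perturbation_spec(4)
  expect_equal(perturb_patch(z, 1, 2, spec), z)

  ones <- matrix(1, 2, 10)
  p <- perturb_patch(ones, 2, 4, spec)
  expect_equal(rowSums(p), c(10, 6))
  expect_equal(sum(p == 0), 4)

  x <- rand_input(2, 10, seed = 3)
  p <- perturb_patch(x, 1, 5, spec)
  p[1, 5:8] <- x[1, 5:8]
  expect_identical(p, x)

  expect_error(perturb_patch(ones, 1, 8, spec), "input error")
  expect_error(perturb_patch(ones, 3, 1, spec), "input error")
})

test_that("sensitivity PCC is exactly 1 for gradient x input on a linear model", {
  set.seed(2)
  W <- matrix(rnorm(2 * 4 * 50), 2, 4 * 50)
  m <- make_linear_model(W, input_shape = c(4, 50))
  x <- rand_input(4, 50, seed = 12)
  cls <- predict_class(m, x)
  gxi <- compute_contribution(m, x, cls, attribution_config("gradient_x_input"))
  res <- sensitivity_test(m, x, gxi, perturbation_spec(10, seed = 5))
  expect_false(res$undefined)
  expect_equal(res$pcc, 1.0, tolerance = 1e-12)
  # oracle: delta scores equal the patch sums of w * x by linearity
  wc <- matrix(W[cls, ], 4, 50)
  brute <- vapply(seq_len(nrow(res$records)), function(k) {
    ch <- res$records$channel[k]; st <- res$records$start[k]
    sum(wc[ch, st:(st + 9)] * x[ch, st:(st + 9)])
  }, numeric(1))
  expect_equal(res$records$delta_score, brute, tolerance = 1e-9)
  # pcc agrees with the direct correlation formula
  r <- res$records
  direct <- sum(scale(r$delta_score) * scale(r$contribution)) / (nrow(r) - 1)
  expect_equal(res$pcc, direct, tolerance = 1e-12)
})

test_that("an input-independent map correlates poorly on the linear fixture", {
  set.seed(2)
  W <- matrix(rnorm(2 * 4 * 50), 2, 4 * 50)
  m <- make_linear_model(W, input_shape = c(4, 50))
  pccs <- vapply(1:10, function(d) {
    x <- rand_input(4, 50, seed = 10 + d)
    cls <- predict_class(m, x)
    sal <- compute_contribution(m, x, cls, attribution_config("saliency"))
    sensitivity_test(m, x, sal, perturbation_spec(10, seed = 5))$pcc
  }, numeric(1))
  expect_lt(median(abs(pccs)), 0.5)
})

test_that("channel-level sensitivity: exact correlation and degenerate flags", {
  set.seed(7)
  W <- matrix(rnorm(2 * 4 * 20), 2, 4 * 20)
  m <- make_linear_model(W, input_shape = c(4, 20))
  x <- rand_input(4, 20, seed = 2)
  cls <- predict_class(m, x)
  ch <- channel_contribution(
    compute_contribution(m, x, cls, attribution_config("gradient_x_input")))
  res <- sensitivity_test_channels(m, x, ch)
  expect_equal(res$pcc, 1.0, tolerance = 1e-12)

  flat <- channel_contribution_map(rep(0.3, 4), cls, "uniform")
  res2 <- sensitivity_test_channels(m, x, flat)
  expect_true(res2$undefined)
  expect_true(is.na(res2$pcc))

  m2 <- make_linear_model(matrix(rnorm(2 * 2 * 20), 2), input_shape = c(2, 20))
  x2 <- rand_input(2, 20, seed = 2)
  ch2 <- channel_contribution(
    compute_contribution(m2, x2, 1, attribution_config("gradient_x_input")))
  expect_true(sensitivity_test_channels(m2, x2, ch2)$low_power)
})

test_that("deletion curve matches the closed form on a sum model", {
  # S1(x) = sum(x), S2(x) = 0; map = the input itself
  W <- rbind(rep(1, 20), rep(0, 20))
  m <- make_linear_model(W, input_shape = c(2, 10))
  x <- matrix(as.numeric(1:20), 2, 10)
  cmap <- contribution_map(x, 1, "gradient_x_input")
  dc <- deletion_curve(m, x, cmap, fractions = seq(0.1, 1, by = 0.1))
  # closed form: remaining sum after zeroing the k largest values
  sorted <- sort(as.vector(x), decreasing = TRUE)
  probs <- vapply(seq(0.1, 1, by = 0.1), function(fr) {
    k <- round(fr * 20)
    s_rem <- sum(x) - sum(sorted[seq_len(k)])
    exp(s_rem) / (exp(s_rem) + 1)
  }, numeric(1))
  expect_equal(dc$probabilities, probs, tolerance = 1e-9)
  expect_equal(dc$auc,
               sum(diff(dc$fractions) * (head(probs, -1) + tail(probs, -1)) / 2),
               tolerance = 1e-12)
  # nonnegative inputs, map = inputs: information removal is monotone
  expect_true(all(diff(dc$probabilities) <= 1e-12))
})

test_that("uniform maps delete in the documented raster tie-break order", {
  W <- rbind(rep(1, 20), rep(0, 20))
  m <- make_linear_model(W, input_shape = c(2, 10))
  x <- matrix(as.numeric(20:1), 2, 10)
  uni <- contribution_map(matrix(5, 2, 10), 1, "uniform")
  dc <- deletion_curve(m, x, uni, fractions = c(0.25, 0.5, 1))
  manual <- vapply(c(5, 10, 20), function(k) {
    xp <- x
    # raster order: channel 1 across time, then channel 2
    ord <- as.vector(t(matrix(seq_len(20), 2, 10)))
    xp[ord[seq_len(k)]] <- 0
    p <- forward_scores(m, xp)$probabilities[1]
    p
  }, numeric(1))
  expect_equal(dc$probabilities, manual, tolerance = 1e-12)
})

test_that("deletion at fraction 1 evaluates the all-fill sample in both modes", {
  m <- frozen_stock("relu-compact", N = 4, T = 64, seed = 5)
  x <- rand_input(4, 64, seed = 8, sd = 10)
  cls <- predict_class(m, x)
  cmap <- compute_contribution(m, x, cls, attribution_config("gradient_x_input"))
  p_zero <- forward_scores(m, matrix(0, 4, 64))$probabilities[cls]
  dc <- deletion_curve(m, x, cmap)
  expect_equal(dc$probabilities[length(dc$probabilities)], p_zero,
               tolerance = 1e-12)
  chm <- channel_contribution(cmap)
  dcc <- deletion_curve(m, x, chm, mode = "channel")
  expect_equal(dcc$probabilities[length(dcc$probabilities)], p_zero,
               tolerance = 1e-12)
  expect_error(deletion_curve(m, x, cmap, fractions = numeric(0)), "input error")
  expect_error(deletion_curve(m, x, cmap, fractions = c(0.5, 0.2)), "input error")
})

test_that("random maps are seeded and uncorrelated with model behaviour", {
  r1 <- random_contribution_map(20, 50, seed = 42)
  r2 <- random_contribution_map(20, 50, seed = 42)
  expect_identical(r1$scores, r2$scores)
  expect_lt(abs(mean(r1$scores)), 3 / sqrt(1000))

  set.seed(1)
  W <- matrix(rnorm(2 * 4 * 50), 2, 4 * 50)
  m <- make_linear_model(W, input_shape = c(4, 50))
  x <- rand_input(4, 50, seed = 31)
  cls <- predict_class(m, x)
  pccs <- vapply(1:200, function(s) {
    rm <- random_contribution_map(4, 50, seed = s, target_class = cls)
    sensitivity_test(m, x, rm, perturbation_spec(10, seed = 77))$pcc
  }, numeric(1))
  expect_lt(abs(median(pccs)), 0.1)
})

test_that("benchmark emits one row per cell and is order-invariant", {
  set.seed(4)
  W <- matrix(rnorm(2 * 4 * 40), 2, 4 * 40)
  m <- make_linear_model(W, input_shape = c(4, 40))
  samples <- lapply(1:4, function(i) rand_input(4, 40, seed = i))

  one <- benchmark(m, samples[1], methods = "gradient_x_input",
                   tests = "sensitivity", patch_fractions = 0.2,
                   include_random = FALSE, seed = 2)
  expect_equal(nrow(one$details), 1L)

  b1 <- benchmark(m, samples, methods = c("gradient_x_input", "saliency"),
                  tests = "sensitivity", patch_fractions = c(0.1, 0.3),
                  include_random = FALSE, seed = 2)
  b2 <- benchmark(m, rev(samples), methods = c("gradient_x_input", "saliency"),
                  tests = "sensitivity", patch_fractions = c(0.1, 0.3),
                  include_random = FALSE, seed = 2)
  s1 <- b1$summary[order(b1$summary$method, b1$summary$fraction), ]
  s2 <- b2$summary[order(b2$summary$method, b2$summary$fraction), ]
  expect_equal(s1$median, s2$median, tolerance = 1e-12)

  expect_error(benchmark(m, samples, methods = "cam"), "configuration error")
  expect_error(benchmark(m, samples, tests = "occlusion"), "configuration error")
})

test_that("evaluation-batch bookkeeping reproduces standard sizing arithmetic", {
  expect_identical(trial_count(list(c(4, 12, 5), c(1, 20, 5))), 340)
  expect_identical(evaluation_set_size(9, 4, 25), 900)
  expect_identical(evaluation_set_size(11, 2, 50), 1100)
  # 10 subjects, 2 classes, quota 50; two subjects short in class 1 get
  # topped up from class 2
  avail <- cbind(c1 = c(80, 90, 75, 60, 85, 70, 30, 40, 95, 88),
                 c2 = rep(200, 10))
  sel <- quota_selection(avail, 50)
  expect_equal(sel, rep(100, 10))
  expect_equal(sum(sel), 1000)
})
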