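test_that("z-score normalization is exact, degenerate-safe and idempotent", {
  cm <- contribution_map(matrix(c(1, 2, 3, 4), 1, 4), 1, "gradient_x_input")
  nm <- normalize_map(cm)
  expect_equal(mean(nm$scores), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(nm$scores^2)), 1, tolerance = 1e-12)
  expect_false(nm$degenerate)
  nm2 <- normalize_map(nm)
  expect_equal(nm2$scores, nm$scores, tolerance = 1e-12)

  flat <- normalize_map(contribution_map(matrix(3, 2, 5), 1, "x"))
  expect_true(flat$degenerate)
  expect_true(all(flat$scores == 0))
})

test_that("thresholding keeps the upper tail and enforces pipeline order", {
  cm <- normalize_map(contribution_map(rand_input(10, 100, seed = 1), 1, "x"))
  t0 <- threshold_map(cm, 0)
  expect_true(all(t0$scores >= 0))
  expect_equal(t0$scores[cm$scores >= 0], cm$scores[cm$scores >= 0])

  thi <- threshold_map(cm, max(cm$scores) + 1)
  expect_true(all(thi$scores == 0))

  # unnormalized input is rejected: the pipeline order is fixed
  raw <- contribution_map(rand_input(4, 10, seed = 2), 1, "x")
  expect_error(threshold_map(raw, 2), "normalize")

  # Monte-Carlo against the Gaussian tail: ~2.3% of a standard-normal map
  # survives threshold 2
  big <- normalize_map(contribution_map(rand_input(100, 100, seed = 9), 1, "x"))
  surv <- mean(threshold_map(big, 2)$scores != 0)
  expect_lt(abs(surv - 0.023), 0.01)

  # signed mode keeps both tails
  signed <- threshold_map(big, 2, signed = TRUE)
  expect_true(any(signed$scores < 0))
})

test_that("smoothing is a shrinking-window moving average preserving mass", {
  imp <- normalize_map(contribution_map(matrix(c(0, 0, 1, 0, 0), 1, 5), 1, "x"))
  imp$scores <- matrix(c(0, 0, 1, 0, 0), 1, 5)   # raw impulse, window checks
  sm <- smooth_map(imp, 5L)
  expect_equal(sm$scores[1, 3], 0.2, tolerance = 1e-12)
  expect_equal(sm$scores[1, 1], 1 / 3, tolerance = 1e-12)  # shrunk boundary

  ident <- smooth_map(imp, 1L)
  expect_identical(ident$scores, imp$scores)

  # interior-supported row: total mass preserved, matches direct convolution
  row <- numeric(40); row[15:25] <- runif(11)
  cm <- contribution_map(matrix(row, 1, 40), 1, "x")
  cm$normalized <- TRUE
  sm <- smooth_map(cm, 5L)
  expect_equal(sum(sm$scores), sum(row), tolerance = 1e-9)
  brute <- stats::filter(row, rep(1 / 5, 5), sides = 2)
  expect_equal(sm$scores[1, 3:38], as.numeric(brute[3:38]), tolerance = 1e-12)

  expect_error(visualization_config(smoothing_window = 4), "window")
})

test_that("an all-sub-threshold map yields an empty deletion and unchanged probability", {
  set.seed(3)
  W <- matrix(rnorm(2 * 4 * 60), 2, 4 * 60)
  m <- make_linear_model(W, input_shape = c(4, 60))
  x <- rand_input(4, 60, seed = 5)
  cls <- predict_class(m, x)
  cmap <- compute_contribution(m, x, cls, attribution_config("gradient_x_input"))
  rep <- generate_report(m, x, cmap,
                         vis_config = visualization_config(sample_threshold = 99,
                                                           channel_threshold = 99),
                         patch_fractions = c(0.1, 0.3),
                         num_perturbations = 20, seed = 2)
  expect_equal(rep$sample_deletion$portion, 0)
  expect_equal(rep$sample_deletion$probability,
               forward_scores(m, x)$probabilities[cls], tolerance = 1e-12)
  expect_equal(nrow(rep$sample_deletion$top_channels), 0)
})

test_that("report deletion numbers equal direct re-evaluation of the deleted sample", {
  fit <- trained_fixture()
  s <- fit$heldout$samples[[which(fit$heldout$labels == 2)[2]]]
  cls <- predict_class(fit$model, s)
  cmap <- compute_contribution(fit$model, s, cls,
                               attribution_config("gradient_x_input"))
  vis <- visualization_config()
  rep <- generate_report(fit$model, s, cmap, vis_config = vis,
                         patch_fractions = c(0.1, 0.5),
                         num_perturbations = 30, seed = 4)
  proc <- process_map(cmap, vis)
  xdel <- s$values
  xdel[proc$scores != 0] <- 0
  expect_equal(rep$sample_deletion$probability,
               forward_scores(fit$model, xdel)$probabilities[cls],
               tolerance = 1e-9)
  # portion accounting is exact rational arithmetic
  expect_equal(rep$sample_deletion$portion,
               sum(proc$scores != 0) / length(proc$scores), tolerance = 0)
  expect_lte(sum(rep$sample_deletion$top_channels$portion),
             rep$sample_deletion$portion + 1e-9)
  # channel-level: explicit removal agrees
  xch <- s$values
  xch[rep$channel_deletion$channels, ] <- 0
  expect_equal(rep$channel_deletion$probability,
               forward_scores(fit$model, xch)$probabilities[cls],
               tolerance = 1e-9)
})

test_that("top deleted channels coincide with the implanted feature channels", {
  fit <- trained_fixture()
  hits <- 0; total <- 0
  for (i in which(fit$heldout$labels == 2)[1:5]) {
    s <- fit$heldout$samples[[i]]
    cls <- predict_class(fit$model, s)
    if (cls != 2) next
    cmap <- compute_contribution(fit$model, s, cls,
                                 attribution_config("gradient_x_input"))
    rep <- generate_report(fit$model, s, cmap,
                           patch_fractions = 0.3, num_perturbations = 10,
                           seed = 6)
    total <- total + 1
    top <- rep$sample_deletion$top_channels$channel
    if (any(top %in% fit$spec$feature_channels[[2]])) hits <- hits + 1
  }
  expect_gte(hits, total - 1)   # allow one hard sample
  expect_gt(total, 0)
})

test_that("reports round-trip through JSON and render a four-line text block", {
  set.seed(8)
  W <- matrix(rnorm(2 * 4 * 60), 2, 4 * 60)
  m <- make_linear_model(W, input_shape = c(4, 60))
  x <- rand_input(4, 60, seed = 3)
  cls <- predict_class(m, x)
  cmap <- compute_contribution(m, x, cls, attribution_config("gradient_x_input"))
  rep <- generate_report(m, x, cmap, patch_fractions = c(0.1, 0.2),
                         num_perturbations = 20, seed = 11)
  txt <- report_text(rep)
  expect_length(txt, 4)
  expect_match(txt[1], "method: gradient_x_input")

  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$sample_deletion$probability,
               rep$sample_deletion$probability, tolerance = 1e-12)
  expect_equal(back$sensitivity$sample$pcc, rep$sensitivity$sample$pcc,
               tolerance = 1e-12)
  expect_equal(as.integer(back$channel_deletion$channels),
               as.integer(rep$channel_deletion$channels))
  expect_equal(back$header$method, rep$header$method)
})

test_that("overlay rendering writes a deterministic, non-empty image", {
  spec <- synthetic_spec()
  g <- generate_sample(spec, 2, 123)
  cmap <- contribution_map(g$mask * 1.0, 2, "oracle")
  proc <- process_map(cmap, visualization_config(sample_threshold = 0.5))
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  render_overlay(g$sample, proc, f1)
  render_overlay(g$sample, proc, f2)
  expect_true(file.exists(f1) && file.size(f1) > 0)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # zero map still renders plain traces
  zero <- contribution_map(matrix(0, 8, 256), 2, "none")
  zero$normalized <- TRUE
  f3 <- tempfile(fileext = ".png")
  render_overlay(g$sample, zero, f3)
  expect_true(file.size(f3) > 0)
})
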