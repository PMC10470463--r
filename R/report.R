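#' Visualization settings for contribution maps
#'
#' Raw backpropagation maps are too noisy to read directly; the pipeline is
#' normalize (global z-score), threshold (drop scores below the cutoff), then
#' smooth (centered moving average along time). Thresholds of 2 (sample map)
#' and 1 (channel map) on the standardized scores, with a window of 5
#' points, are the defaults.
#'
#' @param sample_threshold cutoff on the normalized sample map (>= 0).
#' @param channel_threshold cutoff on the normalized channel map (>= 0).
#' @param smoothing_window odd positive moving-average window (points).
#' @param signed if TRUE, thresholding keeps entries with `|score| >=`
#'   threshold (both polarities); the default keeps only positive evidence.
#' @return a `visualization_config` list.
#' @export
visualization_config <- function(sample_threshold = 2, channel_threshold = 1,
                                 smoothing_window = 5L, signed = FALSE) {
  stopifnot(sample_threshold >= 0, channel_threshold >= 0,
            smoothing_window >= 1, smoothing_window %% 2 == 1)
  structure(list(sample_threshold = sample_threshold,
                 channel_threshold = channel_threshold,
                 smoothing_window = as.integer(smoothing_window),
                 signed = isTRUE(signed),
                 normalization = "zscore"),
            class = "visualization_config")
}

#' Normalize, threshold and smooth a contribution map
#'
#' `normalize_map()` standardizes all entries to zero mean and unit standard
#' deviation (a constant map becomes all zeros and is flagged degenerate).
#' `threshold_map()` requires a normalized map and zeroes entries below the
#' cutoff (or below `|threshold|` in signed mode). `smooth_map()` applies a
#' centered moving average along the time axis per channel; boundary windows
#' shrink to the valid overlap rather than inventing padding. The pipeline
#' order is fixed — normalize, then threshold, then smooth — and is enforced
#' by `threshold_map()` refusing unnormalized input; [process_map()] runs the
#' full pipeline.
#'
#' @param cmap a [contribution_map] or [channel_contribution_map].
#' @return the transformed map (same class), with `normalized` and
#'   `degenerate` fields maintained.
#' @export
normalize_map <- function(cmap) {
  sc <- if (inherits(cmap, "channel_contribution_map")) cmap$scores else cmap$scores
  mu <- mean(sc)
  sdv <- sqrt(mean((sc - mu)^2))
  if (sdv < 1e-12) {
    cmap$scores <- sc * 0
    cmap$degenerate <- TRUE
  } else {
    cmap$scores <- (sc - mu) / sdv
    cmap$degenerate <- FALSE
  }
  cmap$normalized <- TRUE
  cmap
}

#' @rdname normalize_map
#' @param threshold cutoff on the standardized scores.
#' @param signed keep both polarities (`|score| >= threshold`).
#' @export
threshold_map <- function(cmap, threshold, signed = FALSE) {
  if (!isTRUE(cmap$normalized)) {
    stop("threshold_map() expects a normalized map; run normalize_map() first",
         call. = FALSE)
  }
  sc <- cmap$scores
  keep <- if (signed) abs(sc) >= threshold else sc >= threshold
  sc[!keep] <- 0
  cmap$scores <- sc
  cmap
}

#' @rdname normalize_map
#' @param window odd moving-average window length.
#' @export
smooth_map <- function(cmap, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1L || inherits(cmap, "channel_contribution_map")) return(cmap)
  half <- (window - 1L) %/% 2L
  sc <- cmap$scores
  T <- ncol(sc)
  out <- sc
  csum <- cbind(0, t(apply(sc, 1, cumsum)))
  for (j in seq_len(T)) {
    lo <- max(1L, j - half); hi <- min(T, j + half)
    out[, j] <- (csum[, hi + 1L] - csum[, lo]) / (hi - lo + 1L)
  }
  cmap$scores <- out
  cmap
}

#' @rdname normalize_map
#' @param config a [visualization_config()].
#' @export
process_map <- function(cmap, config = visualization_config()) {
  thr <- if (inherits(cmap, "channel_contribution_map")) {
    config$channel_threshold
  } else config$sample_threshold
  out <- normalize_map(cmap)
  out <- threshold_map(out, thr, signed = config$signed)
  smooth_map(out, config$smoothing_window)
}

#' Sample-wise evaluation report
#'
#' Bundles, for one sample, the processing settings, the faithfulness-test
#' results and the prediction metadata into a trust report. The sensitivity
#' test runs on the original (unprocessed) contribution map — it measures the
#' map's best local correlation with the model output — while the deletion
#' checks run on the processed map: exactly the points surviving
#' threshold-and-smooth (sample level) and the channels surviving the channel
#' threshold are zeroed, and the new probabilities recorded, so the numbers
#' relate directly to what the overlay displays.
#'
#' @param model an `eeg_model` (statistics frozen).
#' @param sample the sample (matrix or [eeg_sample]).
#' @param cmap contribution map for the model's predicted class.
#' @param chmap its channel contribution map (default: temporal mean of
#'   `cmap`).
#' @param vis_config a [visualization_config()].
#' @param patch_fractions sensitivity-test patch fractions.
#' @param num_perturbations perturbations per fraction.
#' @param seed seed for the perturbation draws.
#' @return an `evaluation_report`.
#' @export
generate_report <- function(model, sample, cmap, chmap = NULL,
                            vis_config = visualization_config(),
                            patch_fractions = seq(0.1, 0.5, by = 0.1),
                            num_perturbations = 100L, seed = 1L) {
  x <- .as_matrix_sample(sample)
  .check_shape(model, x)
  if (is.null(chmap)) chmap <- channel_contribution(cmap)
  N <- nrow(x); T <- ncol(x)
  sc <- forward_scores(model, x)
  pred <- which.max(sc$activations)
  if (pred != cmap$target_class) {
    warning("contribution map targets class ", cmap$target_class,
            " but the model predicts class ", pred)
  }
  cls <- cmap$target_class

  sens <- data.frame(fraction = patch_fractions, pcc = NA_real_)
  for (i in seq_along(patch_fractions)) {
    spec <- perturbation_spec(patch_length(patch_fractions[i], T),
                              num_perturbations = num_perturbations,
                              seed = .derive_seed(seed, i))
    sens$pcc[i] <- sensitivity_test(model, x, cmap, spec)$pcc
  }
  ch_sens <- sensitivity_test_channels(model, x, chmap)

  proc <- process_map(cmap, vis_config)
  degenerate <- isTRUE(proc$degenerate)
  if (!degenerate) {
    deleted <- proc$scores != 0
    n_del <- sum(deleted)
    xp <- x; xp[deleted] <- 0
    new_prob <- .softmax(.forward1(model, xp)$scores)[cls]
    per_ch <- rowSums(deleted)
    ord <- order(-per_ch, seq_len(N))
    top <- ord[per_ch[ord] > 0]
    top <- utils::head(top, 3L)
    sample_del <- list(probability = new_prob, portion = n_del / (N * T),
                       top_channels = data.frame(
                         channel = top,
                         portion = per_ch[top] / (N * T)))
  } else {
    sample_del <- list(probability = sc$probabilities[cls], portion = 0,
                       top_channels = data.frame(channel = integer(0),
                                                 portion = numeric(0)))
  }

  proc_ch <- normalize_map(chmap)
  ch_degenerate <- isTRUE(proc_ch$degenerate)
  removed <- if (ch_degenerate) integer(0) else {
    which(proc_ch$scores >= vis_config$channel_threshold)
  }
  ch_prob <- channel_removal_probability(model, x, removed, cls)

  structure(list(
    header = list(model = model$tag, method = cmap$method,
                  smoothing_window = vis_config$smoothing_window,
                  sample_threshold = vis_config$sample_threshold,
                  channel_threshold = vis_config$channel_threshold,
                  seed = seed),
    prediction = list(predicted_class = pred,
                      label = if (inherits(sample, "eeg_sample")) sample$label else NULL,
                      probabilities = as.numeric(sc$probabilities)),
    sensitivity = list(sample = sens, channel_pcc = ch_sens$pcc),
    sample_deletion = sample_del,
    channel_deletion = list(probability = ch_prob, channels = removed),
    degenerate = degenerate || ch_degenerate,
    processed_map = proc),
    class = "evaluation_report")
}

#' Four-line text rendering of an evaluation report
#'
#' Line 1: model, method and processing settings. Line 2: sensitivity
#' results (sample-map correlation range over the patch fractions, and the
#' channel-map correlation). Line 3: sample-level deletion (new probability,
#' deleted portion, top-3 channels with their portions). Line 4:
#' channel-level deletion (new probability, removed channels).
#'
#' @param report an `evaluation_report`.
#' @param channel_names optional channel names used in lines 3-4.
#' @return character vector of four lines.
#' @export
report_text <- function(report, channel_names = NULL) {
  h <- report$header
  cname <- function(i) {
    if (is.null(channel_names)) paste0("ch", i) else channel_names[i]
  }
  r <- report$sensitivity$sample$pcc
  l1 <- sprintf("model: %s | method: %s | window: %d | thresholds: %g (sample), %g (channel)",
                h$model, h$method, h$smoothing_window, h$sample_threshold,
                h$channel_threshold)
  l2 <- sprintf("sensitivity r: %.2f-%.2f (sample) | %.2f (channel)",
                min(r, na.rm = TRUE), max(r, na.rm = TRUE),
                report$sensitivity$channel_pcc)
  tc <- report$sample_deletion$top_channels
  tc_txt <- if (nrow(tc) == 0) "none" else {
    paste(sprintf("%s (%.2f)", vapply(tc$channel, cname, character(1)),
                  tc$portion), collapse = ", ")
  }
  l3 <- sprintf("sample deletion: p = %.2f | portion = %.2f | top channels: %s",
                report$sample_deletion$probability,
                report$sample_deletion$portion, tc_txt)
  chs <- report$channel_deletion$channels
  l4 <- sprintf("channel deletion: p = %.2f | channels: %s",
                report$channel_deletion$probability,
                if (length(chs) == 0) "none" else
                  paste(vapply(chs, cname, character(1)), collapse = ", "))
  c(l1, l2, l3, l4)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Serialize / restore an evaluation report
#'
#' @param report an `evaluation_report`.
#' @param path file path for the JSON document.
#' @return `write_report()` the path, invisibly; `read_report()` the restored
#'   `evaluation_report` (without the processed map, which is recomputable).
#' @export
write_report <- function(report, path) {
  obj <- report
  obj$processed_map <- NULL
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sensitivity$sample <- as.data.frame(obj$sensitivity$sample)
  obj$sample_deletion$top_channels <-
    as.data.frame(obj$sample_deletion$top_channels)
  structure(obj, class = "evaluation_report")
}

#' Render the processed map as a colored overlay on the signal traces
#'
#' Draws one stacked-trace figure: each channel's signal as a line, with the
#' surviving (processed) contribution scores shown as color intensity over
#' the trace, and the four-line evaluation report printed underneath when
#' given. Output is a PNG file, deterministic for fixed inputs.
#'
#' @param sample the sample (matrix or [eeg_sample]).
#' @param processed_map a processed [contribution_map] (same shape).
#' @param out_path output PNG path.
#' @param report optional `evaluation_report` whose text box is added.
#' @param width,height device size in pixels.
#' @return `out_path`, invisibly.
#' @export
render_overlay <- function(sample, processed_map, out_path, report = NULL,
                           width = 900, height = 600) {
  x <- .as_matrix_sample(sample)
  sc <- processed_map$scores
  stopifnot(all(dim(sc) == dim(x)))
  N <- nrow(x); T <- ncol(x)
  fs <- if (inherits(sample, "eeg_sample")) sample$sampling_rate else 1
  cn <- if (inherits(sample, "eeg_sample")) sample$channel_names
        else paste0("ch", seq_len(N))
  smax <- max(sc)
  pal <- grDevices::colorRamp(c("grey30", "orange", "red"))
  spacing <- 2 * max(stats::sd(x), 1e-9) * 3
  grDevices::png(out_path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(if (is.null(report)) 4 else 10, 5, 2, 1))
  tt <- (seq_len(T) - 1) / fs
  graphics::plot(NA, xlim = range(tt), ylim = c(-spacing * N, 0),
                 xlab = if (fs == 1) "time (points)" else "time (s)",
                 ylab = "", yaxt = "n")
  graphics::axis(2, at = -spacing * (seq_len(N) - 0.5), labels = cn, las = 1)
  for (i in seq_len(N)) {
    y <- x[i, ] - spacing * (i - 0.5)
    inten <- if (smax > 0) pmin(sc[i, ] / smax, 1) else rep(0, T)
    seg_int <- pmax(utils::head(inten, -1), utils::tail(inten, -1))
    cols <- grDevices::rgb(pal(seg_int), maxColorValue = 255)
    graphics::segments(utils::head(tt, -1), utils::head(y, -1),
                       utils::tail(tt, -1), utils::tail(y, -1),
                       col = cols, lwd = ifelse(seg_int > 0, 2, 1))
  }
  if (!is.null(report)) {
    graphics::mtext(paste(report_text(report, cn), collapse = "\n"),
                    side = 1, line = 8, cex = 0.8, adj = 0)
  }
  invisible(out_path)
}
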