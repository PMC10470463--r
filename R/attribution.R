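#' EEG sample container
#'
#' A sample is an N x T numeric matrix of signal amplitudes (microvolts),
#' N channels by T sampling points, with channel names and a sampling rate.
#'
#' @param values N x T numeric matrix (rows are channels).
#' @param channel_names character vector of N unique channel names; defaults
#'   to `ch1..chN`.
#' @param sampling_rate sampling rate in Hz.
#' @param label optional class label (integer).
#' @param subject optional subject identifier.
#' @return an `eeg_sample` object.
#' @export
eeg_sample <- function(values, channel_names = NULL, sampling_rate = 128,
                       label = NULL, subject = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("input error: sample must have at least one channel and one timepoint",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("input error: sample values must be finite", call. = FALSE)
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(values)))
  if (length(channel_names) != nrow(values) || anyDuplicated(channel_names)) {
    stop("input error: channel_names must be unique and match the row count",
         call. = FALSE)
  }
  stopifnot(sampling_rate > 0)
  structure(list(values = unname(values), channel_names = as.character(channel_names),
                 sampling_rate = as.numeric(sampling_rate),
                 label = if (is.null(label)) NULL else as.integer(label),
                 subject = subject),
            class = "eeg_sample")
}

#' @export
print.eeg_sample <- function(x, ...) {
  cat("<eeg_sample> ", nrow(x$values), " channels x ", ncol(x$values),
      " points @ ", x$sampling_rate, " Hz", sep = "")
  if (!is.null(x$label)) cat("; label ", x$label, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.eeg_sample <- function(x) dim(x$values)

#' Contribution map containers
#'
#' A contribution map assigns a score R_c(i, j) to every sampling point of
#' one sample, quantifying its contribution to the model's pre-softmax score
#' for target class c. Averaging over the temporal dimension yields the
#' channel contribution map (one score per electrode).
#'
#' @param scores N x T numeric matrix (or length-N vector for the channel
#'   variant).
#' @param target_class 1-based class index the map explains.
#' @param method method tag.
#' @param model_tag identifier of the model that produced the map.
#' @return a `contribution_map` / `channel_contribution_map` object.
#' @export
contribution_map <- function(scores, target_class, method, model_tag = "model") {
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stop("contribution scores must be finite", call. = FALSE)
  structure(list(scores = unname(scores), target_class = as.integer(target_class),
                 method = method, model_tag = model_tag),
            class = "contribution_map")
}

#' @rdname contribution_map
#' @export
channel_contribution_map <- function(scores, target_class, method,
                                     model_tag = "model") {
  scores <- as.numeric(scores)
  if (!all(is.finite(scores))) stop("contribution scores must be finite", call. = FALSE)
  structure(list(scores = scores, target_class = as.integer(target_class),
                 method = method, model_tag = model_tag),
            class = "channel_contribution_map")
}

#' @export
print.contribution_map <- function(x, ...) {
  cat("<contribution_map> ", x$method, ", class ", x$target_class, ", ",
      nrow(x$scores), "x", ncol(x$scores), "\n", sep = "")
  invisible(x)
}

#' @export
print.channel_contribution_map <- function(x, ...) {
  cat("<channel_contribution_map> ", x$method, ", class ", x$target_class,
      ", ", length(x$scores), " channels\n", sep = "")
  invisible(x)
}

#' Attribution configuration
#'
#' @param method one of `"saliency"`, `"deconvolution"`, `"guided_backprop"`,
#'   `"gradient_x_input"`, `"integrated_gradient"`, `"lrp_eps"`,
#'   `"deeplift_rescale"`.
#' @param baseline baseline sample (matrix of the model's input shape);
#'   default all zeros. Used by integrated gradients and DeepLIFT.
#' @param ig_steps number of path steps for integrated gradients.
#' @param lrp_epsilon stabilizer for the epsilon rule (also the DeepLIFT
#'   degeneracy cutoff). The default 1e-9 is small enough that, on ReLU-only
#'   models, the epsilon rule coincides with gradient x input to well below
#'   1e-5 relative.
#' @param saliency_absolute return `|gradient|` instead of the signed
#'   gradient for the saliency method.
#' @return an `attribution_config` list.
#' @export
attribution_config <- function(method = "gradient_x_input", baseline = NULL,
                               ig_steps = 100L, lrp_epsilon = 1e-9,
                               saliency_absolute = FALSE) {
  methods <- c("saliency", "deconvolution", "guided_backprop",
               "gradient_x_input", "integrated_gradient", "lrp_eps",
               "deeplift_rescale")
  if (!method %in% methods) {
    stop("configuration error: unknown method '", method, "'", call. = FALSE)
  }
  stopifnot(ig_steps >= 1, lrp_epsilon > 0)
  structure(list(method = method, baseline = baseline,
                 ig_steps = as.integer(ig_steps),
                 lrp_epsilon = as.numeric(lrp_epsilon),
                 saliency_absolute = isTRUE(saliency_absolute)),
            class = "attribution_config")
}

#' Modified-gradient backward pass
#'
#' Computes the gradient of the pre-softmax class score with respect to the
#' input, with the local derivative at every elementwise nonlinearity
#' replaced by a rule-specific factor. This single primitive underlies all
#' seven attribution methods.
#'
#' @param model an `eeg_model` (batch-normalization statistics frozen or
#'   running).
#' @param sample input sample (matrix or [eeg_sample]).
#' @param target_class 1-based class index.
#' @param rule one of `"plain"`, `"deconv"`, `"guided"`, `"lrp_eps"`,
#'   `"deeplift"`.
#' @param eps stabilizer / degeneracy cutoff for `"lrp_eps"` and
#'   `"deeplift"`.
#' @param baseline baseline sample for `"deeplift"` (default all zeros).
#' @return N x T numeric matrix of modified gradients.
#' @export
modified_gradient <- function(model, sample, target_class,
                              rule = c("plain", "deconv", "guided",
                                       "lrp_eps", "deeplift"),
                              eps = 1e-6, baseline = NULL) {
  rule <- match.arg(rule)
  x <- .as_matrix_sample(sample)
  .check_shape(model, x)
  if (target_class < 1L || target_class > model$num_classes) {
    stop("input error: target_class out of range", call. = FALSE)
  }
  fwd <- .forward1(model, x)
  bl_caches <- NULL
  if (rule == "deeplift") {
    xb <- if (is.null(baseline)) matrix(0, nrow(x), ncol(x)) else .as_matrix_sample(baseline)
    if (!all(dim(xb) == dim(x))) stop("input error: baseline shape mismatch", call. = FALSE)
    bl_caches <- .forward1(model, xb)$caches
  }
  onehot <- numeric(model$num_classes)
  onehot[target_class] <- 1
  .backward1(model, fwd$caches, onehot, rule = rule, eps = eps,
             bl_caches = bl_caches)$grad_input
}

#' Compute a contribution map
#'
#' Dispatches the seven backpropagation-based attribution methods through the
#' modified-gradient engine:
#' \describe{
#'   \item{saliency}{the plain gradient of the class score (absolute value if
#'     `saliency_absolute`).}
#'   \item{deconvolution / guided_backprop}{the corresponding modified
#'     gradients.}
#'   \item{gradient_x_input}{input times plain gradient.}
#'   \item{integrated_gradient}{`(x - baseline)` times the average plain
#'     gradient along the straight path from the baseline, `ig_steps` steps.}
#'   \item{lrp_eps}{input times the epsilon-rule modified gradient
#'     (layer-wise relevance propagation).}
#'   \item{deeplift_rescale}{`(x - baseline)` times the rescale-rule modified
#'     gradient.}
#' }
#'
#' @param model an `eeg_model`.
#' @param sample input sample.
#' @param target_class 1-based class index to explain.
#' @param config an [attribution_config()].
#' @return a [contribution_map].
#' @export
compute_contribution <- function(model, sample, target_class,
                                 config = attribution_config()) {
  x <- .as_matrix_sample(sample)
  .check_shape(model, x)
  xb <- if (is.null(config$baseline)) matrix(0, nrow(x), ncol(x))
        else .as_matrix_sample(config$baseline)
  if (!all(dim(xb) == dim(x))) {
    stop("input error: baseline shape mismatch", call. = FALSE)
  }
  eps <- config$lrp_epsilon
  scores <- switch(config$method,
    saliency = {
      gr <- modified_gradient(model, x, target_class, "plain")
      if (config$saliency_absolute) abs(gr) else gr
    },
    deconvolution = modified_gradient(model, x, target_class, "deconv"),
    guided_backprop = modified_gradient(model, x, target_class, "guided"),
    gradient_x_input = x * modified_gradient(model, x, target_class, "plain"),
    integrated_gradient = {
      m <- config$ig_steps
      acc <- matrix(0, nrow(x), ncol(x))
      # midpoint rule along the straight path: second-order accurate, so
      # 100 steps suffice for completeness to well under 1%
      for (k in seq_len(m)) {
        xk <- xb + ((k - 0.5) / m) * (x - xb)
        acc <- acc + modified_gradient(model, xk, target_class, "plain")
      }
      (x - xb) * (acc / m)
    },
    lrp_eps = x * modified_gradient(model, x, target_class, "lrp_eps", eps = eps),
    deeplift_rescale = (x - xb) *
      modified_gradient(model, x, target_class, "deeplift", eps = eps,
                        baseline = xb),
    stop("configuration error: unknown method '", config$method, "'",
         call. = FALSE)
  )
  contribution_map(scores, target_class, config$method, model$tag)
}

#' Channel contribution map (temporal average)
#'
#' Averages a contribution map over the temporal dimension, yielding the mean
#' contribution of each EEG channel to the classification.
#'
#' @param cmap a [contribution_map].
#' @return a [channel_contribution_map].
#' @export
channel_contribution <- function(cmap) {
  stopifnot(inherits(cmap, "contribution_map"))
  channel_contribution_map(rowMeans(cmap$scores), cmap$target_class,
                           cmap$method, cmap$model_tag)
}

# Methods whose maps scale with the input (used by the benchmark grouping).
.GROUP1_METHODS <- c("gradient_x_input", "integrated_gradient", "lrp_eps",
                     "deeplift_rescale")
.GROUP2_METHODS <- c("saliency", "deconvolution", "guided_backprop")
.ALL_METHODS <- c(.GROUP1_METHODS, .GROUP2_METHODS)
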