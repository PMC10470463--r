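#' Build a compact EEG classifier
#'
#' Constructs a feed-forward convolutional network from an ordered list of
#' [layer_spec] objects and initializes its parameters reproducibly from a
#' seed. Two stock architectures are available through
#' [stock_architecture()]: `"relu-compact"` and `"elu-compact"`, each a
#' temporal convolution and a spatial (cross-channel) convolution — each
#' followed by batch normalization, as in EEGNet-style models, which keeps
#' optimization well-conditioned for microvolt-scale inputs — then a
#' nonlinearity, mean pooling and a dense output: the minimal structure that
#' exercises every gradient rule a modern EEG classifier triggers during
#' attribution.
#'
#' @param arch list of [layer_spec] objects (or a stock architecture name).
#' @param num_classes number of output classes (>= 2).
#' @param input_shape integer pair `c(channels, timepoints)` of the samples
#'   the model accepts.
#' @param seed integer seed for weight initialization.
#' @param tag optional model identifier carried into contribution maps.
#' @return an object of class `eeg_model`.
#' @examples
#' m <- build_model(stock_architecture("relu-compact"), num_classes = 2,
#'                  input_shape = c(8, 128), seed = 7)
#' forward_scores(m, list(matrix(0, 8, 128)))
#' @export
build_model <- function(arch, num_classes, input_shape, seed = 1L,
                        tag = NULL) {
  if (is.character(arch) && length(arch) == 1L) arch <- stock_architecture(arch)
  stopifnot(num_classes >= 2, length(input_shape) == 2)
  if (is.null(tag)) tag <- "eeg_model"
  arch <- lapply(arch, function(l) {
    if (l$kind == "dense" && is.null(l$units)) l$units <- as.integer(num_classes)
    l
  })
  info <- .infer_shapes(arch, input_shape)
  if (info$out != num_classes) {
    stop("configuration error: output layer produces ", info$out,
         " scores for ", num_classes, " classes", call. = FALSE)
  }
  old <- .seed_push(seed)
  on.exit(.seed_pop(old), add = TRUE)
  layers <- vector("list", length(arch))
  for (i in seq_along(arch)) {
    l <- arch[[i]]
    s_in <- info$shapes[[i]]
    layers[[i]] <- switch(l$kind,
      conv_time = {
        fan_in <- s_in[1] * l$kernel
        list(kind = "conv_time", kernel = l$kernel, filters = l$filters,
             W = array(stats::rnorm(l$filters * s_in[1] * l$kernel,
                                    sd = sqrt(2 / fan_in)),
                       dim = c(l$filters, s_in[1], l$kernel)),
             b = numeric(l$filters))
      },
      conv_channels = {
        fan_in <- s_in[1] * s_in[2]
        list(kind = "conv_channels", filters = l$filters,
             W = array(stats::rnorm(l$filters * fan_in, sd = sqrt(2 / fan_in)),
                       dim = c(l$filters, s_in[1], s_in[2])),
             b = numeric(l$filters))
      },
      batchnorm = list(kind = "batchnorm", gamma = rep(1, s_in[1]),
                       beta = numeric(s_in[1]),
                       running_mean = numeric(s_in[1]),
                       running_var = rep(1, s_in[1]),
                       frozen = FALSE, frozen_mean = NULL, frozen_var = NULL),
      nonlinearity = list(kind = "nonlinearity", fun = l$fun),
      pool = list(kind = "pool", type = l$type, window = l$window),
      flatten = list(kind = "flatten", shape = s_in),
      dense = {
        fan_in <- s_in[1]
        list(kind = "dense",
             W = matrix(stats::rnorm(l$units * fan_in, sd = sqrt(2 / fan_in)),
                        nrow = l$units, ncol = fan_in),
             b = numeric(l$units))
      }
    )
  }
  structure(list(arch = arch, layers = layers,
                 input_shape = as.integer(input_shape),
                 num_classes = as.integer(num_classes),
                 seed = as.integer(seed), tag = tag,
                 shapes = info$shapes),
            class = "eeg_model")
}

#' @rdname build_model
#' @param name stock architecture name.
#' @param filters feature maps per convolutional stage.
#' @param kernel temporal kernel length (sampling points).
#' @param pool mean-pooling window.
#' @export
stock_architecture <- function(name = c("relu-compact", "elu-compact"),
                               filters = 8L, kernel = 17L, pool = 8L) {
  name <- match.arg(name)
  fun <- if (name == "relu-compact") "relu" else "elu"
  list(layer_conv_time(filters, kernel),
       layer_batchnorm(),
       layer_conv_channels(filters),
       layer_batchnorm(),
       layer_nonlinearity(fun),
       layer_pool("mean", pool),
       layer_flatten(),
       layer_dense())
}

#' @export
print.eeg_model <- function(x, ...) {
  kinds <- vapply(x$layers, function(l) l$kind, character(1))
  cat("<eeg_model> ", x$tag, "\n", sep = "")
  cat("  input: ", x$input_shape[1], " channels x ", x$input_shape[2],
      " timepoints; ", x$num_classes, " classes\n", sep = "")
  cat("  layers: ", paste(kinds, collapse = " -> "), "\n", sep = "")
  frozen <- any(vapply(x$layers,
                       function(l) identical(l$kind, "batchnorm") && isTRUE(l$frozen),
                       logical(1)))
  if (frozen) cat("  batchnorm statistics: frozen\n")
  invisible(x)
}

# ---- RNG helpers ------------------------------------------------------------

.seed_push <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

.seed_pop <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Derive a child seed < 2^31 from a parent seed and an index.
.derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629)
}

# ---- elementwise nonlinearities --------------------------------------------

.nl_f <- function(fun, z) {
  switch(fun,
    relu = pmax(z, 0),
    elu = ifelse(z > 0, z, expm1(z)),
    stop("unknown nonlinearity '", fun, "'", call. = FALSE))
}

.nl_fprime <- function(fun, z) {
  switch(fun,
    relu = as.numeric(z > 0),
    elu = ifelse(z > 0, 1, exp(z)),
    stop("unknown nonlinearity '", fun, "'", call. = FALSE))
}

.BN_EPS <- 1e-5

# ---- single-sample forward --------------------------------------------------

# x: channels x time matrix. Returns list(scores, caches) where caches[[i]]
# stores what layer i's backward pass needs. Batchnorm uses frozen statistics
# when present, running statistics otherwise, unless `bn_stats` supplies
# per-layer batch statistics (training mode).
.forward1 <- function(model, x, bn_stats = NULL) {
  a <- array(x, dim = c(1L, nrow(x), ncol(x)))
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    res <- switch(l$kind,
      conv_time = .fwd_conv_time(l, a),
      conv_channels = .fwd_conv_channels(l, a),
      batchnorm = {
        st <- if (!is.null(bn_stats) && !is.null(bn_stats[[i]])) bn_stats[[i]]
              else .bn_current_stats(l)
        .fwd_batchnorm(l, a, st)
      },
      nonlinearity = {
        out <- .nl_f(l$fun, a)
        if (!is.null(dim(a))) dim(out) <- dim(a)
        list(out = out, cache = list(z = a))
      },
      pool = .fwd_pool(l, a),
      flatten = list(out = as.vector(a), cache = list(dim = dim(a))),
      dense = list(out = drop(l$W %*% a) + l$b, cache = list(x = a))
    )
    a <- res$out
    caches[[i]] <- res$cache
  }
  list(scores = a, caches = caches)
}

.bn_current_stats <- function(l) {
  if (isTRUE(l$frozen)) list(mean = l$frozen_mean, var = l$frozen_var)
  else list(mean = l$running_mean, var = l$running_var)
}

.fwd_conv_time <- function(l, a) {
  d <- dim(a); G <- d[1]; C <- d[2]; T_in <- d[3]
  L <- l$kernel; Tout <- T_in - L + 1L; F_out <- l$filters
  idx <- outer(seq_len(Tout), 0:(L - 1L), `+`)      # Tout x L time indices
  Z <- matrix(0, C * Tout, F_out)
  wins <- vector("list", G)
  for (g in seq_len(G)) {
    Xg <- matrix(a[g, , ], nrow = C)                # C x T
    m <- Xg[, as.vector(idx), drop = FALSE]         # C x (Tout*L)
    dim(m) <- c(C * Tout, L)                        # row = c + (t-1)*C
    wins[[g]] <- m
    Wg <- matrix(l$W[, g, ], nrow = F_out)          # F x L
    Z <- Z + m %*% t(Wg)
  }
  out <- aperm(array(Z, dim = c(C, Tout, F_out)), c(3, 1, 2)) + l$b
  list(out = out, cache = list(wins = wins, dims = c(G, C, T_in, Tout)))
}

.fwd_conv_channels <- function(l, a) {
  d <- dim(a); G <- d[1]; C <- d[2]; T_in <- d[3]
  inmat <- matrix(a, nrow = G * C)                  # (G*C) x T
  Wmat <- matrix(l$W, nrow = l$filters)             # F x (G*C)
  out <- array(Wmat %*% inmat + l$b, dim = c(l$filters, 1L, T_in))
  list(out = out, cache = list(inmat = inmat, dims = d))
}

.fwd_batchnorm <- function(l, a, st) {
  d <- dim(a)
  inv_sd <- 1 / sqrt(st$var + .BN_EPS)
  xhat <- (a - st$mean) * inv_sd                    # recycles over (c,t)
  out <- array(xhat * l$gamma + l$beta, dim = d)
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd))
}

.fwd_pool <- function(l, a) {
  d <- dim(a); G <- d[1]; C <- d[2]; T_in <- d[3]
  w <- l$window; Tout <- T_in %/% w
  if (l$type == "mean") {
    A <- matrix(a, G * C, T_in)
    P <- matrix(0, T_in, Tout)
    P[cbind(seq_len(Tout * w), rep(seq_len(Tout), each = w))] <- 1 / w
    pooled <- A %*% P
    cache <- list(dims = d, Tout = Tout)
  } else {
    used <- a[, , seq_len(Tout * w), drop = FALSE]
    dim(used) <- c(G * C, w, Tout)
    arg <- apply(used, c(1, 3), which.max)          # first index on ties
    pooled <- apply(used, c(1, 3), max)
    cache <- list(dims = d, Tout = Tout, argmax = arg)
  }
  list(out = array(pooled, dim = c(G, C, Tout)), cache = cache)
}

# ---- scores -----------------------------------------------------------------

.softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

.as_matrix_sample <- function(s) {
  if (inherits(s, "eeg_sample")) s$values else as.matrix(s)
}

.check_shape <- function(model, x) {
  if (!all(dim(x) == model$input_shape)) {
    stop("input error: sample is ", nrow(x), "x", ncol(x),
         " but the model expects ", model$input_shape[1], "x",
         model$input_shape[2], call. = FALSE)
  }
  if (!all(is.finite(x))) stop("input error: sample contains non-finite values", call. = FALSE)
  invisible(TRUE)
}

#' Forward pass: class scores and probabilities
#'
#' Runs a batch of samples through the model with its current (frozen or
#' running) batch-normalization statistics and returns, per sample, the
#' pre-softmax activation score for each class together with the softmax
#' probabilities.
#'
#' @param model an `eeg_model`.
#' @param batch list of samples (matrices or [eeg_sample] objects), or a
#'   single sample.
#' @return list of `class_scores` objects (fields `activations`,
#'   `probabilities`); a single object if a single sample was given.
#' @export
forward_scores <- function(model, batch) {
  single <- !is.list(batch) || inherits(batch, "eeg_sample")
  if (single) batch <- list(batch)
  out <- lapply(batch, function(s) {
    x <- .as_matrix_sample(s)
    .check_shape(model, x)
    act <- .forward1(model, x)$scores
    structure(list(activations = act, probabilities = .softmax(act)),
              class = "class_scores")
  })
  if (single) out[[1]] else out
}

#' @export
print.class_scores <- function(x, ...) {
  cat("<class_scores> activations:", format(x$activations, digits = 4),
      "\n  probabilities:", format(x$probabilities, digits = 4), "\n")
  invisible(x)
}

#' Predicted class of a sample
#'
#' @param model an `eeg_model`.
#' @param sample a matrix or [eeg_sample].
#' @return integer class index (1-based).
#' @export
predict_class <- function(model, sample) {
  which.max(forward_scores(model, sample)$activations)
}

#' Freeze batch-normalization statistics from a reference batch
#'
#' Replaces every batch-normalization layer's statistics with the mean and
#' variance captured from a single forward pass of `reference_batch`, and
#' marks them frozen. A frozen layer is a fixed affine map, so forward and
#' backward passes treat the statistics as constants and single-sample
#' attribution no longer depends on batch companions.
#'
#' @param model an `eeg_model`.
#' @param reference_batch non-empty list of samples.
#' @return the model with frozen statistics (unchanged if it has no
#'   batch-normalization layers).
#' @export
freeze_batch_stats <- function(model, reference_batch) {
  if (!is.list(reference_batch) || inherits(reference_batch, "eeg_sample")) {
    reference_batch <- list(reference_batch)
  }
  if (length(reference_batch) == 0L) {
    stop("input error: reference batch is empty", call. = FALSE)
  }
  bn_idx <- which(vapply(model$layers, function(l) l$kind == "batchnorm", logical(1)))
  if (length(bn_idx) == 0L) return(model)
  xs <- lapply(reference_batch, function(s) {
    x <- .as_matrix_sample(s); .check_shape(model, x); x
  })
  stats <- .batch_bn_stats(model, xs)
  for (i in bn_idx) {
    model$layers[[i]]$frozen <- TRUE
    model$layers[[i]]$frozen_mean <- stats[[i]]$mean
    model$layers[[i]]$frozen_var <- stats[[i]]$var
  }
  model
}

# Forward the whole batch layer by layer, computing per-feature-map batch
# statistics at each batchnorm layer (biased variance, as used at freeze
# time). Returns the list of stats indexed by layer.
.batch_bn_stats <- function(model, xs) {
  acts <- lapply(xs, function(x) array(x, dim = c(1L, nrow(x), ncol(x))))
  stats <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$kind == "batchnorm") {
      st <- .bn_batch_moments(acts)
      stats[[i]] <- st
      acts <- lapply(acts, function(a) .fwd_batchnorm(l, a, st)$out)
    } else {
      acts <- lapply(acts, function(a) .fwd_generic(model, i, a))
    }
  }
  stats
}

.bn_batch_moments <- function(acts) {
  G <- dim(acts[[1]])[1]
  per_map <- function(f) unlist(lapply(acts, function(a) a[f, , ]))
  m <- numeric(G); v <- numeric(G)
  for (f in seq_len(G)) {
    vals <- per_map(f)
    m[f] <- mean(vals)
    v[f] <- mean((vals - m[f])^2)
  }
  list(mean = m, var = v)
}

.fwd_generic <- function(model, i, a) {
  l <- model$layers[[i]]
  switch(l$kind,
    conv_time = .fwd_conv_time(l, a)$out,
    conv_channels = .fwd_conv_channels(l, a)$out,
    nonlinearity = {
      out <- .nl_f(l$fun, a)
      if (!is.null(dim(a))) dim(out) <- dim(a)
      out
    },
    pool = .fwd_pool(l, a)$out,
    flatten = as.vector(a),
    dense = drop(l$W %*% a) + l$b
  )
}
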