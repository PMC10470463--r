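#' Layer specifications for compact EEG classifiers
#'
#' A model is a finite ordered list of layer specifications. Convolutional
#' stages operate on activation arrays of shape (filters, channels, time);
#' after [layer_flatten()] activations are plain vectors. Every nonlinearity
#' is elementwise, and a valid architecture ends in exactly one dense layer
#' that produces one pre-softmax score per class.
#'
#' @param filters number of output feature maps.
#' @param kernel temporal kernel length in sampling points.
#' @param fun nonlinearity name, `"relu"` or `"elu"`.
#' @param type pooling type, `"mean"` or `"max"`.
#' @param window pooling window length (stride equals the window).
#' @param units output dimension of a dense layer; the final dense layer may
#'   leave this `NULL`, in which case [build_model()] sets it to the number of
#'   classes.
#'
#' @return a `layer_spec` list with a `kind` field.
#' @name layer_spec
NULL

#' @rdname layer_spec
#' @export
layer_conv_time <- function(filters, kernel) {
  stopifnot(filters >= 1, kernel >= 1)
  structure(list(kind = "conv_time", filters = as.integer(filters),
                 kernel = as.integer(kernel)), class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_conv_channels <- function(filters) {
  stopifnot(filters >= 1)
  structure(list(kind = "conv_channels", filters = as.integer(filters)),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_batchnorm <- function() {
  structure(list(kind = "batchnorm"), class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_nonlinearity <- function(fun = c("relu", "elu")) {
  fun <- match.arg(fun)
  structure(list(kind = "nonlinearity", fun = fun), class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_pool <- function(type = c("mean", "max"), window = 2L) {
  type <- match.arg(type)
  stopifnot(window >= 1)
  structure(list(kind = "pool", type = type, window = as.integer(window)),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_flatten <- function() {
  structure(list(kind = "flatten"), class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_dense <- function(units = NULL) {
  if (!is.null(units)) stopifnot(units >= 1)
  structure(list(kind = "dense",
                 units = if (is.null(units)) NULL else as.integer(units)),
            class = "layer_spec")
}

# Validate layer ordering and infer the activation shape entering each layer.
# Shapes in the convolutional stage are integer triples (filters, channels,
# time); after flatten they are a single length. Returns a list with one
# in_shape per layer plus the output length.
.infer_shapes <- function(arch, input_shape) {
  if (length(arch) == 0L) stop("architecture must contain at least one layer", call. = FALSE)
  kinds <- vapply(arch, function(l) l$kind, character(1))
  if (kinds[length(kinds)] != "dense") {
    stop("configuration error: the final layer must be a dense output layer", call. = FALSE)
  }
  if (sum(kinds == "dense") > 1L && any(kinds[-length(kinds)] == "dense")) {
    # interior dense layers are allowed only after flatten; checked below
  }
  shape <- c(1L, as.integer(input_shape[1]), as.integer(input_shape[2]))
  flat <- FALSE
  shapes <- vector("list", length(arch))
  for (i in seq_along(arch)) {
    l <- arch[[i]]
    shapes[[i]] <- if (flat) shape[1] else shape
    switch(l$kind,
      conv_time = {
        if (flat) stop("configuration error: conv_time after flatten", call. = FALSE)
        if (l$kernel > shape[3]) {
          stop("configuration error: temporal kernel (", l$kernel,
               ") longer than time axis (", shape[3], ")", call. = FALSE)
        }
        shape <- c(l$filters, shape[2], shape[3] - l$kernel + 1L)
      },
      conv_channels = {
        if (flat) stop("configuration error: conv_channels after flatten", call. = FALSE)
        shape <- c(l$filters, 1L, shape[3])
      },
      batchnorm = {
        if (flat) stop("configuration error: batchnorm after flatten", call. = FALSE)
      },
      nonlinearity = NULL,
      pool = {
        if (flat) stop("configuration error: pooling after flatten", call. = FALSE)
        t_out <- shape[3] %/% l$window
        if (t_out < 1L) stop("configuration error: pooling window exceeds time axis", call. = FALSE)
        shape <- c(shape[1], shape[2], t_out)
      },
      flatten = {
        if (flat) stop("configuration error: repeated flatten", call. = FALSE)
        shape <- prod(shape)
        flat <- TRUE
      },
      dense = {
        if (!flat) stop("configuration error: dense layer before flatten", call. = FALSE)
        shape <- if (is.null(l$units)) NA_integer_ else l$units
      },
      stop("configuration error: unknown layer kind '", l$kind, "'", call. = FALSE)
    )
  }
  list(shapes = shapes, out = shape)
}
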