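#' Read and write EEG samples as delimited text with a JSON sidecar
#'
#' The native interchange format is a plain comma-delimited matrix (one row
#' per channel, 17 significant digits, `#` comment lines allowed) plus a JSON
#' sidecar `<path>.json` carrying channel names, sampling rate and optional
#' label / subject metadata. `write_sample()` then `read_sample()` is the
#' identity to 1e-12.
#'
#' @param sample an [eeg_sample].
#' @param path payload file path; the sidecar is written at `<path>.json`.
#' @return `write_sample()` the path, invisibly; `read_sample()` an
#'   [eeg_sample].
#' @export
write_sample <- function(sample, path) {
  stopifnot(inherits(sample, "eeg_sample"))
  .write_matrix(sample$values, path)
  side <- list(channel_names = sample$channel_names,
               sampling_rate = sample$sampling_rate)
  if (!is.null(sample$label)) side$label <- sample$label
  if (!is.null(sample$subject)) side$subject <- sample$subject
  jsonlite::write_json(side, .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sample
#' @export
read_sample <- function(path) {
  values <- .read_matrix(path)
  sp <- .sidecar(path)
  if (!file.exists(sp)) {
    stop("format error: missing sidecar file '", sp, "'", call. = FALSE)
  }
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(side$sampling_rate)) {
    stop("format error: sidecar '", sp, "' missing field 'sampling_rate'",
         call. = FALSE)
  }
  if (is.null(side$channel_names)) {
    stop("format error: sidecar '", sp, "' missing field 'channel_names'",
         call. = FALSE)
  }
  if (length(side$channel_names) != nrow(values)) {
    stop("format error: sidecar has ", length(side$channel_names),
         " channel names for ", nrow(values), " payload rows", call. = FALSE)
  }
  eeg_sample(values, channel_names = side$channel_names,
             sampling_rate = side$sampling_rate,
             label = side$label, subject = side$subject)
}

.sidecar <- function(path) paste0(path, ".json")

.write_matrix <- function(m, path, header = character(0)) {
  lines <- c(header,
             apply(m, 1, function(r) {
               paste(formatC(r, digits = 17, format = "g"), collapse = ",")
             }))
  writeLines(lines, path)
  invisible(path)
}

.read_matrix <- function(path) {
  if (!file.exists(path)) stop("format error: no such file '", path, "'", call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (length(lines) == 0) stop("format error: '", path, "' has no data rows", call. = FALSE)
  rows <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(rows)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop("format error: '", path, "' row ", bad, " has ", nf[bad],
         " fields, expected ", nf[1], call. = FALSE)
  }
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(nf[1])))
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("format error: '", path, "' contains non-numeric or non-finite values",
         call. = FALSE)
  }
  if (nf[1] == 1L) matrix(vals, nrow = length(rows))
  else t(vals)
}

#' Read and write contribution maps
#'
#' Maps use the same matrix-plus-sidecar format as samples; the sidecar
#' echoes method, target class and model tag.
#'
#' @param cmap a [contribution_map].
#' @param path payload file path.
#' @return `write_map()` the path, invisibly; `read_map()` a
#'   [contribution_map].
#' @export
write_map <- function(cmap, path) {
  stopifnot(inherits(cmap, "contribution_map"))
  .write_matrix(cmap$scores, path)
  jsonlite::write_json(list(method = cmap$method,
                            target_class = cmap$target_class,
                            model_tag = cmap$model_tag),
                       .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  values <- .read_matrix(path)
  sp <- .sidecar(path)
  if (!file.exists(sp)) {
    stop("format error: missing sidecar file '", sp, "'", call. = FALSE)
  }
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("method", "target_class")) {
    if (is.null(side[[f]])) {
      stop("format error: sidecar '", sp, "' missing field '", f, "'",
           call. = FALSE)
    }
  }
  contribution_map(values, side$target_class, side$method,
                   if (is.null(side$model_tag)) "model" else side$model_tag)
}

#' Save / load a model checkpoint (JSON)
#'
#' Checkpoints are a single JSON document holding the architecture, the
#' initialization seed, all parameters (17 significant digits, exact for
#' doubles) and any frozen batch-normalization statistics.
#'
#' @param model an `eeg_model`.
#' @param path checkpoint path.
#' @return `save_model()` the path, invisibly; `load_model()` an
#'   `eeg_model`.
#' @export
save_model <- function(model, path) {
  ser_arr <- function(x) {
    if (is.null(x)) NULL
    else list(data = as.vector(x), dim = if (is.null(dim(x))) length(x) else dim(x))
  }
  layers <- lapply(model$layers, function(l) {
    out <- list(kind = l$kind)
    for (f in c("W", "b", "gamma", "beta", "running_mean", "running_var",
                "frozen_mean", "frozen_var")) {
      if (!is.null(l[[f]])) out[[f]] <- ser_arr(l[[f]])
    }
    for (f in c("kernel", "filters", "fun", "type", "window", "frozen")) {
      if (!is.null(l[[f]])) out[[f]] <- l[[f]]
    }
    if (!is.null(l$shape)) out$shape <- as.integer(l$shape)
    out
  })
  arch <- lapply(model$arch, unclass)
  doc <- list(format = "eegattr-model", version = 1L, tag = model$tag,
              seed = model$seed, num_classes = model$num_classes,
              input_shape = model$input_shape, arch = arch, layers = layers)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop("format error: no such checkpoint '", path, "'", call. = FALSE)
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(doc$format, "eegattr-model")) {
    stop("format error: '", path, "' is not a model checkpoint", call. = FALSE)
  }
  de_arr <- function(a) {
    if (is.null(a)) return(NULL)
    if (length(a$dim) <= 1L) as.numeric(a$data)
    else array(as.numeric(a$data), dim = as.integer(a$dim))
  }
  layers <- lapply(doc$layers, function(l) {
    out <- list(kind = l$kind)
    for (f in c("W", "b", "gamma", "beta", "running_mean", "running_var",
                "frozen_mean", "frozen_var")) {
      if (!is.null(l[[f]])) out[[f]] <- de_arr(l[[f]])
    }
    for (f in c("fun", "type")) if (!is.null(l[[f]])) out[[f]] <- l[[f]]
    for (f in c("kernel", "filters", "window")) {
      if (!is.null(l[[f]])) out[[f]] <- as.integer(l[[f]])
    }
    if (!is.null(l$frozen)) out$frozen <- isTRUE(l$frozen)
    if (!is.null(l$shape)) out$shape <- as.integer(l$shape)
    out
  })
  arch <- lapply(doc$arch, function(a) {
    spec <- a[!vapply(a, is.null, logical(1))]
    for (f in c("filters", "kernel", "window", "units")) {
      if (!is.null(spec[[f]])) spec[[f]] <- as.integer(spec[[f]])
    }
    structure(spec, class = "layer_spec")
  })
  info <- .infer_shapes(arch, doc$input_shape)
  structure(list(arch = arch, layers = layers,
                 input_shape = as.integer(doc$input_shape),
                 num_classes = as.integer(doc$num_classes),
                 seed = as.integer(doc$seed), tag = doc$tag,
                 shapes = info$shapes),
            class = "eeg_model")
}
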