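# Shared fixtures, all built in code.

# Purely linear classifier: scores = W %*% vec(x) + b. W is K x (N*T); the
# input is flattened channel-major (column j of x contributes entries
# (j-1)*N + 1 .. j*N), matching base R's column-major vec().
make_linear_model <- function(W, b = NULL, input_shape) {
  K <- nrow(W)
  m <- build_model(list(layer_flatten(), layer_dense()), num_classes = K,
                   input_shape = input_shape, seed = 1L, tag = "linear")
  m$layers[[2]]$W <- W
  m$layers[[2]]$b <- if (is.null(b)) numeric(K) else b
  m
}

# Two-input single-ReLU toy: S1 = ReLU(1*x1 - 2*x2 + 0.5), S2 = 0.
make_relu_toy <- function() {
  m <- build_model(list(layer_flatten(), layer_dense(1L),
                        layer_nonlinearity("relu"), layer_dense()),
                   num_classes = 2, input_shape = c(2, 1), seed = 1L,
                   tag = "relu-toy")
  m$layers[[2]]$W <- matrix(c(1, -2), 1, 2)
  m$layers[[2]]$b <- 0.5
  m$layers[[4]]$W <- matrix(c(1, 0), 2, 1)
  m$layers[[4]]$b <- c(0, 0)
  m
}

rand_input <- function(N, T, seed = 1, sd = 1) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  x <- matrix(rnorm(N * T, sd = sd), N, T)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  x
}

# Random-init stock model with statistics frozen on a small reference batch.
frozen_stock <- function(name = "relu-compact", N = 8, T = 128, seed = 3) {
  m <- build_model(stock_architecture(name), num_classes = 2,
                   input_shape = c(N, T), seed = seed, tag = name)
  ref <- lapply(1:4, function(i) rand_input(N, T, seed = 100 + i, sd = 10))
  freeze_batch_stats(m, ref)
}

# One trained model on the default synthetic task, cached for the whole run.
.fixture_env <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  spec <- synthetic_spec()
  ds <- generate_dataset(spec, 200)
  model <- build_model(stock_architecture("relu-compact"), num_classes = 2,
                       input_shape = c(spec$n_channels, spec$n_timepoints),
                       seed = 7, tag = "relu-compact")
  model <- train(model, ds$samples,
                 train_config(epochs = 20, batch_size = 10, seed = 7),
                 labels = ds$labels)
  model <- freeze_batch_stats(model, ds$samples[1:50])
  heldout <- generate_dataset(synthetic_spec(seed = 990001L), 60)
  .fixture_env$fit <- list(model = model, spec = spec, data = ds,
                           heldout = heldout)
  .fixture_env$fit
}
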