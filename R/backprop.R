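# Reverse pass through the network.
#
# `rule` selects the local backward factor at every elementwise nonlinearity:
#   plain    — the instant derivative f'(z)
#   deconv   — f'(z) gated by its own positivity: g = f'(z) * (f'(z) > 0)
#              (for ReLU this zeroes inactive units; for ELU f' > 0 always)
#   guided   — the deconv factor additionally gated by forward positivity:
#              g = f'(z) * (f'(z) > 0) * (f(z) > 0)
#   lrp_eps  — g = f(z) / (z + eps * sign(z)), sign(0) taken as +1
#   deeplift — g = (f(z) - f(zbar)) / (z - zbar) against baseline
#              pre-activations zbar, falling back to f'(z) where
#              |z - zbar| < eps (the 0/0 limit)
#
# All other layers backpropagate through their exact linear adjoint; frozen
# batch-normalization statistics are constants. With `want_param_grads` the
# parameter gradients (plain rule only, used by the trainer) are returned.
.backward1 <- function(model, caches, grad_scores, rule = "plain",
                       eps = 1e-6, bl_caches = NULL,
                       want_param_grads = FALSE) {
  g <- grad_scores
  pgrads <- if (want_param_grads) vector("list", length(model$layers)) else NULL
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    cache <- caches[[i]]
    switch(l$kind,
      dense = {
        if (want_param_grads) {
          pgrads[[i]] <- list(W = outer(g, as.vector(cache$x)), b = g)
        }
        g <- drop(crossprod(l$W, g))
      },
      flatten = {
        g <- array(g, dim = cache$dim)
      },
      pool = {
        g <- .bwd_pool(l, g, cache)
      },
      nonlinearity = {
        z <- cache$z
        g <- switch(rule,
          plain = g * .nl_fprime(l$fun, z),
          deconv = {
            fp <- .nl_fprime(l$fun, z)
            g * fp * (fp > 0)
          },
          guided = {
            fp <- .nl_fprime(l$fun, z)
            g * fp * (fp > 0) * (.nl_f(l$fun, z) > 0)
          },
          lrp_eps = {
            denom <- z + eps * ifelse(z >= 0, 1, -1)
            g * (.nl_f(l$fun, z) / denom)
          },
          deeplift = {
            zbar <- bl_caches[[i]]$z
            dz <- z - zbar
            fac <- ifelse(abs(dz) < eps,
                          .nl_fprime(l$fun, z),
                          (.nl_f(l$fun, z) - .nl_f(l$fun, zbar)) / dz)
            g * fac
          },
          stop("unknown backward rule '", rule, "'", call. = FALSE))
        if (!is.null(dim(z))) dim(g) <- dim(z)
      },
      batchnorm = {
        inv_sd <- cache$inv_sd
        if (want_param_grads) {
          G <- dim(g)[1]
          ggam <- vapply(seq_len(G), function(f) sum(g[f, , ] * cache$xhat[f, , ]),
                         numeric(1))
          gbet <- vapply(seq_len(G), function(f) sum(g[f, , ]), numeric(1))
          pgrads[[i]] <- list(gamma = ggam, beta = gbet)
        }
        g <- g * (l$gamma * inv_sd)
      },
      conv_channels = {
        d <- cache$dims
        Gm <- matrix(g, nrow = l$filters)             # F x T
        Wmat <- matrix(l$W, nrow = l$filters)         # F x (G*C)
        if (want_param_grads) {
          gW <- Gm %*% t(cache$inmat)
          dim(gW) <- dim(l$W)
          pgrads[[i]] <- list(W = gW, b = rowSums(Gm))
        }
        g <- array(crossprod(Wmat, Gm), dim = d)
      },
      conv_time = {
        d <- cache$dims                               # c(G, C, T_in, Tout)
        G_in <- d[1]; C <- d[2]; T_in <- d[3]; Tout <- d[4]
        F_out <- l$filters; L <- l$kernel
        Gmat <- matrix(0, F_out, C * Tout)            # row f, col c + (t-1)*C
        for (f in seq_len(F_out)) Gmat[f, ] <- as.vector(g[f, , ])
        if (want_param_grads) {
          gW <- array(0, dim = dim(l$W))
          for (gg in seq_len(G_in)) gW[, gg, ] <- Gmat %*% caches[[i]]$wins[[gg]]
          pgrads[[i]] <- list(W = gW, b = rowSums(Gmat))
        }
        gin <- array(0, dim = c(G_in, C, T_in))
        for (gg in seq_len(G_in)) {
          acc <- matrix(0, C, T_in)
          for (k in seq_len(L)) {
            contrib <- matrix(drop(l$W[, gg, k] %*% Gmat), C, Tout)
            acc[, k:(k + Tout - 1L)] <- acc[, k:(k + Tout - 1L)] + contrib
          }
          gin[gg, , ] <- acc
        }
        g <- gin
      }
    )
  }
  if (!all(is.finite(g))) stop("numerical error: non-finite gradient", call. = FALSE)
  list(grad_input = matrix(g, nrow = dim(g)[2]), param_grads = pgrads)
}

.bwd_pool <- function(l, g, cache) {
  d <- cache$dims; G <- d[1]; C <- d[2]; T_in <- d[3]
  w <- l$window; Tout <- cache$Tout
  gflat <- matrix(0, G * C, T_in)
  gout <- matrix(g, nrow = G * C)
  if (l$type == "mean") {
    for (t in seq_len(Tout)) {
      span <- ((t - 1L) * w + 1L):(t * w)
      gflat[, span] <- gflat[, span] + gout[, t] / w
    }
  } else {
    gm <- cache$argmax                                # (G*C) x Tout
    for (t in seq_len(Tout)) {
      pos <- (t - 1L) * w + gm[, t]
      ij <- cbind(seq_len(G * C), pos)
      gflat[ij] <- gflat[ij] + gout[, t]
    }
  }
  array(gflat, dim = d)
}
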