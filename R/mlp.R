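# Small feed-forward regression network used by the reporter surrogate:
# fully connected layers with batch normalization, ReLU and inverted
# dropout, plus a linear input-to-output skip connection, trained by Adam
# on mean-squared error. The skip makes additive (one-hot lookup) structure
# the network's baseline; the deep path only has to learn what is left.
# Implemented directly with matrix operations; deterministic given the seed.

mlp_init <- function(d_in, hidden, d_out) {
  dims <- c(d_in, hidden, d_out)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    din <- dims[l]; dout <- dims[l + 1]
    layers[[l]] <- list(
      W = matrix(rnorm(din * dout, 0, sqrt(2 / din)), din, dout),
      b = rep(0, dout),
      # batchnorm parameters (unused on the output layer)
      gamma = rep(1, dout), beta = rep(0, dout),
      run_mean = rep(0, dout), run_var = rep(1, dout))
  }
  layers
}

mlp_forward <- function(layers, x, skip = NULL, dropout = 0, train = FALSE,
                        momentum = 0.9, eps = 1e-5) {
  nl <- length(layers)
  cache <- vector("list", nl)
  h <- x
  for (l in seq_len(nl)) {
    ly <- layers[[l]]
    z <- h %*% ly$W
    z <- sweep(z, 2, ly$b, "+")
    if (l < nl) {
      if (train) {
        mu <- colMeans(z)
        v <- colMeans(sweep(z, 2, mu, "-")^2)
        layers[[l]]$run_mean <- momentum * ly$run_mean + (1 - momentum) * mu
        layers[[l]]$run_var <- momentum * ly$run_var + (1 - momentum) * v
      } else {
        mu <- ly$run_mean
        v <- ly$run_var
      }
      invstd <- 1 / sqrt(v + eps)
      xhat <- sweep(sweep(z, 2, mu, "-"), 2, invstd, "*")
      zn <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
      a <- pmax(zn, 0)
      if (train && dropout > 0) {
        mask <- matrix(stats::rbinom(length(a), 1, 1 - dropout),
                       nrow(a), ncol(a)) / (1 - dropout)
        a <- a * mask
      } else mask <- NULL
      cache[[l]] <- list(h_in = h, xhat = xhat, invstd = invstd, zn = zn,
                         mask = mask)
      h <- a
    } else {
      cache[[l]] <- list(h_in = h)
      h <- z
    }
  }
  if (!is.null(skip)) h <- h + x %*% skip
  list(out = h, cache = cache, layers = layers)
}

mlp_backward <- function(layers, cache, dout, x = NULL) {
  nl <- length(layers)
  grads <- vector("list", nl)
  skip_grad <- if (is.null(x)) NULL else crossprod(x, dout)
  dh <- dout
  for (l in rev(seq_len(nl))) {
    ly <- layers[[l]]
    cc <- cache[[l]]
    if (l < nl) {
      if (!is.null(cc$mask)) dh <- dh * cc$mask
      dzn <- dh * (cc$zn > 0)                     # ReLU
      n <- nrow(dzn)
      dgamma <- colSums(dzn * cc$xhat)
      dbeta <- colSums(dzn)
      dxhat <- sweep(dzn, 2, ly$gamma, "*")
      # batchnorm backward (batch statistics)
      t1 <- colSums(dxhat)
      t2 <- colSums(dxhat * cc$xhat)
      dz <- sweep(
        dxhat - matrix(t1 / n, n, length(t1), byrow = TRUE) -
          sweep(cc$xhat, 2, t2 / n, "*"),
        2, cc$invstd, "*")
    } else {
      dz <- dh
      dgamma <- NULL; dbeta <- NULL
    }
    grads[[l]] <- list(W = crossprod(cc$h_in, dz), b = colSums(dz),
                       gamma = dgamma, beta = dbeta)
    if (l > 1) dh <- dz %*% t(ly$W)
  }
  list(grads = grads, skip = skip_grad)
}

mlp_train <- function(x, y, hidden = c(64, 64, 32, 16), dropout = 0.1,
                      epochs = 200, batch = 64, lr = 1e-3, seed = 1,
                      verbose = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  with_seed(seed, {
    layers <- mlp_init(ncol(x), hidden, ncol(y))
    skip <- matrix(0, ncol(x), ncol(y))
    # Adam state
    m <- lapply(layers, function(ly) lapply(ly[c("W", "b", "gamma", "beta")],
                                            function(p) p * 0))
    v <- m
    m_skip <- v_skip <- skip * 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      # step decay: sharpen late training once the coarse map is in place
      lr_ep <- lr * if (ep > 0.75 * epochs) 0.1
                    else if (ep > 0.5 * epochs) 0.3 else 1
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1, n)]
        if (length(idx) < 2) next      # batchnorm needs > 1 sample
        xb <- x[idx, , drop = FALSE]
        fw <- mlp_forward(layers, xb, skip = skip, dropout = dropout,
                          train = TRUE)
        layers <- fw$layers
        resid <- fw$out - y[idx, , drop = FALSE]
        loss <- mean(resid^2)
        ep_loss <- ep_loss + loss; nb <- nb + 1
        dout <- 2 * resid / length(resid)
        bk <- mlp_backward(layers, fw$cache, dout, x = xb)
        grads <- bk$grads
        step <- step + 1
        m_skip <- b1 * m_skip + (1 - b1) * bk$skip
        v_skip <- b2 * v_skip + (1 - b2) * bk$skip^2
        skip <- skip - lr_ep * (m_skip / (1 - b1^step)) /
          (sqrt(v_skip / (1 - b2^step)) + eps)
        for (l in seq_along(layers)) {
          for (p in c("W", "b", "gamma", "beta")) {
            g <- grads[[l]][[p]]
            if (is.null(g)) next
            m[[l]][[p]] <- b1 * m[[l]][[p]] + (1 - b1) * g
            v[[l]][[p]] <- b2 * v[[l]][[p]] + (1 - b2) * g^2
            mhat <- m[[l]][[p]] / (1 - b1^step)
            vhat <- v[[l]][[p]] / (1 - b2^step)
            layers[[l]][[p]] <- layers[[l]][[p]] -
              lr_ep * mhat / (sqrt(vhat) + eps)
          }
        }
      }
      losses[ep] <- ep_loss / max(nb, 1)
      if (verbose && ep %% 20 == 0)
        message("epoch ", ep, " loss ", signif(losses[ep], 4))
    }
    # finalise batchnorm statistics on the full training set (momentum 0
    # replaces the lagging exponential averages with exact full-data stats)
    layers <- mlp_forward(layers, x, skip = skip, dropout = 0,
                          train = TRUE, momentum = 0)$layers
    structure(list(layers = layers, skip = skip, hidden = hidden,
                   dropout = dropout, losses = losses),
              class = "mlp_model")
  })
}

mlp_predict <- function(model, x) {
  mlp_forward(model$layers, as.matrix(x), skip = model$skip,
              train = FALSE)$out
}
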