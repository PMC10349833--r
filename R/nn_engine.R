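# Minimal dense / 1-d convolutional network trainer (forward, backprop, Adam)
# for the two fixed Table-style architectures used on 6-feature superpixel
# records. Layers operate on a batch matrix; conv layers reshape the flat
# input into (positions x channels) blocks. Binary cross-entropy loss,
# sigmoid output, inverted dropout during training.
#
# This is deliberately a small special-purpose engine, not a general deep
# learning framework: fixed feedforward chains, full-batch shapes known at
# construction time.

nn_init_layer <- function(type, ...) {
  l <- list(type = type, ...)
  class(l) <- "nn_layer"
  l
}

# Glorot-uniform initialization, the convention the architectures assume.
glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

#' @noRd
nn_build <- function(arch, input_len, seed = 1L) {
  with_seed(seed, {
    layers <- list()
    len <- input_len   # positions
    ch <- 1L           # channels (1 until the first conv; dense flattens)
    flat <- input_len
    for (spec in arch) {
      l <- switch(spec$type,
        conv1d = {
          out_len <- len - spec$kernel + 1L
          fan_in <- spec$kernel * ch
          W <- matrix(glorot(fan_in, spec$filters, fan_in * spec$filters),
                      fan_in, spec$filters)
          lay <- nn_init_layer("conv1d", W = W, b = rep(0, spec$filters),
                               kernel = spec$kernel, in_ch = ch,
                               in_len = len, out_len = out_len,
                               filters = spec$filters,
                               activation = spec$activation)
          len <- out_len
          ch <- spec$filters
          flat <- len * ch
          lay
        },
        dropout = nn_init_layer("dropout", rate = spec$rate),
        maxpool1d = {
          out_len <- len %/% spec$pool
          lay <- nn_init_layer("maxpool1d", pool = spec$pool, in_len = len,
                               out_len = out_len, ch = ch)
          len <- out_len
          flat <- len * ch
          lay
        },
        flatten = nn_init_layer("flatten"),
        dense = {
          W <- matrix(glorot(flat, spec$units, flat * spec$units),
                      flat, spec$units)
          lay <- nn_init_layer("dense", W = W, b = rep(0, spec$units),
                               activation = spec$activation)
          flat <- spec$units
          len <- spec$units
          ch <- 1L
          lay
        },
        stopf("unknown layer type '%s'", spec$type)
      )
      layers <- c(layers, list(l))
    }
    structure(list(layers = layers, input_len = input_len), class = "nn_net")
  })
}

nn_n_parameters <- function(net) {
  sum(vapply(net$layers, function(l) {
    if (!is.null(l$W)) length(l$W) + length(l$b) else 0L
  }, numeric(1)))
}

activate <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z)
}

activate_grad <- function(z, a, act) {
  switch(act,
         relu = (z > 0) * 1,
         tanh = 1 - a^2,
         sigmoid = a * (1 - a),
         linear = matrix(1, nrow(z), ncol(z)))
}

# x: batch x flat matrix. Conv layers interpret the flat vector as
# (position-major, channel-minor) blocks, i.e. column j of channel c sits at
# flat index (j - 1) * ch + c.
nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  a <- x
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    cache <- list(input = a)
    if (l$type == "dense") {
      z <- sweep(a %*% l$W, 2, l$b, "+")
      a <- activate(z, l$activation)
      cache$z <- z
      cache$a <- a
    } else if (l$type == "conv1d") {
      # Unfold: rows = batch * out_len, cols = kernel * in_ch.
      B <- nrow(a)
      unf <- conv_unfold(a, B, l$in_len, l$in_ch, l$kernel, l$out_len)
      z <- sweep(unf %*% l$W, 2, l$b, "+")   # (B*out_len) x filters
      act <- activate(z, l$activation)
      cache$unfold <- unf
      cache$z <- z
      cache$a_blocks <- act
      a <- conv_refold(act, B, l$out_len, l$filters)
      cache$a <- a
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        keep <- matrix(stats::runif(length(a)) >= l$rate, nrow(a), ncol(a))
        a <- a * keep / (1 - l$rate)
        cache$keep <- keep
      }
    } else if (l$type == "maxpool1d") {
      if (l$pool > 1L) {
        stopf("maxpool1d with pool > 1 is not needed by these architectures")
      }
      # pool_size = 1: identity.
    } else if (l$type == "flatten") {
      # Flat layout is maintained throughout; nothing to do.
    }
    caches[[i]] <- cache
  }
  list(output = a, caches = caches)
}

conv_unfold <- function(a, B, in_len, in_ch, kernel, out_len) {
  # a: B x (in_len * in_ch), position-major blocks of in_ch channels.
  cols <- integer(kernel * in_ch)
  out <- matrix(0, B * out_len, kernel * in_ch)
  for (p in seq_len(out_len)) {
    for (kk in seq_len(kernel)) {
      src <- ((p + kk - 2L) * in_ch + 1L):((p + kk - 1L) * in_ch)
      dst <- ((kk - 1L) * in_ch + 1L):(kk * in_ch)
      out[((p - 1L) * B + 1L):(p * B), dst] <- a[, src, drop = FALSE]
    }
  }
  out
}

conv_refold <- function(blocks, B, out_len, filters) {
  # blocks: (B*out_len) x filters, position-major row groups of size B.
  out <- matrix(0, B, out_len * filters)
  for (p in seq_len(out_len)) {
    out[, ((p - 1L) * filters + 1L):(p * filters)] <-
      blocks[((p - 1L) * B + 1L):(p * B), , drop = FALSE]
  }
  out
}

nn_backward <- function(net, fw, grad_out) {
  grads <- vector("list", length(net$layers))
  g <- grad_out
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cache <- fw$caches[[i]]
    if (l$type == "dense") {
      dz <- g * activate_grad(cache$z, cache$a, l$activation)
      grads[[i]] <- list(dW = crossprod(cache$input, dz), db = colSums(dz))
      g <- dz %*% t(l$W)
    } else if (l$type == "conv1d") {
      B <- nrow(cache$input)
      # g: B x (out_len * filters) -> blocks (B*out_len) x filters
      gb <- conv_unrefold(g, B, l$out_len, l$filters)
      dz <- gb * activate_grad(cache$z, cache$a_blocks, l$activation)
      grads[[i]] <- list(dW = crossprod(cache$unfold, dz), db = colSums(dz))
      dunf <- dz %*% t(l$W)   # (B*out_len) x (kernel*in_ch)
      g <- conv_fold_grad(dunf, B, l$in_len, l$in_ch, l$kernel, l$out_len)
    } else if (l$type == "dropout") {
      if (!is.null(cache$keep)) g <- g * cache$keep / (1 - l$rate)
    }
    # maxpool1d(pool=1) and flatten are identities.
  }
  grads
}

conv_unrefold <- function(g, B, out_len, filters) {
  out <- matrix(0, B * out_len, filters)
  for (p in seq_len(out_len)) {
    out[((p - 1L) * B + 1L):(p * B), ] <-
      g[, ((p - 1L) * filters + 1L):(p * filters), drop = FALSE]
  }
  out
}

conv_fold_grad <- function(dunf, B, in_len, in_ch, kernel, out_len) {
  g <- matrix(0, B, in_len * in_ch)
  for (p in seq_len(out_len)) {
    rows <- ((p - 1L) * B + 1L):(p * B)
    for (kk in seq_len(kernel)) {
      src <- ((kk - 1L) * in_ch + 1L):(kk * in_ch)
      dst <- ((p + kk - 2L) * in_ch + 1L):((p + kk - 1L) * in_ch)
      g[, dst] <- g[, dst] + dunf[rows, src, drop = FALSE]
    }
  }
  g
}

# Adam on binary cross-entropy; y in {0,1}; x: n x input_len matrix.
nn_train <- function(net, x, y, epochs = 100L, batch_size = 32L,
                     learning_rate = 0.001, seed = 1L,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  n <- nrow(x)
  mstate <- lapply(net$layers, function(l) {
    if (!is.null(l$W)) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    }
  })
  step <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      for (b0 in seq(1L, n, by = batch_size)) {
        ids <- perm[b0:min(b0 + batch_size - 1L, n)]
        xb <- x[ids, , drop = FALSE]
        yb <- y[ids]
        fw <- nn_forward(net, xb, training = TRUE)
        p <- pmin(pmax(fw$output, 1e-12), 1 - 1e-12)
        # d(BCE)/d(p) averaged over the batch; sigmoid grad handled in layer.
        gout <- (p - yb) / (p * (1 - p)) / length(yb)
        grads <- nn_backward(net, fw, gout)
        step <- step + 1L
        for (i in seq_along(net$layers)) {
          if (is.null(grads[[i]])) next
          st <- mstate[[i]]
          st$mW <- beta1 * st$mW + (1 - beta1) * grads[[i]]$dW
          st$vW <- beta2 * st$vW + (1 - beta2) * grads[[i]]$dW^2
          st$mb <- beta1 * st$mb + (1 - beta1) * grads[[i]]$db
          st$vb <- beta2 * st$vb + (1 - beta2) * grads[[i]]$db^2
          mhW <- st$mW / (1 - beta1^step)
          vhW <- st$vW / (1 - beta2^step)
          mhb <- st$mb / (1 - beta1^step)
          vhb <- st$vb / (1 - beta2^step)
          net$layers[[i]]$W <- net$layers[[i]]$W -
            learning_rate * mhW / (sqrt(vhW) + eps)
          net$layers[[i]]$b <- net$layers[[i]]$b -
            learning_rate * mhb / (sqrt(vhb) + eps)
          mstate[[i]] <- st
        }
      }
    }
  })
  net
}

nn_predict_prob <- function(net, x) {
  as.vector(nn_forward(net, x, training = FALSE)$output)
}
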