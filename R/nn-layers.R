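# Minimal CNN engine for small GSN maps: im2col convolution, batch
# normalization, swish, pooling, dense layers and residual blocks, with
# reverse-mode gradients and an Adam optimizer. Batches are arrays of
# dim (H, W, C, N); all matmuls go through BLAS.

.conv_prep_cache <- new.env(parent = emptyenv())

# im2col index for a k x k "same"-padded convolution on an (H, W, C)
# volume; output positions subsampled by `stride`. Column order: kernel row
# fastest, then kernel column, then input channel; row order: output row
# fastest, then output column.
conv_prep <- function(H, W, C, k, stride = 1L) {
  key <- paste(H, W, C, k, stride, sep = "_")
  hit <- .conv_prep_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  rows <- seq.int(1L, H, by = stride)
  cols <- seq.int(1L, W, by = stride)
  kr <- rep(seq_len(k), times = k)
  kc <- rep(seq_len(k), each = k)
  r0 <- rep(rows, times = length(cols))
  c0 <- rep(cols, each = length(rows))
  base_rc <- outer(r0, kr - 1L, "+") + Hp * (outer(c0, kc - 1L, "+") - 1L)
  npos <- length(r0)
  idx <- matrix(0L, npos, k * k * C)
  for (ch in seq_len(C)) {
    idx[, (ch - 1L) * k * k + seq_len(k * k)] <-
      as.integer(base_rc + Hp * Wp * (ch - 1L))
  }
  out <- list(idx = idx, Hp = Hp, Wp = Wp, p = p,
              Ho = length(rows), Wo = length(cols))
  .conv_prep_cache[[key]] <- out
  out
}

# Gather the im2col matrix: (Ho*Wo*N) x (k*k*C), image-major row blocks.
im2col <- function(x, k, stride = 1L) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  prep <- conv_prep(H, W, C, k, stride)
  xpad <- array(0, c(prep$Hp, prep$Wp, C, N))
  xpad[prep$p + seq_len(H), prep$p + seq_len(W), , ] <- x
  vol <- as.integer(prep$Hp * prep$Wp * C)
  npos <- nrow(prep$idx)
  Xc <- matrix(0, npos * N, ncol(prep$idx))
  xv <- as.vector(xpad)
  for (n in seq_len(N)) {
    Xc[(n - 1L) * npos + seq_len(npos), ] <- xv[prep$idx + (n - 1L) * vol]
  }
  Xc
}

# "Same"-padded convolution. Returns the output array and the im2col matrix
# (cached for the weight gradient).
conv_fwd <- function(x, Wm, b, k, stride = 1L) {
  d <- dim(x)
  Cout <- ncol(Wm)
  prep <- conv_prep(d[1], d[2], d[3], k, stride)
  Xc <- im2col(x, k, stride)
  Y <- Xc %*% Wm
  Y <- sweep(Y, 2L, b, "+")
  out <- aperm(array(Y, c(prep$Ho, prep$Wo, d[4], Cout)), c(1, 2, 4, 3))
  list(out = out, Xc = Xc)
}

# Kernel flipped 180 degrees with in/out channels swapped, so that the
# input gradient of a stride-1 same convolution is itself such a convolution.
flip_kernel <- function(Wm, k, Cin, Cout) {
  Wa <- array(Wm, c(k, k, Cin, Cout))
  Wa <- Wa[rev(seq_len(k)), rev(seq_len(k)), , , drop = FALSE]
  matrix(aperm(Wa, c(1, 2, 4, 3)), k * k * Cout, Cin)
}

# (H, W, Cout, N) array -> (H*W*N) x Cout matrix matching im2col row order.
to_rows <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(1, 2, 4, 3)), nrow = d[1] * d[2] * d[4], ncol = d[3])
}

odd_seq <- function(n) seq.int(1L, n, by = 2L)

## ---- layer constructors -------------------------------------------------

he_init <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))

layer_conv <- function(in_c, out_c, kernel = 7L, stride = 1L) {
  list(type = "conv", k = as.integer(kernel), stride = as.integer(stride),
       in_c = in_c, out_c = out_c,
       W = matrix(he_init(kernel * kernel * in_c, kernel * kernel * in_c * out_c),
                  ncol = out_c),
       b = numeric(out_c))
}

# Running statistics start at zero and are bias-corrected by the update
# count at inference time (an exponential average started at zero
# underestimates, and any nonzero start would dominate short trainings).
layer_bn <- function(channels, eps = 1e-5, momentum = 0.9) {
  list(type = "bn", c = channels, eps = eps, momentum = momentum,
       gamma = rep(1, channels), beta = numeric(channels),
       running_mean = numeric(channels), running_var = numeric(channels),
       bn_steps = 0L)
}

layer_swish <- function() list(type = "swish")
layer_maxpool <- function() list(type = "maxpool")
layer_gap <- function() list(type = "gap")
layer_flatten <- function() list(type = "flatten")

layer_dense <- function(in_n, out_n) {
  list(type = "dense", in_n = in_n, out_n = out_n,
       W = matrix(he_init(in_n, in_n * out_n), ncol = out_n),
       b = numeric(out_n))
}

layer_resblock <- function(main, shortcut = NULL) {
  list(type = "resblock", main = main, shortcut = shortcut)
}

## ---- forward / backward -------------------------------------------------

layer_forward <- function(node, x, training = FALSE) {
  switch(node$type,
    conv = {
      cs <- conv_fwd(x, node$W, node$b, node$k, node$stride)
      list(out = cs$out, cache = list(Xc = cs$Xc, dims = dim(x)), node = node)
    },
    bn = {
      d <- dim(x)
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
      if (training) {
        mu <- colMeans(xm)
        cen <- sweep(xm, 2L, mu)
        va <- colMeans(cen^2)
        node$running_mean <- node$momentum * node$running_mean + (1 - node$momentum) * mu
        node$running_var <- node$momentum * node$running_var + (1 - node$momentum) * va
        node$bn_steps <- node$bn_steps + 1L
      } else {
        if (node$bn_steps > 0L) {
          debias <- 1 - node$momentum^node$bn_steps
          mu <- node$running_mean / debias
          va <- node$running_var / debias
        } else {
          mu <- numeric(node$c)
          va <- rep(1, node$c)
        }
        cen <- sweep(xm, 2L, mu)
      }
      istd <- 1 / sqrt(va + node$eps)
      xhat <- sweep(cen, 2L, istd, "*")
      ym <- sweep(sweep(xhat, 2L, node$gamma, "*"), 2L, node$beta, "+")
      out <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(out = out,
           cache = list(xhat = xhat, istd = istd, dims = d, training = training),
           node = node)
    },
    swish = {
      s <- 1 / (1 + exp(-x))
      list(out = x * s, cache = list(x = x, s = s), node = node)
    },
    maxpool = {
      d <- dim(x)
      r <- odd_seq(d[1]); c <- odd_seq(d[2])
      x11 <- x[r, c, , , drop = FALSE]; x21 <- x[r + 1L, c, , , drop = FALSE]
      x12 <- x[r, c + 1L, , , drop = FALSE]; x22 <- x[r + 1L, c + 1L, , , drop = FALSE]
      out <- pmax(x11, x21, x12, x22)
      which4 <- (x11 == out) * 1L
      which4[which4 == 0 & x21 == out] <- 2L
      which4[which4 == 0 & x12 == out] <- 3L
      which4[which4 == 0 & x22 == out] <- 4L
      list(out = out, cache = list(which4 = which4, dims = d), node = node)
    },
    gap = {
      d <- dim(x)
      # mean over spatial dims: reshape to (H*W, C*N) and take colMeans
      m <- colMeans(matrix(x, nrow = d[1] * d[2]))
      out <- t(matrix(m, d[3], d[4]))
      list(out = out, cache = list(dims = d), node = node)
    },
    flatten = {
      d <- dim(x)
      out <- t(matrix(x, ncol = d[4]))
      list(out = out, cache = list(dims = d), node = node)
    },
    dense = {
      out <- sweep(x %*% node$W, 2L, node$b, "+")
      list(out = out, cache = list(x = x), node = node)
    },
    resblock = {
      mf <- net_forward(node$main, x, training)
      node$main <- mf$nodes
      if (is.null(node$shortcut)) {
        short <- x
        scache <- NULL
      } else {
        sf <- net_forward(node$shortcut, x, training)
        node$shortcut <- sf$nodes
        short <- sf$out
        scache <- sf$caches
      }
      list(out = mf$out + short,
           cache = list(main = mf$caches, shortcut = scache),
           node = node)
    },
    stop("unknown layer type: ", node$type)
  )
}

layer_backward <- function(node, cache, dout) {
  switch(node$type,
    conv = {
      d <- cache$dims
      dYmat <- to_rows(dout)
      dW <- crossprod(cache$Xc, dYmat)
      db <- colSums(dYmat)
      # input gradient: zero-stuff strided output grads back to full
      # resolution, then correlate with the flipped kernel (stride 1).
      if (node$stride > 1L) {
        dfull <- array(0, c(d[1], d[2], node$out_c, d[4]))
        dfull[seq.int(1L, d[1], by = node$stride),
              seq.int(1L, d[2], by = node$stride), , ] <- dout
        dout <- dfull
      }
      Wf <- flip_kernel(node$W, node$k, node$in_c, node$out_c)
      dx <- conv_fwd(dout, Wf, numeric(node$in_c), node$k)$out
      list(dx = dx, grads = list(W = dW, b = db))
    },
    bn = {
      d <- cache$dims
      dym <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = d[3])
      M <- nrow(dym)
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      if (cache$training) {
        dxhat <- sweep(dym, 2L, node$gamma, "*")
        t1 <- sweep(dxhat, 2L, colMeans(dxhat))
        t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
        dxm <- sweep(t1 - t2, 2L, cache$istd, "*")
      } else {
        dxm <- sweep(sweep(dym, 2L, node$gamma, "*"), 2L, cache$istd, "*")
      }
      dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    swish = {
      s <- cache$s
      list(dx = dout * (s + cache$x * s * (1 - s)), grads = NULL)
    },
    maxpool = {
      d <- cache$dims
      dx <- array(0, d)
      r <- odd_seq(d[1]); c <- odd_seq(d[2])
      w <- cache$which4
      dx[r, c, , ] <- dout * (w == 1L)
      dx[r + 1L, c, , ] <- dx[r + 1L, c, , , drop = FALSE] + dout * (w == 2L)
      dx[r, c + 1L, , ] <- dx[r, c + 1L, , , drop = FALSE] + dout * (w == 3L)
      dx[r + 1L, c + 1L, , ] <- dx[r + 1L, c + 1L, , , drop = FALSE] + dout * (w == 4L)
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache$dims
      per_pixel <- t(dout) / (d[1] * d[2])           # C x N
      dx <- array(rep(as.vector(per_pixel), each = d[1] * d[2]), d)
      list(dx = dx, grads = NULL)
    },
    flatten = {
      dx <- array(t(dout), cache$dims)
      list(dx = dx, grads = NULL)
    },
    dense = {
      list(dx = dout %*% t(node$W),
           grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
    },
    resblock = {
      mb <- net_backward(node$main, cache$main, dout)
      if (is.null(node$shortcut)) {
        dshort <- dout
        sgrads <- NULL
      } else {
        sb <- net_backward(node$shortcut, cache$shortcut, dout)
        dshort <- sb$dx
        sgrads <- sb$grads
      }
      list(dx = mb$dx + dshort,
           grads = list(main = mb$grads, shortcut = sgrads))
    },
    stop("unknown layer type: ", node$type)
  )
}

net_forward <- function(nodes, x, training = FALSE) {
  caches <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    res <- layer_forward(nodes[[i]], x, training)
    x <- res$out
    caches[[i]] <- res$cache
    nodes[[i]] <- res$node
  }
  list(out = x, caches = caches, nodes = nodes)
}

net_backward <- function(nodes, caches, dout) {
  grads <- vector("list", length(nodes))
  for (i in rev(seq_along(nodes))) {
    res <- layer_backward(nodes[[i]], caches[[i]], dout)
    dout <- res$dx
    grads[i] <- list(res$grads)   # [[<- would drop NULL grads and shift indices
  }
  list(dx = dout, grads = grads)
}

## ---- Adam ---------------------------------------------------------------

PARAM_NAMES <- c("W", "b", "gamma", "beta")

adam_step_nodes <- function(nodes, grads, state, t, lr,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) state <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    g <- grads[[i]]
    if (is.null(g)) next
    node <- nodes[[i]]
    if (node$type == "concat") {
      if (is.null(state[[i]])) state[[i]] <- vector("list", length(node$branches))
      for (bi in seq_along(node$branches)) {
        up <- adam_step_nodes(node$branches[[bi]], g$branches[[bi]],
                              state[[i]][[bi]], t, lr, beta1, beta2, eps)
        node$branches[[bi]] <- up$nodes
        state[[i]][[bi]] <- up$state
      }
    } else if (node$type == "resblock") {
      up_m <- adam_step_nodes(node$main, g$main, state[[i]]$main, t, lr, beta1, beta2, eps)
      node$main <- up_m$nodes
      st <- list(main = up_m$state, shortcut = state[[i]]$shortcut)
      if (!is.null(node$shortcut) && !is.null(g$shortcut)) {
        up_s <- adam_step_nodes(node$shortcut, g$shortcut, st$shortcut, t, lr, beta1, beta2, eps)
        node$shortcut <- up_s$nodes
        st$shortcut <- up_s$state
      }
      state[[i]] <- st
    } else {
      st <- state[[i]]
      if (is.null(st)) st <- list()
      for (pn in intersect(names(g), PARAM_NAMES)) {
        if (is.null(st[[pn]])) {
          st[[pn]] <- list(m = g[[pn]] * 0, v = g[[pn]] * 0)
        }
        st[[pn]]$m <- beta1 * st[[pn]]$m + (1 - beta1) * g[[pn]]
        st[[pn]]$v <- beta2 * st[[pn]]$v + (1 - beta2) * g[[pn]]^2
        mhat <- st[[pn]]$m / (1 - beta1^t)
        vhat <- st[[pn]]$v / (1 - beta2^t)
        node[[pn]] <- node[[pn]] - lr * mhat / (sqrt(vhat) + eps)
      }
      state[[i]] <- st
    }
    nodes[[i]] <- node
  }
  list(nodes = nodes, state = state)
}

#' Numerically stable softmax
#'
#' Maps a vector of logits (or each row of a matrix) to a probability
#' distribution `exp(z_j) / sum_k exp(z_k)`, with max subtraction for
#' numerical stability.
#'
#' @param logits Numeric vector or matrix (rows = observations).
#' @return Probabilities of the same shape; each (row) sums to 1.
#' @export
softmax <- function(logits) {
  if (is.matrix(logits)) {
    z <- logits - apply(logits, 1L, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    z <- logits - max(logits)
    e <- exp(z)
    e / sum(e)
  }
}

# Cross-entropy loss and logit gradient for one-hot integer targets.
softmax_ce <- function(logits, yidx) {
  probs <- softmax(logits)
  n <- nrow(probs)
  eps <- 1e-12
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), yidx)], eps)))
  dlogits <- probs
  dlogits[cbind(seq_len(n), yidx)] <- dlogits[cbind(seq_len(n), yidx)] - 1
  list(loss = loss, probs = probs, dlogits = dlogits / n)
}
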