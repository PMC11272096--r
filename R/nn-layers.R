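# Minimal batched neural-network engine.
#
# Feature maps are 4-D arrays [H, W, C, N] (column-major, batch last).
# Convolutions are stride-1, odd-kernel, "same" padding, implemented as
# im2col + GEMM; backward-data is a convolution with the spatially flipped,
# channel-transposed kernel (exact for stride 1 / same padding). All layers
# return both output and cache, and expose a matching backward; gradient
# correctness is pinned by finite-difference tests.

.nn_cache_env <- new.env(parent = emptyenv())

# conv parameter initializer (He), weights stored as [k*k*Cin, Cout]
nn_conv_init <- function(k, c_in, c_out, gain = sqrt(2)) {
  fan_in <- k * k * c_in
  list(
    W = matrix(stats::rnorm(fan_in * c_out, 0, gain / sqrt(fan_in)),
               fan_in, c_out),
    b = numeric(c_out),
    k = k, c_in = c_in, c_out = c_out
  )
}

nn_conv_fwd <- function(x, layer) {
  d <- dim(x)
  k <- layer$k
  stopifnot(d[3] == layer$c_in)
  if (!is.double(x)) storage.mode(x) <- "double"
  if (k == 1L) {
    cols <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  } else {
    cols <- .nn_im2col_cpp(x, d[1], d[2], d[3], d[4], k)
  }
  y <- cols %*% layer$W
  y <- y + rep(layer$b, each = nrow(y))
  out <- aperm(array(y, c(d[1], d[2], d[4], layer$c_out)), c(1, 2, 4, 3))
  list(out = out, cols = cols, in_dim = d)
}

nn_conv_bwd <- function(dy, fwd, layer) {
  d <- fwd$in_dim
  dmat <- matrix(aperm(dy, c(1, 2, 4, 3)), d[1] * d[2] * d[4], layer$c_out)
  dW <- crossprod(fwd$cols, dmat)
  db <- colSums(dmat)
  # backward-data: conv with flipped kernel, channels transposed
  k <- layer$k
  warr <- array(layer$W, c(k, k, layer$c_in, layer$c_out))
  wflip <- aperm(warr[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3))
  back <- list(W = matrix(wflip, k * k * layer$c_out, layer$c_in),
               b = numeric(layer$c_in), k = k,
               c_in = layer$c_out, c_out = layer$c_in)
  dx <- nn_conv_fwd(dy, back)$out
  list(dx = dx, dW = dW, db = db)
}

nn_relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}
nn_relu_bwd <- function(dy, fwd) dy * fwd$mask

# 2x2 max pooling, stride 2 (H, W even); ties resolved in fixed slice order
nn_pool_fwd <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  s <- list(
    x[i1, j1, , , drop = FALSE], x[i1 + 1L, j1, , , drop = FALSE],
    x[i1, j1 + 1L, , , drop = FALSE], x[i1 + 1L, j1 + 1L, , , drop = FALSE]
  )
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  w1 <- s[[1]] == y
  w2 <- (s[[2]] == y) & !w1
  w3 <- (s[[3]] == y) & !(w1 | w2)
  w4 <- (s[[4]] == y) & !(w1 | w2 | w3)
  list(out = y, masks = list(w1, w2, w3, w4), in_dim = d)
}

nn_pool_bwd <- function(dy, fwd) {
  d <- fwd$in_dim
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  dx <- array(0, d)
  dx[i1, j1, , ] <- dy * fwd$masks[[1]]
  dx[i1 + 1L, j1, , ] <- dy * fwd$masks[[2]]
  dx[i1, j1 + 1L, , ] <- dy * fwd$masks[[3]]
  dx[i1 + 1L, j1 + 1L, , ] <- dy * fwd$masks[[4]]
  dx
}

# 2x nearest-neighbor upsampling
nn_upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

nn_upsample_bwd <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  dy[i1, j1, , , drop = FALSE] + dy[i1 + 1L, j1, , , drop = FALSE] +
    dy[i1, j1 + 1L, , , drop = FALSE] + dy[i1 + 1L, j1 + 1L, , , drop = FALSE]
}

nn_dense_init <- function(n_in, n_out, gain = sqrt(2)) {
  list(W = matrix(stats::rnorm(n_in * n_out, 0, gain / sqrt(n_in)),
                  n_in, n_out),
       b = numeric(n_out))
}

nn_dense_fwd <- function(x, layer) {
  y <- x %*% layer$W
  list(out = sweep(y, 2, layer$b, "+"), x = x)
}

nn_dense_bwd <- function(dy, fwd, layer) {
  list(dx = dy %*% t(layer$W), dW = crossprod(fwd$x, dy), db = colSums(dy))
}

# [H, W, C, N] -> [N, H*W*C]
nn_flatten <- function(x) {
  d <- dim(x)
  t(matrix(x, d[1] * d[2] * d[3], d[4]))
}

# [N, H*W*C] -> [H, W, C, N]
nn_unflatten <- function(x, H, W, C) {
  array(t(x), c(H, W, C, nrow(x)))
}

# softmax over the spatial positions of each (channel, sample) slice
nn_softmax_spatial_fwd <- function(x) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3] * d[4])
  mx <- xm[cbind(max.col(t(xm), ties.method = "first"), seq_len(ncol(xm)))]
  e <- exp(sweep(xm, 2, mx, "-"))
  p <- sweep(e, 2, colSums(e), "/")
  list(out = array(p, d), p = p, dim = d)
}

nn_softmax_spatial_bwd <- function(dy, fwd) {
  d <- fwd$dim
  dm <- matrix(dy, d[1] * d[2], d[3] * d[4])
  s <- colSums(fwd$p * dm)
  array(fwd$p * sweep(dm, 2, s, "-"), d)
}

# separable bilinear resampling between square spatial sizes (linear map)
.nn_resample_mat <- function(from, to) {
  key <- paste("rs", from, to, sep = "x")
  m <- .nn_cache_env[[key]]
  if (!is.null(m)) return(m)
  m <- matrix(0, to, from)
  for (i in seq_len(to)) {
    u <- (i - 0.5) * from / to + 0.5 # center-aligned source coordinate
    i0 <- floor(u - 1e-12)
    w <- u - i0
    i0c <- min(max(i0, 1L), from)
    i1c <- min(max(i0 + 1L, 1L), from)
    m[i, i0c] <- m[i, i0c] + (1 - w)
    m[i, i1c] <- m[i, i1c] + w
  }
  .nn_cache_env[[key]] <- m
  m
}

nn_resample_fwd <- function(x, to) {
  d <- dim(x)
  if (d[1] == to && d[2] == to) return(x)
  R <- .nn_resample_mat(d[1], to)
  y <- R %*% matrix(x, d[1], prod(d[-1]))         # rows
  y <- array(y, c(to, d[2], d[3], d[4]))
  y <- aperm(y, c(2, 1, 3, 4))
  y <- R %*% matrix(y, d[2], to * d[3] * d[4])    # columns
  aperm(array(y, c(to, to, d[3], d[4])), c(2, 1, 3, 4))
}

# adjoint of nn_resample_fwd (gradient propagation)
nn_resample_bwd <- function(dy, from) {
  d <- dim(dy)
  if (d[1] == from && d[2] == from) return(dy)
  R <- t(.nn_resample_mat(from, d[1]))
  y <- R %*% matrix(dy, d[1], prod(d[-1]))
  y <- array(y, c(from, d[2], d[3], d[4]))
  y <- aperm(y, c(2, 1, 3, 4))
  y <- R %*% matrix(y, d[2], from * d[3] * d[4])
  aperm(array(y, c(from, from, d[3], d[4])), c(2, 1, 3, 4))
}

nn_concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

nn_split_channels <- function(x, c1) {
  d <- dim(x)
  list(x[, , seq_len(c1), , drop = FALSE],
       x[, , (c1 + 1):d[3], , drop = FALSE])
}

# ---- parameter-tree utilities ----
# Parameters live in nested named lists whose trainable leaves are the
# elements named "W" and "b"; structural fields (k, c_in, ...) are untouched.

nn_tree_map <- function(f, tree) {
  nms <- names(tree)
  for (i in seq_along(tree)) {
    if (!is.null(nms) && nms[i] %in% c("W", "b")) {
      tree[[i]] <- f(tree[[i]])
    } else if (is.list(tree[[i]])) {
      tree[[i]] <- nn_tree_map(f, tree[[i]])
    }
  }
  tree
}

nn_tree_map2 <- function(f, a, b) {
  nms <- names(a)
  for (i in seq_along(a)) {
    if (!is.null(nms) && nms[i] %in% c("W", "b")) {
      a[[i]] <- f(a[[i]], b[[i]])
    } else if (is.list(a[[i]])) {
      a[[i]] <- nn_tree_map2(f, a[[i]], b[[i]])
    }
  }
  a
}

nn_tree_count <- function(tree) {
  n <- 0
  nms <- names(tree)
  for (i in seq_along(tree)) {
    if (!is.null(nms) && nms[i] %in% c("W", "b")) {
      n <- n + length(tree[[i]])
    } else if (is.list(tree[[i]])) {
      n <- n + nn_tree_count(tree[[i]])
    }
  }
  n
}

# Adam update; state holds first/second moments and the step counter
nn_adam_init <- function(params) {
  list(m = nn_tree_map(function(x) x * 0, params),
       v = nn_tree_map(function(x) x * 0, params),
       t = 0L)
}

nn_adam_step <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nn_tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                          state$m, grads)
  state$v <- nn_tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                          state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- nn_tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                      state$m, state$v)
  params <- nn_tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
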