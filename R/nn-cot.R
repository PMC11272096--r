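# Contextual-transformer (CoT) attention block.
#
# Given a feature map X (H x W x C), the block sets keys K = X and queries
# Q = X, embeds values V = X * Wv by 1x1 convolution, mines a static context
# K1 by k x k convolution over the neighbor keys, forms the attention logits
# Im = Ae[K1, Q] (two 1x1 convolutions with a rectifier in between, applied
# to the channel concatenation), turns them into an attention map by softmax,
# computes the dynamic context K2 = V * softmax(Im) element-wise, and
# returns the fusion K1 + K2. Output shape equals input shape.

cot_init <- function(channels, k = 3L) {
  list(
    kconv = nn_conv_init(k, channels, channels),
    vconv = nn_conv_init(1L, channels, channels),
    ae1 = nn_conv_init(1L, 2L * channels, channels),
    ae2 = nn_conv_init(1L, channels, channels)
  )
}

.cot_softmax_fwd <- function(x, axis) {
  if (axis == "spatial") {
    nn_softmax_spatial_fwd(x)
  } else {
    nn_softmax_channel_fwd(x)
  }
}

.cot_softmax_bwd <- function(dy, fwd, axis) {
  if (axis == "spatial") {
    nn_softmax_spatial_bwd(dy, fwd)
  } else {
    nn_softmax_channel_bwd(dy, fwd)
  }
}

cot_fwd <- function(x, params, softmax_axis = "spatial") {
  vf <- nn_conv_fwd(x, params$vconv)
  k1f <- nn_conv_fwd(x, params$kconv)
  catf <- nn_concat_channels(k1f$out, x)
  a1f <- nn_conv_fwd(catf, params$ae1)
  r1f <- nn_relu_fwd(a1f$out)
  a2f <- nn_conv_fwd(r1f$out, params$ae2)
  smf <- .cot_softmax_fwd(a2f$out, softmax_axis)
  k2 <- vf$out * smf$out
  list(out = k1f$out + k2,
       cache = list(vf = vf, k1f = k1f, a1f = a1f, r1f = r1f, a2f = a2f,
                    smf = smf, v = vf$out, att = smf$out,
                    c_in = dim(x)[3], axis = softmax_axis))
}

cot_bwd <- function(dout, cache, params) {
  dk1 <- dout
  dv <- dout * cache$att
  datt <- dout * cache$v
  dim_ <- .cot_softmax_bwd(datt, cache$smf, cache$axis)
  b2 <- nn_conv_bwd(dim_, cache$a2f, params$ae2)
  dpre1 <- nn_relu_bwd(b2$dx, cache$r1f)
  b1 <- nn_conv_bwd(dpre1, cache$a1f, params$ae1)
  sp <- nn_split_channels(b1$dx, cache$c_in)
  dk1 <- dk1 + sp[[1]]
  bk <- nn_conv_bwd(dk1, cache$k1f, params$kconv)
  bv <- nn_conv_bwd(dv, cache$vf, params$vconv)
  list(
    dx = bk$dx + bv$dx + sp[[2]],
    grads = list(
      kconv = list(W = bk$dW, b = bk$db),
      vconv = list(W = bv$dW, b = bv$db),
      ae1 = list(W = b1$dW, b = b1$db),
      ae2 = list(W = b2$dW, b = b2$db)
    )
  )
}

# channel-axis softmax variant (alternative attention normalization)
nn_softmax_channel_fwd <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(3, 1, 2, 4))
  xm <- matrix(xp, d[3], d[1] * d[2] * d[4])
  mx <- apply(xm, 2, max)
  e <- exp(sweep(xm, 2, mx, "-"))
  p <- sweep(e, 2, colSums(e), "/")
  list(out = aperm(array(p, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4)),
       p = p, dim = d)
}

nn_softmax_channel_bwd <- function(dy, fwd) {
  d <- fwd$dim
  dm <- matrix(aperm(dy, c(3, 1, 2, 4)), d[3], d[1] * d[2] * d[4])
  s <- colSums(fwd$p * dm)
  g <- fwd$p * sweep(dm, 2, s, "-")
  aperm(array(g, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

#' Contextual-transformer attention block
#'
#' Applies one CoT self-attention block to a feature map: the static context
#' `K1` is a k x k convolution over the neighbor keys `K = X`, the values are
#' `V = X Wv` (1 x 1 convolution), the attention logits are
#' `Im = Ae[K1, Q]` with `Q = X` and `Ae` two 1 x 1 convolutions with a
#' rectifier between them, and the output is the fusion
#' `K1 + V * softmax(Im)`. Spatial size and channel count are preserved.
#'
#' @param x feature map, array `[H, W, C]` or `[H, W, C, N]`.
#' @param params CoT parameters as produced by the model initializer: a list
#'   with conv layers `kconv` (k x k, C to C), `vconv`, `ae1`
#'   (1 x 1, 2C to C), `ae2` (1 x 1, C to C), each a `list(W, b, k, c_in,
#'   c_out)` with `W` of shape `(k*k*c_in, c_out)`.
#' @param softmax_axis `"spatial"` (default) normalizes the attention map
#'   over spatial positions per channel; `"channel"` normalizes over channels
#'   per position.
#' @return The refined feature map, same shape as `x`.
#' @export
cot_block <- function(x, params, softmax_axis = c("spatial", "channel")) {
  softmax_axis <- match.arg(softmax_axis)
  squeeze <- length(dim(x)) == 3
  if (squeeze) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] != params$kconv$c_in) stop("channel mismatch")
  out <- cot_fwd(x, params, softmax_axis)$out
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}
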