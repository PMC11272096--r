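#' Loss-term weights
#'
#' Coefficients of the composite training loss
#' `alpha * L_p + beta * L_i + gamma * L_f` and the voxel weights of the
#' weighted MSE (`a` inside the lesion region, `b` outside). Defaults are the
#' grid-searched values alpha = 5, beta = 1, gamma = 0.01, a = 0.98,
#' b = 0.02.
#'
#' @param alpha weight of the perturbation (bottleneck) loss.
#' @param beta weight of the weighted image MSE.
#' @param gamma weight of the perceptual feature loss.
#' @param a,b voxel weights for lesion / background.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(alpha = 5, beta = 1, gamma = 0.01,
                         a = 0.98, b = 0.02) {
  if (any(c(alpha, beta, gamma, a, b) < 0)) stop("weights must be >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, a = a, b = b),
            class = "loss_weights")
}

#' Lesion-weighted mean squared error (image loss)
#'
#' Mean over voxels of `w * (output - truth)^2` with `w = a` inside the
#' (dilated) lesion region and `w = b` outside, prioritizing lesion fidelity
#' over the background. With an empty mask it degrades to a plain MSE with a
#' warning.
#'
#' @param output,ground_truth arrays of identical shape (batched or not).
#' @param lesion_mask logical array of the same shape marking the lesion
#'   (typically the ground-truth mask dilated by one voxel).
#' @param a,b nonnegative voxel weights.
#' @return scalar loss.
#' @export
loss_weighted_mse <- function(output, ground_truth, lesion_mask,
                              a = 0.98, b = 0.02) {
  stopifnot(all(dim(output) == dim(ground_truth)),
            a >= 0, b >= 0)
  if (!any(lesion_mask)) {
    warning("empty lesion mask: falling back to plain MSE")
    return(mean((output - ground_truth)^2))
  }
  w <- ifelse(lesion_mask, a, b)
  mean(w * (output - ground_truth)^2)
}

# gradient of loss_weighted_mse w.r.t. output
.loss_weighted_mse_grad <- function(output, ground_truth, lesion_mask, a, b) {
  w <- if (any(lesion_mask)) ifelse(lesion_mask, a, b) else 1
  2 * w * (output - ground_truth) / length(output)
}

#' Fixed convolutional feature extractor for the perceptual loss
#'
#' A frozen two-stage convolutional feature extractor (conv-relu-pool twice,
#' then flatten) whose weights are drawn once from a recorded seed. It plays
#' the role of the pretrained perceptual backbone: the perceptual loss only
#' needs a fixed, expressive, differentiable feature map to compare semantic
#' structure, and a frozen random convolutional network provides one without
#' any external weight download. Each depth layer of a volume is replicated
#' to 3 channels before extraction, mirroring how an RGB-pretrained backbone
#' would ingest single-channel maps.
#'
#' @param grid_size lateral input size (default 36).
#' @param seed seed of the frozen weights (the provenance is
#'   `fixed-random(seed)`).
#' @param channels channel widths of the two stages.
#' @return A `feature_extractor`.
#' @export
feature_extractor <- function(grid_size = 36, seed = 1234L,
                              channels = c(8, 16)) {
  layers <- .with_seed(seed, list(
    conv1 = nn_conv_init(3L, 3L, channels[1]),
    conv2 = nn_conv_init(3L, channels[1], channels[2])
  ))
  structure(
    list(layers = layers, grid_size = grid_size, channels = channels,
         provenance = sprintf("fixed-random(%d)", as.integer(seed))),
    class = "feature_extractor"
  )
}

# features of a stack of single-channel images [H, W, N]; returns the
# feature matrix and caches for input-gradient propagation
.extract_features <- function(extractor, imgs) {
  d <- dim(imgs)
  x <- array(imgs, c(d[1], d[2], 1L, d[3]))[, , c(1, 1, 1), , drop = FALSE]
  c1 <- nn_conv_fwd(x, extractor$layers$conv1)
  r1 <- nn_relu_fwd(c1$out)
  p1 <- nn_pool_fwd(r1$out)
  c2 <- nn_conv_fwd(p1$out, extractor$layers$conv2)
  r2 <- nn_relu_fwd(c2$out)
  p2 <- nn_pool_fwd(r2$out)
  list(features = nn_flatten(p2$out),
       cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                    dim = dim(p2$out)))
}

# gradient of the features w.r.t. the input images, given dFeatures
.extract_features_grad <- function(extractor, cache, dfeat) {
  d <- cache$dim
  dh <- nn_unflatten(dfeat, d[1], d[2], d[3])
  dh <- nn_pool_bwd(dh, cache$p2)
  dh <- nn_relu_bwd(dh, cache$r2)
  dh <- nn_conv_bwd(dh, cache$c2, extractor$layers$conv2)$dx
  dh <- nn_pool_bwd(dh, cache$p1)
  dh <- nn_relu_bwd(dh, cache$r1)
  dh <- nn_conv_bwd(dh, cache$c1, extractor$layers$conv1)$dx
  # collapse the 3 replicated channels back to one
  dh[, , 1, ] + dh[, , 2, ] + dh[, , 3, ]
}

#' Perceptual (feature-domain) loss
#'
#' Squared L2 distance between extractor features of the output and the
#' ground truth, computed per depth layer (each layer replicated to 3
#' channels), normalized per feature element, summed over layers, and
#' averaged over the batch. The per-element normalization keeps the loss on
#' a scale commensurate with the image MSE regardless of the extractor's
#' feature dimension.
#'
#' @param output,ground_truth volumes `[H, W, L]` or `[H, W, L, N]`.
#' @param extractor a [feature_extractor()].
#' @return scalar loss.
#' @export
loss_perceptual <- function(output, ground_truth, extractor) {
  if (!inherits(extractor, "feature_extractor")) {
    stop("extractor must be an initialized feature_extractor")
  }
  .loss_perceptual_impl(output, ground_truth, extractor, grad = FALSE)$loss
}

.loss_perceptual_impl <- function(output, ground_truth, extractor,
                                  grad = FALSE) {
  if (length(dim(output)) == 3) {
    dim(output) <- c(dim(output), 1L)
    dim(ground_truth) <- dim(output)
  }
  d <- dim(output)
  n <- d[4]
  loss <- 0
  dout <- if (grad) array(0, d) else NULL
  for (l in seq_len(d[3])) {
    fo <- .extract_features(extractor, array(output[, , l, ], c(d[1], d[2], n)))
    fg <- .extract_features(extractor,
                            array(ground_truth[, , l, ], c(d[1], d[2], n)))
    diff <- fo$features - fg$features
    nf <- ncol(diff)
    loss <- loss + sum(diff^2) / (n * nf)
    if (grad) {
      g <- .extract_features_grad(extractor, fo$cache, 2 * diff / (n * nf))
      dout[, , l, ] <- array(g, c(d[1], d[2], n))
    }
  }
  list(loss = loss, grad = dout)
}

#' Perturbation (bottleneck) loss
#'
#' Mean squared error between the network's bottleneck prediction and the
#' realified clean measurement vector, over the 2m real components.
#'
#' @param predicted real vector (or `[N, 2m]` matrix) of predictions.
#' @param usc_clean the clean `perturbation` (complex, realified internally)
#'   or an already-realified numeric vector/matrix.
#' @return scalar loss.
#' @export
loss_perturbation <- function(predicted, usc_clean) {
  target <- if (is.complex(unclass(usc_clean))) {
    realify_perturbation(usc_clean)
  } else {
    unclass(usc_clean)
  }
  predicted <- unclass(predicted)
  if (is.matrix(predicted) && !is.matrix(target)) {
    target <- matrix(target, nrow(predicted), length(target), byrow = TRUE)
  }
  if (length(predicted) != length(target)) stop("length mismatch")
  mean((predicted - target)^2)
}

#' Composite training loss
#'
#' `alpha * L_p + beta * L_i + gamma * L_f` with the configured weights.
#'
#' @param L_p,L_i,L_f the component losses.
#' @param weights a [loss_weights()].
#' @return scalar total loss.
#' @export
total_loss <- function(L_p, L_i, L_f, weights = loss_weights()) {
  stopifnot(is.finite(L_p), is.finite(L_i), is.finite(L_f))
  weights$alpha * L_p + weights$beta * L_i + weights$gamma * L_f
}
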