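#' APU-Net model configuration
#'
#' The network processes the reconstruction volume as a 2-D image whose
#' channels are the depth layers: the input is the channel concatenation of
#' the reconstruction (`n_layers` channels) and the fine-mesh mask
#' (`n_layers` channels), bilinearly resampled from the `grid_size` lateral
#' grid to the power-of-two `spatial` size. The encoder applies `n_blocks`
#' attention-convolution blocks (convolution, rectifier, CoT attention, 2x2
#' max pool), the bottleneck maps the flattened code through fully connected
#' layers to the length-`perturbation_dim` measurement prediction and back,
#' and the decoder mirrors the encoder with skip concatenations, re-concats
#' the fine-mesh mask, and finishes with two convolutions. A final rectifier
#' keeps the enhanced absorption map nonnegative.
#'
#' @param grid_size lateral grid size of the input volumes (default 36).
#' @param n_layers number of depth layers (default 7).
#' @param spatial internal spatial size; must be divisible by
#'   `2^n_blocks` (default 64).
#' @param n_blocks encoder/decoder depth (default 4).
#' @param base_channels channels of the first block; doubled per block.
#' @param kernel convolution kernel size (odd).
#' @param cot_kernel neighbor-key kernel size of the CoT blocks (odd).
#' @param fc_width width of the fully connected layers flanking the
#'   perturbation head.
#' @param perturbation_dim length of the realified measurement vector
#'   (2 x n_measurements; 252 for the default probe).
#' @param use_cot `FALSE` builds the attention-ablated topology (CoT blocks
#'   replaced by identity).
#' @param final_relu apply the nonnegativity rectifier to the output.
#' @param softmax_axis attention softmax axis, `"spatial"` or `"channel"`.
#' @return An `apunet_config`.
#' @export
apunet_config <- function(grid_size = 36, n_layers = 7, spatial = 64,
                          n_blocks = 4, base_channels = 32, kernel = 3,
                          cot_kernel = 3, fc_width = 512,
                          perturbation_dim = 252, use_cot = TRUE,
                          final_relu = TRUE,
                          softmax_axis = c("spatial", "channel")) {
  softmax_axis <- match.arg(softmax_axis)
  if (spatial %% 2^n_blocks != 0) {
    stop("spatial size must be divisible by 2^n_blocks")
  }
  if (kernel %% 2 == 0 || cot_kernel %% 2 == 0) {
    stop("kernel sizes must be odd")
  }
  channels <- base_channels * 2^(seq_len(n_blocks) - 1)
  structure(
    list(grid_size = grid_size, n_layers = n_layers, spatial = spatial,
         n_blocks = n_blocks, base_channels = base_channels,
         channels = channels, kernel = kernel, cot_kernel = cot_kernel,
         fc_width = fc_width, perturbation_dim = perturbation_dim,
         use_cot = use_cot, final_relu = final_relu,
         softmax_axis = softmax_axis,
         deep_spatial = spatial %/% 2^n_blocks,
         flat_dim = (spatial %/% 2^n_blocks)^2 * channels[n_blocks]),
    class = "apunet_config"
  )
}

#' Small preset configuration for desk-scale experiments
#'
#' A reduced APU-Net (32 x 32 internal resolution, 3 blocks, 8 base
#' channels, 64-wide bottleneck) used for the package's toy training and
#' ablation demonstrations.
#'
#' @param ... overrides passed to [apunet_config()].
#' @return An `apunet_config`.
#' @export
apunet_config_small <- function(...) {
  apunet_config(spatial = 32, n_blocks = 3, base_channels = 8,
                fc_width = 64, ...)
}

#' Build an APU-Net model
#'
#' Initializes all parameters (He-scaled Gaussian weights, zero biases)
#' deterministically from a seed.
#'
#' @param config an [apunet_config()].
#' @param seed integer RNG seed for the initialization.
#' @return An `apunet` model: `list(config, params, seed)`.
#' @export
build_apunet <- function(config = apunet_config(), seed = 1L) {
  cfg <- config
  params <- .with_seed(seed, {
    enc <- vector("list", cfg$n_blocks)
    c_in <- 2L * cfg$n_layers
    for (b in seq_len(cfg$n_blocks)) {
      enc[[b]] <- list(conv = nn_conv_init(cfg$kernel, c_in, cfg$channels[b]))
      if (cfg$use_cot) {
        enc[[b]]$cot <- cot_init(cfg$channels[b], cfg$cot_kernel)
      }
      c_in <- cfg$channels[b]
    }
    dec <- vector("list", cfg$n_blocks)
    c_prev <- cfg$channels[cfg$n_blocks]
    for (i in seq_len(cfg$n_blocks)) {
      b <- cfg$n_blocks - i + 1L
      dec[[i]] <- list(conv = nn_conv_init(cfg$kernel,
                                           c_prev + cfg$channels[b],
                                           cfg$channels[b]))
      if (cfg$use_cot) {
        dec[[i]]$cot <- cot_init(cfg$channels[b], cfg$cot_kernel)
      }
      c_prev <- cfg$channels[b]
    }
    list(
      enc = enc,
      fc1 = nn_dense_init(cfg$flat_dim, cfg$fc_width),
      fc_pert = nn_dense_init(cfg$fc_width, cfg$perturbation_dim, gain = 1),
      fc2 = nn_dense_init(cfg$perturbation_dim, cfg$fc_width),
      fc3 = nn_dense_init(cfg$fc_width, cfg$flat_dim),
      dec = dec,
      head1 = nn_conv_init(cfg$kernel, cfg$base_channels + cfg$n_layers,
                           cfg$base_channels),
      head2 = nn_conv_init(cfg$kernel, cfg$base_channels, cfg$n_layers,
                           gain = 1)
    )
  })
  structure(list(config = cfg, params = params, seed = as.integer(seed)),
            class = "apunet")
}

#' Build the attention-ablated model
#'
#' Identical topology with every CoT block replaced by the identity; the
#' parameter count is strictly lower than the full model's.
#'
#' @param config an [apunet_config()] (its `use_cot` flag is overridden).
#' @param seed integer RNG seed.
#' @return An `apunet` model without attention blocks.
#' @export
build_ablated_model <- function(config = apunet_config(), seed = 1L) {
  config$use_cot <- FALSE
  build_apunet(config, seed)
}

#' Number of trainable parameters
#' @param model an `apunet` model.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  nn_tree_count(model$params)
}

#' @export
print.apunet <- function(x, ...) {
  cat(sprintf(
    "APU-Net: %d blocks, base %d channels, %d x %d internal, %s attention, %d parameters\n",
    x$config$n_blocks, x$config$base_channels, x$config$spatial,
    x$config$spatial, if (x$config$use_cot) "CoT" else "no",
    count_parameters(x)
  ))
  invisible(x)
}

# ---- forward pass (with caches for backprop) ----

.apunet_encode <- function(params, cfg, xin) {
  h <- xin
  caches <- vector("list", cfg$n_blocks)
  skips <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    cf <- nn_conv_fwd(h, params$enc[[b]]$conv)
    rf <- nn_relu_fwd(cf$out)
    h <- rf$out
    ct <- NULL
    if (cfg$use_cot) {
      ct <- cot_fwd(h, params$enc[[b]]$cot, cfg$softmax_axis)
      h <- ct$out
    }
    skips[[b]] <- h
    pf <- nn_pool_fwd(h)
    h <- pf$out
    caches[[b]] <- list(conv = cf, relu = rf, cot = ct, pool = pf)
  }
  list(skips = skips, code = nn_flatten(h), caches = caches)
}

.apunet_bottleneck <- function(params, cfg, code) {
  f1 <- nn_dense_fwd(code, params$fc1)
  r1 <- nn_relu_fwd(f1$out)
  fp <- nn_dense_fwd(r1$out, params$fc_pert)
  f2 <- nn_dense_fwd(fp$out, params$fc2)
  r2 <- nn_relu_fwd(f2$out)
  f3 <- nn_dense_fwd(r2$out, params$fc3)
  r3 <- nn_relu_fwd(f3$out)
  feat <- nn_unflatten(r3$out, cfg$deep_spatial, cfg$deep_spatial,
                       cfg$channels[cfg$n_blocks])
  list(perturbation = fp$out, feat = feat,
       caches = list(f1 = f1, r1 = r1, fp = fp, f2 = f2, r2 = r2,
                     f3 = f3, r3 = r3))
}

.apunet_decode <- function(params, cfg, feat, skips, mask_s) {
  h <- feat
  caches <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    b <- cfg$n_blocks - i + 1L
    up <- nn_upsample_fwd(h)
    cat_ <- nn_concat_channels(up, skips[[b]])
    cf <- nn_conv_fwd(cat_, params$dec[[i]]$conv)
    rf <- nn_relu_fwd(cf$out)
    h <- rf$out
    ct <- NULL
    if (cfg$use_cot) {
      ct <- cot_fwd(h, params$dec[[i]]$cot, cfg$softmax_axis)
      h <- ct$out
    }
    caches[[i]] <- list(up_ch = dim(up)[3], conv = cf, relu = rf, cot = ct)
  }
  catm <- nn_concat_channels(h, mask_s)
  h1 <- nn_conv_fwd(catm, params$head1)
  hr <- nn_relu_fwd(h1$out)
  h2 <- nn_conv_fwd(hr$out, params$head2)
  out <- h2$out
  fr <- NULL
  if (cfg$final_relu) {
    fr <- nn_relu_fwd(out)
    out <- fr$out
  }
  list(out = out,
       caches = list(blocks = caches, h1 = h1, hr = hr, h2 = h2, fr = fr))
}

# full forward; recon/mask are [g, g, L, N] arrays on the imaging grid
.apunet_fwd <- function(params, cfg, recon, mask) {
  xs <- nn_resample_fwd(recon, cfg$spatial)
  ms <- nn_resample_fwd(mask, cfg$spatial)
  xin <- nn_concat_channels(xs, ms)
  enc <- .apunet_encode(params, cfg, xin)
  bot <- .apunet_bottleneck(params, cfg, enc$code)
  dec <- .apunet_decode(params, cfg, bot$feat, enc$skips, ms)
  enhanced <- nn_resample_fwd(dec$out, cfg$grid_size)
  list(enhanced = enhanced, perturbation = bot$perturbation,
       cache = list(enc = enc, bot = bot, dec = dec))
}

# full backward: d_enh [g, g, L, N], d_pert [N, pert_dim] -> gradient tree
.apunet_bwd <- function(params, cfg, cache, d_enh, d_pert) {
  grads <- nn_tree_map(function(x) x * 0, params)
  dec <- cache$dec$caches
  enc <- cache$enc$caches
  bot <- cache$bot$caches

  dh <- nn_resample_bwd(d_enh, cfg$spatial)
  if (cfg$final_relu) dh <- nn_relu_bwd(dh, dec$fr)
  b2 <- nn_conv_bwd(dh, dec$h2, params$head2)
  grads$head2$W <- b2$dW; grads$head2$b <- b2$db
  dh <- nn_relu_bwd(b2$dx, dec$hr)
  b1 <- nn_conv_bwd(dh, dec$h1, params$head1)
  grads$head1$W <- b1$dW; grads$head1$b <- b1$db
  sp <- nn_split_channels(b1$dx, cfg$base_channels)
  dh <- sp[[1]] # mask-channel gradient sp[[2]] is not needed

  dskips <- vector("list", cfg$n_blocks)
  for (i in rev(seq_len(cfg$n_blocks))) {
    b <- cfg$n_blocks - i + 1L
    blk <- dec$blocks[[i]]
    if (cfg$use_cot) {
      cb <- cot_bwd(dh, blk$cot$cache, params$dec[[i]]$cot)
      grads$dec[[i]]$cot <- utils::modifyList(grads$dec[[i]]$cot, cb$grads)
      dh <- cb$dx
    }
    dh <- nn_relu_bwd(dh, blk$relu)
    cv <- nn_conv_bwd(dh, blk$conv, params$dec[[i]]$conv)
    grads$dec[[i]]$conv$W <- cv$dW; grads$dec[[i]]$conv$b <- cv$db
    spc <- nn_split_channels(cv$dx, blk$up_ch)
    dskips[[b]] <- spc[[2]]
    dh <- nn_upsample_bwd(spc[[1]])
  }

  dcode <- nn_flatten(dh)
  d3 <- nn_relu_bwd(dcode, bot$r3)
  g3 <- nn_dense_bwd(d3, bot$f3, params$fc3)
  grads$fc3$W <- g3$dW; grads$fc3$b <- g3$db
  d2 <- nn_relu_bwd(g3$dx, bot$r2)
  g2 <- nn_dense_bwd(d2, bot$f2, params$fc2)
  grads$fc2$W <- g2$dW; grads$fc2$b <- g2$db
  dp <- g2$dx + d_pert
  gp <- nn_dense_bwd(dp, bot$fp, params$fc_pert)
  grads$fc_pert$W <- gp$dW; grads$fc_pert$b <- gp$db
  d1 <- nn_relu_bwd(gp$dx, bot$r1)
  g1 <- nn_dense_bwd(d1, bot$f1, params$fc1)
  grads$fc1$W <- g1$dW; grads$fc1$b <- g1$db

  deep_c <- cfg$channels[cfg$n_blocks]
  dh <- nn_unflatten(g1$dx, cfg$deep_spatial, cfg$deep_spatial, deep_c)
  for (b in rev(seq_len(cfg$n_blocks))) {
    blk <- enc[[b]]
    dh <- nn_pool_bwd(dh, blk$pool)
    dh <- dh + dskips[[b]]
    if (cfg$use_cot) {
      cb <- cot_bwd(dh, blk$cot$cache, params$enc[[b]]$cot)
      grads$enc[[b]]$cot <- utils::modifyList(grads$enc[[b]]$cot, cb$grads)
      dh <- cb$dx
    }
    dh <- nn_relu_bwd(dh, blk$relu)
    cv <- nn_conv_bwd(dh, blk$conv, params$enc[[b]]$conv)
    grads$enc[[b]]$conv$W <- cv$dW; grads$enc[[b]]$conv$b <- cv$db
    dh <- cv$dx
  }
  grads
}

# ---- public forward interfaces ----

#' Run the APU-Net forward pass
#'
#' @param model an `apunet` from [build_apunet()].
#' @param recon input reconstruction, array `[grid, grid, n_layers]` or
#'   `[grid, grid, n_layers, N]`, cm^-1.
#' @param mask fine-mesh mask volume, same shape (numeric or logical).
#' @return list with `enhanced` (same shape/units as `recon`) and
#'   `predicted_perturbation` (`[N, perturbation_dim]` real matrix, in the
#'   standardized measurement units used during training).
#' @export
apunet_forward <- function(model, recon, mask) {
  cfg <- model$config
  squeeze <- length(dim(recon)) == 3
  if (squeeze) {
    dim(recon) <- c(dim(recon), 1L)
    dim(mask) <- c(dim(mask), 1L)
  }
  recon <- recon * 1.0
  mask <- mask * 1.0
  # a trained model carries the standardization scale of its training set;
  # inputs are scaled into and outputs back out of network units
  s <- if (!is.null(model$scales)) model$scales$image else 1
  fw <- .apunet_fwd(model$params, cfg, recon / s, mask)
  enhanced <- fw$enhanced * s
  if (squeeze) dim(enhanced) <- dim(enhanced)[1:3]
  list(enhanced = enhanced, predicted_perturbation = fw$perturbation)
}

#' Encoder: attention-convolution feature pyramid
#'
#' Runs the four (by default) attention-convolution blocks on the
#' concatenated reconstruction and fine-mesh channels, each halving the
#' spatial size.
#'
#' @param model an `apunet`.
#' @param recon,mask input volumes as in [apunet_forward()] (batched 4-D).
#' @return list with `skips` (per-block feature maps) and `code` (flattened
#'   deepest features, `[N, flat_dim]`).
#' @export
apunet_encode <- function(model, recon, mask) {
  cfg <- model$config
  if (dim(recon)[3] != cfg$n_layers) stop("wrong channel count")
  xs <- nn_resample_fwd(recon * 1.0, cfg$spatial)
  ms <- nn_resample_fwd(mask * 1.0, cfg$spatial)
  e <- .apunet_encode(model$params, cfg, nn_concat_channels(xs, ms))
  list(skips = e$skips, code = e$code)
}

#' Bottleneck: perturbation prediction head
#'
#' Maps the flattened encoder code through fully connected layers to the
#' realified measurement vector (the physical forward-model prediction) and
#' on to the decoder's entry features.
#'
#' @param model an `apunet`.
#' @param code `[N, flat_dim]` matrix from [apunet_encode()].
#' @return list with `predicted_perturbation` (`[N, perturbation_dim]`) and
#'   `feat` (reshaped decoder entry features).
#' @export
apunet_bottleneck <- function(model, code) {
  b <- .apunet_bottleneck(model$params, model$config, code)
  list(predicted_perturbation = b$perturbation, feat = b$feat)
}

#' Decoder: enhanced-volume synthesis
#'
#' Upsampling attention-convolution blocks with encoder skip concatenation,
#' fine-mesh re-concatenation, and the two final convolutions.
#'
#' @param model an `apunet`.
#' @param feat decoder entry features from [apunet_bottleneck()].
#' @param skips encoder skip list from [apunet_encode()].
#' @param mask fine-mesh mask volume (batched 4-D, grid resolution).
#' @return enhanced volume, `[grid, grid, n_layers, N]`.
#' @export
apunet_decode <- function(model, feat, skips, mask) {
  cfg <- model$config
  ms <- nn_resample_fwd(mask * 1.0, cfg$spatial)
  d <- .apunet_decode(model$params, cfg, feat, skips, ms)
  nn_resample_fwd(d$out, cfg$grid_size)
}

#' Enhance the reconstructions of a dataset or sample list
#'
#' @param model a trained `apunet`.
#' @param samples a `dot_dataset`, list of `dot_sample`s, or one sample.
#' @param batch_size forward-pass batch size.
#' @return list of enhanced 3-D volumes (cm^-1), one per sample.
#' @export
apunet_enhance <- function(model, samples, batch_size = 16) {
  if (inherits(samples, "dot_dataset")) samples <- samples$samples
  if (inherits(samples, "dot_sample")) samples <- list(samples)
  n <- length(samples)
  out <- vector("list", n)
  g <- model$config$grid_size
  L <- model$config$n_layers
  for (start in seq(1, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1, n)
    recon <- array(0, c(g, g, L, length(ix)))
    mask <- array(0, c(g, g, L, length(ix)))
    for (j in seq_along(ix)) {
      recon[, , , j] <- samples[[ix[j]]]$input_recon
      mask[, , , j] <- samples[[ix[j]]]$fine_mesh_mask * 1.0
    }
    fw <- apunet_forward(model, recon, mask)
    for (j in seq_along(ix)) out[[ix[j]]] <- fw$enhanced[, , , j]
  }
  out
}
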