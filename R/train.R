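#' Training configuration
#'
#' Defaults follow the two-phase schedule: phase 1 trains on multi-target
#' simulations at learning rate 1e-4 for 200 epochs; an optional fine-tuning
#' phase on single-target and phantom-preset data uses 5e-5 for 200 epochs.
#' The learning rate is multiplied by `decay_factor` whenever the relative
#' training-loss improvement over the last `decay_patience` epochs falls
#' below `decay_threshold` (0.01).
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param epochs number of epochs (>= 1).
#' @param batch_size minibatch size.
#' @param decay_factor,decay_patience,decay_threshold learning-rate decay
#'   rule.
#' @param weights a [loss_weights()].
#' @param augment apply random rotation/translation/scaling/noise
#'   augmentation each epoch (requires per-sample weight matrices; see
#'   [augment_sample()]).
#' @param extractor_seed seed of the frozen perceptual feature extractor.
#' @param seed global training seed (shuffling, augmentation).
#' @param fine_tune optional second-phase `train_config` (applied to the
#'   fine-tuning dataset passed to [train_apunet()]).
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 200, batch_size = 16,
                         decay_factor = 0.5, decay_patience = 10,
                         decay_threshold = 0.01, weights = loss_weights(),
                         augment = FALSE, extractor_seed = 1234L,
                         seed = 1L, fine_tune = NULL) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(
    list(learning_rate = learning_rate, epochs = epochs,
         batch_size = batch_size, decay_factor = decay_factor,
         decay_patience = decay_patience, decay_threshold = decay_threshold,
         weights = weights, augment = augment,
         extractor_seed = as.integer(extractor_seed),
         seed = as.integer(seed), fine_tune = fine_tune),
    class = "train_config"
  )
}

# lateral affine resampling of a volume (rotation about the grid center,
# then scaling, then translation), bilinear, zero outside
.affine_lateral <- function(vol, grid, theta, tx, ty, s) {
  d <- dim(vol)
  xg <- grid$xs; yg <- grid$ys
  px <- rep(xg, times = d[2]); py <- rep(yg, each = d[1])
  # backward map: undo translation, scaling, rotation
  qx <- (px - tx) / s; qy <- (py - ty) / s
  ct <- cos(-theta); st <- sin(-theta)
  sx <- ct * qx - st * qy
  sy <- st * qx + ct * qy
  # fractional voxel indices
  fx <- (sx - xg[1]) / grid$fine_lateral_spacing + 1
  fy <- (sy - yg[1]) / grid$fine_lateral_spacing + 1
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  out <- array(0, d)
  gather <- function(ii, jj) {
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
    ii <- pmin(pmax(ii, 1L), d[1]); jj <- pmin(pmax(jj, 1L), d[2])
    idx <- cbind(ii, jj)
    function(layer) {
      v <- layer[idx]
      v[!ok] <- 0
      v
    }
  }
  g00 <- gather(i0, j0); g10 <- gather(i0 + 1, j0)
  g01 <- gather(i0, j0 + 1); g11 <- gather(i0 + 1, j0 + 1)
  for (l in seq_len(d[3])) {
    layer <- vol[, , l]
    out[, , l] <- matrix(
      (1 - wx) * (1 - wy) * g00(layer) + wx * (1 - wy) * g10(layer) +
        (1 - wx) * wy * g01(layer) + wx * wy * g11(layer),
      d[1], d[2]
    )
  }
  out
}

#' Augment a training sample
#'
#' Applies one random lateral affine transform (rotation within +/- 45
#' degrees, translation, scaling) identically to the input reconstruction,
#' fine-mesh mask, lesion mask and ground truth, then adds Gaussian noise to
#' the input reconstruction only. The perturbation target is recomputed as
#' `W (transformed ground truth)` so the bottleneck regression stays
#' physically consistent with the augmented image. A transform that pushes
#' the lesion out of the grid is rejected and redrawn.
#'
#' @param sample a `dot_sample`.
#' @param W the `weight_matrix` of the sample's mesh (required whenever a
#'   geometric transform is applied).
#' @param seed integer RNG seed.
#' @param max_rotation maximal |rotation| in degrees.
#' @param max_translation maximal |translation| per axis, cm.
#' @param scale_range multiplicative scaling range.
#' @param noise_sd Gaussian noise standard deviation relative to the
#'   reconstruction maximum.
#' @return The augmented `dot_sample` (provenance recorded in metadata).
#' @export
augment_sample <- function(sample, W = NULL, seed = 1L, max_rotation = 45,
                           max_translation = 0.5, scale_range = c(0.9, 1.1),
                           noise_sd = 0.02) {
  grid <- if (!is.null(W)) W$grid else build_grid()
  geo <- max_rotation > 0 || max_translation > 0 || any(scale_range != 1)
  if (geo && is.null(W)) {
    stop("W is required to recompute the perturbation target")
  }
  .with_seed(seed, {
    n_orig <- sum(sample$lesion_mask)
    for (try in 1:10) {
      theta <- stats::runif(1, -max_rotation, max_rotation) * pi / 180
      tx <- stats::runif(1, -max_translation, max_translation)
      ty <- stats::runif(1, -max_translation, max_translation)
      s <- stats::runif(1, scale_range[1], scale_range[2])
      if (!geo) theta <- tx <- ty <- 0
      if (!geo) s <- 1
      lesion <- .affine_lateral(sample$lesion_mask * 1.0, grid,
                                theta, tx, ty, s) > 0.5
      if (sum(lesion) >= 0.5 * n_orig * s^2 || !geo) break
    }
    gt <- .affine_lateral(sample$ground_truth, grid, theta, tx, ty, s)
    recon <- .affine_lateral(sample$input_recon, grid, theta, tx, ty, s)
    fmask <- .affine_lateral(sample$fine_mesh_mask * 1.0, grid,
                             theta, tx, ty, s) > 0.5
    if (noise_sd > 0) {
      recon <- recon + stats::rnorm(length(recon), 0,
                                    noise_sd * max(abs(recon), 1e-6))
    }
    out <- sample
    out$ground_truth <- gt
    out$input_recon <- recon
    out$lesion_mask <- lesion
    out$fine_mesh_mask <- fmask
    if (!is.null(W)) {
      out$perturbation <- forward_perturbation(
        W, voxels_to_cells(W$mesh, gt, "mean")
      )
    }
    out$metadata$augmented <- list(seed = as.integer(seed), rotation = theta,
                                   translation = c(tx, ty), scale = s,
                                   noise_sd = noise_sd)
    out
  })
}

# stack dataset samples into batched tensors
.stack_samples <- function(samples, grid_size, n_layers) {
  n <- length(samples)
  recon <- array(0, c(grid_size, grid_size, n_layers, n))
  mask <- array(0, c(grid_size, grid_size, n_layers, n))
  gt <- array(0, c(grid_size, grid_size, n_layers, n))
  lesion <- array(FALSE, c(grid_size, grid_size, n_layers, n))
  pert <- matrix(0, n, 2 * length(samples[[1]]$perturbation))
  for (i in seq_len(n)) {
    sm <- samples[[i]]
    recon[, , , i] <- sm$input_recon
    mask[, , , i] <- sm$fine_mesh_mask * 1.0
    gt[, , , i] <- sm$ground_truth
    lesion[, , , i] <- .dilate_mask(sm$lesion_mask, 1L, 0L)
    pert[i, ] <- realify_perturbation(sm$perturbation)
  }
  list(recon = recon, mask = mask, gt = gt, lesion = lesion, pert = pert)
}

# one optimization phase; returns updated model/optimizer plus the log
.train_phase <- function(model, tensors, val_tensors, config, extractor,
                         pert_scale, phase_name, adam = NULL) {
  cfg <- model$config
  w <- config$weights
  n <- dim(tensors$recon)[4]
  lr <- config$learning_rate
  adam <- adam %||% nn_adam_init(model$params)
  log <- vector("list", config$epochs)
  epoch_losses <- numeric(config$epochs)
  best <- list(loss = Inf, params = model$params)
  cooldown <- 0L
  target <- tensors$pert / pert_scale

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    comps <- c(total = 0, lp = 0, li = 0, lf = 0)
    nb <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      ix <- ord[start:min(start + config$batch_size - 1, n)]
      recon <- tensors$recon[, , , ix, drop = FALSE]
      mask <- tensors$mask[, , , ix, drop = FALSE]
      gt <- tensors$gt[, , , ix, drop = FALSE]
      lesion <- tensors$lesion[, , , ix, drop = FALSE]
      tg <- target[ix, , drop = FALSE]

      fw <- .apunet_fwd(model$params, cfg, recon, mask)
      lp <- mean((fw$perturbation - tg)^2)
      li <- loss_weighted_mse(fw$enhanced, gt, lesion, w$a, w$b)
      d_enh <- w$beta *
        .loss_weighted_mse_grad(fw$enhanced, gt, lesion, w$a, w$b)
      lf <- 0
      if (w$gamma > 0) {
        pc <- .loss_perceptual_impl(fw$enhanced, gt, extractor, grad = TRUE)
        lf <- pc$loss
        d_enh <- d_enh + w$gamma * pc$grad
      }
      d_pert <- w$alpha * 2 * (fw$perturbation - tg) / length(tg)
      tot <- total_loss(lp, li, lf, w)
      if (!is.finite(tot)) {
        stop(sprintf("training diverged at %s epoch %d (loss %g)",
                     phase_name, epoch, tot))
      }
      grads <- .apunet_bwd(model$params, cfg, fw$cache, d_enh, d_pert)
      step <- nn_adam_step(model$params, grads, adam, lr)
      model$params <- step$params
      adam <- step$state
      comps <- comps + c(tot, lp, li, lf)
      nb <- nb + 1
    }
    comps <- comps / nb
    epoch_losses[epoch] <- comps["total"]

    val_loss <- NA_real_
    if (!is.null(val_tensors)) {
      fw <- .apunet_fwd(model$params, cfg, val_tensors$recon,
                        val_tensors$mask)
      vlp <- mean((fw$perturbation - val_tensors$pert / pert_scale)^2)
      vli <- loss_weighted_mse(fw$enhanced, val_tensors$gt,
                               val_tensors$lesion, w$a, w$b)
      vlf <- if (w$gamma > 0) {
        loss_perceptual(fw$enhanced, val_tensors$gt, extractor)
      } else {
        0
      }
      val_loss <- total_loss(vlp, vli, vlf, w)
    }
    track <- if (is.na(val_loss)) comps["total"] else val_loss
    if (track < best$loss) best <- list(loss = track, params = model$params)

    # plateau rule: relative improvement below threshold over the window
    if (cooldown > 0) cooldown <- cooldown - 1L
    if (epoch > config$decay_patience && cooldown == 0L) {
      ref <- epoch_losses[epoch - config$decay_patience]
      if ((ref - epoch_losses[epoch]) / abs(ref) < config$decay_threshold) {
        lr <- lr * config$decay_factor
        cooldown <- config$decay_patience
      }
    }
    log[[epoch]] <- data.frame(
      phase = phase_name, epoch = epoch, loss = unname(comps["total"]),
      loss_perturbation = unname(comps["lp"]),
      loss_image = unname(comps["li"]),
      loss_perceptual = unname(comps["lf"]),
      val_loss = val_loss, learning_rate = lr
    )
  }
  model$params <- best$params
  list(model = model, adam = adam, log = do.call(rbind, log))
}

#' Train an APU-Net model
#'
#' Runs the composite-loss training loop (Adam, minibatches, plateau
#' learning-rate decay) on the dataset's train split, checkpointing the
#' best validation loss (or training loss when the val split is empty). If
#' `config$fine_tune` and `fine_tune_dataset` are given, a second phase
#' continues from the trained weights. The perturbation regression target is
#' standardized by the dataset-level measurement spread and the image
#' volumes by the spread of the nonzero ground-truth absorption; both
#' scales are recorded on the returned model and applied transparently at
#' inference. Fully seeded and deterministic.
#'
#' @param model an `apunet` from [build_apunet()].
#' @param dataset a `dot_dataset`.
#' @param config a [train_config()].
#' @param fine_tune_dataset optional dataset for the fine-tuning phase.
#' @return list with `model` (trained), `log` (per-epoch loss components and
#'   learning rate), `pert_scale`, and `extractor_provenance`.
#' @export
train_apunet <- function(model, dataset, config = train_config(),
                         fine_tune_dataset = NULL) {
  cfg <- model$config
  extractor <- feature_extractor(grid_size = cfg$grid_size,
                                 seed = config$extractor_seed)
  pick <- function(ds, lab) ds$samples[ds$split == lab]
  tr <- pick(dataset, "train")
  if (!length(tr)) tr <- dataset$samples
  va <- pick(dataset, "val")
  tensors <- .stack_samples(tr, cfg$grid_size, cfg$n_layers)
  val_tensors <- if (length(va)) {
    .stack_samples(va, cfg$grid_size, cfg$n_layers)
  } else {
    NULL
  }
  pert_scale <- stats::sd(tensors$pert)
  if (!is.finite(pert_scale) || pert_scale == 0) pert_scale <- 1
  # standardize the image domain as well: absorption values are O(0.01-0.1)
  # cm^-1 and would otherwise make the image loss negligible next to the
  # standardized perturbation loss
  img_scale <- stats::sd(tensors$gt[tensors$gt != 0])
  if (!is.finite(img_scale) || img_scale == 0) img_scale <- 1
  scale_imgs <- function(t) {
    if (is.null(t)) return(NULL)
    t$recon <- t$recon / img_scale
    t$gt <- t$gt / img_scale
    t
  }
  tensors <- scale_imgs(tensors)
  val_tensors <- scale_imgs(val_tensors)

  out <- .with_seed(config$seed, {
    ph1 <- .train_phase(model, tensors, val_tensors, config, extractor,
                        pert_scale, "phase1")
    log <- ph1$log
    model <- ph1$model
    if (!is.null(config$fine_tune) && !is.null(fine_tune_dataset)) {
      tr2 <- pick(fine_tune_dataset, "train")
      if (!length(tr2)) tr2 <- fine_tune_dataset$samples
      va2 <- pick(fine_tune_dataset, "val")
      t2 <- scale_imgs(.stack_samples(tr2, cfg$grid_size, cfg$n_layers))
      v2 <- if (length(va2)) {
        scale_imgs(.stack_samples(va2, cfg$grid_size, cfg$n_layers))
      } else {
        NULL
      }
      ph2 <- .train_phase(model, t2, v2, config$fine_tune, extractor,
                          pert_scale, "phase2")
      model <- ph2$model
      log <- rbind(log, ph2$log)
    }
    list(model = model, log = log)
  })
  out$model$scales <- list(image = img_scale, perturbation = pert_scale)
  list(model = out$model, log = out$log, pert_scale = pert_scale,
       image_scale = img_scale, extractor_provenance = extractor$provenance)
}
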