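# helpers for path-indexed access into parameter trees
getp <- function(tree, path) {
  for (p in path) tree <- tree[[p]]
  tree
}
setp <- function(tree, path, i, v) {
  if (length(path) == 1) {
    tree[[path[[1]]]][i] <- v
    return(tree)
  }
  tree[[path[[1]]]] <- setp(tree[[path[[1]]]], path[-1], i, v)
  tree
}

test_that("CoT block matches a step-by-step scripted evaluation", {
  # 2 x 2 x 1 map with hand-set weights; every stage recomputed with loops
  x <- array(c(0.5, -1, 2, 0.25), c(2, 2, 1))
  params <- list(
    kconv = list(W = matrix(c(0.1, -0.2, 0.3, 0, 1, 0.2, -0.1, 0.4, 0.05),
                            9, 1),
                 b = 0.02, k = 3L, c_in = 1L, c_out = 1L),
    vconv = list(W = matrix(1.5, 1, 1), b = -0.1, k = 1L,
                 c_in = 1L, c_out = 1L),
    ae1 = list(W = matrix(c(0.7, -0.3), 2, 1), b = 0.05, k = 1L,
               c_in = 2L, c_out = 1L),
    ae2 = list(W = matrix(-0.8, 1, 1), b = 0.1, k = 1L,
               c_in = 1L, c_out = 1L)
  )
  # scripted oracle: K = Q = X; V = X Wv; K1 = 3x3 conv; Im = Ae[K1, Q];
  # K2 = V * softmax(Im); out = K1 + K2
  conv3 <- function(img, w, b) { # w indexed [di, dj] over a 3x3 window
    out <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      acc <- b
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        val <- if (ii >= 1 && ii <= 2 && jj >= 1 && jj <= 2) img[ii, jj] else 0
        acc <- acc + val * w[(di + 2) + 3 * (dj + 1)]
      }
      out[i, j] <- acc
    }
    out
  }
  X <- x[, , 1]
  V <- X * 1.5 - 0.1
  K1 <- conv3(X, params$kconv$W[, 1], 0.02)
  h <- pmax(K1 * 0.7 + X * (-0.3) + 0.05, 0)
  Im <- h * (-0.8) + 0.1
  att <- exp(Im - max(Im)); att <- att / sum(att)
  expected <- K1 + V * att

  got <- cot_block(x, params)
  expect_equal(dim(got), dim(x))
  expect_lt(max(abs(got[, , 1] - expected)), 1e-10)
})

test_that("CoT block preserves shape, zeroes with zero inputs, and checks channels", {
  set.seed(2)
  for (dims in list(c(5, 7, 3, 2), c(4, 4, 6, 1))) {
    params <- .with_seed(1, cot_init(dims[3]))
    x <- array(rnorm(prod(dims)), dims)
    out <- cot_fwd(x, params, "spatial")$out
    expect_equal(dim(out), dims)
    # zero input with zero biases gives K1 = 0 and output = 0
    zp <- params
    zp$kconv$b <- zp$kconv$b * 0; zp$vconv$b <- zp$vconv$b * 0
    zp$ae1$b <- zp$ae1$b * 0; zp$ae2$b <- zp$ae2$b * 0
    z <- cot_fwd(array(0, dims), zp, "spatial")$out
    expect_true(all(z == 0))
  }
  expect_error(cot_block(array(0, c(3, 3, 2)), .with_seed(1, cot_init(4))),
               "channel")
})

test_that("encoder/bottleneck/decoder contracts hold across depths", {
  for (nb in c(3, 4)) {
    cfg <- apunet_config(grid_size = 36, n_layers = 7, spatial = 64,
                         n_blocks = nb, base_channels = 4, fc_width = 16,
                         perturbation_dim = 252)
    model <- build_apunet(cfg, seed = 2)
    inp <- list(recon = array(abs(rnorm(36 * 36 * 7 * 2, 0, 0.05)),
                              c(36, 36, 7, 2)),
                mask = array(1, c(36, 36, 7, 2)))
    enc <- apunet_encode(model, inp$recon, inp$mask)
    expect_length(enc$skips, nb)
    expect_equal(dim(enc$skips[[nb]])[1], 64 / 2^(nb - 1))
    expect_equal(ncol(enc$code), (64 / 2^nb)^2 * 4 * 2^(nb - 1))
    bot <- apunet_bottleneck(model, enc$code)
    expect_equal(dim(bot$predicted_perturbation), c(2, 252))
    out <- apunet_decode(model, bot$feat, enc$skips, inp$mask)
    expect_equal(dim(out), c(36, 36, 7, 2))
  }
  expect_error(apunet_encode(build_apunet(tiny_net_config(), 1),
                             array(0, c(12, 12, 5, 1)),
                             array(0, c(12, 12, 5, 1))),
               "channel")
})

test_that("forward pass is deterministic and the mask channel is live", {
  cfg <- tiny_net_config()
  model <- build_apunet(cfg, seed = 3)
  inp <- tiny_input()
  f1 <- apunet_forward(model, inp$recon, inp$mask)
  f2 <- apunet_forward(model, inp$recon, inp$mask)
  expect_identical(f1, f2)
  expect_equal(dim(f1$enhanced), dim(inp$recon))
  expect_true(all(is.finite(f1$enhanced)))
  expect_true(all(f1$enhanced >= 0)) # nonnegativity rectifier
  # changing the mask changes the output
  f3 <- apunet_forward(model, inp$recon, inp$mask * 0)
  expect_false(identical(f1$enhanced, f3$enhanced))
  # extreme inputs keep the perturbation head finite
  f4 <- apunet_forward(model, inp$recon * 0 + 1e3, inp$mask)
  expect_true(all(is.finite(f4$predicted_perturbation)))
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_net_config()
  model <- build_apunet(cfg, seed = 7)
  inp <- tiny_input()
  fw <- .apunet_fwd(model$params, cfg, inp$recon, inp$mask)
  set.seed(4)
  R1 <- array(rnorm(length(fw$enhanced)), dim(fw$enhanced))
  R2 <- matrix(rnorm(length(fw$perturbation)), nrow(fw$perturbation))
  gr <- .apunet_bwd(model$params, cfg, fw$cache, R1, R2)
  lossf <- function(params) {
    f <- .apunet_fwd(params, cfg, inp$recon, inp$mask)
    sum(f$enhanced * R1) + sum(f$perturbation * R2)
  }
  paths <- list(list("enc", 1, "conv", "W"), list("enc", 2, "cot", "kconv", "W"),
                list("enc", 1, "cot", "ae1", "W"),
                list("enc", 2, "cot", "vconv", "b"),
                list("fc1", "W"), list("fc_pert", "W"), list("fc_pert", "b"),
                list("fc3", "W"), list("dec", 1, "conv", "W"),
                list("dec", 2, "cot", "ae2", "W"),
                list("head1", "W"), list("head2", "W"), list("head2", "b"))
  eps <- 1e-6
  for (p in paths) {
    g_an <- getp(gr, p)
    set.seed(length(g_an))
    for (i in sample(length(g_an), min(4, length(g_an)))) {
      v0 <- getp(model$params, p)[i]
      lp <- lossf(setp(model$params, p, i, v0 + eps))
      lm <- lossf(setp(model$params, p, i, v0 - eps))
      g_num <- (lp - lm) / (2 * eps)
      expect_lt(abs(g_num - g_an[i]) / max(1e-6, abs(g_num) + abs(g_an[i])),
                1e-3)
    }
  }
})

test_that("gradients are finite and nonzero through the perturbation head", {
  cfg <- tiny_net_config()
  model <- build_apunet(cfg, seed = 9)
  inp <- tiny_input()
  fw <- .apunet_fwd(model$params, cfg, inp$recon, inp$mask)
  # pure bottleneck loss still reaches the encoder weights
  d_pert <- 2 * fw$perturbation / length(fw$perturbation)
  gr <- .apunet_bwd(model$params, cfg, fw$cache,
                    array(0, dim(fw$enhanced)), d_pert)
  enc_g <- gr$enc[[1]]$conv$W
  expect_true(all(is.finite(enc_g)))
  expect_gt(max(abs(enc_g)), 0)
})

test_that("attention ablation reduces parameters and is reproducible by crafted weights", {
  cfg <- tiny_net_config()
  full <- build_apunet(cfg, seed = 11)
  ablated <- build_ablated_model(cfg, seed = 11)
  expect_lt(count_parameters(ablated), count_parameters(full))
  expect_false(ablated$config$use_cot)

  # craft CoT weights that make each block the identity: key conv = delta
  # kernel (K1 = X), value embedding = 0 (K2 = 0), so K1 + K2 = X
  crafted <- full
  crafted$params$enc <- lapply(seq_along(full$params$enc), function(b) {
    blk <- full$params$enc[[b]]
    blk$conv <- ablated$params$enc[[b]]$conv
    C <- blk$cot$kconv$c_out
    delta <- array(0, c(3, 3, C, C))
    for (c in seq_len(C)) delta[2, 2, c, c] <- 1
    blk$cot$kconv$W <- matrix(delta, 9 * C, C)
    blk$cot$kconv$b <- numeric(C)
    blk$cot$vconv$W <- blk$cot$vconv$W * 0
    blk$cot$vconv$b <- numeric(C)
    blk
  })
  crafted$params$dec <- lapply(seq_along(full$params$dec), function(i) {
    blk <- full$params$dec[[i]]
    blk$conv <- ablated$params$dec[[i]]$conv
    C <- blk$cot$kconv$c_out
    delta <- array(0, c(3, 3, C, C))
    for (c in seq_len(C)) delta[2, 2, c, c] <- 1
    blk$cot$kconv$W <- matrix(delta, 9 * C, C)
    blk$cot$kconv$b <- numeric(C)
    blk$cot$vconv$W <- blk$cot$vconv$W * 0
    blk$cot$vconv$b <- numeric(C)
    blk
  })
  for (nm in c("fc1", "fc_pert", "fc2", "fc3", "head1", "head2")) {
    crafted$params[[nm]] <- ablated$params[[nm]]
  }
  inp <- tiny_input()
  f_crafted <- apunet_forward(crafted, inp$recon, inp$mask)
  f_ablated <- apunet_forward(ablated, inp$recon, inp$mask)
  expect_equal(f_crafted$enhanced, f_ablated$enhanced, tolerance = 1e-12)
})
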