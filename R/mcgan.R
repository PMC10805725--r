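#' Multi-channel cycleGAN configuration
#'
#' Hyperparameters of the colorization model. The translation model follows
#' the cycleGAN recipe -- UNet generators, PatchGAN discriminators,
#' least-squares adversarial loss, cycle-consistency and identity terms,
#' Adam with `beta1 = 0.5`, `beta2 = 0.999`, learning rate 0.0002 with
#' stepped linear decay every 10 epochs over the second half of training,
#' and a replay buffer of generated images for discriminator updates --
#' extended to `n_channels` input channels. Because training feeds
#' co-registered pairs, a supervised L1 term between the translated image
#' and its registered counterpart (`paired_weight`) is included; set it to 0
#' (or `paired = FALSE`) for the classical unpaired objective.
#'
#' @param n_channels number of input channels N (>= 1).
#' @param patch_size square training patch side; must be a multiple of
#'   `2^downsampling_depth` (default 256).
#' @param max_epochs training epoch cap (default 200).
#' @param early_stop_patience epochs without generator-loss improvement
#'   before stopping (default 10).
#' @param lr initial Adam learning rate (default 0.0002).
#' @param lr_decay_interval epochs between decay steps (default 10).
#' @param adam_beta1,adam_beta2 Adam moment decays (defaults 0.5, 0.999).
#' @param cycle_weight cycle-consistency weight lambda_cyc (default 10).
#' @param identity_weight identity-loss weight (default `0.5 * cycle_weight`).
#' @param paired_weight supervised L1 weight on registered pairs (default
#'   `cycle_weight`; ignored when `paired = FALSE`).
#' @param paired feed registered pairs as corresponding items (default
#'   `TRUE`).
#' @param seed integer seed for initialization and data ordering.
#' @param downsampling_depth number of stride-2 encoder stages (default 3;
#'   reduce for small patches).
#' @param filters,disc_filters base channel counts of generator and
#'   discriminator (defaults 16).
#' @param buffer_size replay-buffer capacity (default 50).
#' @return an `mcgan_config` object.
#' @export
mcgan_config <- function(n_channels,
                         patch_size = 256L,
                         max_epochs = 200L,
                         early_stop_patience = 10L,
                         lr = 2e-4,
                         lr_decay_interval = 10L,
                         adam_beta1 = 0.5,
                         adam_beta2 = 0.999,
                         cycle_weight = 10,
                         identity_weight = 0.5 * cycle_weight,
                         paired_weight = cycle_weight,
                         paired = TRUE,
                         seed = 1L,
                         downsampling_depth = 3L,
                         filters = 16L,
                         disc_filters = 16L,
                         buffer_size = 50L) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) stop("`n_channels` must be >= 1")
  if (lr <= 0) stop("`lr` must be positive")
  if (cycle_weight < 0 || identity_weight < 0 || paired_weight < 0)
    stop("loss weights must be non-negative")
  patch_size <- as.integer(patch_size)
  downsampling_depth <- as.integer(downsampling_depth)
  if (patch_size %% 2L^downsampling_depth != 0L)
    stop("`patch_size` must be a multiple of 2^downsampling_depth")
  structure(list(n_channels = n_channels, patch_size = patch_size,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr = lr, lr_decay_interval = as.integer(lr_decay_interval),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 cycle_weight = cycle_weight,
                 identity_weight = identity_weight,
                 paired_weight = if (paired) paired_weight else 0,
                 paired = paired, seed = as.integer(seed),
                 downsampling_depth = downsampling_depth,
                 filters = as.integer(filters),
                 disc_filters = as.integer(disc_filters),
                 buffer_size = as.integer(buffer_size)),
            class = "mcgan_config")
}

#' Learning rate at a given epoch
#'
#' Constant at `lr` for the first half of `max_epochs`, then stepped down
#' every `lr_decay_interval` epochs, linearly to exactly zero on the final
#' step.
#'
#' @param epoch 1-based epoch number.
#' @param cfg an [mcgan_config].
#' @return the effective learning rate.
#' @export
lr_at_epoch <- function(epoch, cfg) {
  half <- cfg$max_epochs %/% 2L
  if (epoch <= half) return(cfg$lr)
  n_steps <- (cfg$max_epochs - half - 1L) %/% cfg$lr_decay_interval + 1L
  step <- (epoch - half - 1L) %/% cfg$lr_decay_interval + 1L
  cfg$lr * max(0, 1 - step / n_steps)
}

#' Expand an RGB target image to N channels
#'
#' The generators map N channels to N channels, but the target H&E domain is
#' RGB; the target is expanded to N channels by duplicating its last (blue)
#' channel, `[R, G, B, B, ..., B]`.
#'
#' @param rgb an [rgb_image] (or `H x W x 3` array).
#' @param n_channels N >= 3.
#' @return `H x W x N` array; the first three channels equal the input.
#' @export
expand_target_channels <- function(rgb, n_channels) {
  v <- if (inherits(rgb, "rgb_image")) rgb$values else rgb
  if (!is.array(v) || dim(v)[3] != 3L) stop("input must be RGB")
  n_channels <- as.integer(n_channels)
  if (n_channels < 3L)
    stop("the target domain is RGB; N must be >= 3")
  out <- array(0, c(dim(v)[1], dim(v)[2], n_channels))
  out[, , 1:3] <- v
  if (n_channels > 3L) for (k in 4:n_channels) out[, , k] <- v[, , 3]
  out
}

#' Discard the surplus N-3 generated channels
#'
#' The generated image always carries N channels; only the first three (the
#' RGB estimate) are kept, clipped to `[0, 1]`.
#'
#' @param img `H x W x C` array with `C >= 3`.
#' @return an [rgb_image].
#' @export
discard_surplus_channels <- function(img) {
  v <- if (inherits(img, "rgb_image")) img$values else img
  if (!is.array(v) || length(dim(v)) != 3L || dim(v)[3] < 3L)
    stop("input must have at least 3 channels")
  rgb_image(clip01(v[, , 1:3, drop = FALSE]))
}

# ---- generator (UNet) ------------------------------------------------------

unet_arch <- function(c_in, c_out, depth, filters, size) {
  list(c_in = c_in, c_out = c_out, depth = depth, size = size,
       c_enc = filters * 2L^(seq_len(depth) - 1L))
}

unet_init <- function(arch) {
  p <- list()
  cprev <- arch$c_in
  for (i in seq_len(arch$depth)) {
    ci <- arch$c_enc[i]
    p[[sprintf("enc%d_W", i)]] <- init_param(c(16L * cprev, ci), "weight")
    p[[sprintf("enc%d_b", i)]] <- init_param(ci, "bias")
    if (i > 1L) {
      p[[sprintf("enc%d_g", i)]] <- init_param(ci, "gamma")
      p[[sprintf("enc%d_bt", i)]] <- init_param(ci, "beta")
    }
    cprev <- ci
  }
  for (j in arch$depth:1L) {
    cin <- if (j == arch$depth) arch$c_enc[j] else 2L * arch$c_enc[j]
    cout <- if (j > 1L) arch$c_enc[j - 1L] else arch$c_out
    p[[sprintf("dec%d_W", j)]] <- init_param(c(16L * cout, cin), "weight")
    p[[sprintf("dec%d_b", j)]] <- init_param(cout, "bias")
    if (j > 1L) {
      p[[sprintf("dec%d_g", j)]] <- init_param(cout, "gamma")
      p[[sprintf("dec%d_bt", j)]] <- init_param(cout, "beta")
    }
  }
  p
}

unet_fwd <- function(p, x, arch) {
  d <- arch$depth
  enc_out <- vector("list", d)
  cache <- list(enc = vector("list", d), dec = vector("list", d))
  h <- x
  for (i in seq_len(d)) {
    sz <- arch$size %/% 2L^(i - 1L)
    s <- conv_struct(sz, sz, dim(h)[3], 4L, 2L, 1L)
    cf <- conv_fwd(h, p[[sprintf("enc%d_W", i)]], p[[sprintf("enc%d_b", i)]], s)
    if (i > 1L) {
      nf <- inorm_fwd(cf$y, p[[sprintf("enc%d_g", i)]],
                      p[[sprintf("enc%d_bt", i)]])
      act_in <- nf$y; norm_cache <- nf$cache
    } else {
      act_in <- cf$y; norm_cache <- NULL
    }
    h <- lrelu_fwd(act_in)$y
    enc_out[[i]] <- h
    cache$enc[[i]] <- list(s = s, cols = cf$cols, norm = norm_cache,
                           act_in = act_in)
  }
  for (j in d:1L) {
    if (j < d) {
      skip <- enc_out[[j]]
      h <- array(c(h, skip), c(dim(h)[1], dim(h)[2],
                               dim(h)[3] + dim(skip)[3]))
    }
    cout <- if (j > 1L) arch$c_enc[j - 1L] else arch$c_out
    out_sz <- arch$size %/% 2L^(j - 1L)
    sT <- conv_struct(out_sz, out_sz, cout, 4L, 2L, 1L)
    tf <- convT_fwd(h, p[[sprintf("dec%d_W", j)]], p[[sprintf("dec%d_b", j)]],
                    sT)
    if (j > 1L) {
      nf <- inorm_fwd(tf$y, p[[sprintf("dec%d_g", j)]],
                      p[[sprintf("dec%d_bt", j)]])
      h <- relu_fwd(nf$y)$y
      cache$dec[[j]] <- list(sT = sT, xmat = tf$xmat, norm = nf$cache,
                             act_in = nf$y)
    } else {
      h <- sigmoid_fwd(tf$y)$y
      cache$dec[[j]] <- list(sT = sT, xmat = tf$xmat, y = h)
    }
  }
  list(y = h, cache = cache)
}

unet_bwd <- function(p, cache, dy, arch) {
  d <- arch$depth
  g <- list()
  d_enc <- vector("list", d)
  dh <- dy
  for (j in seq_len(d)) {
    cc <- cache$dec[[j]]
    if (j == 1L) {
      dpre <- sigmoid_bwd(dh, cc$y)
    } else {
      dr <- relu_bwd(dh, cc$act_in)
      nb <- inorm_bwd(dr, p[[sprintf("dec%d_g", j)]], cc$norm)
      g[[sprintf("dec%d_g", j)]] <- nb$dgamma
      g[[sprintf("dec%d_bt", j)]] <- nb$dbeta
      dpre <- nb$dx
    }
    tb <- convT_bwd(dpre, p[[sprintf("dec%d_W", j)]], cc$sT, cc$xmat)
    g[[sprintf("dec%d_W", j)]] <- tb$dW
    g[[sprintf("dec%d_b", j)]] <- tb$db
    if (j == d) {
      d_enc[[d]] <- if (is.null(d_enc[[d]])) tb$dx else d_enc[[d]] + tb$dx
    } else {
      cj <- arch$c_enc[j]
      dh <- tb$dx[, , seq_len(cj), drop = FALSE]
      part <- tb$dx[, , cj + seq_len(cj), drop = FALSE]
      d_enc[[j]] <- if (is.null(d_enc[[j]])) part else d_enc[[j]] + part
    }
  }
  dh <- d_enc[[d]]
  for (i in d:1L) {
    cc <- cache$enc[[i]]
    dl <- lrelu_bwd(dh, cc$act_in)
    if (i > 1L) {
      nb <- inorm_bwd(dl, p[[sprintf("enc%d_g", i)]], cc$norm)
      g[[sprintf("enc%d_g", i)]] <- nb$dgamma
      g[[sprintf("enc%d_bt", i)]] <- nb$dbeta
      dpre <- nb$dx
    } else dpre <- dl
    cb <- conv_bwd(dpre, p[[sprintf("enc%d_W", i)]], cc$s, cc$cols)
    g[[sprintf("enc%d_W", i)]] <- cb$dW
    g[[sprintf("enc%d_b", i)]] <- cb$db
    dh <- cb$dx
    if (i > 1L && !is.null(d_enc[[i - 1L]])) dh <- dh + d_enc[[i - 1L]]
  }
  list(grads = g, dx = dh)
}

# ---- discriminator (PatchGAN) ----------------------------------------------
# conv s2 + lrelu | conv s2 + instance norm + lrelu | conv s1 (patch logits)

disc_arch <- function(c_in, filters, size) {
  list(c_in = c_in, f = filters, size = size)
}

disc_init <- function(arch) {
  list(l1_W = init_param(c(16L * arch$c_in, arch$f), "weight"),
       l1_b = init_param(arch$f, "bias"),
       l2_W = init_param(c(16L * arch$f, 2L * arch$f), "weight"),
       l2_b = init_param(2L * arch$f, "bias"),
       l2_g = init_param(2L * arch$f, "gamma"),
       l2_bt = init_param(2L * arch$f, "beta"),
       l3_W = init_param(c(16L * 2L * arch$f, 1L), "weight"),
       l3_b = init_param(1L, "bias"))
}

disc_fwd <- function(p, x, arch) {
  s1 <- conv_struct(arch$size, arch$size, dim(x)[3], 4L, 2L, 1L)
  c1 <- conv_fwd(x, p$l1_W, p$l1_b, s1)
  h1 <- lrelu_fwd(c1$y)$y
  s2 <- conv_struct(s1$ho, s1$wo, arch$f, 4L, 2L, 1L)
  c2 <- conv_fwd(h1, p$l2_W, p$l2_b, s2)
  n2 <- inorm_fwd(c2$y, p$l2_g, p$l2_bt)
  h2 <- lrelu_fwd(n2$y)$y
  s3 <- conv_struct(s2$ho, s2$wo, 2L * arch$f, 4L, 1L, 1L)
  c3 <- conv_fwd(h2, p$l3_W, p$l3_b, s3)
  list(y = c3$y,
       cache = list(s1 = s1, s2 = s2, s3 = s3, cols1 = c1$cols,
                    cols2 = c2$cols, cols3 = c3$cols, a1 = c1$y,
                    n2 = n2$cache, a2 = n2$y))
}

disc_bwd <- function(p, cache, dy, arch) {
  g <- list()
  b3 <- conv_bwd(dy, p$l3_W, cache$s3, cache$cols3)
  g$l3_W <- b3$dW; g$l3_b <- b3$db
  dl2 <- lrelu_bwd(b3$dx, cache$a2)
  n2 <- inorm_bwd(dl2, p$l2_g, cache$n2)
  g$l2_g <- n2$dgamma; g$l2_bt <- n2$dbeta
  b2 <- conv_bwd(n2$dx, p$l2_W, cache$s2, cache$cols2)
  g$l2_W <- b2$dW; g$l2_b <- b2$db
  dl1 <- lrelu_bwd(b2$dx, cache$a1)
  b1 <- conv_bwd(dl1, p$l1_W, cache$s1, cache$cols1)
  g$l1_W <- b1$dW; g$l1_b <- b1$db
  list(grads = g, dx = b1$dx)
}

# ---- model bundle ----------------------------------------------------------

#' Build the MC-GAN generators and discriminators
#'
#' Creates the two N-to-N-channel UNet generators (`A -> B` and `B -> A`)
#' and the two PatchGAN discriminators with all parameters drawn from the
#' seeded initializer (normal, sd 0.02). Identical seeds give identical
#' initial parameters.
#'
#' @param cfg an [mcgan_config].
#' @return a `model_bundle`: generator/discriminator parameter sets, layer
#'   architecture descriptions, the config, and an (initially empty)
#'   training history.
#' @export
build_models <- function(cfg) {
  stopifnot(inherits(cfg, "mcgan_config"))
  if (cfg$patch_size %/% 2L^cfg$downsampling_depth < 1L)
    stop("patch_size incompatible with downsampling depth")
  g_arch <- unet_arch(cfg$n_channels, cfg$n_channels,
                      cfg$downsampling_depth, cfg$filters, cfg$patch_size)
  d_arch <- disc_arch(cfg$n_channels, cfg$disc_filters, cfg$patch_size)
  params <- with_seed(cfg$seed, list(
    gAB = unet_init(g_arch), gBA = unet_init(g_arch),
    dA = disc_init(d_arch), dB = disc_init(d_arch)))
  structure(list(params = params, g_arch = g_arch, d_arch = d_arch,
                 cfg = cfg, history = NULL),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> N = %d, patch = %d, depth = %d, %s\n",
              x$cfg$n_channels, x$cfg$patch_size, x$cfg$downsampling_depth,
              if (is.null(x$history)) "untrained"
              else sprintf("trained %d epoch(s)", nrow(x$history))))
  invisible(x)
}

#' Apply a trained generator to one image array
#'
#' @param bundle a [model_bundle].
#' @param x `H x W x N` array with spatial size equal to the training patch
#'   size.
#' @param direction `"AB"` (PARS to H&E, default) or `"BA"`.
#' @return `H x W x N` array in `[0, 1]`.
#' @export
generate <- function(bundle, x, direction = c("AB", "BA")) {
  direction <- match.arg(direction)
  p <- if (direction == "AB") bundle$params$gAB else bundle$params$gBA
  unet_fwd(p, x, bundle$g_arch)$y
}

# replay buffer draw: push the new image; return it directly while filling,
# otherwise return either it or a random stored image (swapped out)
buffer_draw <- function(buf, img, capacity) {
  if (length(buf) < capacity) {
    buf[[length(buf) + 1L]] <- img
    return(list(buf = buf, img = img))
  }
  if (stats::runif(1) < 0.5) return(list(buf = buf, img = img))
  i <- sample.int(length(buf), 1L)
  out <- buf[[i]]
  buf[[i]] <- img
  list(buf = buf, img = out)
}

# one optimization step on a registered (a, b) patch pair
mcgan_step <- function(a, b, P, st, buf, cfg, g_arch, d_arch, lr) {
  fAB <- unet_fwd(P$gAB, a, g_arch); fake_b <- fAB$y
  rAB <- unet_fwd(P$gBA, fake_b, g_arch); rec_a <- rAB$y
  fBA <- unet_fwd(P$gBA, b, g_arch); fake_a <- fBA$y
  rBA <- unet_fwd(P$gAB, fake_a, g_arch); rec_b <- rBA$y
  dB_fake <- disc_fwd(P$dB, fake_b, d_arch)
  dA_fake <- disc_fwd(P$dA, fake_a, d_arch)
  nd <- length(dB_fake$y); np <- length(a)

  l_adv <- mean((dB_fake$y - 1)^2) + mean((dA_fake$y - 1)^2)
  l_cyc <- cfg$cycle_weight * (mean(abs(rec_a - a)) + mean(abs(rec_b - b)))
  use_idt <- cfg$identity_weight > 0
  if (use_idt) {
    idB <- unet_fwd(P$gAB, b, g_arch)
    idA <- unet_fwd(P$gBA, a, g_arch)
    l_idt <- cfg$identity_weight *
      (mean(abs(idB$y - b)) + mean(abs(idA$y - a)))
  } else l_idt <- 0
  l_pair <- cfg$paired_weight *
    (mean(abs(fake_b - b)) + mean(abs(fake_a - a)))
  loss_g <- l_adv + l_cyc + l_idt + l_pair

  # generator gradients; collect every path into fake_b / fake_a first
  gG <- list(); gF <- list()
  bb <- unet_bwd(P$gBA, rAB$cache,
                 cfg$cycle_weight * sign(rec_a - a) / np, g_arch)
  gF <- grad_add(gF, bb$grads)
  d_fake_b <- bb$dx +
    disc_bwd(P$dB, dB_fake$cache, 2 * (dB_fake$y - 1) / nd, d_arch)$dx
  if (cfg$paired_weight > 0)
    d_fake_b <- d_fake_b + cfg$paired_weight * sign(fake_b - b) / np
  bb <- unet_bwd(P$gAB, fAB$cache, d_fake_b, g_arch)
  gG <- grad_add(gG, bb$grads)

  bb <- unet_bwd(P$gAB, rBA$cache,
                 cfg$cycle_weight * sign(rec_b - b) / np, g_arch)
  gG <- grad_add(gG, bb$grads)
  d_fake_a <- bb$dx +
    disc_bwd(P$dA, dA_fake$cache, 2 * (dA_fake$y - 1) / nd, d_arch)$dx
  if (cfg$paired_weight > 0)
    d_fake_a <- d_fake_a + cfg$paired_weight * sign(fake_a - a) / np
  bb <- unet_bwd(P$gBA, fBA$cache, d_fake_a, g_arch)
  gF <- grad_add(gF, bb$grads)

  if (use_idt) {
    bb <- unet_bwd(P$gAB, idB$cache,
                   cfg$identity_weight * sign(idB$y - b) / np, g_arch)
    gG <- grad_add(gG, bb$grads)
    bb <- unet_bwd(P$gBA, idA$cache,
                   cfg$identity_weight * sign(idA$y - a) / np, g_arch)
    gF <- grad_add(gF, bb$grads)
  }

  up <- adam_step(P$gAB, gG, st$gAB, lr, cfg$adam_beta1, cfg$adam_beta2)
  P$gAB <- up$params; st$gAB <- up$state
  up <- adam_step(P$gBA, gF, st$gBA, lr, cfg$adam_beta1, cfg$adam_beta2)
  P$gBA <- up$params; st$gBA <- up$state

  # discriminators, fakes drawn through the replay buffer
  db <- buffer_draw(buf$B, fake_b, cfg$buffer_size); buf$B <- db$buf
  da <- buffer_draw(buf$A, fake_a, cfg$buffer_size); buf$A <- da$buf
  loss_d <- 0
  for (side in c("A", "B")) {
    pd <- if (side == "A") P$dA else P$dB
    real <- if (side == "A") a else b
    fake <- if (side == "A") da$img else db$img
    fr <- disc_fwd(pd, real, d_arch)
    ff <- disc_fwd(pd, fake, d_arch)
    nr <- length(fr$y)
    loss_d <- loss_d + 0.5 * (mean((fr$y - 1)^2) + mean(ff$y^2))
    gD <- grad_add(disc_bwd(pd, fr$cache, (fr$y - 1) / nr, d_arch)$grads,
                   disc_bwd(pd, ff$cache, ff$y / nr, d_arch)$grads)
    stn <- if (side == "A") st$dA else st$dB
    up <- adam_step(pd, gD, stn, lr, cfg$adam_beta1, cfg$adam_beta2)
    if (side == "A") { P$dA <- up$params; st$dA <- up$state }
    else { P$dB <- up$params; st$dB <- up$state }
  }

  list(P = P, st = st, buf = buf,
       losses = c(g = loss_g, adv = l_adv, cyc = l_cyc, idt = l_idt,
                  pair = l_pair, d = loss_d))
}

#' Train the multi-channel cycleGAN on registered patch pairs
#'
#' Optimizes the adversarial + cycle-consistency (+ identity, + paired L1)
#' objective with Adam at the configured learning-rate schedule. Training
#' stops at `max_epochs`, or earlier when the 5-epoch moving average of the
#' total generator loss fails to improve by at least 0.1% (relative) for
#' `early_stop_patience` consecutive epochs.
#'
#' @param pairs list of [registered_pair] patches; every stack must have
#'   `cfg$n_channels` channels of size `cfg$patch_size`.
#' @param cfg an [mcgan_config].
#' @param bundle optionally, a [model_bundle] to continue training.
#' @param verbose print per-epoch losses.
#' @return a trained [model_bundle]; `$history` holds per-epoch mean losses
#'   (generator total, adversarial, cycle, identity, paired, discriminator)
#'   and the effective learning rate.
#' @export
mcgan_train <- function(pairs, cfg, bundle = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "mcgan_config"))
  if (!length(pairs)) stop("no training pairs")
  for (pr in pairs) {
    if (length(pr$stack$channels) != cfg$n_channels)
      stop("channel-count mismatch between config and data")
    if (pr$stack$height != cfg$patch_size || pr$stack$width != cfg$patch_size)
      stop("patch size mismatch between config and data")
  }
  if (is.null(bundle)) bundle <- build_models(cfg)
  P <- bundle$params
  st <- list(gAB = adam_init(P$gAB), gBA = adam_init(P$gBA),
             dA = adam_init(P$dA), dB = adam_init(P$dB))
  buf <- list(A = list(), B = list())
  a_list <- lapply(pairs, function(pr) stack_to_array(pr$stack))
  b_list <- lapply(pairs, function(pr)
    expand_target_channels(pr$truth, cfg$n_channels))

  hist <- NULL
  ma <- numeric(0); best_ma <- Inf; stale <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- lr_at_epoch(epoch, cfg)
    acc <- NULL
    with_seed(cfg$seed + 7919L * epoch, {
      ord <- sample.int(length(pairs))
      for (i in ord) {
        stp <- mcgan_step(a_list[[i]], b_list[[i]], P, st, buf, cfg,
                          bundle$g_arch, bundle$d_arch, lr)
        P <- stp$P; st <- stp$st; buf <- stp$buf
        if (!all(is.finite(stp$losses)))
          stop("non-finite loss at epoch ", epoch)
        acc <- rbind(acc, stp$losses)
      }
    })
    m <- colMeans(acc)
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   loss_g = m["g"], loss_adv = m["adv"],
                                   loss_cyc = m["cyc"], loss_idt = m["idt"],
                                   loss_pair = m["pair"], loss_d = m["d"]))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  G %.4f  D %.4f", epoch, lr,
                      m["g"], m["d"]))
    ma <- c(ma, mean(utils::tail(hist$loss_g, 5)))
    cur <- utils::tail(ma, 1)
    if (cur < best_ma * (1 - 1e-3)) { best_ma <- cur; stale <- 0L }
    else stale <- stale + 1L
    if (stale >= cfg$early_stop_patience) break
  }
  rownames(hist) <- NULL
  bundle$params <- P
  bundle$history <- hist
  bundle
}

# ---- patch grid, blending and whole-image inference ------------------------

patch_grid_starts <- function(len, patch_size, stride) {
  if (patch_size > len) stop("patch larger than image")
  unique(c(seq.int(1L, len - patch_size + 1L, by = stride),
           len - patch_size + 1L))
}

patch_grid_count <- function(len, patch_size, stride) {
  length(patch_grid_starts(len, patch_size, stride))
}

#' Overlapping patch grid covering an image
#'
#' Top-left patch coordinates at the given stride; the final row/column of
#' patches is clamped to the image border so the grid always covers the full
#' image. `overlap = 1 - stride / patch_size`.
#'
#' @param height,width image dimensions.
#' @param patch_size square patch side.
#' @param stride step between patch origins, `1 <= stride <= patch_size`.
#' @return a `patch_grid` object: `coords` (data frame `row`, `col`,
#'   1-based), `patch_size`, `stride`.
#' @export
patch_grid <- function(height, width, patch_size, stride) {
  stride <- as.integer(stride)
  if (stride < 1L || stride > patch_size)
    stop("`stride` must lie in [1, patch_size]")
  rows <- patch_grid_starts(height, patch_size, stride)
  cols <- patch_grid_starts(width, patch_size, stride)
  structure(list(coords = expand.grid(row = rows, col = cols,
                                      KEEP.OUT.ATTRS = FALSE),
                 patch_size = as.integer(patch_size), stride = stride),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d patch(es) of %d px, stride %d\n",
              nrow(x$coords), x$patch_size, x$stride))
  invisible(x)
}

# separable tent (triangular) blending weights peaking at the patch center
patch_tent <- function(patch_size) {
  w1 <- pmin(seq_len(patch_size), patch_size + 1L - seq_len(patch_size))
  outer(w1, w1)
}

#' Total blending weight accumulated at each pixel of an image
#'
#' @param grid a [patch_grid].
#' @param height,width image dimensions the grid covers.
#' @return matrix of summed (unnormalized) tent weights; strictly positive
#'   whenever the grid covers the image. Dividing each patch's contribution
#'   by this map makes the per-pixel blending weights sum to exactly 1.
#' @export
blend_weight_map <- function(grid, height, width) {
  wt <- patch_tent(grid$patch_size)
  den <- matrix(0, height, width)
  for (g in seq_len(nrow(grid$coords))) {
    ys <- grid$coords$row[g] + seq_len(grid$patch_size) - 1L
    xs <- grid$coords$col[g] + seq_len(grid$patch_size) - 1L
    den[ys, xs] <- den[ys, xs] + wt
  }
  den
}

#' Colorize a whole channel stack by blended patch inference
#'
#' Runs the `A -> B` generator over an overlapping patch grid, discards the
#' surplus generated channels, and blends patches into the full image with
#' tent-shaped per-pixel weights (continuous at seams; weights sum to 1 at
#' every pixel). ~50% overlap is usually enough to avoid border artifacts.
#'
#' @param bundle a trained [model_bundle] (ignored when `generator` given).
#' @param stack a [channel_stack] with `N = cfg$n_channels` channels.
#' @param overlap fractional patch overlap used to derive the stride
#'   (default 0.5).
#' @param grid optional explicit [patch_grid].
#' @param generator optional replacement function `H x W x N array -> H x W
#'   x (>=3) array` (e.g. a stub in tests).
#' @return an [rgb_image].
#' @export
colorize <- function(bundle, stack, overlap = 0.5, grid = NULL,
                     generator = NULL) {
  if (is.null(generator)) {
    stopifnot(inherits(bundle, "model_bundle"))
    if (length(stack$channels) != bundle$cfg$n_channels)
      stop("stack channel count does not match the model")
    ps <- bundle$cfg$patch_size
    generator <- function(x) generate(bundle, x, "AB")
  } else {
    ps <- if (!is.null(grid)) grid$patch_size
          else if (!is.null(bundle)) bundle$cfg$patch_size
          else stop("need a grid or bundle to set the patch size")
  }
  if (is.null(grid)) {
    stride <- max(1L, as.integer(round(ps * (1 - overlap))))
    grid <- patch_grid(stack$height, stack$width, ps, stride)
  }
  if (grid$patch_size != ps)
    stop("grid patch size does not match the model")
  arr <- stack_to_array(stack)
  wt <- patch_tent(grid$patch_size)
  num <- array(0, c(stack$height, stack$width, 3L))
  den <- matrix(0, stack$height, stack$width)
  for (g in seq_len(nrow(grid$coords))) {
    ys <- grid$coords$row[g] + seq_len(grid$patch_size) - 1L
    xs <- grid$coords$col[g] + seq_len(grid$patch_size) - 1L
    out <- generator(arr[ys, xs, , drop = FALSE])
    rgb <- discard_surplus_channels(out)$values
    for (ch in 1:3) num[ys, xs, ch] <- num[ys, xs, ch] + rgb[, , ch] * wt
    den[ys, xs] <- den[ys, xs] + wt
  }
  for (ch in 1:3) num[, , ch] <- num[, , ch] / den
  rgb_image(clip01(num))
}
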