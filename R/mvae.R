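# Morphology VAE: compresses 5-channel images to a spatial Gaussian latent
# and reconstructs them. Trained with pixel L1 reconstruction, a weak KL
# regularizer towards N(0, I), a 5-channel perceptual (LPIPS-style) loss,
# and a patch discriminator with logistic (softplus cross-entropy)
# adversarial losses. Convolutions are realized as non-overlapping strided
# patch linear maps (kernel = stride), which keeps the downsampling-factor
# arithmetic exact and CPU training fast.

#' MVAE configuration
#'
#' @param H image side length (square images).
#' @param patch encoder/decoder downsampling factor (power of 2; the
#'   latent is spatial `H/patch x H/patch`).
#' @param hidden width of the per-token hidden layers.
#' @param latent_channels latent channels per spatial position.
#' @param lambda_rec,lambda_kl,lambda_lpips,lambda_adv,lambda_grad,lambda_cov
#'   loss weights; `lambda_grad` scales an L1 penalty on horizontal and
#'   vertical image gradients (protects fine texture against the blur an
#'   L1 pixel loss tolerates); `lambda_cov` scales a Gram-style loss
#'   matching the per-image 5x5 channel covariance of the reconstruction
#'   to the target's, which preserves cross-channel correlation
#'   structure. Covariance entries are O(1e-2), hence the large default
#'   weight.
#' @param adv_warmup steps before the adversarial terms switch on.
#' @param disc_patch patch size of the discriminator tokens (its logits
#'   map is `H/disc_patch` squared, always larger than 1 x 1).
#' @param refine_hidden width of the overlapping 3x3 refinement
#'   convolution appended to the patch decoder.
#' @param lr Adam learning rate.
#' @return a list of class `mvae_config`.
#' @export
mvae_config <- function(H = 32, patch = 4, hidden = 128, latent_channels = 32,
                        lambda_rec = 1, lambda_kl = 1e-6, lambda_lpips = 1,
                        lambda_adv = 0.5, lambda_grad = 1, lambda_cov = 0,
                        adv_warmup = 500,
                        disc_patch = 8, refine_hidden = 32, lr = 3e-3,
                        lr_decay = FALSE) {
  pd_assert(H %% patch == 0, "patch must divide H")
  pd_assert(bitwAnd(patch, patch - 1L) == 0L, "downsampling factor must be a power of 2")
  pd_assert(all(c(lambda_rec, lambda_kl, lambda_lpips, lambda_adv) >= 0),
            "loss weights must be non-negative")
  pd_assert(H %/% disc_patch > 1L, "discriminator logits map must be larger than 1x1")
  structure(list(H = H, patch = patch, hidden = hidden,
                 latent_channels = latent_channels,
                 lambda_rec = lambda_rec, lambda_kl = lambda_kl,
                 lambda_lpips = lambda_lpips, lambda_adv = lambda_adv,
                 lambda_grad = lambda_grad, lambda_cov = lambda_cov,
                 adv_warmup = adv_warmup,
                 disc_patch = disc_patch, refine_hidden = refine_hidden, lr = lr,
                 lr_decay = lr_decay),
            class = "mvae_config")
}

#' Initialize an untrained MVAE
#'
#' @param config an [mvae_config].
#' @param seed integer seed for weight initialization.
#' @return object of class `mvae` holding encoder, decoder, discriminator
#'   and the built-in perceptual extractor.
#' @export
mvae_init <- function(config = mvae_config(), seed = 1) {
  p <- config$patch; din <- 5L * p * p
  dp <- config$disc_patch
  with_seed(derive_seed(seed, "mvae_init"), {
    enc <- list(l1 = nn_linear(din, config$hidden),
                l2 = nn_linear(config$hidden, config$hidden),
                l3 = nn_linear(config$hidden, 2L * config$latent_channels, gain = 0.1))
    # l1..l3: per-token (strided-conv) stack producing a draft image;
    # l4: overlapping 3x3 refinement convolution that removes patch-
    # boundary artifacts (learned residual on the draft)
    dec <- list(l1 = nn_linear(config$latent_channels, config$hidden),
                l2 = nn_linear(config$hidden, config$hidden),
                l3 = nn_linear(config$hidden, din),
                l4a = nn_linear(45L, config$refine_hidden),
                l4b = nn_linear(config$refine_hidden, 5L, gain = 0.1))
    disc <- list(l1 = nn_linear(5L * dp * dp, config$hidden),
                 l2 = nn_linear(config$hidden, config$hidden),
                 l3 = nn_linear(config$hidden, 1L))
    structure(list(config = config, enc = enc, dec = dec, disc = disc,
                   extractor = perceptual_extractor(config$H, seed = derive_seed(seed, "lpips")),
                   seed = seed),
              class = "mvae")
  })
}

enc_forward <- function(model, x_tokens) {
  h <- ag_silu(nn_apply_linear(model$enc$l1, x_tokens))
  h <- ag_silu(nn_apply_linear(model$enc$l2, h))
  out <- nn_apply_linear(model$enc$l3, h)
  cz <- model$config$latent_channels
  n <- nrow(out$value)
  lin_mean <- matrix(seq_len(n), n, cz) + (matrix(seq_len(cz), n, cz, byrow = TRUE) - 1L) * n
  lin_lv <- lin_mean + cz * n
  list(mean = ag_gather_cells(out, lin_mean), logvar = ag_gather_cells(out, lin_lv))
}

# Decoder output is in pixel layout: (B*H^2) x 5, rows = pixels
# (column-major within each image, batch-blocked), columns = channels.
dec_forward <- function(model, z_tokens, n_batch) {
  maps <- mvae_maps(model$config, n_batch)
  h <- ag_silu(nn_apply_linear(model$dec$l1, z_tokens))
  h <- ag_silu(nn_apply_linear(model$dec$l2, h))
  draft <- nn_apply_linear(model$dec$l3, h)
  px <- ag_gather_cells(draft, maps$pix)
  # overlapping 3x3 refinement convolution (two per-pixel linear layers
  # on the gathered neighbourhood); the residual keeps the draft as the
  # backbone
  h1 <- ag_silu(nn_apply_linear(model$dec$l4a,
                                ag_gather_cells(px, maps$nbr, maps$nbr_plan)))
  ref <- nn_apply_linear(model$dec$l4b, h1)
  ag_sigmoid(ag_add(px, ref))
}

# images -> pixel-layout matrix matching dec_forward output.
images_to_pixmat <- function(images) {
  do.call(rbind, lapply(images, function(im) {
    vapply(1:5, function(c) as.vector(im$channels[, , c]), numeric(length(im$channels[, , 1])))
  }))
}

pixmat_to_array <- function(M, H, n_batch) {
  arr <- array(0, c(n_batch, H, H, 5L))
  for (b in seq_len(n_batch)) {
    rows <- ((b - 1L) * H * H + 1L):(b * H * H)
    for (c in 1:5) arr[b, , , c] <- matrix(M[rows, c], H, H)
  }
  arr
}

# Index-map bundle for one (config, batch size): draft->pixel gather,
# 3x3 neighbourhood gather, per-channel LPIPS layer-1 maps, token-merge
# maps, and the discriminator patch map. Cached per (H, patch, B).
.mvae_map_cache <- new.env(parent = emptyenv())
mvae_maps <- function(cfg, B) {
  key <- sprintf("H%d_p%d_dp%d_rh%d_B%d", cfg$H, cfg$patch, cfg$disc_patch,
                 cfg$refine_hidden, B)
  if (!is.null(.mvae_map_cache[[key]])) return(.mvae_map_cache[[key]])
  H <- cfg$H; p <- cfg$patch; dp <- cfg$disc_patch
  hp <- H %/% p; Tn <- hp * hp; pp <- p * p
  HH <- H * H; NB <- B * HH
  ii <- rep(seq_len(H), H); jj <- rep(seq_len(H), each = H)  # column-major pixels
  pr <- ((ii - 1L) %/% p) + 1L; pc <- ((jj - 1L) %/% p) + 1L
  tok <- (pc - 1L) * hp + pr
  off <- (jj - (pc - 1L) * p - 1L) * p + (ii - (pr - 1L) * p)
  # draft matrix has B*Tn rows
  pix_one <- vapply(1:5, function(c) {
    as.integer(((c - 1L) * pp + off - 1L) * (B * Tn) + tok)
  }, integer(HH))
  pix <- do.call(rbind, lapply(seq_len(B) - 1L, function(b) pix_one + b * Tn))
  # 3x3 neighbourhoods (replicate padding) into a pixel-layout matrix
  # with n_ch channel columns
  nbr_for <- function(n_ch) {
    one <- matrix(0L, HH, 9L * n_ch)
    col <- 0L
    for (c in seq_len(n_ch)) for (dj in -1:1) for (di in -1:1) {
      col <- col + 1L
      ni <- pmin(pmax(ii + di, 1L), H); nj <- pmin(pmax(jj + dj, 1L), H)
      one[, col] <- (c - 1L) * NB + (nj - 1L) * H + ni
    }
    do.call(rbind, lapply(seq_len(B) - 1L, function(b) one + b * HH))
  }
  nbr <- nbr_for(5L)
  nbr_hidden <- nbr_for(cfg$refine_hidden)
  # LPIPS layer-1 maps: for channel c, token s of the (H/2)^2 grid
  l1_idx <- patch_index(H, 2L, 1L)
  g1 <- H %/% 2L
  lpips_channel <- lapply(1:5, function(c) {
    one <- cbind(l1_idx, l1_idx, l1_idx) + (c - 1L) * NB
    do.call(rbind, lapply(seq_len(B) - 1L, function(b) one + b * HH))
  })
  # channel-stacked map: rows = 5 * B * (H/2)^2, channels as extra batch
  lpips_all <- do.call(rbind, lpips_channel)
  merges <- list(); g <- g1
  while (g >= 2L) {
    merges[[length(merges) + 1L]] <- merge_index(g, 5L * B)
    g <- g %/% 2L
  }
  # discriminator patches from the pixel matrix
  didx <- patch_index(H, dp, 1L)
  dpp <- dp * dp
  disc_one <- do.call(cbind, lapply(1:5, function(c) didx + (c - 1L) * NB))
  disc <- do.call(rbind, lapply(seq_len(B) - 1L, function(b) disc_one + b * HH))
  # row-index pairs for image-gradient losses on the pixel matrix
  v_m <- which(ii < H); v_p <- v_m + 1L            # vertical neighbours
  h_m <- which(jj < H); h_p <- h_m + H             # horizontal neighbours
  expand <- function(v) as.integer(outer(v, (seq_len(B) - 1L) * HH, "+"))
  .mvae_map_cache[[key]] <- list(pix = pix, nbr = nbr, nbr_hidden = nbr_hidden,
                                 nbr_plan = make_scatter_plan(as.vector(nbr)),
                                 lpips_all = lpips_all,
                                 lpips_plan = make_scatter_plan(as.vector(lpips_all)),
                                 lpips_merge = merges, disc = disc,
                                 gv_m = expand(v_m), gv_p = expand(v_p),
                                 gh_m = expand(h_m), gh_p = expand(h_p))
  .mvae_map_cache[[key]]
}

disc_forward <- function(model, images_tokens) {
  h <- ag_silu(nn_apply_linear(model$disc$l1, images_tokens))
  h <- ag_silu(nn_apply_linear(model$disc$l2, h))
  nn_apply_linear(model$disc$l3, h)
}

# latent tokens <-> latent arrays (c_z, h_z, w_z); tokens are column-major
# over the h_z x w_z grid.
latent_tokens_to_array <- function(M, cz, hz) {
  arr <- array(0, c(cz, hz, hz))
  for (c in seq_len(cz)) arr[c, , ] <- matrix(M[, c], hz, hz)
  arr
}

latent_array_to_tokens <- function(arr) {
  cz <- dim(arr)[1L]; hz <- dim(arr)[2L]
  M <- matrix(0, hz * hz, cz)
  for (c in seq_len(cz)) M[, c] <- as.vector(arr[c, , ])
  M
}

#' Encode an image to a latent code
#'
#' The posterior mean and log-variance are deterministic functions of the
#' image; the sample `z = mean + exp(logvar/2) * eps` uses the provided
#' seed. The latent spatial size is `H / patch`.
#'
#' @param model a trained or untrained [mvae_init] model.
#' @param image a [morph_image] matching the configured size.
#' @param seed seed for the reparameterization draw.
#' @return object of class `latent_code` with `mean`, `logvar`, `z`
#'   (arrays `c_z x h_z x w_z`) and `shape`.
#' @export
encode <- function(model, image, seed = 1) {
  pd_assert(inherits(model, "mvae"), "model must be an mvae")
  pd_assert(inherits(image, "morph_image"), "image must be a morph_image")
  pd_assert(image_size(image) == model$config$H,
            sprintf("image size %d does not match configured H = %d",
                    image_size(image), model$config$H))
  X <- images_to_patches(list(image), model$config$patch)
  ag_tape_reset()
  out <- enc_forward(model, ag_const(X))
  cz <- model$config$latent_channels
  hz <- model$config$H %/% model$config$patch
  mean_arr <- latent_tokens_to_array(out$mean$value, cz, hz)
  lv_arr <- latent_tokens_to_array(out$logvar$value, cz, hz)
  eps <- with_seed(derive_seed(seed, "reparam"),
                   array(stats::rnorm(length(mean_arr)), dim(mean_arr)))
  structure(list(mean = mean_arr, logvar = lv_arr,
                 z = mean_arr + exp(lv_arr / 2) * eps,
                 shape = c(cz, hz, hz)),
            class = "latent_code")
}

#' Decode a latent code to an image
#'
#' Deterministic; the output is squashed to `[0, 1]` by a sigmoid.
#'
#' @param model an [mvae_init] model.
#' @param code a `latent_code` (its `z` is decoded) or a plain latent
#'   array `c_z x h_z x w_z`.
#' @param perturbation_id,plate_id labels attached to the output image.
#' @param noise_seed when non-NULL and the model carries a fitted
#'   observation scale (`obs_sd`, estimated at the end of training),
#'   per-channel Gaussian observation noise is sampled with this seed --
#'   a draw from the decoder's Gaussian observation model rather than
#'   its mean. Reconstruction use leaves this NULL.
#' @return a [morph_image].
#' @export
decode <- function(model, code, perturbation_id = "generated", plate_id = "generated",
                   noise_seed = NULL) {
  pd_assert(inherits(model, "mvae"), "model must be an mvae")
  z <- if (inherits(code, "latent_code")) code$z else code
  cz <- model$config$latent_channels
  hz <- model$config$H %/% model$config$patch
  pd_assert(length(dim(z)) == 3L && all(dim(z) == c(cz, hz, hz)),
            "latent shape does not match model config")
  ag_tape_reset()
  out <- dec_forward(model, ag_const(latent_array_to_tokens(z)), 1L)
  arr <- pixmat_to_array(out$value, model$config$H, 1L)[1L, , , ]
  if (!is.null(noise_seed) && !is.null(model$obs_sd)) {
    arr <- with_seed(derive_seed(noise_seed, "obs_noise"), {
      H <- model$config$H
      arr + array(stats::rnorm(length(arr)), dim(arr)) *
        rep(model$obs_sd, each = H * H)
    })
    arr <- clip01(arr)
  }
  morph_image(arr, perturbation_id = perturbation_id, plate_id = plate_id)
}

#' Kullback-Leibler regularizer of a diagonal Gaussian against N(0, I)
#'
#' `0.5 * sum(exp(logvar) + mean^2 - 1 - logvar)`; non-negative.
#'
#' @param mean,logvar equal-shape numeric arrays.
#' @return scalar KL divergence.
#' @export
kl_reg <- function(mean, logvar) {
  pd_assert(identical(dim(mean), dim(logvar)) || length(mean) == length(logvar),
            "mean and logvar shapes differ")
  pd_assert(all(is.finite(mean)) && all(is.finite(logvar)), "non-finite inputs")
  0.5 * sum(exp(logvar) + mean^2 - 1 - logvar)
}

# ---------------------------------------------------------------------------
# Perceptual (LPIPS-style) loss on 5-channel images

#' Seed-fixed random strided-convolution perceptual extractor
#'
#' A 5-layer feature pyramid of non-overlapping 2x2 stride-2 random
#' convolutions with tanh activations, taking a 3-channel image (each
#' morphology channel is replicated to 3 planes before entry). Weights
#' are drawn once from a fixed seed, so the extractor is deterministic
#' and self-contained; any user extractor with the same interface
#' (`$forward(arr)` returning a list of `H_l x W_l x C_l` feature arrays,
#' `$weights` a list of per-channel scaling vectors) is accepted by
#' [lpips_5ch].
#'
#' @param H input image side length.
#' @param n_layers number of stride-2 layers (default 5).
#' @param n_channels feature channels per layer.
#' @param seed weight seed.
#' @return object of class `perceptual_extractor`.
#' @export
perceptual_extractor <- function(H = 32, n_layers = 5, n_channels = 16, seed = 77) {
  pd_assert(H %% 2L == 0L, "H must be even")
  mats <- list(); c_in <- 3L
  with_seed(derive_seed(seed, "perceptual"), {
    for (l in seq_len(n_layers)) {
      fan <- 4L * c_in
      mats[[l]] <- matrix(stats::rnorm(fan * n_channels, sd = 1 / sqrt(fan)), fan, n_channels)
      c_in <- n_channels
    }
  })
  weights <- lapply(seq_len(n_layers), function(l) rep(1, n_channels))
  ex <- list(id = "builtin-randconv", H = H, n_layers = n_layers,
             n_channels = n_channels, mats = mats, weights = weights)
  ex$forward <- function(arr) {
    g <- dim(arr)[1L]
    feats <- list()
    tok <- patchify_arr(arr, 2L)
    for (l in seq_len(ex$n_layers)) {
      tok <- tanh(tok %*% ex$mats[[l]])
      g <- g %/% 2L
      feats[[l]] <- tokens_to_arr(tok, g)
      if (l < ex$n_layers) {
        if (g < 2L) break
        tok <- regroup_tokens(tok, g)
      }
    }
    feats
  }
  class(ex) <- "perceptual_extractor"
  ex
}

# (H, W, C) array -> tokens ((H/p)^2) x (C*p*p), channel-major column
# blocks, tokens column-major over the patch grid.
patchify_arr <- function(arr, p) {
  H <- dim(arr)[1L]; C <- dim(arr)[3L]
  pidx <- patch_index(H, p, 1L)
  Tn <- nrow(pidx); pp <- p * p
  out <- matrix(0, Tn, C * pp)
  for (c in seq_len(C)) {
    v <- as.vector(arr[, , c])
    out[, ((c - 1L) * pp + 1L):(c * pp)] <- matrix(v[as.vector(pidx)], Tn, pp)
  }
  out
}

tokens_to_arr <- function(tok, g) {
  C <- ncol(tok)
  arr <- array(0, c(g, g, C))
  for (c in seq_len(C)) arr[, , c] <- matrix(tok[, c], g, g)
  arr
}

# group 2x2 neighbouring tokens of a g x g token grid into rows of 4*C
regroup_tokens <- function(tok, g) {
  idx <- merge_index(g, 1L)
  C <- ncol(tok)
  out <- matrix(0, nrow(idx), 4L * C)
  for (j in 1:4) out[, ((j - 1L) * C + 1L):(j * C)] <- tok[idx[, j], , drop = FALSE]
  out
}

#' Five-channel perceptual distance
#'
#' Each morphology channel is replicated to three identical planes, passed
#' through the perceptual extractor, and the per-layer spatially averaged,
#' weight-scaled squared feature differences are summed over layers; the
#' result is the unweighted mean over the five channels.
#'
#' @param x,x0 [morph_image]s of equal size.
#' @param extractor a [perceptual_extractor] (or any object with the same
#'   `$forward` / `$weights` interface).
#' @return non-negative scalar.
#' @export
lpips_5ch <- function(x, x0, extractor = NULL) {
  pd_assert(inherits(x, "morph_image") && inherits(x0, "morph_image"),
            "inputs must be morph_images")
  pd_assert(identical(dim(x$channels), dim(x0$channels)), "image shapes differ")
  if (is.null(extractor)) extractor <- perceptual_extractor(image_size(x))
  total <- 0
  for (c in pd_channels) {
    a <- x$channels[, , c]; b <- x0$channels[, , c]
    arr_a <- array(a, c(dim(a), 3L)); arr_b <- array(b, c(dim(b), 3L))
    fa <- extractor$forward(arr_a); fb <- extractor$forward(arr_b)
    d <- 0
    for (l in seq_along(fa)) {
      w <- extractor$weights[[l]]
      diff <- fa[[l]] - fb[[l]]
      Hl <- dim(diff)[1L]; Wl <- dim(diff)[2L]
      wd <- sweep(diff, 3L, w, "*")
      d <- d + sum(wd^2) / (Hl * Wl)
    }
    total <- total + d
  }
  total / 5
}

# In-graph LPIPS between the decoder pixel-layout output and a constant
# target pixel matrix, using the builtin extractor. The five channels are
# processed as one stacked batch (the extractor acts on each channel
# independently, so row-stacking is exact); the target branch carries no
# gradient and uses plain matrix ops. maps comes from mvae_maps.
lpips_graph <- function(dec_px, target_px, extractor, maps, n_batch, H) {
  lm <- maps$lpips_all
  ha <- ag_gather_cells(dec_px, lm, maps$lpips_plan)
  hb <- matrix(target_px[as.vector(lm)], nrow(lm), ncol(lm))
  g <- H %/% 2L
  total <- NULL
  for (l in seq_len(extractor$n_layers)) {
    Wm <- extractor$mats[[l]]
    ha <- ag_tanh(ag_matmul(ha, ag_const(Wm)))
    hb <- tanh(hb %*% Wm)
    w <- extractor$weights[[l]]
    diff <- ag_sub(ha, ag_const(hb))
    if (any(w != 1)) {
      diff <- ag_mul(diff, ag_const(matrix(w, nrow(hb), length(w), byrow = TRUE)))
    }
    term <- ag_scale(ag_sum(ag_square(diff)), 1 / (g * g * n_batch))
    total <- if (is.null(total)) term else ag_add(total, term)
    if (l < extractor$n_layers) {
      if (g < 2L) break
      midx <- maps$lpips_merge[[l]]
      ha <- ag_gather_concat(ha, midx)
      C <- ncol(hb)
      hb2 <- matrix(0, nrow(midx), 4L * C)
      for (j in 1:4) hb2[, ((j - 1L) * C + 1L):(j * C)] <- hb[midx[, j], , drop = FALSE]
      hb <- hb2
      g <- g %/% 2L
    }
  }
  ag_scale(total, 1 / 5)
}

# Per-channel linear index maps from the decoder token matrix layout
# ((B*T) x (5*p*p)) to the LPIPS layer-1 input token layout
# ((B*(H/2)^2) x 12, channel replicated 3x).
mvae_lpips_maps <- function(H, p, n_batch) {
  hp <- H %/% p; Tn <- hp * hp; pp <- p * p
  nrow_dec <- n_batch * Tn
  g1 <- H %/% 2L
  # pixel (i,j) -> decoder (row within image, col offset within channel blk)
  pix_token <- matrix(0L, H, H); pix_off <- matrix(0L, H, H)
  for (j in seq_len(H)) {
    for (i in seq_len(H)) {
      pr <- ((i - 1L) %/% p) + 1L; pc <- ((j - 1L) %/% p) + 1L
      pix_token[i, j] <- (pc - 1L) * hp + pr
      ii <- i - (pr - 1L) * p; jj <- j - (pc - 1L) * p
      pix_off[i, j] <- (jj - 1L) * p + ii
    }
  }
  l1_idx <- patch_index(H, 2L, 1L)  # (g1^2) x 4 pixel linear indices
  maps <- list()
  for (c in 1:5) {
    one <- matrix(0L, g1 * g1, 12L)
    for (s in seq_len(g1 * g1)) {
      pix <- l1_idx[s, ]
      i <- ((pix - 1L) %% H) + 1L; j <- ((pix - 1L) %/% H) + 1L
      rows <- pix_token[cbind(i, j)]
      cols <- (c - 1L) * pp + pix_off[cbind(i, j)]
      lin <- (cols - 1L) * nrow_dec + rows
      one[s, ] <- rep(lin, 3L)
    }
    # shift rows by b*Tn within each column's linear index
    maps[[c]] <- do.call(rbind, lapply(seq_len(n_batch) - 1L, function(b) one + b * Tn))
  }
  merges <- list()
  g <- g1
  while (g >= 2L) {
    merges[[length(merges) + 1L]] <- merge_index(g, n_batch)
    g <- g %/% 2L
  }
  list(channel = maps, merge = merges)
}

ag_softplus <- function(a) {
  x <- a$value
  ag_new(pmax(x, 0) + log1p(exp(-abs(x))), list(a), function(node, g) {
    ag_accum(node$parents[[1L]], g / (1 + exp(-node$parents[[1L]]$value)))
  })
}

#' One MVAE training step
#'
#' Performs one autoencoder update (reconstruction + KL + perceptual +,
#' after the warm-up, the generator's adversarial term) and, after the
#' warm-up, one discriminator update, in alternation. Adversarial terms
#' are reported as non-negative logistic cross-entropies.
#'
#' @param model an [mvae_init] model (updated in place; parameters are
#'   environments).
#' @param images batch (non-empty list of [morph_image]).
#' @param state optimizer state from a previous call, or `NULL` to start.
#' @param seed seed for the reparameterization draws of this step.
#' @return list with `losses` (L_rec, L_adv_gen, L_adv_disc, L_reg,
#'   L_lpips, total, disc_accuracy) and `state`.
#' @export
mvae_step <- function(model, images, state = NULL, seed = 1) {
  pd_assert(length(images) >= 1L, "empty batch")
  cfg <- model$config
  B <- length(images)
  if (is.null(state)) {
    state <- list(step = 0L,
                  opt_ae = adam_init(c(nn_params(model$enc), nn_params(model$dec)), lr = cfg$lr),
                  opt_disc = adam_init(nn_params(model$disc), lr = cfg$lr))
  }
  state$step <- state$step + 1L
  maps <- mvae_maps(cfg, B)
  Xp <- images_to_patches(images, cfg$patch)   # encoder input
  Xpix <- images_to_pixmat(images)             # decoder target
  adv_on <- state$step > cfg$adv_warmup && cfg$lambda_adv > 0

  ag_tape_reset()
  post <- enc_forward(model, ag_const(Xp))
  eps <- with_seed(derive_seed(seed, paste0("mvae_eps_", state$step)),
                   matrix(stats::rnorm(length(post$mean$value)), nrow(post$mean$value)))
  z <- ag_add(post$mean, ag_mul(ag_exp(ag_scale(post$logvar, 0.5)), ag_const(eps)))
  xhat <- dec_forward(model, z, B)

  l_rec <- ag_mean(ag_abs(ag_sub(xhat, ag_const(Xpix))))
  l_kl <- ag_scale(ag_sum(ag_sub(ag_add(ag_exp(post$logvar), ag_square(post$mean)),
                                 ag_add(post$logvar, ag_const(matrix(1, nrow(post$mean$value),
                                                                     ncol(post$mean$value)))))),
                   0.5 / B)
  l_lpips <- lpips_graph(xhat, Xpix, model$extractor, maps, B, cfg$H)

  total <- ag_add(ag_add(ag_scale(l_rec, cfg$lambda_rec), ag_scale(l_kl, cfg$lambda_kl)),
                  ag_scale(l_lpips, cfg$lambda_lpips))
  if (cfg$lambda_cov > 0) {
    HH <- cfg$H^2
    ones <- ag_const(matrix(1 / HH, 1L, HH))
    l_cov <- NULL
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * HH + 1L):(b * HH)
      Xb <- ag_gather_rows(xhat, rows)
      mb <- ag_matmul(ones, Xb)
      Xc <- ag_sub(Xb, ag_gather_rows(mb, rep(1L, HH)))
      Cb <- ag_scale(ag_matmul(ag_transpose(Xc), Xc), 1 / HH)
      Tb <- Xpix[rows, , drop = FALSE]
      Tc <- sweep(Tb, 2L, colMeans(Tb))
      Ct <- crossprod(Tc) / HH
      term <- ag_sum(ag_square(ag_sub(Cb, ag_const(Ct))))
      l_cov <- if (is.null(l_cov)) term else ag_add(l_cov, term)
    }
    total <- ag_add(total, ag_scale(l_cov, cfg$lambda_cov / B))
  }
  if (cfg$lambda_grad > 0) {
    gv_hat <- ag_sub(ag_gather_rows(xhat, maps$gv_p), ag_gather_rows(xhat, maps$gv_m))
    gh_hat <- ag_sub(ag_gather_rows(xhat, maps$gh_p), ag_gather_rows(xhat, maps$gh_m))
    gv_t <- Xpix[maps$gv_p, , drop = FALSE] - Xpix[maps$gv_m, , drop = FALSE]
    gh_t <- Xpix[maps$gh_p, , drop = FALSE] - Xpix[maps$gh_m, , drop = FALSE]
    l_grad <- ag_add(ag_mean(ag_abs(ag_sub(gv_hat, ag_const(gv_t)))),
                     ag_mean(ag_abs(ag_sub(gh_hat, ag_const(gh_t)))))
    total <- ag_add(total, ag_scale(l_grad, cfg$lambda_grad))
  }
  l_gen_val <- 0
  if (adv_on) {
    logits_fake <- disc_forward(model, ag_gather_cells(xhat, maps$disc))
    l_gen <- ag_mean(ag_softplus(ag_scale(logits_fake, -1)))
    total <- ag_add(total, ag_scale(l_gen, cfg$lambda_adv))
    l_gen_val <- l_gen$value[1L]
  }
  comp <- c(L_rec = l_rec$value[1L], L_reg = l_kl$value[1L], L_lpips = l_lpips$value[1L])
  if (any(!is.finite(c(comp, total$value[1L])))) {
    bad <- names(comp)[!is.finite(comp)]
    stop("non-finite training loss in component(s): ",
         paste(if (length(bad)) bad else "total", collapse = ", "), call. = FALSE)
  }
  nn_zero_grads(state$opt_ae$params)
  ag_backward(total)
  state$opt_ae <- adam_step(state$opt_ae)

  # discriminator update on real vs reconstructed (detached)
  disc_acc <- NA_real_
  l_disc_val <- 0
  if (adv_on) {
    ag_tape_reset()
    Xd_real <- images_to_patches(images, cfg$disc_patch)
    xf <- xhat$value
    Xd_fake <- matrix(xf[as.vector(maps$disc)], nrow(maps$disc), ncol(maps$disc))
    lr_ <- disc_forward(model, ag_const(Xd_real))
    lf_ <- disc_forward(model, ag_const(Xd_fake))
    l_disc <- ag_add(ag_mean(ag_softplus(ag_scale(lr_, -1))), ag_mean(ag_softplus(lf_)))
    nn_zero_grads(state$opt_disc$params)
    ag_backward(l_disc)
    state$opt_disc <- adam_step(state$opt_disc)
    l_disc_val <- l_disc$value[1L]
    disc_acc <- (mean(lr_$value > 0) + mean(lf_$value < 0)) / 2
  }
  list(losses = c(L_rec = unname(comp["L_rec"]), L_adv_gen = l_gen_val,
                  L_adv_disc = l_disc_val, L_reg = unname(comp["L_reg"]),
                  L_lpips = unname(comp["L_lpips"]), total = total$value[1L],
                  disc_accuracy = disc_acc),
       state = state)
}

#' Train an MVAE on a set of images
#'
#' Mini-batch Adam training with [mvae_step]; batches are sampled with the
#' run seed, so training is fully reproducible.
#'
#' @param model an [mvae_init] model (updated in place and returned).
#' @param images list of [morph_image].
#' @param steps number of optimizer steps.
#' @param batch_size images per step.
#' @param seed integer seed.
#' @param verbose print running losses every 200 steps.
#' @return list `model`, `state`, `history` (matrix of per-step losses).
#' @export
train_mvae <- function(model, images, steps = 1200, batch_size = 16, seed = 1,
                       verbose = FALSE) {
  state <- NULL
  hist <- matrix(NA_real_, steps, 7L)
  colnames(hist) <- c("L_rec", "L_adv_gen", "L_adv_disc", "L_reg", "L_lpips",
                      "total", "disc_accuracy")
  batch_ids <- with_seed(derive_seed(seed, "mvae_batches"), {
    lapply(seq_len(steps), function(s) sample.int(length(images), batch_size, replace = TRUE))
  })
  lr0 <- model$config$lr
  for (s in seq_len(steps)) {
    res <- mvae_step(model, images[batch_ids[[s]]], state,
                     seed = derive_seed(seed, paste0("step", s)))
    state <- res$state
    if (isTRUE(model$config$lr_decay)) {
      # cosine decay to lr0/10
      lr_s <- lr0 * (0.1 + 0.45 * (1 + cos(pi * s / steps)))
      state$opt_ae$lr <- lr_s
      state$opt_disc$lr <- lr_s
    }
    hist[s, ] <- res$losses
    if (verbose && s %% 200L == 0L) {
      message(sprintf("step %d: rec %.4f lpips %.4f", s, res$losses["L_rec"],
                      res$losses["L_lpips"]))
    }
  }
  # fit the Gaussian observation scale: the data's per-channel
  # acquisition-noise level minus (in variance) the high-frequency noise
  # the decoder already reproduces, so a generated draw carries the same
  # total pixel-noise energy as a real acquisition
  sub <- images[with_seed(derive_seed(seed, "obs_sd"),
                          sample.int(length(images), min(32L, length(images))))]
  sd_data <- min(rowMeans(vapply(sub, estimate_noise_sd, numeric(5))))
  sd_rec <- min(rowMeans(vapply(sub, function(im) {
    estimate_noise_sd(decode(model, encode(model, im)$mean))
  }, numeric(5))))
  # homoscedastic acquisition noise: the least structure-contaminated
  # channel estimates the iid level; subtract (in variance) what the
  # decoder already reproduces
  model$obs_sd <- rep(sqrt(max(sd_data^2 - sd_rec^2, 0)), 5L)
  list(model = model, state = state, history = hist)
}

# Robust per-channel noise estimate: median absolute deviation of
# horizontal first differences. Smooth structure (cells, granules,
# texture waves) contributes little to the median; iid noise gives
# differences with SD sigma * sqrt(2).
estimate_noise_sd <- function(image) {
  vapply(1:5, function(c) {
    m <- image$channels[, , c]
    a <- m[, -1, drop = FALSE]; b <- m[, -ncol(m), drop = FALSE]
    # exclude pairs touching the clip boundaries (censored differences).
    # Smooth structure still contaminates the estimate, but it
    # contaminates the reconstruction estimate equally, so the variance
    # subtraction in train_mvae cancels it.
    ok <- a > 0 & a < 1 & b > 0 & b < 1
    d <- (a - b)[ok]
    if (length(d) < 20L) return(0)
    stats::mad(d, center = 0) / sqrt(2)
  }, 0)
}
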