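# Conditional latent DDPM. The forward process adds Gaussian noise over T
# steps with a linear beta schedule; the denoiser is a two-resolution
# token U-Net (non-overlapping patch merges, residual MLP blocks at the
# top resolution, self- plus cross-attention at the lowest resolution)
# that predicts the added noise conditioned on a fixed linear projection
# of the expression profile; sampling is ancestral (one Gaussian draw per
# step, none at t = 1).

#' Build a DDPM noise schedule
#'
#' Linear beta schedule: `beta_t` interpolates `beta_min..beta_max`,
#' `alpha_t = 1 - beta_t`, `alpha_bar_t = prod(alpha_1..alpha_t)`,
#' sampling noise scale `sigma_t = sqrt(beta_t)`.
#'
#' @param T number of diffusion steps (>= 1).
#' @param beta_min,beta_max noise-rate range, `0 < beta_min <= beta_max < 1`.
#' @param kind schedule shape; only `"linear"` is implemented.
#' @return object of class `noise_schedule` with fields `T`, `beta`,
#'   `alpha`, `alpha_bar`, `sigma`.
#' @export
make_schedule <- function(T = 1000, beta_min = 1e-4, beta_max = 2e-2,
                          kind = c("linear")) {
  kind <- match.arg(kind)
  pd_assert(T >= 1, "T must be >= 1")
  pd_assert(beta_min > 0 && beta_min <= beta_max && beta_max < 1,
            "need 0 < beta_min <= beta_max < 1")
  beta <- if (T == 1L) beta_max else seq(beta_min, beta_max, length.out = T)
  alpha <- 1 - beta
  structure(list(T = as.integer(T), beta = beta, alpha = alpha,
                 alpha_bar = cumprod(alpha), sigma = sqrt(beta), kind = kind),
            class = "noise_schedule")
}

#' Closed-form forward noising
#'
#' `z_t = sqrt(alpha_bar_t) z_0 + sqrt(1 - alpha_bar_t) eps`, the
#' marginal of t successive Gaussian noising steps.
#'
#' @param z0 numeric array (any shape).
#' @param t integer step in `1..T`.
#' @param eps standard-normal draw with the shape of `z0`.
#' @param schedule a [make_schedule] object.
#' @return array shaped like `z0`.
#' @export
q_sample <- function(z0, t, eps, schedule) {
  pd_assert(length(t) == 1L && t >= 1 && t <= schedule$T, "t out of range 1..T")
  pd_assert(length(eps) == length(z0), "eps must match the shape of z0")
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * z0 + sqrt(1 - ab) * eps
}

#' Encode an expression profile into a cross-attention context
#'
#' A fixed (non-learned) seeded Gaussian linear map, without bias, from
#' the G-dimensional expression vector to `n_tokens x context_dim` context
#' tokens; identical at training and sampling time.
#'
#' @param l numeric expression vector of length G.
#' @param seed seed fixing the projection (must match between training
#'   and sampling; stored inside trained models).
#' @param G expected length of `l`.
#' @param n_tokens,context_dim context shape (defaults 8 x 64).
#' @return `n_tokens x context_dim` matrix of class `condition_context`.
#' @export
encode_condition <- function(l, seed = 1, G = length(l), n_tokens = 8, context_dim = 64) {
  pd_assert(length(l) == G, sprintf("expression length %d != configured G = %d", length(l), G))
  W <- condition_projection(G, n_tokens, context_dim, seed)
  ctx <- matrix(W %*% as.numeric(l), n_tokens, context_dim, byrow = TRUE)
  structure(ctx, class = c("condition_context", "matrix", "array"), seed = seed)
}

.cond_cache <- new.env(parent = emptyenv())
condition_projection <- function(G, n_tokens, context_dim, seed) {
  key <- sprintf("G%d_t%d_d%d_s%d", G, n_tokens, context_dim, seed)
  if (is.null(.cond_cache[[key]])) {
    .cond_cache[[key]] <- with_seed(derive_seed(seed, "cond_enc"), {
      matrix(stats::rnorm(n_tokens * context_dim * G, sd = 1 / sqrt(G)),
             n_tokens * context_dim, G)
    })
  }
  .cond_cache[[key]]
}

#' Scaled dot-product cross-attention (single head)
#'
#' `softmax(Q K^T / sqrt(d)) V` with `Q = Q_input W_Q`,
#' `K = context W_K`, `V = context W_V` (inputs as rows).
#'
#' @param Q_input query tokens (rows).
#' @param context context tokens (rows), e.g. an [encode_condition]
#'   output.
#' @param projections list with matrices `W_Q`, `W_K`, `W_V`.
#' @return list with `output` (query tokens x value dim) and `weights`
#'   (rows non-negative, summing to 1).
#' @export
cross_attention <- function(Q_input, context, projections) {
  pd_assert(ncol(as.matrix(Q_input)) == nrow(projections$W_Q) &&
              ncol(as.matrix(context)) == nrow(projections$W_K) &&
              ncol(as.matrix(context)) == nrow(projections$W_V),
            "projection dimensions do not match the inputs")
  Q <- as.matrix(Q_input) %*% projections$W_Q
  K <- as.matrix(context) %*% projections$W_K
  V <- as.matrix(context) %*% projections$W_V
  pd_assert(ncol(Q) == ncol(K), "query/key projection dimensions differ")
  s <- Q %*% t(K) / sqrt(ncol(Q))
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  w <- e / rowSums(e)
  list(output = w %*% V, weights = w)
}

#' Latent diffusion model configuration
#'
#' @param latent_channels channels of the latent per spatial position.
#' @param grid latent spatial side (tokens form a `grid x grid` map).
#' @param d_model width of the denoiser.
#' @param n_blocks residual blocks per stage.
#' @param levels 1 (single resolution) or 2 (one 2x2 token merge; the
#'   attention blocks sit at the lowest resolution).
#' @param n_tokens_ctx,context_dim condition context shape.
#' @param T,beta_min,beta_max schedule parameters ([make_schedule]); the
#'   desk default (T = 50, betas 2e-3..0.4) scales the reference
#'   1000-step range 1e-4..2e-2 by 1000/T, preserving the cumulative
#'   noise so the chain still terminates near pure noise.
#' @param lr Adam learning rate.
#' @param denominator `"ddpm"` uses `sqrt(1 - alpha_bar_t)` in the
#'   sampler update (the variance-preserving form); `"one-minus-root"` uses
#'   `1 - sqrt(alpha_bar_t)` as occasionally printed in the literature.
#' @param clip_z0 sampling-time clamp on the implied clean-latent
#'   prediction (standardized units), the standard denoised-clipping
#'   stabilizer of ancestral DDPM samplers; prediction errors otherwise
#'   amplify by `1/sqrt(alpha_bar_T)` over the chain. `Inf` disables;
#'   when the clamp is inactive the update equals the plain rule exactly.
#' @return list of class `ldm_config`.
#' @export
ldm_config <- function(latent_channels = 32, grid = 8, d_model = 64,
                       n_blocks = 2, levels = 2, n_tokens_ctx = 8,
                       context_dim = 64, T = 50, beta_min = 2e-3,
                       beta_max = 0.4, lr = 3e-3,
                       denominator = c("ddpm", "one-minus-root"), clip_z0 = 4) {
  pd_assert(levels %in% c(1L, 2L), "levels must be 1 or 2")
  if (levels == 2L) pd_assert(grid %% 2L == 0L, "grid must be even for 2 levels")
  structure(list(latent_channels = latent_channels, grid = grid,
                 d_model = d_model, n_blocks = n_blocks, levels = levels,
                 n_tokens_ctx = n_tokens_ctx, context_dim = context_dim,
                 T = as.integer(T), beta_min = beta_min, beta_max = beta_max,
                 lr = lr, denominator = match.arg(denominator),
                 clip_z0 = clip_z0),
            class = "ldm_config")
}

#' Initialize an untrained conditional latent diffusion model
#'
#' @param config an [ldm_config].
#' @param G expression vector length (condition input).
#' @param seed weight-initialization seed; also fixes the condition
#'   projection used at training and sampling time.
#' @return object of class `ldm`.
#' @export
ldm_init <- function(config = ldm_config(), G = 64, seed = 1) {
  d <- config$d_model
  with_seed(derive_seed(seed, "ldm_init"), {
    res_block <- function() list(ln = nn_layernorm(d),
                                 l1 = nn_linear(d, 2L * d), l2 = nn_linear(2L * d, d, gain = 0.5))
    attn_block <- function() list(
      ln1 = nn_layernorm(d),
      Wq = nn_linear(d, d), Wk = nn_linear(config$context_dim, d),
      Wv = nn_linear(config$context_dim, d), Wo = nn_linear(d, d, gain = 0.5),
      ln_s = nn_layernorm(d),
      Sq = nn_linear(d, d), Sk = nn_linear(d, d), Sv = nn_linear(d, d),
      So = nn_linear(d, d, gain = 0.5),
      ln2 = nn_layernorm(d), m1 = nn_linear(d, 2L * d), m2 = nn_linear(2L * d, d, gain = 0.5))
    net <- list(
      embed = nn_linear(config$latent_channels, d),
      pos = ag_param(matrix(stats::rnorm(config$grid^2 * d, sd = 0.02), config$grid^2, d)),
      time1 = nn_linear(d, d), time2 = nn_linear(d, d),
      cond1 = nn_linear(config$context_dim, d), cond2 = nn_linear(d, d),
      top = lapply(seq_len(config$n_blocks), function(i) res_block()),
      attn = lapply(seq_len(config$n_blocks), function(i) attn_block()),
      ln_out = nn_layernorm(d),
      out = nn_linear(d, config$latent_channels, gain = 0.1))
    if (config$levels == 2L) {
      net$down <- nn_linear(4L * d, d)
      net$up <- nn_linear(d, 4L * d)
    }
    structure(list(config = config, net = net, G = G,
                   seed = seed, cond_seed = derive_seed(seed, "cond"),
                   schedule = make_schedule(config$T, config$beta_min, config$beta_max),
                   z_loc = 0, z_scale = 1),
              class = "ldm")
  })
}

apply_res_block <- function(blk, h) {
  u <- nn_apply_layernorm(blk$ln, h)
  ag_add(h, nn_apply_linear(blk$l2, ag_silu(nn_apply_linear(blk$l1, u))))
}

apply_attn_block <- function(blk, h, ctx, B, Tl, Tc) {
  u <- nn_apply_layernorm(blk$ln_s, h)
  sa <- ag_attention(nn_apply_linear(blk$Sq, u), nn_apply_linear(blk$Sk, u),
                     nn_apply_linear(blk$Sv, u), B, Tl, Tl)
  h <- ag_add(h, nn_apply_linear(blk$So, sa))
  u <- nn_apply_layernorm(blk$ln1, h)
  ca <- ag_attention(nn_apply_linear(blk$Wq, u), nn_apply_linear(blk$Wk, ctx),
                     nn_apply_linear(blk$Wv, ctx), B, Tl, Tc)
  h <- ag_add(h, nn_apply_linear(blk$Wo, ca))
  u <- nn_apply_layernorm(blk$ln2, h)
  ag_add(h, nn_apply_linear(blk$m2, ag_silu(nn_apply_linear(blk$m1, u))))
}

# Denoiser forward pass on token matrices.
# z_tokens: (B*Tn) x cz node or matrix; t_vec: length-B steps;
# ctx: (B*Tc) x context_dim constant matrix.
ldm_forward <- function(model, z_tokens, t_vec, ctx, B) {
  cfg <- model$config
  Tn <- cfg$grid^2
  if (!inherits(z_tokens, "ag_tensor")) z_tokens <- ag_const(z_tokens)
  h <- nn_apply_linear(model$net$embed, z_tokens)
  h <- ag_add(h, ag_gather_rows(model$net$pos, rep(seq_len(Tn), B)))
  te <- ag_const(sinusoidal_embedding(t_vec / cfg$T * 1000, cfg$d_model))
  te <- nn_apply_linear(model$net$time2, ag_silu(nn_apply_linear(model$net$time1, te)))
  h <- ag_add(h, ag_gather_rows(te, rep(seq_len(B), each = Tn)))
  # additive conditioning path: mean-pooled context per item, alongside
  # the cross-attention (key/value) path below
  ctxv <- if (inherits(ctx, "ag_tensor")) ctx$value else ctx
  pooled <- rowsum(ctxv, rep(seq_len(B), each = cfg$n_tokens_ctx)) / cfg$n_tokens_ctx
  ce <- nn_apply_linear(model$net$cond2,
                        ag_silu(nn_apply_linear(model$net$cond1, ag_const(pooled))))
  h <- ag_add(h, ag_gather_rows(ce, rep(seq_len(B), each = Tn)))
  for (blk in model$net$top) h <- apply_res_block(blk, h)
  ctxn <- if (inherits(ctx, "ag_tensor")) ctx else ag_const(ctx)
  if (cfg$levels == 2L) {
    skip <- h
    midx <- merge_index(cfg$grid, B)
    h <- nn_apply_linear(model$net$down, ag_gather_concat(h, midx))
    Tl <- (cfg$grid %/% 2L)^2
    for (blk in model$net$attn) h <- apply_attn_block(blk, h, ctxn, B, Tl, cfg$n_tokens_ctx)
    h <- ag_split_rows(nn_apply_linear(model$net$up, h), midx, cfg$d_model)
    h <- ag_add(h, skip)
  } else {
    for (blk in model$net$attn) h <- apply_attn_block(blk, h, ctxn, B, Tn, cfg$n_tokens_ctx)
  }
  nn_apply_linear(model$net$out, nn_apply_layernorm(model$net$ln_out, h))
}

# Context token matrix (B*Tc) x context_dim for a list of expression
# vectors, using the model's fixed condition encoder.
ldm_context <- function(model, l_list) {
  cfg <- model$config
  do.call(rbind, lapply(l_list, function(l) {
    unclass(encode_condition(l, seed = model$cond_seed, G = model$G,
                             n_tokens = cfg$n_tokens_ctx,
                             context_dim = cfg$context_dim))
  }))
}

# Model evaluation for one batch at one shared step t (plain matrix out).
ldm_predict <- function(model, z_tokens, t, l_list) {
  if (is.function(model)) return(model(z_tokens, t, l_list))
  B <- length(l_list)
  ag_tape_reset()
  out <- ldm_forward(model, z_tokens, rep(t, B), ldm_context(model, l_list), B)
  out$value
}

#' Noise-prediction training loss for one draw
#'
#' The squared L2 error `||eps - eps_theta(z_t, t, EC(l))||^2` of the
#' simplified DDPM objective, evaluated for a given `(z0, t, eps)` draw.
#'
#' @param model an [ldm_init] model, or a function
#'   `(z_tokens, t, l_list) -> matrix` standing in for the denoiser.
#' @param z0 latent token matrix (`grid^2 x latent_channels`).
#' @param l expression vector (the condition).
#' @param t integer step.
#' @param eps standard-normal array shaped like `z0`.
#' @param schedule optional [make_schedule]; defaults to the model's.
#' @return scalar squared error.
#' @export
training_loss <- function(model, z0, l, t, eps, schedule = NULL) {
  if (is.null(schedule)) {
    pd_assert(inherits(model, "ldm"), "schedule required for function models")
    schedule <- model$schedule
  }
  zt <- q_sample(z0, t, eps, schedule)
  eps_hat <- ldm_predict(model, zt, t, list(l))
  pd_assert(identical(dim(eps_hat), dim(as_mat(zt))), "model output shape mismatch")
  sum((eps - eps_hat)^2)
}

#' Train the conditional latent diffusion model
#'
#' Mini-batch Adam on the noise-prediction objective: each step samples a
#' batch of latents with their conditions, a uniform step `t` and fresh
#' Gaussian noise. Latents are standardized (global location/scale stored
#' on the model) so the forward process terminates near N(0, I).
#'
#' @param model an [ldm_init] model (updated in place).
#' @param latents list of latent token matrices (`grid^2 x cz`), e.g.
#'   posterior means from [encode].
#' @param conditions list of expression vectors, one per latent.
#' @param steps,batch_size optimization schedule.
#' @param seed integer seed.
#' @param verbose print the running loss every 200 steps.
#' @return list `model`, `history` (per-step mean squared noise error).
#' @export
train_ldm <- function(model, latents, conditions, steps = 2000, batch_size = 16,
                      seed = 1, verbose = FALSE) {
  pd_assert(length(latents) == length(conditions), "latents/conditions length mismatch")
  cfg <- model$config
  allz <- do.call(rbind, latents)
  model$z_loc <- colMeans(allz)
  model$z_scale <- apply(allz, 2L, stats::sd)
  model$z_scale[!is.finite(model$z_scale) | model$z_scale == 0] <- 1
  zs <- lapply(latents, function(z) {
    sweep(sweep(z, 2L, model$z_loc), 2L, model$z_scale, "/")
  })
  Tn <- cfg$grid^2
  opt <- adam_init(nn_params(model$net), lr = cfg$lr)
  hist <- numeric(steps)
  sched <- model$schedule
  plan <- with_seed(derive_seed(seed, "ldm_batches"), {
    lapply(seq_len(steps), function(s) {
      list(idx = sample.int(length(zs), batch_size, replace = TRUE),
           t = sample.int(sched$T, batch_size, replace = TRUE))
    })
  })
  lr0 <- cfg$lr
  for (s in seq_len(steps)) {
    opt$lr <- lr0 * (0.1 + 0.45 * (1 + cos(pi * s / steps)))
    idx <- plan[[s]]$idx; tv <- plan[[s]]$t
    z0 <- do.call(rbind, zs[idx])
    eps <- with_seed(derive_seed(seed, paste0("ldm_eps_", s)),
                     matrix(stats::rnorm(length(z0)), nrow(z0)))
    ab <- sched$alpha_bar[tv]
    scl_a <- rep(sqrt(ab), each = Tn); scl_b <- rep(sqrt(1 - ab), each = Tn)
    zt <- z0 * scl_a + eps * scl_b
    ctx <- ldm_context(model, conditions[idx])
    ag_tape_reset()
    out <- ldm_forward(model, zt, tv, ctx, batch_size)
    loss <- ag_mean(ag_square(ag_sub(out, ag_const(eps))))
    if (!is.finite(loss$value[1L])) stop("non-finite diffusion training loss", call. = FALSE)
    nn_zero_grads(opt$params)
    ag_backward(loss)
    opt <- adam_step(opt)
    hist[s] <- loss$value[1L]
    if (verbose && s %% 200L == 0L) message(sprintf("ldm step %d: %.4f", s, hist[s]))
  }
  list(model = model, history = hist)
}

#' Ancestral DDPM sampling conditioned on an expression profile
#'
#' Starts from `z_T ~ N(0, I)` and applies the reverse update
#' `z_{t-1} = (z_t - (1 - alpha_t)/sqrt(1 - alpha_bar_t) eps_theta) /
#' sqrt(alpha_t) + sigma_t z`, with `z = 0` at `t = 1`. The alternative
#' denominator `1 - sqrt(alpha_bar_t)` is available via the model config
#' (`denominator = "one-minus-root"`).
#'
#' @param model an [ldm_init] model or a denoiser function
#'   `(z_tokens, t, l_list) -> matrix`.
#' @param l expression vector (condition); ignored by function models
#'   that ignore it.
#' @param n number of samples.
#' @param seed integer seed (same seed, same output).
#' @param schedule required for function models.
#' @param shape latent `c(grid^2, latent_channels)`; required for
#'   function models.
#' @param denominator override for function models.
#' @param unstandardize return latents on the training scale
#'   (`z * z_scale + z_loc`); default TRUE for `ldm` models.
#' @return list of latent token matrices (`grid^2 x cz`), length `n`.
#' @export
ddpm_sample <- function(model, l, n = 1, seed = 1, schedule = NULL, shape = NULL,
                        denominator = NULL, unstandardize = TRUE) {
  if (inherits(model, "ldm")) {
    schedule <- model$schedule
    shape <- c(model$config$grid^2, model$config$latent_channels)
    if (is.null(denominator)) denominator <- model$config$denominator
  } else {
    pd_assert(!is.null(schedule) && !is.null(shape),
              "function models need explicit schedule and shape")
    if (is.null(denominator)) denominator <- "ddpm"
  }
  Tn <- shape[1L]; cz <- shape[2L]
  clip <- if (inherits(model, "ldm")) { if (is.null(model$config$clip_z0)) 4 else model$config$clip_z0 } else Inf
  with_seed(derive_seed(seed, "ddpm_sample"), {
    Z <- matrix(stats::rnorm(n * Tn * cz), n * Tn, cz)
    for (t in seq(schedule$T, 1L)) {
      eps_hat <- ldm_predict(model, Z, t, rep(list(l), n))
      eps_hat <- clip_eps(Z, eps_hat, schedule$alpha_bar[t], clip)
      den <- if (denominator == "ddpm") sqrt(1 - schedule$alpha_bar[t])
             else (1 - sqrt(schedule$alpha_bar[t]))
      Z <- (Z - (1 - schedule$alpha[t]) / den * eps_hat) / sqrt(schedule$alpha[t])
      if (t > 1L) {
        Z <- Z + schedule$sigma[t] * matrix(stats::rnorm(length(Z)), nrow(Z))
      }
    }
    out <- lapply(seq_len(n), function(b) Z[((b - 1L) * Tn + 1L):(b * Tn), , drop = FALSE])
    if (inherits(model, "ldm") && unstandardize) {
      out <- lapply(out, function(z) {
        sweep(sweep(z, 2L, model$z_scale, "*"), 2L, model$z_loc, "+")
      })
    }
    out
  })
}

#' Generate images from expression (G2I mode)
#'
#' Samples latents with [ddpm_sample] and decodes them with the MVAE.
#'
#' @param model trained [ldm_init] model.
#' @param mvae trained [mvae_init] model.
#' @param l expression vector.
#' @param n number of images.
#' @param seed integer seed.
#' @param perturbation_id label attached to the generated images.
#' @return list of [morph_image].
#' @export
generate_images <- function(model, mvae, l, n = 1, seed = 1,
                            perturbation_id = "generated") {
  zs <- ddpm_sample(model, l, n = n, seed = seed)
  hz <- model$config$grid
  lapply(seq_along(zs), function(i) {
    decode(mvae, latent_tokens_to_array(zs[[i]], model$config$latent_channels, hz),
           perturbation_id = perturbation_id,
           noise_seed = derive_seed(seed, paste0("obs_", i)))
  })
}

# Denoised clipping: clamp the implied z0 = (z_t - sqrt(1-ab) eps)/sqrt(ab)
# to [-clip, clip] and return the correspondingly adjusted eps. Identity
# whenever the clamp is inactive.
clip_eps <- function(Z, eps_hat, ab, clip) {
  if (!is.finite(clip)) return(eps_hat)
  z0_hat <- (Z - sqrt(1 - ab) * eps_hat) / sqrt(ab)
  z0_cl <- pmin(pmax(z0_hat, -clip), clip)
  if (identical(z0_cl, z0_hat)) return(eps_hat)
  (Z - sqrt(ab) * z0_cl) / sqrt(1 - ab)
}

#' Image-to-image editing via partial noising (SDEdit)
#'
#' Encodes a control image, noises its latent to
#' `t* = round(strength * T)` with the closed-form forward process, then
#' runs the conditional reverse chain from `t*` down to 1 and decodes.
#' `strength = 1` reproduces generation from pure noise in distribution;
#' small strengths stay close to the control image.
#'
#' @param control a control-group [morph_image], or a list of them (the
#'   reverse chain then runs batched and a list is returned).
#' @param l expression vector of the target perturbation.
#' @param strength proportion of the chain to traverse, in `(0, 1]`.
#' @param model trained [ldm_init] model, or a denoiser function
#'   `(z_tokens, t, l_list) -> matrix` (pass `schedule` explicitly then).
#' @param mvae trained [mvae_init] model.
#' @param seed integer seed.
#' @param schedule required when `model` is a function.
#' @return a [morph_image].
#' @export
sdedit_transform <- function(control, l, strength, model, mvae, seed = 1,
                             schedule = NULL) {
  pd_assert(strength > 0 && strength <= 1, "strength must be in (0, 1]")
  single <- inherits(control, "morph_image")
  controls <- if (single) list(control) else control
  B <- length(controls)
  z0 <- do.call(rbind, lapply(seq_len(B), function(i) {
    latent_array_to_tokens(encode(mvae, controls[[i]],
                                  seed = derive_seed(seed, paste0("sdedit_enc", i)))$mean)
  }))
  Tn <- nrow(z0) %/% B
  is_ldm <- inherits(model, "ldm")
  sched <- if (is_ldm) model$schedule else schedule
  pd_assert(!is.null(sched), "schedule required for function models")
  zloc <- if (is_ldm) model$z_loc else 0
  zscl <- if (is_ldm) model$z_scale else 1
  z0 <- sweep(sweep(z0, 2L, zloc), 2L, zscl, "/")
  tstar <- max(1L, as.integer(round(strength * sched$T)))
  out <- with_seed(derive_seed(seed, "sdedit"), {
    eps <- matrix(stats::rnorm(length(z0)), nrow(z0))
    Z <- q_sample(z0, tstar, eps, sched)
    den_kind <- if (is_ldm) model$config$denominator else "ddpm"
    clip <- if (is_ldm) { if (is.null(model$config$clip_z0)) 4 else model$config$clip_z0 } else Inf
    for (t in seq(tstar, 1L)) {
      eps_hat <- ldm_predict(model, Z, t, rep(list(l), B))
      eps_hat <- clip_eps(Z, eps_hat, sched$alpha_bar[t], clip)
      den <- if (den_kind == "ddpm") sqrt(1 - sched$alpha_bar[t])
             else (1 - sqrt(sched$alpha_bar[t]))
      Z <- (Z - (1 - sched$alpha[t]) / den * eps_hat) / sqrt(sched$alpha[t])
      if (t > 1L) Z <- Z + sched$sigma[t] * matrix(stats::rnorm(length(Z)), nrow(Z))
    }
    Z <- sweep(sweep(Z, 2L, zscl, "*"), 2L, zloc, "+")
    lapply(seq_len(B), function(i) {
      Zi <- Z[((i - 1L) * Tn + 1L):(i * Tn), , drop = FALSE]
      decode(mvae, latent_tokens_to_array(Zi, ncol(Zi), as.integer(sqrt(Tn))),
             perturbation_id = controls[[i]]$perturbation_id,
             plate_id = controls[[i]]$plate_id,
             noise_seed = derive_seed(seed, paste0("obs", i)))
    })
  })
  if (single) out[[1L]] else out
}
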