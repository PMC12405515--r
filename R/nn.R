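# Layer constructors and the Adam optimizer used by the bundled networks.
# A "module" is a plain nested list whose leaves are ag_param tensors;
# nn_params() flattens it for the optimizer.

nn_linear <- function(d_in, d_out, gain = 1) {
  sd <- gain * sqrt(2 / (d_in + d_out))
  list(W = ag_param(matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out)),
       b = ag_param(matrix(0, 1L, d_out)))
}

nn_apply_linear <- function(layer, x) ag_add(ag_matmul(x, layer$W), layer$b)

nn_layernorm <- function(d) {
  list(gamma = ag_param(matrix(1, 1L, d)), beta = ag_param(matrix(0, 1L, d)))
}

nn_apply_layernorm <- function(layer, x) ag_layernorm(x, layer$gamma, layer$beta)

nn_params <- function(module) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "ag_tensor")) {
      if (isTRUE(x$is_param)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(module)
  out
}

nn_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Serialize / restore parameter values (checkpoints are plain lists of
# numeric matrices, safe to keep in memory or write as text).
nn_state <- function(module) lapply(nn_params(module), function(p) p$value)

nn_load_state <- function(module, state) {
  params <- nn_params(module)
  stopifnot(length(params) == length(state))
  for (i in seq_along(params)) {
    stopifnot(identical(dim(params[[i]]$value), dim(state[[i]])))
    params[[i]]$value <- state[[i]]
  }
  invisible(module)
}

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       m = lapply(params, function(p) array(0, dim(p$value))),
       v = lapply(params, function(p) array(0, dim(p$value))),
       t = 0L)
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g^2
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    p$value <- p$value - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    p$grad <- NULL
  }
  opt
}

# Sinusoidal embedding of integer timesteps, rows = steps.
sinusoidal_embedding <- function(t, d) {
  half <- d %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / max(half - 1L, 1L))
  ang <- outer(t, freqs)
  emb <- cbind(sin(ang), cos(ang))
  if (ncol(emb) < d) emb <- cbind(emb, 0)
  emb
}

# Row-index matrix mapping an H x H single-channel image (column-major
# pixel rows within one image) to non-overlapping p x p patches, for a batch
# laid out as (B*H*H) rows. Returns (B * (H/p)^2) x (p*p) indices.
patch_index <- function(H, p, n_batch = 1L) {
  stopifnot(H %% p == 0L)
  hp <- H %/% p
  one <- matrix(0L, hp * hp, p * p)
  r <- 1L
  for (pc in seq_len(hp)) {     # patch column
    for (pr in seq_len(hp)) {   # patch row
      cols <- ((pc - 1L) * p + 1L):(pc * p)
      rows <- ((pr - 1L) * p + 1L):(pr * p)
      # column-major: pixel (i,j) -> (j-1)*H + i
      one[r, ] <- as.integer(outer(rows, (cols - 1L) * H, "+"))
      r <- r + 1L
    }
  }
  if (n_batch == 1L) return(one)
  do.call(rbind, lapply(seq_len(n_batch) - 1L, function(b) one + b * H * H))
}

# Token-grid merge: groups 2x2 neighbouring tokens of a g x g grid
# (column-major token order) into one row; (B*(g/2)^2) x 4 indices.
merge_index <- function(g, n_batch = 1L) {
  stopifnot(g %% 2L == 0L)
  patch_index(g, 2L, n_batch)
}
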