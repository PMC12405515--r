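# Noise schedule, exact forward process, conditioning and sampling.

test_that("schedule invariants hold and alpha_bar matches a brute-force product", {
  s1 <- make_schedule(T = 1, beta_min = 0.5, beta_max = 0.5)
  expect_equal(s1$alpha_bar, 0.5)
  s <- make_schedule(T = 1000)
  expect_true(all(s$alpha > 0 & s$alpha < 1))
  expect_true(all(diff(s$alpha_bar) < 0))
  expect_lt(s$alpha_bar[1000], 0.05)
  ab <- numeric(1000); acc <- 1
  for (t in 1:1000) { acc <- acc * s$alpha[t]; ab[t] <- acc }
  expect_equal(s$alpha_bar, ab, tolerance = 1e-12)
  expect_equal(s$sigma, sqrt(s$beta))
  expect_error(make_schedule(T = 0), "T must")
  expect_error(make_schedule(beta_min = 0), "beta")
})

test_that("q_sample is exact, attains both limits, and matches the recursive chain in distribution", {
  sched <- make_schedule(T = 50, beta_min = 2e-3, beta_max = 0.4)
  set.seed(71)
  z0 <- matrix(rnorm(8), 4, 2)
  eps <- matrix(rnorm(8), 4, 2)
  for (t in c(1, 25, 50)) {
    ab <- sched$alpha_bar[t]
    expect_equal(q_sample(z0, t, eps, sched), sqrt(ab) * z0 + sqrt(1 - ab) * eps,
                 tolerance = 1e-12)
  }
  # limits
  s_hi <- make_schedule(T = 1, beta_min = 1e-12, beta_max = 1e-12)
  expect_equal(q_sample(z0, 1, eps, s_hi), z0, tolerance = 1e-5)
  s_lo <- make_schedule(T = 400, beta_min = 0.5, beta_max = 0.5)
  expect_equal(q_sample(z0, 400, eps, s_lo), eps, tolerance = 1e-5)
  expect_error(q_sample(z0, 51, eps, sched), "out of range")

  # Monte-Carlo moments vs the step-by-step recursive chain, 1e4 draws
  z0s <- 0.7
  n <- 1e4
  for (t in c(1, 25, 50)) {
    closed <- vapply(1:n, function(i) q_sample(z0s, t, rnorm(1), sched), 0)
    recur <- rep(z0s, n)
    for (tt in 1:t) {
      recur <- sqrt(sched$alpha[tt]) * recur + sqrt(1 - sched$alpha[tt]) * rnorm(n)
    }
    se_mean <- sd(recur) / sqrt(n)
    expect_lt(abs(mean(closed) - mean(recur)), 3 * sqrt(2) * se_mean)
    se_var <- sd(recur^2) / sqrt(n)
    expect_lt(abs(var(closed) - var(recur)), 3 * sqrt(2) * se_var)
  }
})

test_that("training loss is zero for an oracle, near d for a zero model, and permutation invariant", {
  sched <- make_schedule(T = 50, beta_min = 2e-3, beta_max = 0.4)
  set.seed(72)
  z0 <- matrix(rnorm(16), 8, 2)
  l <- rnorm(4)
  eps <- matrix(rnorm(16), 8, 2)
  oracle <- local({
    e <- eps
    function(z, t, ls) e
  })
  expect_equal(training_loss(oracle, z0, l, 10, eps, sched), 0)
  zero_model <- function(z, t, ls) matrix(0, nrow(z), ncol(z))
  # E ||eps||^2 = d for standard normal eps
  d <- length(z0)
  losses <- vapply(1:1000, function(i) {
    e <- matrix(rnorm(d), nrow(z0))
    training_loss(zero_model, z0, l, sample(50, 1), e, sched)
  }, 0)
  expect_lt(abs(mean(losses) - d) / d, 0.05)
  # batch-order invariance: per-draw losses sum identically under row permutation
  e <- matrix(rnorm(d), nrow(z0))
  p <- sample(nrow(z0))
  expect_equal(training_loss(zero_model, z0, l, 7, e, sched),
               training_loss(zero_model, z0[p, ], l, 7, e[p, ], sched))
})

test_that("the condition encoder is a fixed seeded linear map", {
  l1 <- rnorm(64); l2 <- rnorm(64)
  c1 <- encode_condition(l1, seed = 5)
  expect_identical(unclass(c1), unclass(encode_condition(l1, seed = 5)))
  expect_equal(dim(c1), c(8L, 64L))
  expect_equal(unclass(encode_condition(rep(0, 64), seed = 5)),
               matrix(0, 8, 64), ignore_attr = TRUE)
  expect_equal(unclass(encode_condition(l1 + l2, seed = 5)),
               unclass(encode_condition(l1, seed = 5)) + unclass(encode_condition(l2, seed = 5)),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(unclass(encode_condition(l1, seed = 6)), unclass(c1))))
  expect_error(encode_condition(l1, G = 32), "length")
})

test_that("cross-attention rows are a proper softmax and match hand arithmetic", {
  set.seed(73)
  proj <- list(W_Q = diag(2), W_K = diag(2), W_V = diag(2))
  # single context token: output equals its V projection for every query
  ctx1 <- matrix(c(0.3, -1), 1, 2)
  out1 <- cross_attention(matrix(rnorm(8), 4, 2), ctx1, proj)
  expect_equal(out1$output, matrix(rep(ctx1, each = 4), 4, 2))
  expect_equal(rowSums(out1$weights), rep(1, 4), tolerance = 1e-6)

  # 2x2 hand computation
  Q <- matrix(c(1, 0, 0, 1), 2, 2); K <- matrix(c(1, 1, 0, 1), 2, 2)
  V <- matrix(c(2, 0, 0, 3), 2, 2)
  res <- cross_attention(Q, K, proj = list(W_Q = diag(2), W_K = diag(2), W_V = diag(2)))
  # manual: scores = Q %*% t(K) / sqrt(2), rows softmaxed, times V
  s <- Q %*% t(K) / sqrt(2)
  w <- exp(s) / rowSums(exp(s))
  expect_equal(res$output, w %*% K, tolerance = 1e-12)
  res2 <- cross_attention(Q, V, proj)
  s2 <- Q %*% t(V) / sqrt(2)
  w2 <- exp(s2) / rowSums(exp(s2))
  expect_equal(res2$output, w2 %*% V, tolerance = 1e-12)
  expect_error(cross_attention(Q, matrix(1, 2, 3), proj), "dimensions")
})

test_that("ancestral sampling is seeded-deterministic with the T=1 closed form", {
  s1 <- make_schedule(T = 1, beta_min = 0.3, beta_max = 0.3)
  zero_model <- function(z, t, ls) matrix(0, nrow(z), ncol(z))
  draws <- vapply(1:5000, function(i) {
    ddpm_sample(zero_model, l = NULL, n = 1, seed = i, schedule = s1,
                shape = c(1L, 1L))[[1]][1, 1]
  }, 0)
  # z0 = z1 / sqrt(alpha_1) with z1 ~ N(0,1): variance 1/alpha
  expect_equal(var(draws), 1 / 0.7, tolerance = 0.1)
  s <- make_schedule(T = 20, beta_min = 0.01, beta_max = 0.3)
  a <- ddpm_sample(zero_model, NULL, n = 2, seed = 42, schedule = s, shape = c(4L, 2L))
  b <- ddpm_sample(zero_model, NULL, n = 2, seed = 42, schedule = s, shape = c(4L, 2L))
  expect_identical(a, b)
  c <- ddpm_sample(zero_model, NULL, n = 2, seed = 43, schedule = s, shape = c(4L, 2L))
  expect_false(identical(a, c))
})

test_that("the alternative one-minus-root sampler denominator is available and differs from the default", {
  cfg_d <- ldm_config(latent_channels = 2, grid = 1, levels = 1, d_model = 16,
                      n_blocks = 1, n_tokens_ctx = 2, context_dim = 8, T = 10)
  m <- ldm_init(cfg_d, G = 4, seed = 2)
  za <- ddpm_sample(m, rep(0.5, 4), n = 1, seed = 7, denominator = "ddpm")
  zb <- ddpm_sample(m, rep(0.5, 4), n = 1, seed = 7, denominator = "one-minus-root")
  expect_false(identical(za, zb))
})

test_that("sdedit is seeded-deterministic and reduces to reconstruction at vanishing strength with an oracle denoiser", {
  ds <- fixture_dataset()
  control <- ds$images[[which(ds$manifest$perturbation_id == "DMSO")[1]]]
  mv <- mvae_init(mvae_config(), seed = 8)
  sched <- make_schedule(T = 50, beta_min = 2e-3, beta_max = 0.4)
  z0 <- perturbdiff:::latent_array_to_tokens(encode(mv, control)$mean)
  oracle <- function(z, t, ls) {
    (z - sqrt(sched$alpha_bar[t]) * z0) / sqrt(1 - sched$alpha_bar[t])
  }
  out <- sdedit_transform(control, rep(0, 64), strength = 1 / 50, oracle, mv,
                          seed = 3, schedule = sched)
  recon <- decode(mv, encode(mv, control)$mean)
  roundtrip_err <- mean(abs(recon$channels - control$channels))
  expect_lt(mean(abs(out$channels - control$channels)), roundtrip_err + 0.02)
  out2 <- sdedit_transform(control, rep(0, 64), strength = 1 / 50, oracle, mv,
                           seed = 3, schedule = sched)
  expect_identical(out$channels, out2$channels)
  expect_error(sdedit_transform(control, rep(0, 64), 0, oracle, mv, schedule = sched),
               "strength")
})
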