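# Morphology VAE: closed-form KL, perceptual loss contracts, shape and
# determinism contracts of encode/decode, and a short training run.

test_that("kl_reg matches closed forms and a Monte-Carlo log-density-ratio oracle", {
  expect_equal(kl_reg(rep(0, 6), rep(0, 6)), 0)
  m <- c(0.5, -1, 2)
  expect_equal(kl_reg(m, rep(0, 3)), 0.5 * sum(m^2))
  expect_equal(kl_reg(rep(0, 4), rep(log(4), 4)), 4 * 0.5 * (4 - 1 - log(4)))
  expect_error(kl_reg(c(1, NaN), c(0, 0)), "finite")

  set.seed(61)
  for (rep in 1:3) {
    mu <- rnorm(2); lv <- rnorm(2, sd = 0.5)
    z <- matrix(rnorm(2e5), ncol = 2)
    z <- sweep(sweep(z, 2, exp(lv / 2), "*"), 2, mu, "+")
    logq <- colSums(dnorm(t(z), mu, exp(lv / 2), log = TRUE))
    logp <- colSums(dnorm(t(z), 0, 1, log = TRUE))
    mc <- mean(logq - logp)
    expect_equal(kl_reg(mu, lv), mc, tolerance = 0.02 * max(1, abs(mc)))
  }
})

test_that("lpips_5ch is zero on identical inputs, channel-permutation invariant, and exact for an identity extractor", {
  ds <- fixture_dataset()
  x <- ds$images[[1]]; y <- ds$images[[15]]
  ex <- perceptual_extractor(32, seed = 7)
  expect_equal(lpips_5ch(x, x, ex), 0)
  v <- lpips_5ch(x, y, ex)
  expect_gt(v, 0)

  # permuting channel order of both images identically leaves the value
  # unchanged (unweighted channel mean)
  perm <- c(3, 1, 5, 2, 4)
  px <- morph_image(x$channels[, , perm][, , order(perm)])  # identity check helper
  expect_equal(lpips_5ch(px, morph_image(y$channels), ex), v)
  xp <- x$channels[, , perm]; dimnames(xp)[[3]] <- pd_channels
  yp <- y$channels[, , perm]; dimnames(yp)[[3]] <- pd_channels
  expect_equal(lpips_5ch(morph_image(xp), morph_image(yp), ex), v, tolerance = 1e-12)

  # 1-layer identity extractor: value = mean over channels of MSE summed
  # over pixels of a normalized map; with features = raw pixels and w = 1,
  # d_i = sum_l (1/HW) * sum |diff|^2 = mean squared pixel difference * C
  idext <- list(n_layers = 1L, weights = list(1),
                forward = function(arr) list(arr[, , 1, drop = FALSE]))
  a <- x$channels; b <- y$channels
  expected <- mean(vapply(1:5, function(c) mean((a[, , c] - b[, , c])^2), 0))
  expect_equal(lpips_5ch(x, y, idext), expected, tolerance = 1e-12)
})

test_that("encode/decode respect shapes, determinism and the squashing contract", {
  m <- mvae_init(mvae_config(H = 32, patch = 4), seed = 5)
  ds <- fixture_dataset()
  img <- ds$images[[3]]
  c1 <- encode(m, img, seed = 9)
  c2 <- encode(m, img, seed = 9)
  expect_identical(c1$mean, c2$mean)     # deterministic posterior
  expect_identical(c1$z, c2$z)           # seeded draw
  c3 <- encode(m, img, seed = 10)
  expect_false(identical(c1$z, c3$z))    # stochastic under a new seed
  expect_equal(c1$shape, c(32, 8, 8))    # H = 32, factor 4 -> 8 x 8 spatial
  expect_equal(c1$z, c1$mean + exp(c1$logvar / 2) * ((c1$z - c1$mean) / exp(c1$logvar / 2)))

  wrong <- morph_image(array(0.1, c(16, 16, 5)))
  expect_error(encode(m, wrong), "size")

  set.seed(62)
  z <- array(rnorm(32 * 8 * 8, sd = 3), c(32, 8, 8))
  out <- decode(m, z)
  expect_s3_class(out, "morph_image")
  expect_gte(min(out$channels), 0)
  expect_lte(max(out$channels), 1)
  expect_identical(decode(m, z)$channels, out$channels)
  expect_error(decode(m, array(0, c(4, 4, 4))), "latent shape")
})

test_that("a short VAE-only run reduces reconstruction error and the discriminator starts uninformed", {
  ds <- fixture_dataset()
  cfg <- mvae_config(lambda_adv = 0, lambda_lpips = 0, adv_warmup = 0)
  m <- mvae_init(cfg, seed = 3)

  # an untrained discriminator is uninformed: on two exchangeable halves
  # of the same real batch its real-vs-fake accuracy is chance
  cfg2 <- mvae_config(adv_warmup = 0, lambda_adv = 0.5)
  m2 <- mvae_init(cfg2, seed = 4)
  Xa <- perturbdiff:::images_to_patches(ds$images[1:8], cfg2$disc_patch)
  Xb <- perturbdiff:::images_to_patches(ds$images[9:16], cfg2$disc_patch)
  perturbdiff:::ag_tape_reset()
  la <- perturbdiff:::disc_forward(m2, perturbdiff:::ag_const(Xa))$value
  lb <- perturbdiff:::disc_forward(m2, perturbdiff:::ag_const(Xb))$value
  acc0 <- (mean(la > 0) + mean(lb < 0)) / 2
  expect_true(abs(acc0 - 0.5) < 0.35)
  r0 <- mvae_step(m2, ds$images[1:16], seed = 1)
  expect_true(all(r0$losses[c("L_rec", "L_adv_gen", "L_adv_disc", "L_reg", "L_lpips")] >= 0))

  res <- train_mvae(m, ds$images, steps = 200, batch_size = 16, seed = 6)
  early <- mean(res$history[1:20, "L_rec"])
  late <- mean(res$history[181:200, "L_rec"])
  expect_lt(late, 0.5 * early)

  # held-out round trip beats the untrained model
  m_untrained <- mvae_init(cfg, seed = 99)
  test_imgs <- ds$images[seq(1, length(ds$images), by = 10)]
  err <- function(model) {
    mean(vapply(test_imgs, function(im) {
      mean(abs(decode(model, encode(model, im)$mean)$channels - im$channels))
    }, 0))
  }
  expect_lt(err(res$model), 0.5 * err(m_untrained))
})

test_that("perfect reconstruction and standard-normal posterior give zero losses", {
  expect_equal(kl_reg(matrix(0, 2, 2), matrix(0, 2, 2)), 0)
  ds <- fixture_dataset()
  x <- ds$images[[1]]
  expect_equal(mean(abs(x$channels - x$channels)), 0)
})
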