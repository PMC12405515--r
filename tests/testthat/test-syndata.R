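# Synthetic data generator: determinism, planted MOA structure, rendering
# contracts and split rules.

test_that("generate_panel is deterministic and respects minimal inputs", {
  p1 <- generate_panel(1, 1, G = 16, seed = 0)
  expect_length(p1$programs, 2L)  # one perturbation + control
  expect_true(p1$programs[[2]]$is_control)
  expect_equal(ncol(p1$expression), 16L)
  p2 <- generate_panel(1, 1, G = 16, seed = 0)
  expect_identical(p1, p2)
  expect_error(generate_panel(0, 1), "n_perturbations")
  expect_error(generate_panel(4, 5), "n_moas")
})

test_that("drugs sharing an MOA have more correlated effect vectors than drugs that do not", {
  panel <- generate_panel(20, 5, G = 64, seed = 7)
  progs <- Filter(function(p) !p$is_control, panel$programs)
  effs <- vapply(progs, function(p) p$effect_vector, numeric(18))
  moa <- vapply(progs, function(p) p$moa_labels[1], "")
  C <- stats::cor(effs)
  within <- c(); between <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    if (moa[i] == moa[j]) within <- c(within, C[i, j]) else between <- c(between, C[i, j])
  }
  expect_gt(mean(within), mean(between))
})

test_that("expression is an informative linear readout of the effect vector", {
  # ridge probe from expression to each effect component, held-out R^2
  panel <- generate_panel(100, 10, G = 64, seed = 21)
  progs <- Filter(function(p) !p$is_control, panel$programs)
  E <- panel$expression[vapply(progs, function(p) p$perturbation_id, ""), ]
  Y <- t(vapply(progs, function(p) p$effect_vector, numeric(18)))
  tr <- 1:70; te <- 71:100
  Xc <- scale(E[tr, ], scale = FALSE)
  sv <- svd(Xc)
  lam <- 1
  r2s <- vapply(1:18, function(k) {
    yc <- Y[tr, k] - mean(Y[tr, k])
    beta <- sv$v %*% ((sv$d / (sv$d^2 + lam)) * crossprod(sv$u, yc))
    pred <- scale(E[te, ], center = colMeans(E[tr, ]), scale = FALSE) %*% beta + mean(Y[tr, k])
    r2_score(Y[te, k], as.vector(pred))
  }, 0)
  expect_gt(mean(r2s), 0.8)
})

test_that("rendering is deterministic, clipped, and responds to intensity shifts", {
  pr <- random_program("px", seed = 5)
  i1 <- render_image(pr, H = 32, plate_id = "plate_2", seed = 9)
  i2 <- render_image(pr, H = 32, plate_id = "plate_2", seed = 9)
  expect_identical(i1, i2)
  expect_gte(min(i1$channels), 0)
  expect_lte(max(i1$channels), 1)
  expect_error(render_image(pr, H = 8), "H must be")

  # Monte-Carlo: +0.3 Mito intensity shift moves the Mito channel mean by
  # 0.3 within 0.05
  base <- fixture_panel()$programs[[9]]  # control
  eff <- base$effect_vector; eff["int_Mito"] <- 0.3
  shifted <- perturbation_program(base$perturbation_id, eff, "m", is_control = FALSE)
  m0 <- mean(vapply(1:200, function(s) mean(render_image(base, 32, seed = s)$channels[, , "Mito"]), 0))
  m1 <- mean(vapply(1:200, function(s) mean(render_image(shifted, 32, seed = s)$channels[, , "Mito"]), 0))
  expect_lt(abs((m1 - m0) - 0.3), 0.05)
})

test_that("splits follow the ceiling-10 percent rule and partition the panel", {
  ids <- sprintf("p%02d", 1:10)
  sp <- split_spec(ids, ood_fraction = 0.10, id_fraction = 0.10, seed = 4)
  expect_length(sp$ood_ids, 1L)  # ceiling(0.1 * 10)
  expect_setequal(c(sp$train_ids, sp$id_ids, sp$ood_ids), ids)
  expect_length(intersect(sp$train_ids, sp$ood_ids), 0L)
  expect_length(intersect(sp$id_ids, sp$ood_ids), 0L)
  expect_identical(sp, split_spec(ids, seed = 4))
  expect_error(split_spec(ids[1:2]), "at least 3")
})

test_that("make_dataset labels every image and keeps control out of the OOD pool", {
  ds <- fixture_dataset()
  expect_equal(nrow(ds$manifest), length(ds$images))
  expect_setequal(unique(ds$manifest$role), c("train", "id", "ood", "control"))
  expect_false("DMSO" %in% c(ds$split$train_ids, ds$split$id_ids, ds$split$ood_ids))
  got <- vapply(ds$images, function(i) i$perturbation_id, "")
  expect_identical(got, ds$manifest$perturbation_id)
})

test_that("control-to-perturbation feature distance grows with effect-vector norm", {
  ds <- fixture_dataset()
  enc <- encoder_features()
  ctrl <- colMeans(enc$embed(ds$images[ds$manifest$perturbation_id == "DMSO"]))
  progs <- Filter(function(p) !p$is_control, fixture_panel()$programs)
  norms <- vapply(progs, function(p) sqrt(sum(p$effect_vector^2)), 0)
  dists <- vapply(progs, function(p) {
    f <- colMeans(enc$embed(ds$images[ds$manifest$perturbation_id == p$perturbation_id]))
    sqrt(sum((f - ctrl)^2))
  }, 0)
  expect_gt(cor(norms, dists, method = "spearman"), 0)
})
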