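# Distribution metrics against closed forms and independent brute-force
# oracles.

test_that("Frechet distance matches closed forms", {
  set.seed(41)
  E <- matrix(rnorm(200 * 3), 200, 3)
  expect_lt(frechet_distance(E, E), 1e-8)
  v <- c(1, -2, 0.5)
  expect_equal(frechet_distance(E, sweep(E, 2, v, "+")), sum(v^2), tolerance = 1e-8)
  # 1-D Gaussians N(0,1) vs N(1,4): (0-1)^2 + (1 + 4 - 2*2) = 2
  A <- matrix(rnorm(1e5, 0, 1)); B <- matrix(rnorm(1e5, 1, 2))
  expect_equal(frechet_distance(A, B), 2, tolerance = 0.1)
  expect_error(frechet_distance(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "shrinkage")
})

test_that("inception score matches limits and a double-loop oracle", {
  expect_equal(inception_score(matrix(0.25, 10, 4)), 1)
  onehot <- diag(4)[rep(1:4, 3), ]
  expect_equal(inception_score(onehot), 4)
  set.seed(42)
  P <- matrix(rexp(40), 10, 4); P <- P / rowSums(P)
  # independent loop oracle
  py <- colMeans(P)
  kl <- 0
  for (i in 1:10) for (j in 1:4) kl <- kl + P[i, j] * (log(P[i, j]) - log(py[j])) / 10
  expect_equal(inception_score(P), exp(kl), tolerance = 1e-10)
  expect_error(inception_score(P * 2), "sum to 1")
})

test_that("density and coverage match the identity case and a brute-force membership oracle", {
  set.seed(43)
  E <- matrix(rnorm(60), 30, 2)
  dc <- density_coverage(E, E, k = 5)
  expect_equal(dc$density, 6 / 5, tolerance = 1e-12)
  expect_equal(dc$coverage, 1)

  G <- matrix(rnorm(60) + 100, 30, 2)  # far from every ball
  dc_far <- density_coverage(E, G, k = 5)
  expect_equal(dc_far$density, 0)
  expect_equal(dc_far$coverage, 0)

  Eg <- matrix(rnorm(60), 30, 2)
  dc2 <- density_coverage(E, Eg, k = 4)
  # O(N^2) oracle
  radius <- vapply(1:30, function(i) {
    d <- sqrt(colSums((t(E) - E[i, ])^2)); sort(d)[5]
  }, 0)
  member <- matrix(FALSE, 30, 30)
  for (i in 1:30) for (j in 1:30) {
    member[i, j] <- sqrt(sum((E[i, ] - Eg[j, ])^2)) <= radius[i]
  }
  expect_equal(dc2$density, sum(member) / (4 * 30), tolerance = 1e-10)
  expect_equal(dc2$coverage, mean(rowSums(member) > 0), tolerance = 1e-10)
  expect_error(density_coverage(E[1:4, ], Eg, k = 5), "smaller")
})

test_that("MMD matches a brute-force three-term double sum and separates clusters", {
  X <- matrix(1, 4, 2)
  expect_equal(mmd_cmmd(X, X, bandwidth = 1), 0)
  set.seed(44)
  A <- matrix(rnorm(16), 8, 2); B <- matrix(rnorm(14), 7, 2)
  h <- 1.3
  k <- function(x, y) exp(-sum((x - y)^2) / (2 * h^2))
  t1 <- 0; for (i in 1:8) for (j in 1:8) if (i != j) t1 <- t1 + k(A[i, ], A[j, ])
  t2 <- 0; for (i in 1:7) for (j in 1:7) if (i != j) t2 <- t2 + k(B[i, ], B[j, ])
  t3 <- 0; for (i in 1:8) for (j in 1:7) t3 <- t3 + k(A[i, ], B[j, ])
  oracle <- t1 / (8 * 7) + t2 / (7 * 6) - 2 * t3 / (8 * 7)
  expect_equal(mmd_cmmd(A, B, bandwidth = h), oracle, tolerance = 1e-12)
  expect_equal(mmd_cmmd(A, B, bandwidth = h), mmd_cmmd(B, A, bandwidth = h))
  # two unit-separated tight clusters exceed the same-distribution value
  C1 <- matrix(rnorm(40, sd = 0.05), 20, 2)
  C2 <- sweep(matrix(rnorm(40, sd = 0.05), 20, 2), 2, c(1, 0), "+")
  expect_gt(mmd_cmmd(C1, C2, bandwidth = 1), mmd_cmmd(C1, C1[sample(20), ], bandwidth = 1))
  expect_error(mmd_cmmd(A, B, bandwidth = -1), "bandwidth")
})

test_that("R^2 and Pearson match hand arithmetic and degenerate rules", {
  y <- c(1, 2, 3)
  expect_equal(r2_score(y, y), 1)
  expect_equal(r2_score(y, rep(mean(y), 3)), 0)
  expect_equal(r2_score(y, c(1, 2, 4)), 0.5)
  expect_error(r2_score(c(1, 1, 1), y), "constant")

  expect_equal(pearson_cor(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_cor(1:5, -(1:5)), -1)
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_cor(c(1, 1), c(1, 2)), "constant")
})

test_that("exact Wasserstein matches trivial cases and the 1-D sorted-matching oracle", {
  set.seed(45)
  A <- matrix(rnorm(20), 10, 2)
  expect_lt(wasserstein_set(A, A), 1e-8)
  expect_equal(wasserstein_set(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 5)
  a <- rnorm(4); b <- rnorm(4)
  expect_equal(wasserstein_set(a, b), mean(abs(sort(a) - sort(b))), tolerance = 1e-12)
  # unequal sizes: lcm-grid quantile-coupling oracle in 1-D
  for (rep in 1:10) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    L <- length(a) * length(b)
    qa <- rep(sort(a), each = L / length(a)); qb <- rep(sort(b), each = L / length(b))
    expect_equal(wasserstein_set(a, b), mean(abs(qa - qb)), tolerance = 1e-9)
  }
  # metric axioms spot checks
  B <- matrix(rnorm(20), 10, 2); C <- matrix(rnorm(20), 10, 2)
  wab <- wasserstein_set(A, B); wbc <- wasserstein_set(B, C); wac <- wasserstein_set(A, C)
  expect_equal(wab, wasserstein_set(B, A), tolerance = 1e-12)
  expect_lte(wac, wab + wbc + 1e-9)
})

test_that("F1 over significance flags matches the confusion-matrix formula", {
  expect_equal(f1_significant(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)), 1)
  # TP=2, FP=1, FN=1 -> 4/6
  gt <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  gen <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(f1_significant(gt, gen), 2 * 2 / (2 * 2 + 1 + 1))
  set.seed(46)
  for (rep in 1:10) {
    a <- runif(30) < 0.4; b <- runif(30) < 0.4
    tp <- sum(a & b); fp <- sum(!a & b); fn <- sum(a & !b)
    if (tp + fp + fn == 0) next
    expect_equal(f1_significant(a, b), 2 * tp / (2 * tp + fp + fn))
  }
  expect_warning(v <- f1_significant(c(FALSE, FALSE), c(FALSE, FALSE)), "defined as 1")
  expect_equal(v, 1)
})

test_that("metrics are invariant to row permutation of their inputs", {
  set.seed(47)
  A <- matrix(rnorm(40), 20, 2); B <- matrix(rnorm(30), 15, 2)
  pa <- sample(20); pb <- sample(15)
  expect_equal(mmd_cmmd(A, B), mmd_cmmd(A[pa, ], B[pb, ]))
  expect_equal(frechet_distance(A, B), frechet_distance(A[pa, ], B[pb, ]), tolerance = 1e-10)
  expect_equal(density_coverage(A, B, 3), density_coverage(A[pa, ], B[pb, ], 3))
  expect_equal(wasserstein_set(A, B), wasserstein_set(A[pa, ], B[pb, ]), tolerance = 1e-9)
})
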