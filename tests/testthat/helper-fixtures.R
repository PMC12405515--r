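# Shared fixtures, built in code and memoized for the duration of one
# test run so expensive objects (panels, small trained models) are
# constructed once.

.fix <- new.env(parent = emptyenv())

fixture_panel <- function() {
  if (is.null(.fix$panel)) .fix$panel <- generate_panel(8, 4, G = 64, seed = 3)
  .fix$panel
}

fixture_dataset <- function() {
  if (is.null(.fix$ds)) {
    .fix$ds <- make_dataset(fixture_panel(), images_per_perturbation = 12, seed = 2)
  }
  .fix$ds
}

# numeric gradient of a scalar-valued function of one array
numeric_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

random_program <- function(id = "p1", seed = 1, moa = "moa_x") {
  b <- perturbdiff:::effect_bounds()
  eff <- perturbdiff:::with_seed(seed, stats::runif(length(b$lo), 0.5 * b$lo, 0.5 * b$hi))
  names(eff) <- perturbdiff:::effect_names()
  perturbation_program(id, eff, moa)
}
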