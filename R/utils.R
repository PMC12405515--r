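# Shared helpers: argument checks, seeded RNG scoping, deterministic seed
# fan-out, and conversions between image and patch-token layouts.

pd_assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Canonical Cell Painting channel names
#'
#' The five stains, in the fixed order used throughout the package:
#' DNA (Hoechst), ER (concanavalin A), RNA (SYTO 14), AGP (WGA/phalloidin,
#' Golgi and plasma membrane plus actin) and Mito (MitoTracker).
#'
#' @export
pd_channels <- c("DNA", "ER", "RNA", "AGP", "Mito")

# Evaluate code under a given RNG seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage seed from a global seed
#'
#' One experiment-level seed fans out deterministically to every stage
#' (data simulation, model initialization, training, sampling, splits) so
#' that no step consumes unseeded randomness. The derivation hashes the
#' stage name onto the global seed and reduces modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  pd_assert(is.numeric(seed) && length(seed) == 1L, "seed must be a single number")
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 69069 + h * 30269 + 101) %% (2^31 - 1))
}

#' Construct a five-channel morphology image
#'
#' @param channels numeric array `H x W x 5` with values in `[0,1]`, third
#'   dimension named with [pd_channels], or a named list of five `H x W`
#'   matrices.
#' @param perturbation_id character id of the perturbation applied.
#' @param plate_id character plate label (nuisance covariate).
#' @return an object of class `morph_image`.
#' @export
morph_image <- function(channels, perturbation_id = "unknown", plate_id = "plate_1") {
  if (is.list(channels)) {
    pd_assert(all(pd_channels %in% names(channels)), "missing channel(s)")
    channels <- simplify2array(channels[pd_channels])
  }
  pd_assert(is.array(channels) && length(dim(channels)) == 3L && dim(channels)[3L] == 5L,
            "channels must be an H x W x 5 array")
  pd_assert(dim(channels)[1L] == dim(channels)[2L], "image must be square (H = W)")
  pd_assert(all(is.finite(channels)), "non-finite pixel values")
  pd_assert(min(channels) >= 0 && max(channels) <= 1, "pixel values must lie in [0,1]")
  dimnames(channels) <- list(NULL, NULL, pd_channels)
  structure(list(channels = channels,
                 perturbation_id = as.character(perturbation_id),
                 plate_id = as.character(plate_id)),
            class = "morph_image")
}

#' @export
print.morph_image <- function(x, ...) {
  H <- dim(x$channels)[1L]
  cat(sprintf("<morph_image %dx%dx5 perturbation=%s plate=%s>\n",
              H, H, x$perturbation_id, x$plate_id))
  invisible(x)
}

image_size <- function(image) dim(image$channels)[1L]

# Stack a list of morph_image into an array B x H x W x 5.
images_to_array <- function(images) {
  pd_assert(length(images) >= 1L, "empty image list")
  H <- image_size(images[[1L]])
  pd_assert(all(vapply(images, image_size, 1L) == H), "heterogeneous image sizes")
  arr <- array(0, c(length(images), H, H, 5L))
  for (b in seq_along(images)) arr[b, , , ] <- images[[b]]$channels
  arr
}

# (B*T) x (5*p*p) patch-token matrix; tokens column-major over the patch
# grid, batch-blocked; within a token, channels are contiguous blocks of
# p*p pixels in column-major order.
images_to_patches <- function(images, p) {
  H <- image_size(images[[1L]])
  pidx <- patch_index(H, p, 1L)
  Tn <- nrow(pidx); pp <- p * p
  X <- matrix(0, length(images) * Tn, 5L * pp)
  for (b in seq_along(images)) {
    rows <- ((b - 1L) * Tn + 1L):(b * Tn)
    ch <- images[[b]]$channels
    for (c in 1:5) {
      v <- as.vector(ch[, , c])
      X[rows, ((c - 1L) * pp + 1L):(c * pp)] <- matrix(v[pidx], Tn, pp)
    }
  }
  X
}



clip01 <- function(x) pmin(pmax(x, 0), 1)

# Squared Euclidean cross-distance matrix between row sets.
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}
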