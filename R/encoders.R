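# Pluggable image encoders for the distribution-level metrics. The
# built-in options are (i) the interpretable feature vector and (ii) a
# multinomial logistic classifier trained on those features over the
# synthetic perturbation classes, which supplies class probabilities for
# inception-style scoring. External encoders (e.g. network embeddings
# exported to CSV) can be wrapped in the same interface.

# Raw (unfiltered) feature embedding; fixed 40 columns so that real and
# generated sets are always comparable.
embed_features <- function(images) {
  t(vapply(images, feature_row, feature_row(images[[1L]])))
}

#' Built-in feature encoder
#'
#' @return object of class `encoder_spec` with an `$embed(images)`
#'   function returning one embedding row per image.
#' @export
encoder_features <- function() {
  structure(list(id = "builtin-feature",
                 embed = function(images) {
                   M <- embed_features(images)
                   M[!is.finite(M)] <- 0
                   M
                 },
                 probs = NULL),
            class = "encoder_spec")
}

#' Built-in classifier encoder
#'
#' Trains a multinomial logistic classifier (via `nnet::multinom`) from
#' built-in features to perturbation labels; its class-probability output
#' feeds [inception_score] and its logit layer doubles as an embedding.
#'
#' @param images training images.
#' @param labels perturbation label per image.
#' @param seed integer seed.
#' @return an `encoder_spec` with `$embed` and `$probs`.
#' @export
encoder_classifier <- function(images, labels, seed = 1) {
  X <- embed_features(images)
  X[!is.finite(X)] <- 0
  mu <- colMeans(X); sg <- apply(X, 2L, stats::sd); sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sg, "/")
  df <- data.frame(Xs, y = factor(labels))
  fit <- with_seed(derive_seed(seed, "clf_encoder"), {
    nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 200, MaxNWts = 5000)
  })
  prep <- function(images) {
    M <- embed_features(images)
    M[!is.finite(M)] <- 0
    data.frame(sweep(sweep(M, 2L, mu, "-"), 2L, sg, "/"))
  }
  structure(list(id = "builtin-classifier",
                 embed = function(images) {
                   p <- as.matrix(stats::predict(fit, prep(images), type = "probs"))
                   if (ncol(p) == 1L) p <- cbind(p, 1 - p)
                   log(pmax(p, 1e-12))
                 },
                 probs = function(images) {
                   p <- as.matrix(stats::predict(fit, prep(images), type = "probs"))
                   if (ncol(p) == 1L) p <- cbind(1 - p, p)
                   p / rowSums(p)
                 }),
            class = "encoder_spec")
}
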