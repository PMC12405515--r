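# CellProfiler-style interpretable features for five-channel images:
# per-channel intensity statistics, multi-scale granularity (morphological
# opening residuals), a texture proxy (local gradient energy) and all ten
# pairwise channel correlations. This is a deliberately small (~40 column)
# test surrogate for CellProfiler output; genuine CellProfiler CSVs can be
# imported into the same container with import_feature_csv().

#' Compose a five-channel image to RGB
#'
#' Channel composition weights: R = ER + 0.5 Mito + 0.5 AGP,
#' G = RNA + 0.5 Mito, B = DNA + 0.5 AGP, clipped to `[0, 1]`.
#'
#' @param image a [morph_image].
#' @return `H x W x 3` array (R, G, B).
#' @export
compose_rgb <- function(image) {
  pd_assert(inherits(image, "morph_image"), "image must be a morph_image")
  ch <- image$channels
  pd_assert(all(pd_channels %in% dimnames(ch)[[3L]]), "missing channel")
  out <- array(0, c(dim(ch)[1L], dim(ch)[2L], 3L))
  out[, , 1L] <- ch[, , "ER"] + 0.5 * ch[, , "Mito"] + 0.5 * ch[, , "AGP"]
  out[, , 2L] <- ch[, , "RNA"] + 0.5 * ch[, , "Mito"]
  out[, , 3L] <- ch[, , "DNA"] + 0.5 * ch[, , "AGP"]
  clip01(out)
}

# 3x3 grayscale erosion / dilation with replicate padding.
shift_pad <- function(m, di, dj) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + di, 1L), H)
  rj <- pmin(pmax(seq_len(W) + dj, 1L), W)
  m[ri, rj, drop = FALSE]
}

erode3 <- function(m) {
  out <- m
  for (di in -1:1) for (dj in -1:1) out <- pmin(out, shift_pad(m, di, dj))
  out
}

dilate3 <- function(m) {
  out <- m
  for (di in -1:1) for (dj in -1:1) out <- pmax(out, shift_pad(m, di, dj))
  out
}

# Grayscale opening with a (2s+1)x(2s+1) square structuring element.
gray_opening <- function(m, s) {
  e <- m
  for (i in seq_len(s)) e <- erode3(e)
  for (i in seq_len(s)) e <- dilate3(e)
  e
}

# Mean gradient energy (forward differences).
gradient_energy <- function(m) {
  dx <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
  dy <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  (sum(dx^2) + sum(dy^2)) / length(m)
}

feature_row <- function(image) {
  ch <- image$channels
  vals <- c()
  for (c in pd_channels) {
    m <- ch[, , c]
    vals <- c(vals,
              stats::setNames(c(mean(m), stats::sd(m),
                                stats::quantile(m, 0.25, names = FALSE)),
                              paste0(c("Int_Mean_", "Int_SD_", "Int_LQ_"), c)))
    for (s in 1:2) {
      vals <- c(vals, stats::setNames(mean(m - gray_opening(m, s)),
                                      paste0("Gran_Scale", s, "_", c)))
    }
    vals <- c(vals, stats::setNames(gradient_energy(m), paste0("Tex_GradEnergy_", c)))
  }
  pairs <- utils::combn(pd_channels, 2L)
  for (k in seq_len(ncol(pairs))) {
    a <- ch[, , pairs[1L, k]]; b <- ch[, , pairs[2L, k]]
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
         else stats::cor(as.vector(a), as.vector(b))
    vals <- c(vals, stats::setNames(r, paste0("Corr_", pairs[1L, k], "_", pairs[2L, k])))
  }
  vals
}

#' Construct a feature matrix
#'
#' Columns with any non-finite value or zero variance are removed on
#' construction (mirroring the usual screening-pipeline filter); the
#' dropped names are kept in `attr(, "dropped")`.
#'
#' @param X numeric matrix with unique column names (rows = images).
#' @param extractor_id provenance label.
#' @return object of class `feature_matrix` (a matrix with attributes).
#' @export
feature_matrix <- function(X, extractor_id = "builtin") {
  pd_assert(is.matrix(X) && !is.null(colnames(X)), "X must be a matrix with column names")
  pd_assert(!anyDuplicated(colnames(X)), "feature names must be unique")
  bad <- vapply(seq_len(ncol(X)), function(j) {
    any(!is.finite(X[, j])) || (nrow(X) > 1L && stats::var(X[, j]) == 0)
  }, TRUE)
  dropped <- colnames(X)[bad]
  X <- X[, !bad, drop = FALSE]
  structure(X, class = c("feature_matrix", "matrix", "array"),
            extractor_id = extractor_id, dropped = dropped)
}

#' Extract built-in morphological features from images
#'
#' Per channel: intensity mean, standard deviation and lower quartile;
#' granularity proxies (mean residual of grayscale morphological opening
#' with 3x3 and 5x5 structuring elements); texture proxy (mean squared
#' local gradient); plus the ten pairwise channel Pearson correlations.
#' Deterministic; 40 raw columns before the NaN / zero-variance filter.
#'
#' @param images non-empty list of [morph_image] with a common size.
#' @return a [feature_matrix].
#' @export
extract_features <- function(images) {
  pd_assert(is.list(images) && length(images) >= 1L, "non-empty image list required")
  H <- image_size(images[[1L]])
  pd_assert(all(vapply(images, image_size, 1L) == H), "heterogeneous image shapes")
  rows <- t(vapply(images, feature_row, feature_row(images[[1L]])))
  feature_matrix(rows, extractor_id = "builtin")
}

#' Import an external feature CSV (e.g. CellProfiler output)
#'
#' Numeric columns are passed through verbatim into a [feature_matrix]
#' (same NaN / zero-variance filter).
#'
#' @param path CSV path; non-numeric columns are ignored.
#' @return a [feature_matrix].
#' @export
import_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  num <- vapply(df, is.numeric, TRUE)
  feature_matrix(as.matrix(df[, num, drop = FALSE]), extractor_id = "import")
}

#' Select perturbation-discriminative features by random-forest importance
#'
#' Trains a random forest classifier (default 100 trees) predicting the
#' perturbation label from features and returns the `n_top` features with
#' the highest mean decrease in Gini impurity.
#'
#' @param F a [feature_matrix] (or plain matrix with column names).
#' @param labels class label per row (>= 2 classes).
#' @param n_top number of features to return (<= number of columns).
#' @param n_estimators number of trees.
#' @param seed integer seed (ranking is deterministic given the seed).
#' @return character vector of feature names, most important first.
#' @export
select_discriminative <- function(F, labels, n_top = 10, n_estimators = 100, seed = 1) {
  labels <- factor(labels)
  pd_assert(nlevels(labels) >= 2L, "need at least 2 classes")
  pd_assert(n_top <= ncol(F), "n_top exceeds number of features")
  fit <- with_seed(derive_seed(seed, "rf_importance"),
                   randomForest::randomForest(x = as.matrix(F), y = labels,
                                              ntree = n_estimators))
  imp <- randomForest::importance(fit)[, "MeanDecreaseGini"]
  names(sort(imp, decreasing = TRUE))[seq_len(n_top)]
}

#' Select predictable features by per-feature R squared
#'
#' For every shared column, computes the coefficient of determination of
#' the generated values against the ground-truth values (rows paired) and
#' keeps features exceeding the threshold.
#'
#' @param F_generated,F_ground_truth matrices with matching column names
#'   and equal row counts (rows correspond to the same samples).
#' @param threshold keep features with `R^2 >` threshold (default 0.5).
#' @return character vector of retained feature names.
#' @export
select_predictable <- function(F_generated, F_ground_truth, threshold = 0.5) {
  common <- intersect(colnames(F_generated), colnames(F_ground_truth))
  pd_assert(length(common) == ncol(F_generated) && length(common) == ncol(F_ground_truth),
            "feature columns of the two matrices do not match")
  pd_assert(nrow(F_generated) == nrow(F_ground_truth), "row counts differ")
  keep <- vapply(common, function(f) {
    y <- F_ground_truth[, f]
    if (stats::var(y) == 0) return(FALSE)
    r2_score(y, F_generated[, f]) > threshold
  }, TRUE)
  common[keep]
}

#' Chi-square test for significantly changed features
#'
#' For each feature, pools the control and perturbed values, forms
#' `n_bins` quantile bins of the pooled data, builds the 2 x n_bins
#' contingency table and applies a chi-square test of homogeneity.
#' Features whose pooled values collapse to fewer than two distinct bins
#' are skipped with a warning.
#'
#' @param control_F,perturbed_F matrices with matching columns; at least
#'   20 rows each.
#' @param alpha significance level for the flag (default 0.05).
#' @param n_bins number of quantile bins (default 10).
#' @return a `significance_report` data frame: feature, p_value,
#'   significant (p < alpha), test id.
#' @export
significant_change_test <- function(control_F, perturbed_F, alpha = 0.05, n_bins = 10) {
  common <- intersect(colnames(control_F), colnames(perturbed_F))
  pd_assert(length(common) >= 1L, "no shared features")
  pd_assert(nrow(control_F) >= 20L && nrow(perturbed_F) >= 20L,
            "need at least 20 samples per group")
  out <- lapply(common, function(f) {
    x <- control_F[, f]; y <- perturbed_F[, f]
    pooled <- c(x, y)
    brks <- unique(stats::quantile(pooled, probs = seq(0, 1, length.out = n_bins + 1L),
                                   names = FALSE))
    if (length(brks) < 3L) {  # < 2 usable bins
      warning(sprintf("feature '%s' skipped: degenerate binning", f))
      return(NULL)
    }
    bx <- table(cut(x, brks, include.lowest = TRUE))
    by <- table(cut(y, brks, include.lowest = TRUE))
    tab <- rbind(control = as.integer(bx), perturbed = as.integer(by))
    keep <- colSums(tab) > 0
    p <- suppressWarnings(stats::chisq.test(tab[, keep, drop = FALSE])$p.value)
    data.frame(feature = f, p_value = p, significant = p < alpha,
               test = "chisq_homogeneity", stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(rep)) rep <- data.frame(feature = character(), p_value = numeric(),
                                      significant = logical(), test = character())
  class(rep) <- c("significance_report", "data.frame")
  rep
}
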