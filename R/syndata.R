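# Synthetic paired (expression, image) data generator.
#
# Emulates the structure of Cell Painting perturbation screens: a panel of
# perturbations grouped by mechanism of action (MOA), each with a bounded
# morphological effect vector; an L1000-like expression readout that is a
# fixed linear function of the effect vector plus Gaussian noise; a DMSO
# control; plate-level nuisance brightness; and train/ID/OOD splits.
# All distributional choices here are synthetic fixtures for testing the
# model and metrics, not claims about real screens.

effect_names <- function() {
  c(paste0("int_", pd_channels), "gran_density", "gran_radius", "tex_freq",
    apply(utils::combn(pd_channels, 2), 2,
          function(p) paste0("cor_", p[1], "_", p[2])))
}

# Documented bounds of each effect component (intensity shifts in pixel
# units; the rest are unitless modulation factors).
effect_bounds <- function() {
  lo <- c(rep(-0.35, 5), -1, -1, -1, rep(-0.5, 10))
  hi <- c(rep(0.35, 5), 1, 1, 1, rep(0.5, 10))
  names(lo) <- names(hi) <- effect_names()
  list(lo = lo, hi = hi)
}

#' Construct a perturbation program
#'
#' A perturbation program is the generative "ground truth" for one
#' perturbation: a named effect vector controlling per-channel intensity
#' shifts, granule density and radius, texture frequency and pairwise
#' channel correlations, together with MOA and target labels.
#'
#' @param perturbation_id character id.
#' @param effect_vector named numeric vector over the 18 effect components;
#'   see `perturbdiff:::effect_names()`.
#' @param moa_labels character vector of MOA labels (non-empty unless
#'   control).
#' @param target_label character target gene label.
#' @param is_control logical; the control program must have a zero effect
#'   vector.
#' @return object of class `perturbation_program`.
#' @export
perturbation_program <- function(perturbation_id, effect_vector,
                                 moa_labels = character(), target_label = "",
                                 is_control = FALSE) {
  b <- effect_bounds()
  pd_assert(length(effect_vector) == length(effect_names()), "effect_vector must have 18 components")
  if (is.null(names(effect_vector))) names(effect_vector) <- effect_names()
  pd_assert(all(effect_vector >= b$lo - 1e-12 & effect_vector <= b$hi + 1e-12),
            "effect_vector components out of documented bounds")
  if (is_control) {
    pd_assert(all(effect_vector == 0), "control program must have zero effect_vector")
  } else {
    pd_assert(length(moa_labels) >= 1L, "moa_labels must be non-empty for non-control programs")
  }
  structure(list(perturbation_id = as.character(perturbation_id),
                 effect_vector = effect_vector,
                 moa_labels = unique(as.character(moa_labels)),
                 target_label = as.character(target_label),
                 is_control = isTRUE(is_control)),
            class = "perturbation_program")
}

#' Generate a perturbation panel with paired expression profiles
#'
#' Draws `n_perturbations` programs grouped into `n_moas` mechanisms of
#' action. Programs sharing an MOA are correlated: each is the MOA
#' prototype effect vector plus a small program-specific deviation.
#' Expression is a fixed seeded random linear map of the effect vector
#' plus `N(0, sigma^2)` noise (default `sigma = 0.1`), so expression is
#' informative about morphology by construction. A DMSO control program
#' (zero effect, baseline expression) is always appended.
#'
#' @param n_perturbations number of non-control perturbations (>= 1).
#' @param n_moas number of MOA groups (<= n_perturbations).
#' @param G expression vector length (>= 8; default 64).
#' @param seed integer seed; the expression map and the sampling noise use
#'   separately derived seeds.
#' @param sigma_expr standard deviation of expression noise.
#' @return list with `programs` (list of [perturbation_program], control
#'   last) and `expression` (matrix, rows = perturbation ids, G columns).
#' @export
generate_panel <- function(n_perturbations, n_moas, G = 64, seed = 1,
                           sigma_expr = 0.1) {
  pd_assert(n_perturbations >= 1, "n_perturbations must be >= 1")
  pd_assert(n_moas >= 1 && n_moas <= n_perturbations, "need 1 <= n_moas <= n_perturbations")
  pd_assert(G >= 8, "G must be >= 8")
  b <- effect_bounds()
  ne <- length(effect_names())

  programs <- with_seed(derive_seed(seed, "panel"), {
    protos <- lapply(seq_len(n_moas), function(m) {
      stats::runif(ne, 0.75 * b$lo, 0.75 * b$hi)
    })
    lapply(seq_len(n_perturbations), function(j) {
      m <- ((j - 1L) %% n_moas) + 1L
      dev <- stats::rnorm(ne, sd = 0.12 * (b$hi - b$lo) / 2)
      eff <- pmin(pmax(protos[[m]] + dev, b$lo), b$hi)
      names(eff) <- effect_names()
      moas <- paste0("moa_", m)
      if (j %% 5L == 0L && n_moas > 1L)  # some drugs carry multiple MOAs
        moas <- c(moas, paste0("moa_", (m %% n_moas) + 1L))
      perturbation_program(sprintf("pert_%03d", j), eff, moas,
                           target_label = sprintf("target_%02d", m))
    })
  })
  control <- perturbation_program("DMSO", stats::setNames(rep(0, ne), effect_names()),
                                  is_control = TRUE)
  programs <- c(programs, list(control))

  W <- with_seed(derive_seed(seed, "expression_map"),
                 matrix(stats::rnorm(G * ne), G, ne))
  baseline <- with_seed(derive_seed(seed, "expression_baseline"),
                        stats::rnorm(G, sd = 0.5))
  expr <- with_seed(derive_seed(seed, "expression_noise"), {
    E <- t(vapply(programs, function(pr) {
      as.vector(W %*% pr$effect_vector) + baseline + stats::rnorm(G, sd = sigma_expr)
    }, numeric(G)))
    rownames(E) <- vapply(programs, function(pr) pr$perturbation_id, "")
    colnames(E) <- sprintf("gene_%03d", seq_len(G))
    E
  })
  list(programs = programs, expression = expr)
}

# Small deterministic per-plate brightness offset.
plate_offset <- function(plate_id) {
  h <- sum(utf8ToInt(as.character(plate_id)))
  ((h %% 7L) - 3L) * 0.01
}

#' Render one synthetic five-channel cell image
#'
#' Draws a single elliptical cell with a nucleus on a dark background and
#' applies the program's effect vector: global per-channel intensity
#' shifts, granule count/radius modulation (bright puncta in ER, RNA and
#' Mito), a sinusoidal texture of programmable frequency in ER and AGP,
#' and pairwise channel mixing that induces the programmed cross-channel
#' correlations. The plate id adds a small deterministic brightness
#' offset; pixel values are clipped to `[0, 1]`.
#'
#' @param program a [perturbation_program].
#' @param H image side length in pixels (>= 16).
#' @param plate_id plate label; adds a documented brightness offset.
#' @param seed integer seed; same arguments and seed give a bit-identical
#'   image.
#' @return a [morph_image].
#' @export
render_image <- function(program, H = 32, plate_id = "plate_1", seed = 1) {
  pd_assert(inherits(program, "perturbation_program"), "program must be a perturbation_program")
  pd_assert(H >= 16, "H must be >= 16")
  eff <- program$effect_vector
  with_seed(derive_seed(seed, paste0("render_", program$perturbation_id)), {
    xs <- (seq_len(H) - 0.5) / H
    X <- matrix(xs, H, H); Y <- t(X)

    cx <- 0.5 + stats::runif(1, -0.06, 0.06)
    cy <- 0.5 + stats::runif(1, -0.06, 0.06)
    a <- stats::runif(1, 0.30, 0.38); bb <- stats::runif(1, 0.22, 0.30)
    th <- stats::runif(1, 0, pi)
    Xr <- (X - cx) * cos(th) + (Y - cy) * sin(th)
    Yr <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
    rcell <- (Xr / a)^2 + (Yr / bb)^2
    cell <- rcell <= 1
    nucleus <- (Xr / (0.42 * a))^2 + (Yr / (0.42 * bb))^2 <= 1
    cyto <- cell & !nucleus
    grad <- pmax(1 - rcell, 0)

    ch <- array(0.05, c(H, H, 5L))
    ch[, , 1][nucleus] <- 0.55 + 0.1 * grad[nucleus]   # DNA
    ch[, , 2][cyto] <- 0.28 + 0.10 * grad[cyto]        # ER
    ch[, , 3][cyto] <- 0.24 + 0.08 * grad[cyto]        # RNA
    ch[, , 3][nucleus] <- 0.35                          # nucleoli-rich RNA
    ch[, , 4][cell] <- 0.26 + 0.06 * grad[cell]        # AGP membrane/actin
    ch[, , 5][cyto] <- 0.30 + 0.08 * grad[cyto]        # Mito

    # granules: bright puncta in ER, RNA, Mito
    n_gran <- max(0L, round(10 * (1 + 0.8 * eff["gran_density"])))
    r_gran <- max(0.5, 1.6 * (1 + 0.5 * eff["gran_radius"])) / H
    for (c in c(2L, 3L, 5L)) {
      if (n_gran > 0L) {
        idx <- which(cyto)
        if (length(idx) > 0L) {
          pick <- idx[sample.int(length(idx), min(n_gran, length(idx)))]
          for (q in pick) {
            gi <- ((q - 1L) %% H) + 1L; gj <- ((q - 1L) %/% H) + 1L
            d2 <- (X - xs[gi])^2 + (Y - xs[gj])^2
            ch[, , c] <- ch[, , c] + 0.30 * exp(-d2 / (2 * r_gran^2)) * cell
          }
        }
      }
    }

    # texture: sinusoidal modulation in ER and AGP
    wavelen <- 0.18 / (1 + 0.8 * eff["tex_freq"])
    tex <- 0.05 * sin(2 * pi * Xr / wavelen) * sin(2 * pi * Yr / wavelen)
    ch[, , 2] <- ch[, , 2] + tex * cyto
    ch[, , 4] <- ch[, , 4] + tex * cell

    # pairwise channel mixing -> programmed cross-channel correlation
    pairs <- utils::combn(5L, 2L)
    base <- ch
    flucts <- lapply(1:5, function(c) base[, , c] - mean(base[, , c]))
    for (k in seq_len(ncol(pairs))) {
      rho <- eff[8L + k]
      i <- pairs[1L, k]; j <- pairs[2L, k]
      if (rho != 0) {
        ch[, , i] <- ch[, , i] + rho * flucts[[j]]
        ch[, , j] <- ch[, , j] + rho * flucts[[i]]
      }
    }

    # global intensity shifts, plate offset, acquisition noise
    for (c in 1:5) ch[, , c] <- ch[, , c] + eff[c]
    ch <- ch + plate_offset(plate_id)
    illum <- 1 + stats::rnorm(1, sd = 0.03)
    ch <- ch * illum + array(stats::rnorm(length(ch), sd = 0.02), dim(ch))

    morph_image(clip01(ch), perturbation_id = program$perturbation_id,
                plate_id = plate_id)
  })
}

#' Train / in-distribution / out-of-distribution split of a panel
#'
#' Holds out a fraction of the non-control perturbations entirely (OOD),
#' then splits the remainder into train and ID pools. Counts use
#' `ceiling(fraction * n)` with a minimum of 1, so the OOD set is never
#' empty. The control perturbation belongs to the train and ID pools only.
#'
#' @param ids character vector of non-control perturbation ids.
#' @param ood_fraction,id_fraction fractions in (0, 1).
#' @param seed integer seed.
#' @return object of class `split_spec` with `train_ids`, `id_ids`,
#'   `ood_ids` and the seed.
#' @export
split_spec <- function(ids, ood_fraction = 0.10, id_fraction = 0.10, seed = 1) {
  pd_assert(ood_fraction > 0 && ood_fraction < 1, "ood_fraction must be in (0,1)")
  pd_assert(id_fraction > 0 && id_fraction < 1, "id_fraction must be in (0,1)")
  n <- length(ids)
  pd_assert(n >= 3L, "need at least 3 non-control perturbations to split")
  with_seed(derive_seed(seed, "split"), {
    n_ood <- max(1L, as.integer(ceiling(ood_fraction * n)))
    ood <- sort(sample(ids, n_ood))
    rest <- setdiff(ids, ood)
    pd_assert(length(rest) >= 2L, "too few perturbations for a non-empty train/ID split")
    n_id <- max(1L, as.integer(ceiling(id_fraction * length(rest))))
    idset <- sort(sample(rest, n_id))
    train <- sort(setdiff(rest, idset))
    pd_assert(length(train) >= 1L, "too few perturbations for a non-empty train set")
    structure(list(train_ids = train, id_ids = idset, ood_ids = ood,
                   seed = as.integer(seed)),
              class = "split_spec")
  })
}

#' Build a full synthetic dataset with splits
#'
#' Renders `images_per_perturbation` images for every program in the panel
#' (control included), cycling each perturbation's images over four
#' synthetic plates, and computes the train/ID/OOD [split_spec]. The
#' control contributes images to the train and ID pools only.
#'
#' @param panel output of [generate_panel].
#' @param images_per_perturbation images rendered per perturbation.
#' @param ood_fraction,id_fraction split fractions in (0,1).
#' @param H image side length.
#' @param seed integer seed.
#' @param out_dir optional directory; when given, images and a manifest CSV
#'   are written there via [io_write_images].
#' @return list with `images` (list of [morph_image]), `panel`,
#'   `expression`, `split` (a [split_spec]) and `manifest` (data frame
#'   with perturbation_id, plate_id, moa, target, split role per image).
#' @export
make_dataset <- function(panel, images_per_perturbation = 64,
                         ood_fraction = 0.10, id_fraction = 0.10,
                         H = 32, seed = 1, out_dir = NULL) {
  pd_assert(images_per_perturbation >= 1, "images_per_perturbation must be >= 1")
  programs <- panel$programs
  noncontrol <- vapply(Filter(function(p) !p$is_control, programs),
                       function(p) p$perturbation_id, "")
  split <- split_spec(noncontrol, ood_fraction, id_fraction, seed)

  images <- list(); rows <- list()
  plates <- paste0("plate_", 1:4)
  for (pr in programs) {
    role <- if (pr$is_control) "control"
            else if (pr$perturbation_id %in% split$ood_ids) "ood"
            else if (pr$perturbation_id %in% split$id_ids) "id"
            else "train"
    for (i in seq_len(images_per_perturbation)) {
      plate <- plates[((i - 1L) %% length(plates)) + 1L]
      img <- render_image(pr, H = H, plate_id = plate,
                          seed = derive_seed(seed, paste0("img_", pr$perturbation_id, "_", i)))
      images[[length(images) + 1L]] <- img
      rows[[length(rows) + 1L]] <- data.frame(
        perturbation_id = pr$perturbation_id, plate_id = plate,
        moa = paste(pr$moa_labels, collapse = ";"),
        target = pr$target_label, role = role,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  ds <- list(images = images, panel = panel, expression = panel$expression,
             split = split, manifest = manifest)
  if (!is.null(out_dir)) {
    io_write_images(images, file.path(out_dir, "images"))
    utils::write.csv(cbind(file = sprintf("images/img_%05d.tif", seq_along(images)), manifest),
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(data.frame(perturbation_id = rownames(panel$expression),
                                panel$expression, check.names = FALSE),
                     file.path(out_dir, "expression.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(ds$split), file.path(out_dir, "splits.json"))
  }
  ds
}
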