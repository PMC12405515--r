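# Experiment orchestration: configuration, deterministic seed fan-out,
# file I/O (multi-page float TIFF + CSV), structured logging, and the
# end-to-end desk-scale pipeline: simulate -> train MVAE -> train LDM ->
# generate -> featurize -> evaluate -> retrieve.

#' Experiment configuration
#'
#' All knobs of the end-to-end pipeline with desk-scale defaults: 8
#' perturbations in 4 MOA groups, 64 genes, 64 images of 32 x 32 pixels
#' per perturbation, a 50-step diffusion chain and a small denoiser --
#' sized so the whole experiment runs in minutes on one CPU.
#'
#' @param n_perturbations,n_moas,G,images_per_perturbation,H dataset
#'   parameters (see [generate_panel] / [make_dataset]).
#' @param ood_fraction,id_fraction split fractions.
#' @param mvae_steps,ldm_steps,batch_size,ldm_batch_size training
#'   schedule (the diffusion model trains with larger batches; its
#'   gradient noise otherwise dominates).
#' @param T diffusion steps; `beta_max` is sized so the terminal
#'   signal level is near zero for this T.
#' @param n_generate generated images per perturbation at evaluation.
#' @param k neighbourhood size for density/coverage.
#' @param seed global seed; every stage derives its own via
#'   [derive_seed].
#' @param out_dir optional output directory for reports and images.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_perturbations = 8, n_moas = 4, G = 64,
                              images_per_perturbation = 64, H = 32,
                              ood_fraction = 0.10, id_fraction = 0.10,
                              mvae_steps = 1300, ldm_steps = 2000,
                              batch_size = 16, ldm_batch_size = 32,
                              T = 50, n_generate = 32,
                              k = 5, seed = 1, out_dir = NULL) {
  cfg <- list(n_perturbations = n_perturbations, n_moas = n_moas, G = G,
              images_per_perturbation = images_per_perturbation, H = H,
              ood_fraction = ood_fraction, id_fraction = id_fraction,
              mvae_steps = mvae_steps, ldm_steps = ldm_steps,
              batch_size = batch_size, ldm_batch_size = ldm_batch_size,
              T = T, n_generate = n_generate,
              k = k, seed = seed, out_dir = out_dir)
  class(cfg) <- "experiment_config"
  cfg
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @return [experiment_config] (for the reader).
#' @export
read_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config configuration to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[names(config) != "out_dir" | !vapply(config, is.null, TRUE)],
                   path)
  invisible(path)
}

config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(x) paste(format(x), collapse = ","), ""),
             collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Write / read five-channel images as multi-page float TIFF
#'
#' Each image becomes one 5-page 32-bit TIFF (page order DNA, ER, RNA,
#' AGP, Mito) named `img_%05d.tif`, with an `images.csv` table of
#' perturbation and plate labels. Values survive the round trip to
#' float32 precision.
#'
#' @param images list of [morph_image].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
io_write_images <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- data.frame(file = sprintf("img_%05d.tif", seq_along(images)),
                     perturbation_id = vapply(images, function(i) i$perturbation_id, ""),
                     plate_id = vapply(images, function(i) i$plate_id, ""))
  for (b in seq_along(images)) {
    pages <- lapply(1:5, function(c) images[[b]]$channels[, , c])
    tiff::writeTIFF(pages, file.path(dir, meta$file[b]), bits.per.sample = 32L,
                    reduce = FALSE)
  }
  utils::write.csv(meta, file.path(dir, "images.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname io_write_images
#' @export
io_read_images <- function(dir) {
  meta_path <- file.path(dir, "images.csv")
  pd_assert(file.exists(meta_path), paste("no images.csv in", dir))
  meta <- utils::read.csv(meta_path)
  lapply(seq_len(nrow(meta)), function(b) {
    pages <- tiff::readTIFF(file.path(dir, meta$file[b]), all = TRUE)
    pd_assert(length(pages) == 5L,
              sprintf("file %s: expected 5 channels, found %d", meta$file[b], length(pages)))
    arr <- simplify2array(pages)
    pd_assert(all(is.finite(arr)), sprintf("file %s: non-finite pixels", meta$file[b]))
    morph_image(clip01(arr), perturbation_id = meta$perturbation_id[b],
                plate_id = meta$plate_id[b])
  })
}

#' Read expression profiles from CSV
#'
#' First column `perturbation_id`, remaining columns genes. Duplicate ids
#' are a format error.
#'
#' @param path CSV path.
#' @return numeric matrix with perturbation ids as row names.
#' @export
io_read_expression <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  pd_assert(ncol(df) >= 2L, "expression CSV needs an id column plus genes")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  pd_assert(length(dup) == 0L,
            paste("duplicate perturbation id(s) in expression CSV:",
                  paste(unique(dup), collapse = ", ")))
  M <- as.matrix(df[, -1L, drop = FALSE])
  pd_assert(all(is.finite(M)), "non-finite expression values")
  rownames(M) <- ids
  M
}

log_stage <- function(log, stage, t0, seed, extra = list()) {
  entry <- c(list(stage = stage, seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2),
                  seed = seed), extra)
  log$entries[[length(log$entries) + 1L]] <- entry
  if (!is.null(log$path)) {
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n", file = log$path, append = TRUE)
  }
  log
}

#' Run the full desk-scale experiment
#'
#' Simulates a dataset, trains the MVAE and the conditional latent
#' diffusion model on the non-OOD perturbations, generates images for
#' every perturbation (G2I), extracts features, computes the
#' distribution-level metrics per perturbation and pooled, the
#' significant-change F1 against ground truth, and the MOA retrieval
#' accuracy with a label-permutation null. All stages derive their seeds
#' from `config$seed`; rerunning with the same config reproduces every
#' number.
#'
#' @param config an [experiment_config].
#' @param verbose print stage progress.
#' @return list with `dataset`, `mvae`, `ldm`, `generated` (images per
#'   perturbation), `metrics`, `retrieval`, `log`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  seed <- config$seed
  log <- list(entries = list(),
              path = if (!is.null(config$out_dir)) {
                dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
                file.path(config$out_dir, "log.jsonl")
              })
  say <- function(...) if (verbose) message(sprintf(...))

  # --- simulate ------------------------------------------------------------
  t0 <- Sys.time()
  panel <- generate_panel(config$n_perturbations, config$n_moas, G = config$G,
                          seed = derive_seed(seed, "panel_stage"))
  ds <- make_dataset(panel, config$images_per_perturbation,
                     ood_fraction = config$ood_fraction,
                     id_fraction = config$id_fraction, H = config$H,
                     seed = derive_seed(seed, "dataset_stage"),
                     out_dir = if (!is.null(config$out_dir)) file.path(config$out_dir, "data"))
  log <- log_stage(log, "simulate", t0, seed, list(config_hash = config_hash(config)))
  say("simulated %d images", length(ds$images))

  train_mask <- ds$manifest$role %in% c("train", "id", "control")
  train_images <- ds$images[train_mask]

  # --- MVAE ----------------------------------------------------------------
  t0 <- Sys.time()
  mvae <- mvae_init(mvae_config(H = config$H), seed = derive_seed(seed, "mvae_seed"))
  mres <- train_mvae(mvae, train_images, steps = config$mvae_steps,
                     batch_size = config$batch_size,
                     seed = derive_seed(seed, "mvae_train"))
  mvae <- mres$model
  log <- log_stage(log, "train_mvae", t0, seed,
                   list(final_rec = unname(mres$history[config$mvae_steps, "L_rec"])))
  say("MVAE trained (rec %.3f)", mres$history[config$mvae_steps, "L_rec"])

  # --- latents + LDM -------------------------------------------------------
  t0 <- Sys.time()
  lat <- lapply(seq_along(train_images), function(i) {
    latent_array_to_tokens(encode(mvae, train_images[[i]],
                                  seed = derive_seed(seed, paste0("enc", i)))$mean)
  })
  conds <- lapply(ds$manifest$perturbation_id[train_mask], function(pid) {
    ds$expression[pid, ]
  })
  ldm <- ldm_init(ldm_config(grid = config$H %/% mvae$config$patch,
                             latent_channels = mvae$config$latent_channels,
                             T = config$T),
                  G = config$G, seed = derive_seed(seed, "ldm_seed"))
  lres <- train_ldm(ldm, lat, conds, steps = config$ldm_steps,
                    batch_size = config$ldm_batch_size,
                    seed = derive_seed(seed, "ldm_train"))
  ldm <- lres$model
  log <- log_stage(log, "train_ldm", t0, seed,
                   list(final_loss = mean(utils::tail(lres$history, 50))))
  say("LDM trained (loss %.3f)", mean(utils::tail(lres$history, 50)))

  # --- generate ------------------------------------------------------------
  t0 <- Sys.time()
  pert_ids <- vapply(Filter(function(p) !p$is_control, panel$programs),
                     function(p) p$perturbation_id, "")
  generated <- lapply(pert_ids, function(pid) {
    generate_images(ldm, mvae, ds$expression[pid, ], n = config$n_generate,
                    seed = derive_seed(seed, paste0("gen_", pid)),
                    perturbation_id = pid)
  })
  names(generated) <- pert_ids
  if (!is.null(config$out_dir)) {
    io_write_images(unlist(generated, recursive = FALSE),
                    file.path(config$out_dir, "generated"))
  }
  log <- log_stage(log, "generate", t0, seed)
  say("generated %d x %d images", length(pert_ids), config$n_generate)

  # --- featurize + evaluate ------------------------------------------------
  t0 <- Sys.time()
  enc <- encoder_features()
  gt_by_pert <- lapply(pert_ids, function(pid) {
    ds$images[ds$manifest$perturbation_id == pid]
  })
  names(gt_by_pert) <- pert_ids
  control_images <- ds$images[ds$manifest$perturbation_id == "DMSO"]
  ctrl_F <- enc$embed(control_images)
  colnames(ctrl_F) <- names(feature_row(control_images[[1L]]))

  per_pert <- lapply(pert_ids, function(pid) {
    Er <- enc$embed(gt_by_pert[[pid]])
    Eg <- enc$embed(generated[[pid]])
    dc <- density_coverage(Er, Eg, k = config$k)
    gt_F <- Er; gen_F <- Eg
    colnames(gt_F) <- colnames(gen_F) <- colnames(ctrl_F)
    rep_gt <- significant_change_test(ctrl_F, gt_F)
    rep_gen <- significant_change_test(ctrl_F, gen_F)
    shared <- intersect(rep_gt$feature, rep_gen$feature)
    f1 <- f1_significant(rep_gt$significant[match(shared, rep_gt$feature)],
                         rep_gen$significant[match(shared, rep_gen$feature)])
    list(perturbation_id = pid, density = dc$density, coverage = dc$coverage,
         mmd = mmd_cmmd(Er, Eg), f1_significant = f1)
  })
  names(per_pert) <- pert_ids

  all_real <- do.call(rbind, lapply(pert_ids, function(p) enc$embed(gt_by_pert[[p]])))
  all_gen <- do.call(rbind, lapply(pert_ids, function(p) enc$embed(generated[[p]])))
  clf <- encoder_classifier(ds$images[train_mask],
                            ds$manifest$perturbation_id[train_mask],
                            seed = derive_seed(seed, "clf"))
  metrics <- list(
    per_perturbation = per_pert,
    pooled = list(
      fid = frechet_distance(all_real, all_gen, shrinkage = 1e-6),
      inception_score = inception_score(clf$probs(unlist(generated, recursive = FALSE))),
      mmd = mmd_cmmd(all_real, all_gen),
      density = mean(vapply(per_pert, function(x) x$density, 0)),
      coverage = mean(vapply(per_pert, function(x) x$coverage, 0)),
      f1_significant = mean(vapply(per_pert, function(x) x$f1_significant, 0))))
  log <- log_stage(log, "evaluate", t0, seed)
  say("metrics done (density %.2f coverage %.2f f1 %.2f)",
      metrics$pooled$density, metrics$pooled$coverage, metrics$pooled$f1_significant)

  # --- MOA retrieval -------------------------------------------------------
  t0 <- Sys.time()
  moa_of <- lapply(Filter(function(p) !p$is_control, panel$programs),
                   function(p) p$moa_labels)
  names(moa_of) <- pert_ids
  # reference sets subsampled to the generated-set size: the exact
  # Wasserstein between equal-size uniform clouds reduces to an
  # assignment problem, which keeps retrieval fast
  refs <- lapply(pert_ids, function(pid) {
    E <- enc$embed(gt_by_pert[[pid]])
    if (nrow(E) > config$n_generate) {
      keep <- with_seed(derive_seed(seed, paste0("refsub_", pid)),
                        sample.int(nrow(E), config$n_generate))
      E <- E[keep, , drop = FALSE]
    }
    perturbation_record(pid, moa_of[[pid]], embedding_set = E)
  })
  queries <- lapply(pert_ids, function(pid) {
    perturbation_record(paste0("gen_", pid), moa_of[[pid]],
                        embedding_set = enc$embed(generated[[pid]]))
  })
  results <- lapply(queries, function(q) {
    rr <- rank_references(q, Filter(function(r) r$perturbation_id != sub("^gen_", "", q$perturbation_id),
                                    refs), distance = "wasserstein")
    rr
  })
  k_ret <- 3L
  acc <- topk_accuracy(results, k_ret)
  null_acc <- with_seed(derive_seed(seed, "retrieval_null"), {
    vapply(seq_len(100), function(i) {
      perm <- sample(pert_ids)
      moa_perm <- moa_of[perm]
      names(moa_perm) <- pert_ids
      mean(vapply(seq_along(results), function(qi) {
        r <- results[[qi]]
        qmoa <- moa_perm[[sub("^gen_", "", r$query_id)]]
        topk <- r$reference_ids[seq_len(k_ret)]
        any(vapply(topk, function(rid) length(intersect(moa_perm[[rid]], qmoa)) > 0, TRUE))
      }, 0))
    }, 0)
  })
  retrieval <- list(top3_accuracy = acc, null_mean = mean(null_acc),
                    null_sd = stats::sd(null_acc), k = k_ret,
                    map = mean_average_precision(results))
  log <- log_stage(log, "retrieve", t0, seed)
  say("retrieval top-3 %.2f (null %.2f)", acc, mean(null_acc))

  if (!is.null(config$out_dir)) {
    jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(retrieval, file.path(config$out_dir, "retrieval.json"),
                         auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(config$out_dir, "config.yaml"))
  }
  list(dataset = ds, mvae = mvae, ldm = ldm, generated = generated,
       metrics = metrics, retrieval = retrieval, log = log$entries)
}
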