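Package: perturbdiff
Title: Transcriptome-Conditioned Latent Diffusion for Cell Painting Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates five-channel Cell Painting style single-cell morphology
    images conditioned on perturbed gene-expression profiles using a latent
    denoising diffusion model trained on top of a morphology variational
    autoencoder. Includes a synthetic paired (expression, image) data
    generator with mechanism-of-action structure, CellProfiler-style feature
    extraction with discriminability- and predictability-based feature
    selection, the full distribution-level evaluation suite for generative
    models (Frechet distance, inception score, density and coverage, maximum
    mean discrepancy, exact Wasserstein distance, R squared, Pearson
    correlation, F1 over chi-square-significant features), and a
    mechanism-of-action retrieval pipeline (top-k accuracy, mean average
    precision, folds of enrichment). All models train on CPU at desk scale;
    networks are built on a small bundled reverse-mode autodiff engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    randomForest,
    nnet,
    clue
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
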