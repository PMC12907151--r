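#' End-to-end classification pipeline
#'
#' Runs the complete leakage-controlled workflow on a synthetic cohort or
#' on supplied spectra: preprocessing (despike, rubber-band baseline,
#' fluorescence rejection, vector normalization), class balancing, a
#' grouped stratified 80/20 split, feature standardization and principal
#' component reduction fitted on the training partition only, an optional
#' cross-validated architecture search, MLP training, and held-out
#' evaluation. Every stochastic step is seeded from `seed`, so a run is
#' fully reproducible from `(config, seed)`.
#'
#' @param config A [synthetic_config()]; ignored when `data` is given.
#' @param data Optional [raman_spectra] tibble of measured spectra to use
#'   instead of simulating.
#' @param seed Integer master seed.
#' @param hidden Fixed MLP architecture (default the compact five-layer,
#'   five-neuron network).
#' @param search If `TRUE`, choose the architecture by grouped 10-fold
#'   cross-validation over `architectures` instead of using `hidden`.
#' @param architectures Grid for the search, see [mlp_architectures()].
#' @param preprocess A [preprocess_config()].
#' @param n_components Principal components retained (default 20).
#' @param test_frac Held-out fraction per class (default 0.2).
#' @param ... Passed to [fit_mlp()].
#' @return A `raman_fit` list: `report` (a `raman_report`), `split`,
#'   `qc`, `scaler`, `pca`, `model`, `cv` (when searched), `scores`
#'   (held-out truth/probabilities), `config`, `seed`.
#' @examples
#' \donttest{
#' fit <- run_raman_pipeline(synthetic_config(), seed = 42)
#' glance(fit)
#' }
#' @export
run_raman_pipeline <- function(config = synthetic_config(), data = NULL,
                               seed = 1L, hidden = c(5, 5, 5, 5, 5),
                               search = FALSE,
                               architectures = mlp_architectures(),
                               preprocess = preprocess_config(),
                               n_components = 20L, test_frac = 0.2, ...) {
  seed <- as.integer(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)),
            class = "ramancell_pipeline_error")
    })
  }
  spectra <- if (is.null(data)) {
    stage("simulate", simulate_cohort(config, seed = seed)$spectra)
  } else {
    stage("load", as_raman_spectra(data))
  }
  pre <- stage("preprocess", preprocess_spectra(spectra, preprocess))
  bal <- stage("balance", balance_classes(pre, seed = seed + 1L))
  spl <- stage("split", split_by_cell(bal, test_frac = test_frac,
                                      seed = seed + 2L))
  tr <- bal[spl$set == "train", ]
  te <- bal[spl$set == "test", ]
  x_tr <- intensity_matrix(as_raman_spectra(tr))
  scaler <- stage("scale", fit_scaler(x_tr))
  z_tr <- apply_scaler(scaler, x_tr)
  pca <- stage("pca", fit_spectra_pca(z_tr, n_components = n_components))
  # The score vectors fed to the network are standardized as well (fitted
  # on the training scores only); component scales differ by orders of
  # magnitude otherwise.
  raw_tr <- apply_pca(pca, z_tr)
  score_scaler <- stage("scale", fit_scaler(raw_tr))
  s_tr <- apply_scaler(score_scaler, raw_tr)
  cv <- NULL
  if (search) {
    cv <- stage("search", crossvalidate_mlp(
      s_tr, tr$class_label, spectra_meta(as_raman_spectra(tr)),
      architectures = architectures, seed = seed + 3L, ...))
    hidden <- cv$chosen$layout[[1]]
  }
  model <- stage("train", fit_mlp(s_tr, tr$class_label, hidden = hidden,
                                  seed = seed + 4L, ...))
  report <- NULL
  scores <- NULL
  if (nrow(te) > 0) {
    z_te <- apply_scaler(scaler, intensity_matrix(as_raman_spectra(te)))
    s_te <- apply_scaler(score_scaler, apply_pca(pca, z_te))
    prob <- predict(model, s_te, type = "prob")
    pred <- predict(model, s_te, type = "class")
    report <- stage("evaluate",
                    classification_report(te$class_label, pred, prob))
    scores <- tibble(spectrum_id = te$spectrum_id,
                     truth = te$class_label, predicted = pred,
                     probability = prob)
  }
  structure(list(report = report, split = spl, qc = qc_log(pre),
                 scaler = scaler, pca = pca, score_scaler = score_scaler,
                 model = model, cv = cv,
                 scores = scores, hidden = model$hidden,
                 config = if (is.null(data)) config else NULL,
                 seed = seed),
            class = "raman_fit")
}

#' @export
glance.raman_fit <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$report),
    tibble(variance_retained = sum(x$pca$variance_ratio),
           n_components = x$pca$n_components,
           architecture = paste(x$hidden, collapse = "x"),
           seed = x$seed)
  )
}

#' @export
tidy.raman_fit <- function(x, ...) tidy(x$report)

#' @export
print.raman_fit <- function(x, ...) {
  cat(sprintf("Raman classification pipeline (seed %d)\n", x$seed))
  cat(sprintf("PCA: %d components, %.2f%% variance retained | MLP: %s\n",
              x$pca$n_components, 100 * sum(x$pca$variance_ratio),
              paste(x$hidden, collapse = "x")))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
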