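#' Architecture grid for the MLP search
#'
#' Uniform-width architectures with depth 1 to 10 hidden layers and widths
#' drawn from a configurable subset of 2..100 neurons (default
#' 2, 5, 10, 20, 50, 100). The grid includes the compact five-layer,
#' five-neuron network.
#'
#' @param depths Integer vector of hidden-layer counts (within 1..10).
#' @param widths Integer vector of layer widths (within 2..100).
#' @return Tibble with columns `depth`, `width` and list-column `layout`.
#' @export
mlp_architectures <- function(depths = 1:10,
                              widths = c(2L, 5L, 10L, 20L, 50L, 100L)) {
  stopifnot(all(depths >= 1), all(depths <= 10),
            all(widths >= 2), all(widths <= 100))
  grid <- tidyr::expand_grid(depth = as.integer(depths),
                             width = as.integer(widths))
  grid$layout <- purrr::map2(grid$depth, grid$width, ~rep(.y, .x))
  grid
}

# Assign whole cell groups to k folds, stratified by class: within each
# class, cells are shuffled, ordered by size, and placed greedily into the
# currently lightest fold. Every spectrum of a cell lands in one fold.
cell_folds <- function(meta, k = 10L, seed = 1L) {
  k <- as.integer(k)
  fold <- integer(nrow(meta))
  withr::with_seed(seed, {
    for (cl in unique(meta$class_label)) {
      rows <- which(meta$class_label == cl)
      key <- paste(meta$cell_line[rows], meta$cell_id[rows], sep = "\r")
      cells <- unique(key)
      if (length(cells) < k) {
        abort(sprintf("Class '%s' has %d cells; need >= %d for %d folds.",
                      cl, length(cells), k, k),
              class = "ramancell_cv_error")
      }
      cells <- sample(cells)
      sizes <- table(key)[cells]
      cells <- cells[order(-sizes)]
      load <- numeric(k)
      for (ce in cells) {
        f <- which.min(load)
        fold[rows[key == ce]] <- f
        load[f] <- load[f] + sum(key == ce)
      }
    }
  })
  fold
}

#' Cross-validated MLP architecture search
#'
#' Evaluates each candidate architecture by k-fold cross-validation on the
#' training data only, with folds stratified by class and grouped by cell
#' (no spectra from one cell appear in different folds). The selected
#' architecture maximizes mean fold accuracy; ties are broken toward fewer
#' parameters, then fewer layers.
#'
#' @param x Training feature matrix (e.g. PCA scores).
#' @param y Class labels.
#' @param meta Metadata tibble aligned with `x` rows, providing
#'   `cell_line`, `cell_id`, `class_label` for grouping.
#' @param architectures Grid from [mlp_architectures()].
#' @param k Number of folds (default 10).
#' @param seed RNG seed (fold assignment and per-fit seeds).
#' @param ... Passed to [fit_mlp()] (e.g. `max_epochs`).
#' @return A `raman_cv` object: tibble of per-architecture mean/SD fold
#'   accuracy plus the chosen layout.
#' @export
crossvalidate_mlp <- function(x, y, meta, architectures = mlp_architectures(),
                              k = 10L, seed = 1L, ...) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y), nrow(meta) == nrow(x))
  meta$class_label <- y
  fold <- cell_folds(meta, k = k, seed = seed)
  for (f in seq_len(k)) {
    if (length(unique(y[fold == f])) < 2 || length(unique(y[fold != f])) < 2) {
      abort("Degenerate fold: a fold contains a single class.",
            class = "ramancell_cv_error")
    }
  }
  res <- purrr::pmap(architectures, function(depth, width, layout) {
    acc <- vapply(seq_len(k), function(f) {
      te <- fold == f
      m <- fit_mlp(x[!te, , drop = FALSE], y[!te], hidden = layout,
                   positive = sort(unique(y))[1],
                   seed = seed + 1000L * f + depth * 10L + width, ...)
      mean(predict(m, x[te, , drop = FALSE], type = "class") == y[te])
    }, numeric(1))
    np <- mlp_n_params(ncol(x), layout)
    tibble(depth = depth, width = width, layout = list(layout),
           mean_accuracy = mean(acc), sd_accuracy = sd(acc), n_params = np)
  })
  tab <- dplyr::bind_rows(res)
  ord <- order(-tab$mean_accuracy, tab$n_params, tab$depth)
  chosen <- tab[ord[1], ]
  structure(list(results = tab, chosen = chosen, k = k, seed = seed),
            class = "raman_cv")
}

#' @export
tidy.raman_cv <- function(x, ...) x$results

#' @export
glance.raman_cv <- function(x, ...) {
  tibble(depth = x$chosen$depth, width = x$chosen$width,
         mean_accuracy = x$chosen$mean_accuracy,
         sd_accuracy = x$chosen$sd_accuracy, k = x$k)
}

#' @export
print.raman_cv <- function(x, ...) {
  cat(sprintf("%d-fold grouped CV over %d architectures; chosen: %d x %d (mean accuracy %.3f)\n",
              x$k, nrow(x$results), x$chosen$depth, x$chosen$width,
              x$chosen$mean_accuracy))
  invisible(x)
}
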