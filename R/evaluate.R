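#' Balance a two-class cohort by subsampling the majority class
#'
#' The minority class is kept whole; the majority class is subsampled
#' without replacement to the same spectrum count. Subsampling operates at
#' the cell level (shuffled whole cells are taken until the target is
#' reached; the last cell may contribute only part of its spectra) so the
#' balanced cohort keeps intact cell groups wherever possible.
#'
#' @param x A [raman_spectra] tibble with both classes present.
#' @param seed RNG seed for the subsample.
#' @return A balanced [raman_spectra] tibble.
#' @examples
#' cohort <- simulate_cohort(synthetic_config(per_line_counts =
#'   c("SF188-like" = 9, "adult-1" = 15)), seed = 1)
#' table(balance_classes(cohort$spectra, seed = 1)$class_label)
#' @export
balance_classes <- function(x, seed = 1L) {
  x <- as_raman_spectra(x)
  cc <- table(x$class_label)
  if (length(cc) < 2 || any(cc == 0)) {
    abort("Both classes must be present to balance.",
          class = "ramancell_empty_class_error")
  }
  n_target <- min(cc)
  minority <- names(cc)[which.min(cc)]
  majority <- setdiff(names(cc), minority)
  maj_rows <- which(x$class_label == majority)
  key <- paste(x$cell_line[maj_rows], x$cell_id[maj_rows], sep = "\r")
  pick <- withr::with_seed(seed, {
    cells <- sample(unique(key))
    chosen <- integer(0)
    for (ce in cells) {
      rows <- maj_rows[key == ce]
      need <- n_target - length(chosen)
      if (need <= 0) break
      if (length(rows) <= need) {
        chosen <- c(chosen, rows)
      } else {
        chosen <- c(chosen, sample(rows, need))
      }
    }
    chosen
  })
  out <- x[sort(c(which(x$class_label == minority), pick)), ]
  as_raman_spectra(out)
}

#' Grouped stratified train/test split
#'
#' Splits a balanced cohort into training and held-out test sets with all
#' spectra of a physical cell on the same side (no cell-level leakage) and
#' per-class test counts as close to `test_frac` as whole cell groups
#' allow. Deterministic given `seed`.
#'
#' @param x A balanced [raman_spectra] tibble.
#' @param test_frac Target test fraction per class (default 0.2).
#' @param seed RNG seed.
#' @return A `raman_split` tibble: `spectrum_id`, `cell_line`, `cell_id`,
#'   `class_label`, `set` (`"train"`/`"test"`).
#' @export
split_by_cell <- function(x, test_frac = 0.2, seed = 1L) {
  x <- as_raman_spectra(x)
  stopifnot(test_frac >= 0, test_frac < 1)
  set <- rep("train", nrow(x))
  withr::with_seed(seed, {
    for (cl in unique(x$class_label)) {
      rows <- which(x$class_label == cl)
      key <- paste(x$cell_line[rows], x$cell_id[rows], sep = "\r")
      cells <- unique(key)
      if (length(cells) < 2) {
        abort(sprintf("Class '%s' has fewer than 2 cell groups.", cl),
              class = "ramancell_split_error")
      }
      if (test_frac == 0) next
      cells <- sample(cells)
      sizes <- as.numeric(table(key)[cells])
      target <- test_frac * length(rows)
      cum <- cumsum(sizes)
      k <- which.min(abs(cum - target))
      if (abs(0 - target) < abs(cum[k] - target)) k <- 0L
      if (k > 0) {
        te <- key %in% cells[seq_len(k)]
        set[rows[te]] <- "test"
      }
    }
  })
  out <- tibble(spectrum_id = x$spectrum_id, cell_line = x$cell_line,
                cell_id = x$cell_id, class_label = x$class_label, set = set)
  attr(out, "seed") <- seed
  attr(out, "test_frac") <- test_frac
  class(out) <- c("raman_split", class(out))
  out
}

#' Held-out classification report
#'
#' Confusion counts and derived metrics with the pediatric phenotype as
#' the positive class: sensitivity = TP / (TP + FN) (pediatric recall),
#' specificity = TN / (TN + FP) (adult recall), precision, per-class F1,
#' overall accuracy, and the ROC AUC computed from the continuous
#' positive-class scores via midrank statistics (equivalent to the
#' trapezoidal area with tied scores handled by midpoint ranks).
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param score Positive-class scores in `[0, 1]` (optional but required
#'   for AUC/ROC).
#' @param positive Positive class (default `"pediatric"`).
#' @return A `raman_report` object; see [tidy.raman_report()],
#'   [glance.raman_report()], [autoplot.raman_report()].
#' @examples
#' r <- classification_report(
#'   truth = rep(c("pediatric", "adult"), c(4, 4)),
#'   predicted = c("pediatric", "pediatric", "pediatric", "adult",
#'                 "adult", "adult", "pediatric", "adult"),
#'   score = c(.9, .8, .7, .4, .2, .1, .6, .3)
#' )
#' glance(r)
#' @export
classification_report <- function(truth, predicted, score = NULL,
                                  positive = "pediatric") {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  if (!is.null(score)) {
    stopifnot(length(score) == length(truth), all(is.finite(score)))
  }
  negative <- setdiff(unique(c(truth, predicted)), positive)
  if (length(negative) == 0) negative <- "adult"
  if (length(negative) > 1) abort("More than two classes.",
                                  class = "ramancell_report_error")
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted == negative)
  fp <- sum(truth == negative & predicted == positive)
  tn <- sum(truth == negative & predicted == negative)
  n_pos <- tp + fn
  n_neg <- tn + fp
  sens <- if (n_pos > 0) tp / n_pos else NA_real_
  spec <- if (n_neg > 0) tn / n_neg else NA_real_
  prec_pos <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  prec_neg <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1_pos <- if (!is.na(prec_pos) && !is.na(sens) && prec_pos + sens > 0)
    2 * prec_pos * sens / (prec_pos + sens) else NA_real_
  f1_neg <- if (!is.na(prec_neg) && !is.na(spec) && prec_neg + spec > 0)
    2 * prec_neg * spec / (prec_neg + spec) else NA_real_
  auc <- NA_real_
  roc <- NULL
  if (!is.null(score)) {
    if (n_pos == 0 || n_neg == 0) {
      warn("Single-class truth: AUC undefined, reported as NA.")
    } else {
      auc <- rank_auc(score, truth == positive)
      roc <- roc_points(score, truth == positive)
    }
  }
  structure(list(
    counts = c(tp = tp, fn = fn, fp = fp, tn = tn),
    confusion_pct = matrix(
      100 * c(safe_div(tp, n_pos), safe_div(fn, n_pos),
              safe_div(fp, n_neg), safe_div(tn, n_neg)),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("Actual pediatric", "Actual adult"),
                      c("Predicted pediatric", "Predicted adult"))),
    accuracy = (tp + tn) / length(truth),
    sensitivity = sens, specificity = spec,
    precision = prec_pos,
    f1 = c(pediatric = f1_pos, adult = f1_neg),
    auc = auc, roc = roc,
    n_test = c(pediatric = n_pos, adult = n_neg),
    classes = c(positive = positive, negative = negative)
  ), class = "raman_report")
}

safe_div <- function(a, b) if (b > 0) a / b else NA_real_

# Midrank (Mann-Whitney) AUC: identical to the trapezoidal area under the
# ROC curve when tied scores are walked diagonally.
rank_auc <- function(score, is_pos) {
  r <- rank(score, ties.method = "average")
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(score, is_pos) {
  thr <- sort(unique(score), decreasing = TRUE)
  pts <- vapply(thr, function(t) {
    c(fpr = sum(!is_pos & score >= t) / sum(!is_pos),
      tpr = sum(is_pos & score >= t) / sum(is_pos))
  }, numeric(2))
  tibble(threshold = c(Inf, thr), fpr = c(0, pts["fpr", ]),
         tpr = c(0, pts["tpr", ]))
}

# Round half away from zero, as percentages are conventionally printed.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @describeIn classification_report One row per metric, percentages on
#'   the 0-100 scale alongside raw proportions.
#' @param x A `raman_report`.
#' @param ... Unused.
#' @export
tidy.raman_report <- function(x, ...) {
  tibble(metric = c("accuracy", "sensitivity", "specificity", "precision",
                    "f1_pediatric", "f1_adult", "auc"),
         value = c(x$accuracy, x$sensitivity, x$specificity, x$precision,
                   x$f1[["pediatric"]], x$f1[["adult"]], x$auc),
         percent = round_half_up(100 * .data$value, 1))
}

#' @describeIn classification_report One-row summary.
#' @export
glance.raman_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, auc = x$auc,
         f1_pediatric = x$f1[["pediatric"]], f1_adult = x$f1[["adult"]],
         n_test_pediatric = x$n_test[["pediatric"]],
         n_test_adult = x$n_test[["adult"]])
}

#' @export
print.raman_report <- function(x, ...) {
  cat("Held-out classification report (positive class: pediatric)\n")
  pct <- round_half_up(x$confusion_pct, 1)
  print(pct)
  cat(sprintf("accuracy %.1f%% | sensitivity %.1f%% | specificity %.1f%% | AUC %s\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  cat(sprintf("F1 pediatric %.1f%% | F1 adult %.1f%% | n_test %d + %d\n",
              100 * x$f1[["pediatric"]], 100 * x$f1[["adult"]],
              x$n_test[["pediatric"]], x$n_test[["adult"]]))
  invisible(x)
}
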