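#' Train a small multilayer perceptron for binary classification
#'
#' A fully connected feed-forward network with ReLU hidden activations and
#' a single sigmoid output, trained on binary cross-entropy with the Adam
#' optimizer (step size 1e-3, beta1 0.9, beta2 0.999) on shuffled
#' mini-batches. A stratified fraction of the training rows is held back
#' as a validation split for early stopping (patience in epochs, best
#' weights restored). Training is deterministic given `seed`.
#'
#' @param x Numeric feature matrix (rows = samples), e.g. PCA scores.
#' @param y Class labels; `positive` names the class mapped to output 1.
#' @param hidden Integer vector of hidden-layer widths, e.g. `c(5, 5, 5,
#'   5, 5)`; 1 to 10 layers.
#' @param positive Label of the positive class (default `"pediatric"`).
#' @param learning_rate Adam step size.
#' @param max_epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param validation_fraction Fraction per class held out for early
#'   stopping (0 disables early stopping).
#' @param patience Epochs without validation-loss improvement before
#'   stopping.
#' @param min_epochs Early stopping is not armed before this epoch (the
#'   best weights are tracked throughout); guards against bailing out on
#'   the noisy early part of the validation-loss curve.
#' @param n_starts Number of random initializations raced for
#'   `warmup_epochs` epochs; the one with the lowest monitor loss is
#'   trained to completion. Narrow deep ReLU networks occasionally start
#'   in a near-dead configuration and plateau; a short deterministic
#'   multi-start avoids that without changing the optimizer.
#' @param warmup_epochs Epochs per candidate during the warm-up race.
#' @param seed Integer RNG seed for initialization, shuffling and the
#'   validation split.
#' @return A `raman_mlp` object.
#' @export
fit_mlp <- function(x, y, hidden = c(5, 5, 5, 5, 5),
                    positive = "pediatric",
                    learning_rate = 1e-3, max_epochs = 500L,
                    batch_size = 32L, validation_fraction = 0.1,
                    patience = 20L, min_epochs = 100L, n_starts = 3L,
                    warmup_epochs = 30L, seed = 1L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) abort("Non-finite features.",
                                class = "ramancell_mlp_error")
  hidden <- as.integer(hidden)
  if (length(hidden) < 1 || length(hidden) > 10 || any(hidden < 1)) {
    abort("`hidden` must give 1 to 10 positive layer widths.",
          class = "ramancell_mlp_error")
  }
  y <- as.character(y)
  if (!positive %in% y || length(unique(y)) != 2) {
    abort("`y` must contain exactly 2 classes including `positive`.",
          class = "ramancell_mlp_error")
  }
  negative <- setdiff(unique(y), positive)
  t01 <- as.numeric(y == positive)

  fit <- withr::with_seed(seed, {
    n <- nrow(x)
    val_idx <- integer(0)
    if (validation_fraction > 0) {
      for (cl in c(0, 1)) {
        rows <- which(t01 == cl)
        n_val <- floor(length(rows) * validation_fraction)
        if (n_val >= 1) val_idx <- c(val_idx, sample(rows, n_val))
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(unique(t01[tr_idx])) < 2) {
      abort("Training split lost a class; reduce `validation_fraction`.",
            class = "ramancell_mlp_error")
    }
    monitor_idx <- if (length(val_idx)) val_idx else tr_idx
    run_epoch <- function(state) {
      ord <- sample(tr_idx)
      for (start in seq(1, length(ord), by = batch_size)) {
        b <- ord[start:min(start + batch_size - 1, length(ord))]
        g <- mlp_grad(state$par, x[b, , drop = FALSE], t01[b])
        upd <- adam_update(state$opt, state$par, g, learning_rate)
        state$par <- upd$par
        state$opt <- upd$opt
      }
      state$loss <- mlp_loss(state$par, x[monitor_idx, , drop = FALSE],
                             t01[monitor_idx])
      state
    }
    # warm-up race between a few initializations
    n_starts <- max(1L, as.integer(n_starts))
    warm <- min(warmup_epochs, max_epochs)
    cands <- vector("list", n_starts)
    for (s in seq_len(n_starts)) {
      st <- list(par = mlp_init(ncol(x), hidden), opt = NULL, loss = Inf)
      st$opt <- adam_state(st$par)
      if (n_starts > 1L) {
        for (e in seq_len(warm)) st <- run_epoch(st)
      }
      cands[[s]] <- st
    }
    st <- cands[[which.min(vapply(cands, `[[`, numeric(1), "loss"))]]
    used <- if (n_starts > 1L) warm else 0L
    best <- list(loss = st$loss, par = st$par, epoch = used)
    wait <- 0L
    history <- rep(NA_real_, used)
    for (epoch in seq_len(max_epochs - used) + used) {
      st <- run_epoch(st)
      history <- c(history, st$loss)
      if (st$loss < best$loss - 1e-8) {
        best <- list(loss = st$loss, par = st$par, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience && epoch >= min_epochs) break
      }
    }
    list(par = best$par, epochs = length(history), best_epoch = best$epoch,
         monitor_loss = best$loss, history = history)
  })

  structure(list(weights = fit$par, hidden = hidden,
                 classes = c(positive = positive, negative = negative),
                 n_features = ncol(x), seed = seed,
                 epochs = fit$epochs, best_epoch = fit$best_epoch,
                 monitor_loss = fit$monitor_loss),
            class = "raman_mlp")
}

# He-normal initialization for ReLU layers; zero biases.
mlp_init <- function(n_in, hidden) {
  sizes <- c(n_in, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    list(W = matrix(rnorm(sizes[l] * sizes[l + 1L], 0,
                          sqrt(2 / sizes[l])),
                    nrow = sizes[l]),
         b = rep(0, sizes[l + 1L]))
  })
}

# Forward pass; returns activations for backprop. Final layer is linear
# (logits); the sigmoid is folded into the loss for stability.
mlp_forward <- function(par, x) {
  acts <- vector("list", length(par) + 1L)
  acts[[1]] <- x
  a <- x
  for (l in seq_along(par)) {
    z <- a %*% par[[l]]$W + rep(1, nrow(a)) %o% par[[l]]$b
    a <- if (l < length(par)) pmax(z, 0) else z
    acts[[l + 1L]] <- a
  }
  acts
}

mlp_logits <- function(par, x) drop(mlp_forward(par, x)[[length(par) + 1L]])

sigmoid <- function(z) 1 / (1 + exp(-z))

# Mean binary cross-entropy from logits (numerically stable form).
mlp_loss <- function(par, x, t01) {
  z <- mlp_logits(par, x)
  mean(pmax(z, 0) - z * t01 + log1p(exp(-abs(z))))
}

mlp_grad <- function(par, x, t01) {
  acts <- mlp_forward(par, x)
  n <- nrow(x)
  L <- length(par)
  delta <- matrix(sigmoid(acts[[L + 1L]]) - t01, ncol = 1) / n
  g <- vector("list", L)
  for (l in rev(seq_len(L))) {
    g[[l]] <- list(W = crossprod(acts[[l]], delta),
                   b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(par[[l]]$W)) * (acts[[l]] > 0)
    }
  }
  g
}

adam_state <- function(par) {
  zero <- lapply(par, function(p) list(W = p$W * 0, b = p$b * 0))
  list(m = zero, v = zero, t = 0L)
}

adam_update <- function(opt, par, g, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (l in seq_along(par)) {
    for (nm in c("W", "b")) {
      opt$m[[l]][[nm]] <- beta1 * opt$m[[l]][[nm]] + (1 - beta1) * g[[l]][[nm]]
      opt$v[[l]][[nm]] <- beta2 * opt$v[[l]][[nm]] + (1 - beta2) * g[[l]][[nm]]^2
      par[[l]][[nm]] <- par[[l]][[nm]] - lr * (opt$m[[l]][[nm]] / c1) /
        (sqrt(opt$v[[l]][[nm]] / c2) + eps)
    }
  }
  list(par = par, opt = opt)
}

#' Predict from a fitted MLP
#'
#' @param object A `raman_mlp`.
#' @param newdata Feature matrix with the training feature count.
#' @param type `"prob"` for positive-class probabilities, `"class"` for
#'   hard labels at the 0.5 threshold.
#' @param ... Unused.
#' @return Numeric probabilities in `[0, 1]` or a character label vector.
#' @export
predict.raman_mlp <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$n_features)
  p <- sigmoid(mlp_logits(object$weights, newdata))
  if (type == "prob") return(p)
  ifelse(p >= 0.5, object$classes[["positive"]], object$classes[["negative"]])
}

#' @export
print.raman_mlp <- function(x, ...) {
  cat(sprintf("MLP %s -> 1 (ReLU/Adam), %d epochs (best %d), positive class '%s'\n",
              paste(c(x$n_features, x$hidden), collapse = "-"),
              x$epochs, x$best_epoch, x$classes[["positive"]]))
  invisible(x)
}

mlp_n_params <- function(n_in, hidden) {
  sizes <- c(n_in, hidden, 1L)
  sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])
}
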