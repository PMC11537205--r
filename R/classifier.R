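#' Training configuration for the patch classifier
#'
#' Captures the training contract: minibatch steps with class-balanced
#' batches, Adam, cross-entropy loss, a one-cycle learning-rate schedule,
#' and checkpoint selection by lowest validation loss. The reference
#' protocol trains for 20,000 steps; the desk default of 2,000 keeps a full
#' run on one CPU core to a couple of minutes while exercising the whole
#' contract (the full value remains selectable).
#'
#' @param n_steps Number of optimization steps (desk default 2000).
#' @param batch_size Examples per batch (default 256).
#' @param learning_rate Peak learning rate of the one-cycle schedule
#'   (default 0.001).
#' @param schedule Only \code{"one_cycle"} is implemented: linear warmup
#'   over the first 30\% of steps from \code{learning_rate / 25}, then
#'   cosine annealing to \code{learning_rate / 1e4}.
#' @param hidden_units Width of the hidden layer (default 48).
#' @param pool_factor Average-pooling factor applied to patches before
#'   flattening (default 2).
#' @param checkpoint_every Validation-loss evaluation interval in steps.
#' @param seed Integer seed covering initialization and batch sampling.
#' @return A list of class \code{train_config}.
#' @export
train_config <- function(n_steps = 2000L, batch_size = 256L,
                         learning_rate = 0.001, schedule = "one_cycle",
                         hidden_units = 48L, pool_factor = 2L,
                         checkpoint_every = 100L, seed = 1L) {
  stopifnot(n_steps >= 1, batch_size >= 1, learning_rate > 0,
            hidden_units >= 1, pool_factor >= 1, checkpoint_every >= 1)
  if (!identical(schedule, "one_cycle")) stop("only the one-cycle schedule is implemented")
  structure(list(n_steps = as.integer(n_steps),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, schedule = schedule,
                 hidden_units = as.integer(hidden_units),
                 pool_factor = as.integer(pool_factor),
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

one_cycle_lr <- function(step, n_steps, max_lr, pct_start = 0.3) {
  warm <- max(1, floor(n_steps * pct_start))
  if (step <= warm) {
    max_lr / 25 + (max_lr - max_lr / 25) * (step / warm)
  } else {
    t <- (step - warm) / max(1, n_steps - warm)
    end_lr <- max_lr / 1e4
    end_lr + (max_lr - end_lr) * (1 + cos(pi * t)) / 2
  }
}

# Flatten patch records to a feature matrix: average-pool each channel by
# `pool`, flatten, then standardize so each sample has mean 0 / SD 1 and
# inference is independent of batch composition and size (the per-sample
# normalization contract).
patches_to_features <- function(patches, pool = 2L) {
  stopifnot(length(patches) > 0L)
  d <- dim(patches[[1L]]$pixels)
  nb <- d[1:2] %/% pool
  pool_plane <- function(m) {
    m <- m[seq_len(nb[1] * pool), seq_len(nb[2] * pool), drop = FALSE]
    # block mean via two rowsum-style contractions
    g1 <- rowsum(m, rep(seq_len(nb[1]), each = pool))
    t(rowsum(t(g1), rep(seq_len(nb[2]), each = pool))) / pool^2
  }
  X <- matrix(0, length(patches), nb[1] * nb[2] * d[3])
  for (i in seq_along(patches)) {
    px <- patches[[i]]$pixels
    if (!identical(dim(px), d)) stop("dimension error: patch shapes differ")
    v <- unlist(lapply(seq_len(d[3]), function(k) pool_plane(px[, , k])),
                use.names = FALSE)
    X[i, ] <- v
  }
  mu <- rowMeans(X)
  sdv <- sqrt(rowMeans((X - mu)^2))
  (X - mu) / (sdv + 1e-8)
}

patch_labels <- function(patches) {
  vapply(patches, function(p) p$label, "")
}

#' Train the compact patch classifier
#'
#' A compact single-hidden-layer network over pooled, per-sample
#' standardized patch pixels, trained with class-balanced batches, Adam,
#' cross-entropy and the one-cycle schedule; the returned model carries the
#' weights of the step with the lowest validation loss. The backbone is a
#' configuration choice: the testable surface is the training and
#' normalization contract, and every internal normalization is per sample,
#' so predictions are identical whatever the batch they are computed in.
#'
#' @param train_patches,val_patches Lists of patch records (see
#'   \code{\link{extract_patches}}); both non-empty.
#' @param config A \code{train_config}.
#' @param classes Class list defining output order (default: the 14-class
#'   list of the packaged rule table). Every class must have at least one
#'   training example.
#' @return An object of class \code{patch_classifier} with elements
#'   \code{weights}, \code{classes}, \code{config}, \code{log} (data frame
#'   of step, lr, train_loss, val_loss), \code{best_step},
#'   \code{best_val_loss}.
#' @export
train_classifier <- function(train_patches, val_patches,
                             config = train_config(),
                             classes = rule_classes(default_rule_table())) {
  stopifnot(inherits(config, "train_config"),
            length(train_patches) > 0L, length(val_patches) > 0L)
  ytr <- patch_labels(train_patches)
  extra <- setdiff(unique(ytr), classes)
  if (length(extra)) stop("training labels outside class list: ",
                          paste(extra, collapse = ", "))
  Xtr <- patches_to_features(train_patches, config$pool_factor)
  Xva <- patches_to_features(val_patches, config$pool_factor)
  yva <- match(patch_labels(val_patches), classes)
  if (anyNA(yva)) stop("validation labels outside class list")
  K <- length(classes)
  D <- ncol(Xtr)
  H <- config$hidden_units

  batches <- balanced_batch_indices(
    ytr, n_batches = config$n_steps, batch_size = config$batch_size,
    classes = classes, seed = config$seed)

  ce_loss <- function(S, yidx) {
    S <- S - apply(S, 1L, max)
    logZ <- log(rowSums(exp(S)))
    mean(logZ - S[cbind(seq_along(yidx), yidx)])
  }
  forward_scores <- function(X, W) {
    A <- pmax(X %*% W$W1 + rep(W$b1, each = nrow(X)), 0)
    A %*% W$W2 + rep(W$b2, each = nrow(X))
  }

  with_private_seed(config$seed + 1L, {
    W <- list(
      W1 = matrix(stats::rnorm(D * H, 0, sqrt(2 / D)), D, H),
      b1 = numeric(H),
      W2 = matrix(stats::rnorm(H * K, 0, sqrt(2 / H)), H, K),
      b2 = numeric(K))
    m <- lapply(W, function(p) p * 0)
    v <- lapply(W, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    log_rows <- vector("list", config$n_steps)
    best <- list(loss = Inf, step = 0L, W = W)
    yidx_tr <- match(ytr, classes)

    for (step in seq_len(config$n_steps)) {
      idx <- batches[[step]]
      Xb <- Xtr[idx, , drop = FALSE]
      yb <- yidx_tr[idx]
      Z1 <- Xb %*% W$W1 + rep(W$b1, each = nrow(Xb))
      A <- pmax(Z1, 0)
      S <- A %*% W$W2 + rep(W$b2, each = nrow(Xb))
      Sm <- S - apply(S, 1L, max)
      E <- exp(Sm)
      P <- E / rowSums(E)
      loss <- mean(log(rowSums(E)) - Sm[cbind(seq_along(yb), yb)])
      G <- P
      G[cbind(seq_along(yb), yb)] <- G[cbind(seq_along(yb), yb)] - 1
      G <- G / nrow(Xb)
      grads <- list(
        W1 = crossprod(Xb, (G %*% t(W$W2)) * (Z1 > 0)),
        b1 = colSums((G %*% t(W$W2)) * (Z1 > 0)),
        W2 = crossprod(A, G),
        b2 = colSums(G))
      lr <- one_cycle_lr(step, config$n_steps, config$learning_rate)
      for (nm in names(W)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^step)
        vhat <- v[[nm]] / (1 - beta2^step)
        W[[nm]] <- W[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      val_loss <- NA_real_
      if (step %% config$checkpoint_every == 0L || step == config$n_steps) {
        val_loss <- ce_loss(forward_scores(Xva, W), yva)
        if (val_loss < best$loss) best <- list(loss = val_loss, step = step, W = W)
      }
      log_rows[[step]] <- c(step = step, lr = lr, train_loss = loss,
                            val_loss = val_loss)
    }
    log <- as.data.frame(do.call(rbind, log_rows))
    structure(list(weights = best$W, classes = classes, config = config,
                   log = log, best_step = best$step, best_val_loss = best$loss),
              class = "patch_classifier")
  })
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat(sprintf(
    "<patch_classifier> %d classes, %d hidden units; best val loss %.4f at step %d/%d\n",
    length(x$classes), x$config$hidden_units, x$best_val_loss, x$best_step,
    x$config$n_steps))
  invisible(x)
}

#' Predict classes for patches
#'
#' Per-patch argmax label plus the full per-class score (softmax
#' probability) matrix; the class order is the model's fixed class list.
#' Because all normalization is per sample, predictions do not depend on
#' how patches are batched.
#'
#' @param model A \code{patch_classifier}.
#' @param patches List of patch records with the same patch shape used in
#'   training.
#' @return List with \code{label} (character vector) and \code{scores}
#'   (numeric matrix, one column per class).
#' @export
predict_patches <- function(model, patches) {
  stopifnot(inherits(model, "patch_classifier"))
  X <- patches_to_features(patches, model$config$pool_factor)
  if (ncol(X) != nrow(model$weights$W1)) {
    stop("dimension error: patch features (", ncol(X),
         ") do not match the model input (", nrow(model$weights$W1), ")")
  }
  W <- model$weights
  A <- pmax(X %*% W$W1 + rep(W$b1, each = nrow(X)), 0)
  S <- A %*% W$W2 + rep(W$b2, each = nrow(X))
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  P <- E / rowSums(E)
  colnames(P) <- model$classes
  list(label = model$classes[max.col(P, ties.method = "first")], scores = P)
}

#' Save / load a trained classifier
#'
#' The checkpoint is an RDS file with a JSON sidecar recording the class
#' list and configuration; the training log goes to CSV next to it.
#'
#' @param model A \code{patch_classifier}.
#' @param path RDS path; sidecar and log paths are derived from it.
#' @return \code{write_classifier}: invisibly, \code{path};
#'   \code{read_classifier}: a \code{patch_classifier}.
#' @export
write_classifier <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(classes = model$classes, config = unclass(model$config),
         best_step = model$best_step, best_val_loss = model$best_val_loss),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(model$log, paste0(path, ".log.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  readRDS(path)
}
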