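#' Estimated-model-accuracy features
#'
#' Four per-model features feed the accuracy estimator: the target
#' sequence length, the effective sequence count of the alignment, and
#' the sum and mean over residue pairs of the first-iteration distogram
#' likelihood of the bin containing each pair's model Cβ–Cβ distance
#' (distances of 19 Å or more map to the unbounded final bin).
#'
#' @param model A [fold_model()].
#' @param d The first-iteration [distogram()] (same length).
#' @param neff Effective sequence count of the target's alignment.
#' @param min_separation Minimum |i - j| for a pair to contribute.
#' @return An object of class `ema_features`: named numeric vector
#'   `length`, `neff`, `sum_lik`, `mean_lik`.
#' @export
ema_features <- function(model, d, neff, min_separation = 2) {
  stopifnot(inherits(d, "distogram"))
  if (model$length != d$length)
    stop("model and distogram lengths differ")
  L <- d$length
  cbm <- cb_distance_matrix(model)
  idx <- which(upper.tri(cbm), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] >= min_separation, , drop = FALSE]
  bins <- bin_index(d$scheme, cbm[idx])
  lik <- d$likelihoods[cbind(idx, bins)]
  structure(c(length = L, neff = neff, sum_lik = sum(lik),
              mean_lik = mean(lik)),
            class = "ema_features")
}

selu <- function(x) {
  lambda <- 1.0507009873554805; alpha <- 1.6732632423543772
  lambda * ifelse(x > 0, x, alpha * (exp(x) - 1))
}
selu_grad <- function(x) {
  lambda <- 1.0507009873554805; alpha <- 1.6732632423543772
  lambda * ifelse(x > 0, 1, alpha * exp(x))
}

#' Accuracy-estimator network
#'
#' A small fully connected softmax network: 4 standardized inputs, two
#' hidden layers of 10 units with SELU activations, and 10 softmax
#' outputs corresponding to the TM-score ranges 0 <= s < 0.1, ...,
#' 0.9 < s <= 1.0.
#'
#' @param weights Optional list `W1, b1, W2, b2, W3, b3` (4 x 10,
#'   10 x 10, 10 x 10 weight matrices with length-10 biases); zeros by
#'   default.
#' @param feature_means,feature_sds Standardization statistics for the 4
#'   features.
#' @return An object of class `ema_network`.
#' @export
ema_network <- function(weights = NULL,
                        feature_means = rep(0, 4),
                        feature_sds = rep(1, 4)) {
  if (is.null(weights))
    weights <- list(W1 = matrix(0, 4, 10), b1 = numeric(10),
                    W2 = matrix(0, 10, 10), b2 = numeric(10),
                    W3 = matrix(0, 10, 10), b3 = numeric(10))
  stopifnot(all(dim(weights$W1) == c(4, 10)),
            all(dim(weights$W2) == c(10, 10)),
            all(dim(weights$W3) == c(10, 10)))
  structure(list(weights = weights,
                 feature_means = feature_means,
                 feature_sds = feature_sds),
            class = "ema_network")
}

# forward pass on a feature matrix (n x 4); returns n x 10 probabilities
# plus cached activations when `cache = TRUE`
ema_forward_matrix <- function(net, F, cache = FALSE) {
  Z <- sweep(sweep(F, 2, net$feature_means), 2, net$feature_sds, "/")
  w <- net$weights
  a1 <- sweep(Z %*% w$W1, 2, w$b1, "+"); h1 <- selu(a1)
  a2 <- sweep(h1 %*% w$W2, 2, w$b2, "+"); h2 <- selu(a2)
  a3 <- sweep(h2 %*% w$W3, 2, w$b3, "+")
  a3 <- a3 - apply(a3, 1, max)
  p <- exp(a3); p <- p / rowSums(p)
  if (cache) list(p = p, Z = Z, a1 = a1, h1 = h1, a2 = a2, h2 = h2)
  else p
}

#' Forward pass of the accuracy estimator
#'
#' Standardizes the features with the network's stored means and
#' standard deviations and returns the 10 softmax class probabilities.
#'
#' @param net An [ema_network()].
#' @param f An [ema_features()] vector (or any length-4 numeric).
#' @return Numeric vector of 10 probabilities summing to 1.
#' @export
ema_forward <- function(net, f) {
  stopifnot(inherits(net, "ema_network"))
  as.numeric(ema_forward_matrix(net, matrix(as.numeric(f), 1, 4)))
}

#' Expected TM-score from class probabilities
#'
#' The weighted mean of the TM-range midpoints 0.05, 0.15, ..., 0.95
#' under the softmax output.
#'
#' @param probs Numeric vector of 10 normalized class probabilities.
#' @return Expected TM-score in \[0, 1\].
#' @export
expected_tm <- function(probs) {
  if (length(probs) != 10 || abs(sum(probs) - 1) > 1e-6 || any(probs < 0))
    stop("probs must be 10 normalized class probabilities")
  sum(probs * seq(0.05, 0.95, by = 0.1))
}

# TM-score -> class in 1..10; upper edge inclusive on the last class
tm_class <- function(tm) pmin(pmax(floor(tm * 10) + 1L, 1L), 10L)

#' Train the accuracy estimator
#'
#' Trains the 4-10-10-10 softmax network by cross-entropy on TM-score
#' classes with the adaptive-moment (Adam) optimizer at a maximum
#' learning rate of 1e-3, over repeated random 70/15/15
#' train/validation/test splits (100 repeats by default).  Reported
#' precision and recall compare predicted expected TM > 0.5 against
#' observed TM > 0.5 on the held-out test sets.  The returned network is
#' the one with the best validation loss across repeats.  A dataset
#' whose observed TM values all fall in one class is refused.
#'
#' @param features n x 4 matrix of [ema_features()] rows.
#' @param tm Observed TM-scores, length n (n >= 50).
#' @param rng_seed Integer seed.
#' @param repeats Number of random splits (default 100).
#' @param epochs Training epochs per repeat.
#' @return A list: `network` ([ema_network()]), `precision`, `recall`
#'   (cross-validated, at the 0.5 fold threshold), `repeats`.
#' @export
train_ema <- function(features, tm, rng_seed = 1L, repeats = 100L,
                      epochs = 300L) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == 4, length(tm) == nrow(features))
  if (nrow(features) < 50) stop("training needs at least 50 examples")
  if (length(unique(tm_class(tm))) < 2)
    stop("degenerate dataset: all observed TM-scores in a single class")
  n <- nrow(features)
  mu <- colMeans(features)
  sdv <- pmax(apply(features, 2, stats::sd), 1e-9)
  cls <- tm_class(tm)
  Y <- matrix(0, n, 10); Y[cbind(seq_len(n), cls)] <- 1
  train_one <- function(idx_tr, idx_va) {
    w <- list(W1 = matrix(stats::rnorm(40, sd = sqrt(1 / 4)), 4, 10),
              b1 = numeric(10),
              W2 = matrix(stats::rnorm(100, sd = sqrt(1 / 10)), 10, 10),
              b2 = numeric(10),
              W3 = matrix(stats::rnorm(100, sd = sqrt(1 / 10)), 10, 10),
              b3 = numeric(10))
    ms <- lapply(w, function(x) x * 0); vs <- lapply(w, function(x) x * 0)
    lr <- 1e-3; b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
    net <- ema_network(w, mu, sdv)
    best_va <- Inf; best_w <- w
    Ftr <- features[idx_tr, , drop = FALSE]; Ytr <- Y[idx_tr, , drop = FALSE]
    Fva <- features[idx_va, , drop = FALSE]; Yva <- Y[idx_va, , drop = FALSE]
    t_step <- 0
    for (ep in seq_len(epochs)) {
      net$weights <- w
      fw <- ema_forward_matrix(net, Ftr, cache = TRUE)
      delta3 <- (fw$p - Ytr) / nrow(Ftr)
      gW3 <- crossprod(fw$h2, delta3); gb3 <- colSums(delta3)
      d2 <- (delta3 %*% t(w$W3)) * selu_grad(fw$a2)
      gW2 <- crossprod(fw$h1, d2); gb2 <- colSums(d2)
      d1 <- (d2 %*% t(w$W2)) * selu_grad(fw$a1)
      gW1 <- crossprod(fw$Z, d1); gb1 <- colSums(d1)
      gs <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3,
                 b3 = gb3)
      t_step <- t_step + 1
      for (k in names(w)) {
        ms[[k]] <- b1m * ms[[k]] + (1 - b1m) * gs[[k]]
        vs[[k]] <- b2m * vs[[k]] + (1 - b2m) * gs[[k]]^2
        mhat <- ms[[k]] / (1 - b1m^t_step)
        vhat <- vs[[k]] / (1 - b2m^t_step)
        w[[k]] <- w[[k]] - lr * mhat / (sqrt(vhat) + eps)
      }
      if (ep %% 25 == 0 || ep == epochs) {
        net$weights <- w
        pv <- ema_forward_matrix(net, Fva)
        va <- -mean(log(pmax(pv[Yva == 1], 1e-12)))
        if (va < best_va) { best_va <- va; best_w <- w }
      }
    }
    list(w = best_w, va = best_va)
  }
  with_seed(rng_seed, {
    tp <- fp <- fn <- 0
    best_overall <- NULL; best_va <- Inf
    for (r in seq_len(repeats)) {
      idx <- sample.int(n)
      n_tr <- round(0.70 * n); n_va <- round(0.15 * n)
      idx_tr <- idx[seq_len(n_tr)]
      idx_va <- idx[n_tr + seq_len(n_va)]
      idx_te <- idx[(n_tr + n_va + 1):n]
      fit <- train_one(idx_tr, idx_va)
      net <- ema_network(fit$w, mu, sdv)
      pte <- ema_forward_matrix(net, features[idx_te, , drop = FALSE])
      pred_tm <- pte %*% seq(0.05, 0.95, by = 0.1)
      pred_pos <- pred_tm > 0.5; obs_pos <- tm[idx_te] > 0.5
      tp <- tp + sum(pred_pos & obs_pos)
      fp <- fp + sum(pred_pos & !obs_pos)
      fn <- fn + sum(!pred_pos & obs_pos)
      if (fit$va < best_va) { best_va <- fit$va; best_overall <- fit$w }
    }
    list(network = ema_network(best_overall, mu, sdv),
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         repeats = repeats)
  })
}

#' Serialize an accuracy-estimator network as JSON
#'
#' @param net An [ema_network()].
#' @param path Output file.
#' @export
write_ema <- function(net, path) {
  stopifnot(inherits(net, "ema_network"))
  jsonlite::write_json(
    list(feature_means = net$feature_means,
         feature_sds = net$feature_sds,
         weights = net$weights),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_ema
#' @export
read_ema <- function(path) {
  x <- jsonlite::fromJSON(path)
  w <- x$weights
  ema_network(list(W1 = w$W1, b1 = as.numeric(w$b1),
                   W2 = w$W2, b2 = as.numeric(w$b2),
                   W3 = w$W3, b3 = as.numeric(w$b3)),
              as.numeric(x$feature_means), as.numeric(x$feature_sds))
}
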