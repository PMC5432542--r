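#' One-hidden-layer count regression network
#'
#' Predicts the expected number of plants in an object from its features:
#' `count = b2 + w2 . tanh(W1 x_norm + b1)`, with per-feature z-score input
#' normalization and `k_n` tangent-sigmoid hidden nodes feeding one linear
#' output node. Fitted by Levenberg-Marquardt least squares on the training
#' objects (see [train_network()]).
#'
#' @name count_model
NULL

new_count_model <- function(W1, b1, w2, b2, feature_subset, center, scale,
                            k_n, seed) {
  structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                 feature_subset = feature_subset,
                 center = center, scale = scale, k_n = k_n, seed = seed),
            class = "count_model")
}

#' @export
print.count_model <- function(x, ...) {
  cat(sprintf("<count_model %d hidden nodes, %d features: %s>\n",
              x$k_n, length(x$feature_subset),
              paste(x$feature_subset, collapse = ", ")))
  invisible(x)
}

as_feature_matrix <- function(X, subset = NULL) {
  if (is.data.frame(X)) {
    cols <- subset %||% intersect(FEATURE_NAMES, names(X))
    missing <- setdiff(cols, names(X))
    if (length(missing)) {
      wd_error("wheatdens_schema_error",
               paste("missing feature columns:", paste(missing, collapse = ", ")))
    }
    X <- as.matrix(X[, cols, drop = FALSE])
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
    if (!is.null(subset)) {
      missing <- setdiff(subset, colnames(X))
      if (length(missing)) {
        wd_error("wheatdens_schema_error",
                 paste("missing feature columns:", paste(missing, collapse = ", ")))
      }
      X <- X[, subset, drop = FALSE]
    }
  }
  storage.mode(X) <- "double"
  X
}

mlp_unpack <- function(p, k, m) {
  list(W1 = matrix(p[seq_len(k * m)], k, m),
       b1 = p[k * m + seq_len(k)],
       w2 = p[k * m + k + seq_len(k)],
       b2 = p[k * m + 2 * k + 1])
}

mlp_forward <- function(par, Xn) {
  H <- tanh(Xn %*% t(par$W1) + matrix(par$b1, nrow(Xn), length(par$b1), byrow = TRUE))
  as.numeric(H %*% par$w2 + par$b2)
}

#' Train the plants-per-object network
#'
#' Fits the network weights by Levenberg-Marquardt on the mean squared error
#' over normalized inputs, with a small L2 weight penalty for conditioning.
#' Optimization runs in chunks with an internal validation split: the weights
#' retained are those with the best validation RMSE, and fitting stops early
#' when validation stops improving. Several random restarts are tried and the
#' best kept; everything is deterministic given `seed`.
#'
#' @param X feature matrix or feature-table `data.frame` (columns F1..F13).
#' @param y nonnegative plant counts per object (0 = null object).
#' @param k_n hidden nodes (default 2, the architecture retained at all three
#'   calibration sites).
#' @param seed RNG seed controlling initialization and the validation split.
#' @param n_starts random restarts.
#' @param max_iter total Levenberg-Marquardt iteration budget.
#' @param weight_decay L2 penalty on the weights.
#' @return A [count_model].
#' @export
train_network <- function(X, y, k_n = 2L, seed = 1L, n_starts = 3L,
                          max_iter = 200L, weight_decay = 1e-4) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  wd_assert(n == length(y) && n > 0, "wheatdens_schema_error",
            "X and y sizes disagree or empty")
  wd_assert(all(y >= 0), "wheatdens_schema_error", "counts must be nonnegative")
  wd_assert(k_n >= 1 && k_n <= 10, "wheatdens_schema_error", "k_n must be in 1..10")
  if (n < 10 * k_n) {
    wd_error("wheatdens_schema_error",
             sprintf("need at least %d training objects for k_n = %d", 10 * k_n, k_n))
  }
  sds <- apply(X, 2, stats::sd)
  drop <- sds <= 0 | !is.finite(sds)
  if (any(drop)) {
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(colnames(X)[drop], collapse = ", ")))
    X <- X[, !drop, drop = FALSE]
  }
  wd_assert(ncol(X) >= 1, "wheatdens_schema_error", "no usable features left")
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  Xn <- sweep(sweep(X, 2, center), 2, scale, "/")
  m <- ncol(Xn)
  k <- as.integer(k_n)
  np <- k * m + 2 * k + 1

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(seed, 1L))

  # internal validation split for early stopping (falls back to training
  # error on very small sets)
  n_val <- floor(0.1 * n)
  use_val <- n_val >= 5
  val_idx <- if (use_val) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- Xn[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xva <- Xn[val_idx, , drop = FALSE]; yva <- y[val_idx]

  resid_fn <- function(p) {
    par <- mlp_unpack(p, k, m)
    c(mlp_forward(par, Xtr) - ytr, sqrt(weight_decay) * p)
  }
  chunk <- 25L
  best <- NULL; best_score <- Inf
  for (s in seq_len(n_starts)) {
    p <- stats::runif(np, -0.5, 0.5)
    # give the linear output a head start: init b2 at the mean count
    p[np] <- mean(ytr)
    local_best <- p; local_score <- Inf; stall <- 0L; used <- 0L
    while (used < max_iter && stall < 2L) {
      # maxiter is intentionally hit chunk by chunk; silence that warning
      fit <- suppressWarnings(
        minpack.lm::nls.lm(par = p, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = chunk, ptol = 1e-10, ftol = 1e-10)))
      p <- fit$par
      used <- used + chunk
      par <- mlp_unpack(p, k, m)
      score <- if (use_val) sqrt(mean((mlp_forward(par, Xva) - yva)^2))
               else sqrt(mean((mlp_forward(par, Xtr) - ytr)^2))
      if (score < local_score - 1e-9) {
        local_score <- score; local_best <- p; stall <- 0L
      } else stall <- stall + 1L
      if (fit$info %in% c(1, 2, 3, 4)) break  # converged
    }
    if (local_score < best_score) { best_score <- local_score; best <- local_best }
  }
  par <- mlp_unpack(best, k, m)
  colnames(par$W1) <- colnames(Xn)
  new_count_model(par$W1, par$b1, par$w2, par$b2,
                  feature_subset = colnames(Xn),
                  center = center, scale = scale, k_n = k, seed = seed)
}

#' Predict continuous plants-per-object
#'
#' Predictions are real-valued (the expected count), clipped below at zero,
#' never rounded: averaging continuous counts over many objects is what makes
#' the density estimate unbiased.
#'
#' @param model a [count_model].
#' @param X feature matrix or feature table covering the model's subset.
#' @return Numeric vector of predicted counts.
#' @export
predict_counts <- function(model, X) {
  X <- as_feature_matrix(X, subset = model$feature_subset)
  Xn <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  pred <- mlp_forward(model, Xn)
  pmax(pred, 0)
}

#' @export
predict.count_model <- function(object, newdata, ...) predict_counts(object, newdata)

#' Weight-based feature importance
#'
#' `importance(j) = sum_h |W1[h, j]| * |w2[h]|`: the absolute influence each
#' input can exert on the output through every hidden node. Descending order;
#' ties resolved by feature position.
#'
#' @param model a [count_model].
#' @return `data.frame(feature, importance)` in decreasing importance.
#' @export
feature_importance <- function(model) {
  imp <- as.numeric(abs(model$w2) %*% abs(model$W1))
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = model$feature_subset[ord], importance = imp[ord],
             row.names = NULL)
}

#' Evaluation report: R2, RMSE and bias on held-out objects
#'
#' @param model a [count_model].
#' @param X_test,y_test held-out features and true counts.
#' @return `list(R2, RMSE, Bias, n)`; Bias is `mean(predicted - observed)`.
#' @export
evaluate <- function(model, X_test, y_test) {
  y_test <- as.numeric(y_test)
  wd_assert(length(y_test) > 0, "wheatdens_schema_error", "empty test set")
  pred <- predict_counts(model, X_test)
  resid <- pred - y_test
  ss_tot <- sum((y_test - mean(y_test))^2)
  list(R2 = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_,
       RMSE = sqrt(mean(resid^2)),
       Bias = mean(resid),
       n = length(y_test))
}

# one repeated-split RMSE measurement used by RFE and architecture search
holdout_rmse <- function(X, y, k_n, reps, seed, n_starts = 2L, max_iter = 100L,
                         weight_decay = 1e-4) {
  n <- nrow(X)
  vapply(seq_len(reps), function(r) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(derive_seed(seed, 100 + r))
    test_idx <- sample.int(n, max(1L, floor(0.1 * n)))
    fit <- train_network(X[-test_idx, , drop = FALSE], y[-test_idx], k_n = k_n,
                         seed = derive_seed(seed, 200 + r),
                         n_starts = n_starts, max_iter = max_iter,
                         weight_decay = weight_decay)
    ev <- evaluate(fit, X[test_idx, , drop = FALSE], y[test_idx])
    ev$RMSE
  }, numeric(1))
}

#' Select the number of hidden nodes
#'
#' Repeated random 90/10 splits for each candidate `k_n`; the retained
#' architecture is the smallest one whose mean held-out RMSE is statistically
#' tied with the best (within `tolerance`, by default the same 2% band the
#' feature-elimination criterion uses), so network size is never inflated by
#' split noise.
#'
#' @param X,y training features and counts.
#' @param k_range candidate hidden-node counts.
#' @param reps random splits per candidate.
#' @param seed RNG seed.
#' @param tolerance relative RMSE band counting as a tie.
#' @return `list(k_n, rmse)` where `rmse` is the per-candidate mean curve.
#' @export
select_architecture <- function(X, y, k_range = 1:10, reps = 5L, seed = 1L,
                                tolerance = 1.02) {
  X <- as_feature_matrix(X)
  rmse <- vapply(k_range, function(k)
    mean(holdout_rmse(X, y, k_n = k, reps = reps, seed = seed)),
    numeric(1))
  # absolute floor (0.01 plants) so near-zero RMSE targets still tie
  best <- k_range[which(rmse <= tolerance * min(rmse) + 0.01)[1]]
  list(k_n = as.integer(best), rmse = stats::setNames(rmse, paste0("k", k_range)))
}

#' Recursive feature elimination for the count network
#'
#' Starting from all features, repeatedly: measure the mean held-out RMSE of
#' the current subset over repeated 90/10 splits, rank features by the
#' weight-based importance averaged over the split models, and drop the least
#' important one. After reaching a single feature, the retained subset is the
#' smallest one whose RMSE is below `1.02 x RMSE_best`, where `RMSE_best` is
#' the minimum RMSE observed along the elimination path. The final model is
#' retrained on that subset with the full data.
#'
#' @param X feature matrix or feature table (the 13 standard features).
#' @param y true plants per object.
#' @param k_n hidden nodes (default 2).
#' @param reps 90/10 splits per subset size (default 5).
#' @param seed RNG seed.
#' @param tolerance RMSE inflation tolerated relative to the best subset.
#' @return `list(trace, chosen_n, chosen_features, rmse_best, model)`; `trace`
#'   is a data.frame with one row per subset size n (n, rmse, features).
#' @export
recursive_feature_elimination <- function(X, y, k_n = 2L, reps = 5L, seed = 1L,
                                          tolerance = 1.02, weight_decay = 1e-4) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  current <- colnames(X)
  trace <- data.frame(n = integer(0), rmse = numeric(0), features = character(0))
  subsets <- list()
  while (length(current) >= 1) {
    n_feat <- length(current)
    Xs <- X[, current, drop = FALSE]
    rmse_r <- numeric(reps)
    imp_sum <- stats::setNames(numeric(n_feat), current)
    for (r in seq_len(reps)) {
      # the same `reps` splits are reused at every subset size (a paired
      # design: subset sizes are compared on identical held-out draws, so
      # the 1.02 x RMSE_best rule is not confounded by split noise)
      old_seed <- get0(".Random.seed", envir = globalenv())
      set.seed(derive_seed(seed, 1000 + r))
      test_idx <- sample.int(nrow(Xs), max(1L, floor(0.1 * nrow(Xs))))
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
      fit <- train_network(Xs[-test_idx, , drop = FALSE], y[-test_idx],
                           k_n = k_n, seed = derive_seed(seed, 2000 + r),
                           n_starts = 2L, max_iter = 100L,
                           weight_decay = weight_decay)
      rmse_r[r] <- evaluate(fit, Xs[test_idx, , drop = FALSE], y[test_idx])$RMSE
      imp <- feature_importance(fit)
      # normalize so each split model votes equally
      imp$importance <- imp$importance / max(sum(imp$importance), 1e-12)
      imp_sum[imp$feature] <- imp_sum[imp$feature] + imp$importance
    }
    trace <- rbind(trace, data.frame(n = n_feat, rmse = mean(rmse_r),
                                     features = paste(current, collapse = ",")))
    subsets[[n_feat]] <- current
    if (n_feat == 1) break
    drop_feat <- names(imp_sum)[order(imp_sum, seq_along(imp_sum))][1]
    current <- setdiff(current, drop_feat)
  }
  rmse_best <- min(trace$rmse)
  ok <- trace$n[trace$rmse < tolerance * rmse_best]
  chosen_n <- min(ok)
  chosen <- subsets[[chosen_n]]
  final <- train_network(X[, chosen, drop = FALSE], y, k_n = k_n,
                         seed = derive_seed(seed, 99L), weight_decay = weight_decay)
  structure(list(trace = trace[order(-trace$n), , drop = FALSE],
                 chosen_n = chosen_n, chosen_features = chosen,
                 rmse_best = rmse_best, model = final),
            class = "rfe_trace")
}

#' @export
print.rfe_trace <- function(x, ...) {
  cat(sprintf("<rfe_trace: best RMSE %.3f, chose %d feature(s): %s>\n",
              x$rmse_best, x$chosen_n, paste(x$chosen_features, collapse = ", ")))
  invisible(x)
}

#' Serialize / restore a count model as JSON
#' @param model a [count_model].
#' @param path JSON path.
#' @export
write_count_model <- function(model, path) {
  jsonlite::write_json(
    list(W1 = model$W1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
         feature_subset = model$feature_subset,
         center = model$center, scale = model$scale,
         k_n = model$k_n, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_count_model
#' @export
read_count_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  W1 <- matrix(unlist(j$W1), nrow = j$k_n)
  colnames(W1) <- j$feature_subset
  new_count_model(W1, j$b1, j$w2, j$b2, j$feature_subset,
                  stats::setNames(unlist(j$center), j$feature_subset),
                  stats::setNames(unlist(j$scale), j$feature_subset),
                  j$k_n, j$seed)
}
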