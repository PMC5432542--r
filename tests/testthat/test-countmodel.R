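# hand-built model for closed-form prediction tests
manual_model <- function(W1, b1, w2, b2, feats = paste0("V", seq_len(ncol(W1)))) {
  colnames(W1) <- feats
  structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2, feature_subset = feats,
                 center = stats::setNames(rep(0, length(feats)), feats),
                 scale = stats::setNames(rep(1, length(feats)), feats),
                 k_n = nrow(W1), seed = NA_integer_),
            class = "count_model")
}

test_that("a constant target is fitted to within 0.01 everywhere", {
  set.seed(1)
  X <- matrix(stats::rnorm(300), ncol = 3)
  fit <- train_network(X, rep(1, 100), k_n = 2, seed = 4)
  expect_lt(max(abs(predict_counts(fit, X) - 1)), 0.01)
})

test_that("a linear rule in one feature is learnt almost exactly", {
  tab <- shared_training_table()
  X <- as.matrix(tab[, grep("^F", names(tab))])
  y <- X[, "F1_Area"] / 100
  set.seed(2)
  test_idx <- sample(nrow(X), floor(nrow(X) * 0.2))
  fit <- train_network(X[-test_idx, ], y[-test_idx], k_n = 2, seed = 5)
  ev <- evaluate(fit, X[test_idx, ], y[test_idx])
  expect_gt(ev$R2, 0.99)
})

test_that("training is deterministic given the seed and guards its inputs", {
  set.seed(77)
  X <- matrix(stats::rnorm(240), ncol = 4)
  y <- pmax(0, 1 + X[, 1] + stats::rnorm(60, 0, 0.1))
  f1 <- train_network(X, y, k_n = 2, seed = 42)
  f2 <- train_network(X, y, k_n = 2, seed = 42)
  expect_identical(f1$W1, f2$W1)
  expect_identical(f1$w2, f2$w2)
  Xz <- cbind(X, 0)  # zero-variance feature dropped with a warning
  expect_warning(train_network(Xz, y, k_n = 2, seed = 1), "zero-variance")
  expect_error(train_network(X[1:5, ], y[1:5], k_n = 2, seed = 1),
               class = "wheatdens_schema_error")
  expect_error(train_network(X, -y, k_n = 2, seed = 1),
               class = "wheatdens_schema_error")
})

test_that("weight-based importance follows the |W1| x |w2| formula", {
  m <- manual_model(W1 = matrix(c(2, 0, 1), nrow = 1), b1 = 0, w2 = 1, b2 = 0)
  imp <- feature_importance(m)
  expect_identical(imp$feature, c("V1", "V3", "V2"))
  expect_equal(imp$importance, c(2, 1, 0))
  # two hidden nodes: contributions sum across nodes
  m2 <- manual_model(W1 = matrix(c(1, -3, 0.5, 2), nrow = 2), b1 = c(0, 0),
                     w2 = c(2, 0.5), b2 = 0)
  imp2 <- feature_importance(m2)
  expect_equal(imp2$importance[imp2$feature == "V1"], 1 * 2 + 3 * 0.5)
})

test_that("an informative feature outranks pure noise in most seeds", {
  wins <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 150
    X <- cbind(target = stats::runif(n, 0, 4), noise = stats::rnorm(n))
    y <- X[, 1]
    fit <- train_network(X, y, k_n = 2, seed = 200 + s)
    if (feature_importance(fit)$feature[1] == "target") wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("prediction obeys the closed form, clipping, and schema", {
  m <- manual_model(W1 = matrix(c(1, -0.5, 0.3, 2), nrow = 2), b1 = c(0.2, -0.1),
                    w2 = c(1.5, -0.7), b2 = 0.4)
  x0 <- matrix(0, 1, 2, dimnames = list(NULL, c("V1", "V2")))
  expect_equal(predict_counts(m, x0),
               max(0, 0.4 + sum(c(1.5, -0.7) * tanh(c(0.2, -0.1)))))
  neg <- manual_model(W1 = matrix(0, 1, 1), b1 = 0, w2 = 0, b2 = -3)
  expect_identical(predict_counts(neg, matrix(1, 5, 1, dimnames = list(NULL, "V1"))),
                   rep(0, 5))
  expect_error(predict_counts(m, matrix(1, 2, 1, dimnames = list(NULL, "V1"))),
               class = "wheatdens_schema_error")
})

test_that("a near-interpolating model reproduces its training labels", {
  set.seed(3)
  X <- matrix(stats::rnorm(40), ncol = 2)
  y <- 1 + 0.8 * tanh(X[, 1])
  fit <- train_network(X, y, k_n = 2, seed = 6, n_starts = 4)
  expect_lt(max(abs(predict_counts(fit, X) - y)), 0.1)
})

test_that("evaluation reports R2, RMSE and bias as defined", {
  m <- manual_model(W1 = matrix(0, 1, 1), b1 = 0, w2 = 0, b2 = 2)
  X <- matrix(stats::rnorm(30), ncol = 1, dimnames = list(NULL, "V1"))
  ev <- evaluate(m, X, rep(2, 30))
  expect_equal(ev$RMSE, 0)
  expect_equal(ev$Bias, 0)
  ev2 <- evaluate(m, X, rep(1.5, 30))          # predictions = obs + 0.5
  expect_equal(ev2$Bias, 0.5)
  expect_equal(ev2$RMSE, 0.5)
  y <- c(rep(2, 10), rep(1, 10))
  ev3 <- evaluate(m, X[1:20, , drop = FALSE], y)
  pred <- rep(2, 20)
  expect_equal(ev3$R2, 1 - sum((pred - y)^2) / sum((y - mean(y))^2))
})

test_that("architecture search prefers the smallest adequate network", {
  set.seed(9)
  X <- matrix(stats::rnorm(180), ncol = 3)
  sel <- select_architecture(X, rep(2, 60), k_range = 1:3, reps = 2, seed = 11)
  expect_identical(sel$k_n, 1L)               # all perfect: tie -> smallest
  y <- pmax(0, 2 + X[, 1] + stats::rnorm(60, 0, 0.05))
  sel2 <- select_architecture(X, y, k_range = 1:4, reps = 3, seed = 12)
  expect_lte(sel2$k_n, 3)
})

test_that("RFE collapses fully redundant features to a single one", {
  set.seed(13)
  base <- stats::runif(120, 0, 3)
  X <- matrix(rep(base, 4), ncol = 4)
  colnames(X) <- paste0("copy", 1:4)
  rfe <- recursive_feature_elimination(X, base, k_n = 1, reps = 2, seed = 14)
  expect_identical(rfe$chosen_n, 1L)
  expect_identical(nrow(rfe$trace), 4L)
  expect_identical(rfe$trace$n, c(4L, 3L, 2L, 1L))
})

test_that("RFE keeps informative features and drops noise", {
  set.seed(15)
  n <- 400
  inf <- matrix(stats::runif(4 * n, 0, 2), ncol = 4,
                dimnames = list(NULL, paste0("inf", 1:4)))
  noise <- matrix(stats::rnorm(9 * n), ncol = 9,
                  dimnames = list(NULL, paste0("noise", 1:9)))
  # every informative coefficient is well above the noise floor, so RMSE is
  # flat while noise features are dropped and rises sharply afterwards
  y <- pmax(0, 1 + inf[, 1] + 0.8 * inf[, 2] + 0.6 * inf[, 3] + 0.4 * inf[, 4] +
              stats::rnorm(n, 0, 0.3))
  rfe <- recursive_feature_elimination(cbind(inf, noise), y, k_n = 2, reps = 5,
                                       seed = 16)
  expect_lte(rfe$chosen_n, 5)
  expect_lte(sum(grepl("noise", rfe$chosen_features)), 1)
  # determinism of the whole trace
  rfe2 <- recursive_feature_elimination(cbind(inf, noise), y, k_n = 2, reps = 5,
                                        seed = 16)
  expect_identical(rfe$trace, rfe2$trace)
  expect_identical(rfe$model$W1, rfe2$model$W1)
  # RMSE at the full set is never below the best observed
  expect_gte(rfe$trace$rmse[rfe$trace$n == 13], rfe$rmse_best)
})

test_that("a known 2-node tanh generator is recovered to near the noise floor", {
  set.seed(17)
  n <- 500
  X <- matrix(stats::rnorm(3 * n), ncol = 3)
  W <- matrix(c(1.2, -0.7, 0.4, 0.3, 0.9, -1.1), nrow = 2)
  ytrue <- 2 + as.numeric(tanh(X %*% t(W) + rep(c(0.1, -0.2), each = n)) %*% c(1.5, -1))
  y <- pmax(0, ytrue + stats::rnorm(n, 0, 0.2))
  test_idx <- sample(n, 50)
  fit <- train_network(X[-test_idx, ], y[-test_idx], k_n = 2, seed = 18)
  ev <- evaluate(fit, X[test_idx, ], y[test_idx])
  expect_lt(ev$RMSE, 1.5 * 0.2)
})

test_that("count models serialize losslessly to JSON", {
  set.seed(19)
  X <- matrix(stats::rnorm(120), ncol = 2, dimnames = list(NULL, c("A", "B")))
  y <- pmax(0, 1 + X[, 1])
  fit <- train_network(X, y, k_n = 2, seed = 20)
  f <- withr::local_tempfile(fileext = ".json")
  write_count_model(fit, f)
  back <- read_count_model(f)
  expect_equal(predict_counts(back, X), predict_counts(fit, X), tolerance = 1e-12)
})
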