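test_that("IRLS logistic fit maximizes the likelihood", {
  set.seed(13)
  X <- matrix(rnorm(300 * 2), 300)
  y <- rbinom(300, 1, plogis(0.5 + X %*% c(1, -0.8)))
  fit <- fit_logistic_ml(X, y)
  # independent route: direct likelihood maximization
  nll <- function(b) -sum(y * (cbind(1, X) %*% b) - log1p(exp(cbind(1, X) %*% b)))
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_lt(max(abs(fit$coef - opt$par)), 1e-4)
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_error(fit_logistic_ml(X, rep(1, 300)), class = "netsig_parameter_error")
})

test_that("separation triggers the ridge fallback with a warning", {
  X <- matrix(rep(c(-1, 1), each = 20), ncol = 1)
  y <- as.numeric(X[, 1] > 0)
  expect_warning(fit <- fit_logistic_ml(X, y), class = "netsig_separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coef)))
  # still a perfect ranker
  expect_equal(auc_mw(y, fit$fitted), 1)
})

test_that("null predictors rarely reach Wald significance", {
  hits <- vapply(1:20, function(r) {
    set.seed(700 + r)
    X <- matrix(rnorm(400), ncol = 1)
    y <- rbinom(400, 1, 0.5)
    fit <- fit_logistic_ml(X, y)
    abs(fit$coef[2]) < 0.2 && fit$p[2] > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  set.seed(14)
  for (rep in 1:5) {
    y <- rbinom(60, 1, 0.5)
    s <- rnorm(60) + y
    u <- unname(wilcox.test(s[y == 1], s[y == 0], exact = FALSE)$statistic)
    expect_equal(auc_mw(y, s), u / (sum(y) * sum(1 - y)), tolerance = 1e-12)
  }
})

test_that("classification metrics come straight from the confusion matrix", {
  perfect <- classification_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_true(all(perfect == 1))
  # TP=47 FN=13 TN=50 FP=10
  y <- c(rep(1, 60), rep(0, 60))
  s <- c(rep(0.9, 47), rep(0.1, 13), rep(0.1, 50), rep(0.9, 10))
  m <- classification_metrics(y, s)
  expect_equal(unname(m["sens"]), 47 / 60, tolerance = 1e-12)
  expect_equal(unname(m["spec"]), 50 / 60, tolerance = 1e-12)
  expect_equal(unname(m["ppv"]), 47 / 57, tolerance = 1e-12)
  expect_equal(unname(m["npv"]), 50 / 63, tolerance = 1e-12)
  expect_equal(unname(m["acc"]), 97 / 120, tolerance = 1e-12)
  expect_warning(m0 <- classification_metrics(c(0, 1), c(0.1, 0.2)),
                 class = "netsig_undefined_metric")
  expect_true(is.nan(m0[["ppv"]]))
})

test_that("cross-validation is reproducible, stratified and leakage-free", {
  set.seed(15)
  X <- matrix(rnorm(100 * 3), 100, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(100, 1, plogis(X %*% c(2, -1, 0)))
  if (min(table(y)) < 5) y[1:5] <- 1 - y[1:5]
  cv1 <- crossval_roc(X, y, seed = 21)
  cv2 <- crossval_roc(X, y, seed = 21)
  expect_identical(cv1$fold_auc, cv2$fold_auc)
  # stratification: every fold holds both classes
  for (f in 1:5) expect_equal(length(unique(y[cv1$folds == f])), 2)
  # white-box leakage check: fold-1 scores are reproducible using
  # training-fold standardization only
  tr <- cv1$folds != 1
  mu <- colMeans(X[tr, ]); sdv <- apply(X[tr, ], 2, sd)
  Xtr <- scale(X[tr, ], mu, sdv)
  fit <- fit_logistic_ml(Xtr, y[tr])
  Xte <- scale(X[!tr, ], mu, sdv)
  sc <- plogis(drop(cbind(1, Xte) %*% fit$coef))
  expect_equal(unname(sc), unname(cv1$oof_scores[!tr]), tolerance = 1e-10)
  # ROC curve is monotone nondecreasing
  expect_true(all(diff(cv1$roc$tpr) >= -1e-12))
})

test_that("perfectly informative predictors yield AUC 1, null labels ~0.5", {
  y <- rep(c(0, 1), each = 20)
  X <- matrix(y, ncol = 1)
  cv <- suppressWarnings(crossval_roc(X, y, seed = 5))
  expect_true(all(cv$fold_auc == 1))
  expect_equal(unname(cv$metrics_median[c("sens", "spec")]), c(1, 1))
  aucs <- vapply(1:20, function(r) {
    set.seed(800 + r)
    Xn <- matrix(rnorm(120 * 4), 120)
    yn <- sample(rep(c(0, 1), each = 60))
    crossval_roc(Xn, yn, seed = r)$auc_mean
  }, numeric(1))
  expect_gte(mean(aucs > 0.35 & aucs < 0.65), 0.9)
})

test_that("model comparison detects added signal and ignores duplicates", {
  set.seed(16)
  n <- 120
  X_clin <- matrix(rnorm(n * 2), n)
  lin <- X_clin %*% c(0.5, 0) # weak clinical signal
  X_q <- matrix(rnorm(n * 2), n)
  y <- rbinom(n, 1, plogis(lin + X_q %*% c(2, 1.5)))
  cmp <- compare_models(X_clin, X_q, y, n_perm = 300, seed = 17)
  expect_gt(cmp$delta_auc, 0)
  expect_lte(cmp$p, 0.01)
  # duplicated block adds nothing
  cmp0 <- compare_models(X_clin, X_clin, y, n_perm = 200, seed = 18)
  expect_lt(abs(cmp0$delta_auc), 0.05)
  expect_gt(cmp0$p, 0.2)
  expect_error(compare_models(X_clin, X_q[1:10, ], y),
               class = "netsig_parameter_error")
})

test_that("tidy and glance methods expose model summaries", {
  set.seed(19)
  X <- matrix(rnorm(80 * 2), 80, dimnames = list(NULL, c("f1", "f2")))
  y <- rbinom(80, 1, plogis(X %*% c(1.5, 0)))
  if (min(table(y)) < 5) y[1:6] <- 1 - y[1:6]
  cv <- crossval_roc(X, y, seed = 20)
  td <- tidy(cv)
  expect_true(all(c("term", "estimate", "abs_beta", "p.value") %in% names(td)))
  gl <- glance(cv)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("auc_mean", "sens", "f1") %in% names(gl)))
  fit <- fit_logistic_ml(X, y)
  expect_equal(tidy(fit)$estimate, unname(fit$coef))
})
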