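#' Maximum-likelihood logistic regression (IRLS)
#'
#' Newton-Raphson / iteratively reweighted least squares on the Bernoulli
#' log-likelihood, with Wald standard errors from the observed information.
#' Complete or quasi-complete separation makes the ML estimate diverge; when
#' detected (fitted probabilities pinned at 0/1 or exploding coefficients)
#' the model is refitted with a small ridge penalty (`ridge_fallback`) and a
#' warning is raised.
#'
#' @param X numeric design matrix (subjects x predictors, no intercept
#'   column - one is added internally)
#' @param y binary response (0/1), both classes present
#' @param max_iter maximum IRLS iterations
#' @param tol convergence tolerance on the log-likelihood change
#' @param ridge ridge penalty applied from the start (0 = plain ML)
#' @param ridge_fallback penalty used on detected separation
#' @return a `netsig_logistic` list: `coef`, `se`, `z`, `p`, `loglik`,
#'   `converged`, `separation`, `fitted`
#' @export
fit_logistic_ml <- function(X, y, max_iter = 200, tol = 1e-8, ridge = 0,
                            ridge_fallback = 1e-4) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) {
    abort_netsig("Design matrix must be finite.", "netsig_parameter_error")
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2 || !all(y %in% c(0, 1))) {
    abort_netsig("`y` must be binary with both classes present.",
                 "netsig_parameter_error")
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  p_dim <- ncol(Xd)
  irls <- function(lambda) {
    beta <- rep(0, p_dim)
    ll_old <- -Inf
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- drop(Xd %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      Hpen <- crossprod(Xd, Xd * w)
      diag(Hpen) <- diag(Hpen) + lambda * c(0, rep(1, p_dim - 1))
      score <- crossprod(Xd, y - mu) - lambda * c(0, beta[-1])
      step <- tryCatch(solve(Hpen, score),
                       error = function(e) {
                         if (lambda > 0) {
                           abort_netsig("IRLS normal equations are singular even under ridge.",
                                        "netsig_fit_error")
                         }
                         abort_netsig("IRLS normal equations are singular.",
                                      "netsig_singular_design")
                       })
      beta <- beta + drop(step)
      eta <- drop(Xd %*% beta)
      ll <- sum(y * eta - log1p(exp(eta))) - lambda / 2 * sum(beta[-1]^2)
      if (is.finite(ll) && abs(ll - ll_old) < tol) {
        conv <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    mu <- stats::plogis(drop(Xd %*% beta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, Xd * w)
    diag(H) <- diag(H) + lambda * c(0, rep(1, p_dim - 1))
    list(beta = beta, ll = ll_old, converged = conv, mu = mu, H = H)
  }
  fit <- tryCatch(irls(ridge), netsig_singular_design = function(e) {
    warn_netsig("Singular design (collinear or wide); refitting with a small ridge penalty.",
                "netsig_separation")
    irls(ridge_fallback)
  })
  sep <- any(fit$mu > 1 - 1e-8 | fit$mu < 1e-8) || any(abs(fit$beta) > 30)
  if (sep && ridge < ridge_fallback) {
    warn_netsig("Separation detected; refitting with a small ridge penalty.",
                "netsig_separation")
    fit <- irls(ridge_fallback)
  } else if (!fit$converged) {
    abort_netsig(sprintf("IRLS did not converge in %d iterations (last |beta| max = %.3g).",
                         max_iter, max(abs(fit$beta))), "netsig_fit_error")
  }
  se <- sqrt(diag(solve(fit$H)))
  z <- fit$beta / se
  structure(
    list(coef = stats::setNames(fit$beta, colnames(Xd)),
         se = stats::setNames(se, colnames(Xd)),
         z = z, p = 2 * stats::pnorm(-abs(z)),
         loglik = fit$ll, converged = fit$converged, separation = sep,
         fitted = fit$mu),
    class = "netsig_logistic"
  )
}

#' @export
print.netsig_logistic <- function(x, ...) {
  cat(sprintf("<netsig_logistic> %d coefficients, loglik = %.3f%s\n",
              length(x$coef), x$loglik,
              if (x$separation) " (ridge-stabilized: separation)" else ""))
  print(round(cbind(beta = x$coef, se = x$se, p = x$p), 4))
  invisible(x)
}

#' AUC as the normalized Mann-Whitney U statistic
#'
#' Rank-based AUC: ties get average ranks, so the value equals the
#' probability that a random positive scores above a random negative (plus
#' half the tie probability).
#'
#' @param y binary labels
#' @param scores numeric scores
#' @return AUC in `[0, 1]`
#' @export
auc_mw <- function(y, scores) {
  y <- as.numeric(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix classification metrics
#'
#' Sensitivity, specificity, positive and negative predictive value,
#' accuracy and F1 at a probability threshold. Ratios with a zero
#' denominator are returned as `NaN` with a warning.
#'
#' @param y binary labels
#' @param scores predicted probabilities in `[0, 1]`
#' @param threshold classification threshold
#' @return named numeric vector `sens`, `spec`, `ppv`, `npv`, `acc`, `f1`
#' @export
classification_metrics <- function(y, scores, threshold = 0.5) {
  y <- as.numeric(y)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn_netsig(sprintf("%s undefined (zero denominator).", what),
                  "netsig_undefined_metric")
      return(NaN)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "Sensitivity")
  spec <- safe_div(tn, tn + fp, "Specificity")
  ppv <- safe_div(tp, tp + fp, "PPV")
  npv <- safe_div(tn, tn + fn, "NPV")
  acc <- (tp + tn) / length(y)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn, "F1")
  c(sens = sens, spec = spec, ppv = ppv, npv = npv, acc = acc, f1 = f1)
}

make_folds <- function(y, k, seed, stratified = TRUE) {
  n <- length(y)
  with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    fold
  })
}

#' Stratified k-fold cross-validated logistic ROC analysis
#'
#' Standardization parameters and the logistic fit are learned on training
#' folds only; out-of-fold probabilities give one AUC per fold, threshold
#' metrics at 0.5, and a mean ROC curve by vertical averaging of fold ROCs
#' on a fixed false-positive-rate grid. Coefficients and Wald p-values come
#' from a full-data fit on standardized predictors (their absolute values
#' are the feature saliences).
#'
#' @param X subjects x features numeric matrix (column names = feature
#'   names)
#' @param y binary outcome
#' @param k number of folds
#' @param seed RNG seed for fold assignment
#' @param stratified preserve class balance across folds
#' @param threshold probability threshold for the confusion metrics
#' @param fpr_grid grid for the averaged ROC curve
#' @return a `netsig_cv` object; see [tidy.netsig_cv()] and
#'   [glance.netsig_cv()]
#' @export
crossval_roc <- function(X, y, k = 5, seed = 1L, stratified = TRUE,
                         threshold = 0.5, fpr_grid = seq(0, 1, by = 0.01)) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (min(table(y)) < k) {
    abort_netsig("Each class needs at least `k` members.", "netsig_parameter_error")
  }
  fold <- make_folds(y, k, seed, stratified)
  fold_auc <- numeric(k)
  fold_metrics <- matrix(NA_real_, k, 6)
  roc_tpr <- matrix(NA_real_, k, length(fpr_grid))
  oof <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    fit <- suppressWarnings(fit_logistic_ml(Xtr, y[tr]))
    sc <- stats::plogis(drop(cbind(1, Xte) %*% fit$coef))
    oof[!tr] <- sc
    fold_auc[f] <- auc_mw(y[!tr], sc)
    fold_metrics[f, ] <- suppressWarnings(
      classification_metrics(y[!tr], sc, threshold))
    roc_tpr[f, ] <- roc_at_fpr(y[!tr], sc, fpr_grid)
  }
  colnames(fold_metrics) <- c("sens", "spec", "ppv", "npv", "acc", "f1")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  full_fit <- suppressWarnings(
    fit_logistic_ml(sweep(sweep(X, 2, mu), 2, sdv, "/"), y))
  structure(
    list(fold_auc = fold_auc,
         auc_mean = mean(fold_auc), auc_sd = stats::sd(fold_auc),
         auc_median = stats::median(fold_auc),
         metrics = fold_metrics,
         metrics_median = apply(fold_metrics, 2, stats::median, na.rm = TRUE),
         metrics_sd = apply(fold_metrics, 2, stats::sd, na.rm = TRUE),
         roc = tibble::tibble(fpr = fpr_grid, tpr = colMeans(roc_tpr)),
         oof_scores = oof, folds = fold, y = y,
         coef = full_fit$coef, coef_se = full_fit$se, coef_p = full_fit$p,
         separation = full_fit$separation,
         k = k, seed = seed, threshold = threshold),
    class = "netsig_cv"
  )
}

roc_at_fpr <- function(y, scores, fpr_grid) {
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  tpr <- cumsum(ys == 1) / max(n1, 1)
  fpr <- cumsum(ys == 0) / max(n0, 1)
  vapply(fpr_grid, function(g) {
    ok <- fpr <= g + 1e-12
    if (!any(ok)) 0 else max(tpr[ok])
  }, numeric(1))
}

#' @export
print.netsig_cv <- function(x, ...) {
  cat(sprintf("<netsig_cv> %d-fold CV AUC = %.3f +/- %.3f (median %.3f)\n",
              x$k, x$auc_mean, x$auc_sd, x$auc_median))
  m <- rbind(median = x$metrics_median, sd = x$metrics_sd)
  print(round(m, 3))
  invisible(x)
}

#' Permutation comparison of nested prediction models
#'
#' Observed statistic: the gain in cross-validated AUC when the added
#' feature block `X_add` joins the base block `X_base`. The null
#' distribution permutes the subject rows of `X_add` (breaking its link to
#' the outcome while preserving the base model's information) and
#' recomputes the cross-validated gain with identical folds;
#' `p = (1 + #{gain_perm >= gain_obs}) / (n_perm + 1)`. A label-permutation
#' scheme is available behind `scheme`.
#'
#' @param X_base subjects x features base design (e.g. clinical predictors)
#' @param X_add subjects x features added block (e.g. qEEG features)
#' @param y binary outcome
#' @param k CV folds
#' @param n_perm permutations
#' @param seed RNG seed (folds and permutations derive from it)
#' @param scheme `"permute_added"` (default) or `"permute_labels"`
#' @return a `netsig_model_comparison` list: `auc_base`, `auc_full`,
#'   `delta_auc`, `p`, `n_perm`, `seed`
#' @export
compare_models <- function(X_base, X_add, y, k = 5, n_perm = 10000, seed = 1L,
                           scheme = c("permute_added", "permute_labels")) {
  scheme <- match.arg(scheme)
  X_base <- as.matrix(X_base)
  X_add <- as.matrix(X_add)
  if (nrow(X_base) != nrow(X_add) || nrow(X_base) != length(y)) {
    abort_netsig("Feature blocks must cover the same subjects.",
                 "netsig_parameter_error")
  }
  fold_seed <- derive_seed(seed, 1)
  cv_auc <- function(X, yy) {
    fold <- make_folds(yy, k, fold_seed)
    mean(vapply(seq_len(k), function(f) {
      tr <- fold != f
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      fit <- suppressWarnings(fit_logistic_ml(Xtr, yy[tr]))
      auc_mw(yy[!tr], stats::plogis(drop(cbind(1, Xte) %*% fit$coef)))
    }, numeric(1)))
  }
  auc_base <- cv_auc(X_base, y)
  auc_full <- cv_auc(cbind(X_base, X_add), y)
  delta_obs <- auc_full - auc_base
  deltas <- with_seed(derive_seed(seed, 2), {
    vapply(seq_len(n_perm), function(b) {
      if (scheme == "permute_added") {
        Xp <- X_add[sample.int(nrow(X_add)), , drop = FALSE]
        cv_auc(cbind(X_base, Xp), y) - auc_base
      } else {
        yp <- y[sample.int(length(y))]
        cv_auc(cbind(X_base, X_add), yp) - cv_auc(X_base, yp)
      }
    }, numeric(1))
  })
  p <- (1 + sum(deltas >= delta_obs - 1e-12)) / (n_perm + 1)
  structure(
    list(auc_base = auc_base, auc_full = auc_full, delta_auc = delta_obs,
         p = p, n_perm = n_perm, seed = seed, scheme = scheme,
         null_quantiles = stats::quantile(deltas, c(0.5, 0.95, 0.99))),
    class = "netsig_model_comparison"
  )
}

#' @export
print.netsig_model_comparison <- function(x, ...) {
  cat(sprintf("<netsig_model_comparison> AUC %.3f -> %.3f (delta = %+.3f), p = %.4g (%d perms, %s)\n",
              x$auc_base, x$auc_full, x$delta_auc, x$p, x$n_perm, x$scheme))
  invisible(x)
}
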