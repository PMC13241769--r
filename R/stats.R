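#' Two-sample permutation test
#'
#' Label-shuffling permutation test for a difference in group means (or a
#' user statistic). The two-sided Monte-Carlo p-value uses the add-one
#' correction `p = (1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1)`, so p is
#' never 0 and is valid under exchangeability. With `exact = TRUE` all
#' distinct label assignments are enumerated and the p-value is the exact
#' permutation tail probability (feasible for small samples).
#'
#' @param x,y numeric samples (length >= 2 each)
#' @param stat function of `(x, y)` returning a scalar; default mean
#'   difference `mean(x) - mean(y)`
#' @param n_perm number of Monte-Carlo permutations
#' @param seed RNG seed
#' @param exact enumerate all `choose(n, n1)` assignments instead
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#' @return a `netsig_perm` list: `statistic`, `p`, `n_perm`, `seed`,
#'   `null_summary`
#' @export
permutation_test <- function(x, y, stat = NULL, n_perm = 10000, seed = 1L,
                             exact = FALSE,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2) {
    abort_netsig("Both samples need at least 2 observations.", "netsig_parameter_error")
  }
  z <- c(x, y)
  n1 <- length(x)
  n <- length(z)
  if (length(unique(z)) == 1) {
    warn_netsig("Pooled sample is constant; p = 1.", "netsig_degenerate_sample")
    return(structure(list(statistic = 0, p = 1, n_perm = n_perm, seed = seed,
                          null_summary = c(mean = 0, sd = 0)),
                     class = "netsig_perm"))
  }
  default_stat <- is.null(stat)
  stat <- stat %||% function(a, b) mean(a) - mean(b)
  obs <- stat(x, y)
  tail_count <- function(tp, to) {
    switch(alternative,
           two.sided = sum(abs(tp) >= abs(to) - 1e-12),
           greater = sum(tp >= to - 1e-12),
           less = sum(tp <= to + 1e-12))
  }
  if (exact) {
    if (choose(n, n1) > 2e5) {
      abort_netsig("Too many assignments for exact enumeration.", "netsig_parameter_error")
    }
    combos <- utils::combn(n, n1)
    tp <- apply(combos, 2, function(idx) stat(z[idx], z[-idx]))
    p <- tail_count(tp, obs) / ncol(combos)
    n_used <- ncol(combos)
  } else {
    tp <- with_seed(seed, {
      if (default_stat) {
        tot <- sum(z)
        vapply(seq_len(n_perm), function(b) {
          sA <- sum(z[sample.int(n, n1)])
          sA / n1 - (tot - sA) / (n - n1)
        }, numeric(1))
      } else {
        vapply(seq_len(n_perm), function(b) {
          idx <- sample.int(n, n1)
          stat(z[idx], z[-idx])
        }, numeric(1))
      }
    })
    p <- (1 + tail_count(tp, obs)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(
    list(statistic = obs, p = p, n_perm = n_used, seed = seed,
         null_summary = c(mean = mean(tp), sd = stats::sd(tp),
                          q025 = unname(stats::quantile(tp, 0.025)),
                          q975 = unname(stats::quantile(tp, 0.975)))),
    class = "netsig_perm"
  )
}

#' @export
print.netsig_perm <- function(x, ...) {
  cat(sprintf("<netsig_perm> stat = %.4g, p = %.4g (%d permutations)\n",
              x$statistic, x$p, x$n_perm))
  invisible(x)
}

#' Most-frequent p-value over repeated randomized tests
#'
#' Runs a seeded stochastic test `n_repeats` times with distinct derived
#' seeds and returns the mode of the p-values after rounding to `digits`
#' decimals (ties broken toward the smaller p). This stabilizes Monte-Carlo
#' p-values against seed-to-seed fluctuation; note it is statistically
#' redundant given an add-one-corrected estimator with large `n_perm`, and
#' is provided for procedural fidelity.
#'
#' @param test_closure function of one argument (a seed) returning a p-value
#' @param n_repeats number of repetitions
#' @param seed master seed from which per-repeat seeds derive
#' @param digits rounding applied before taking the mode
#' @return the modal p-value
#' @export
modal_p <- function(test_closure, n_repeats = 100, seed = 1L, digits = 3) {
  stopifnot(n_repeats >= 1)
  ps <- vapply(seq_len(n_repeats),
               function(i) test_closure(derive_seed(seed, i)), numeric(1))
  pr <- round(ps, digits)
  tab <- table(pr)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  # representative raw p of the modal bin, so the result stays a valid
  # (strictly positive) p-value even when the bin rounds to 0
  stats::median(ps[pr == min(modes)])
}

#' Pearson chi-squared test on a contingency table
#'
#' @param tab r x c matrix of nonnegative integer counts
#' @param correct apply Yates continuity correction (default off)
#' @return list with `statistic`, `df`, `p`
#' @export
chi2_contingency <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort_netsig("Counts must be nonnegative integers.", "netsig_parameter_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort_netsig("Zero marginal total in the contingency table.",
                 "netsig_parameter_error")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up procedure: adjusted `p_i = min_{j >= rank(i)} m p_(j) / j`,
#' capped at 1; a feature is rejected when its adjusted p is at most `q`.
#'
#' @param pvals numeric p-values in `[0, 1]`
#' @param q FDR level
#' @return tibble with `p`, `p_adj`, `rejected`
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort_netsig("p-values must lie in [0, 1].", "netsig_parameter_error")
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  tibble::tibble(p = pvals, p_adj = adj, rejected = !is.na(adj) & adj <= q)
}

#' Split-plot (mixed) ANOVA: within-subject band, between-subject group
#'
#' Classical split-plot decomposition for a repeated-measures design with
#' one within-subject factor (frequency band, k levels) and one
#' between-subject factor (group): the Group effect is tested against the
#' subject-within-group stratum, Band and Group x Band against the
#' band-by-subject residual. Sphericity is summarized by Mauchly's W (with
#' its chi-squared approximation) and the Greenhouse-Geisser epsilon
#' computed from the pooled within-group covariance of the band profiles;
#' GG-corrected p-values multiply both degrees of freedom by epsilon.
#' Homogeneity of between-group variance is checked with Bartlett's test on
#' the subject means.
#'
#' @param data data frame with columns `subject`, `group`, `band`, `value`
#'   (one row per subject x band, no missing cells)
#' @return a `netsig_anova` object; see [tidy.netsig_anova()]
#' @export
mixed_anova <- function(data) {
  need <- c("subject", "group", "band", "value")
  if (!all(need %in% names(data))) {
    abort_netsig("`data` needs columns subject, group, band, value.",
                 "netsig_parameter_error")
  }
  data <- dplyr::mutate(data,
                        subject = factor(.data$subject),
                        group = factor(.data$group),
                        band = factor(.data$band, levels = unique(.data$band)))
  if (any(table(data$group) / nlevels(data$band) < 2)) {
    abort_netsig("Each group needs at least 2 subjects.", "netsig_parameter_error")
  }
  wide <- tidyr::pivot_wider(data, id_cols = c("subject", "group"),
                             names_from = "band", values_from = "value")
  k <- nlevels(data$band)
  Y <- as.matrix(wide[, as.character(levels(data$band))])
  if (anyNA(Y)) {
    abort_netsig("Missing cells in the subject x band table.", "netsig_parameter_error")
  }
  fit <- stats::aov(value ~ group * band + Error(subject), data = data)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: subject"]][[1]])
  wth <- as.data.frame(sm[["Error: Within"]][[1]])
  eff <- tibble::tibble(
    effect = c("Group", "Band", "Group:Band"),
    df_num = c(btw$Df[1], wth$Df[1], wth$Df[2]),
    df_den = c(btw$Df[2], rep(wth$Df[3], 2)),
    F = c(btw$`F value`[1], wth$`F value`[1], wth$`F value`[2]),
    p = c(btw$`Pr(>F)`[1], wth$`Pr(>F)`[1], wth$`Pr(>F)`[2])
  )
  # pooled within-group covariance of band profiles
  n <- nrow(Y)
  g <- nlevels(wide$group)
  Yc <- Y - apply(Y, 2, stats::ave, wide$group)
  S <- crossprod(Yc) / (n - g)
  C <- contrast_orthonormal(k)
  D <- C %*% S %*% t(C)
  eps_gg <- (sum(diag(D)))^2 / ((k - 1) * sum(D * D))
  eps_gg <- min(1, max(1 / (k - 1), eps_gg))
  W <- det(D) / (sum(diag(D)) / (k - 1))^(k - 1)
  dfm <- k * (k - 1) / 2 - 1
  cfac <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - g))
  mauchly_chi <- if (W > 0) -cfac * (n - g) * log(W) else Inf
  mauchly_p <- stats::pchisq(mauchly_chi, dfm, lower.tail = FALSE)
  eff$p_gg <- eff$p
  within_idx <- eff$effect != "Group"
  eff$p_gg[within_idx] <- stats::pf(eff$F[within_idx],
                                    eff$df_num[within_idx] * eps_gg,
                                    eff$df_den[within_idx] * eps_gg,
                                    lower.tail = FALSE)
  subj_means <- rowMeans(Y)
  bt <- stats::bartlett.test(subj_means, wide$group)
  structure(
    list(effects = eff, eps_gg = eps_gg,
         mauchly = list(W = W, chisq = mauchly_chi, df = dfm, p = mauchly_p),
         bartlett = list(statistic = unname(bt$statistic), p = bt$p.value),
         n_subjects = n, k_bands = k),
    class = "netsig_anova"
  )
}

contrast_orthonormal <- function(k) {
  # orthonormal contrasts spanning the complement of the unit vector
  C <- stats::contr.helmert(k)
  C <- t(C) / sqrt(colSums(C^2))
  C
}

#' @export
print.netsig_anova <- function(x, ...) {
  cat(sprintf("<netsig_anova> %d subjects x %d bands; GG eps = %.3f, Mauchly p = %.3g\n",
              x$n_subjects, x$k_bands, x$eps_gg, x$mauchly$p))
  print(as.data.frame(x$effects), digits = 4)
  invisible(x)
}

#' Two-between-factor ANOVA applied per frequency band
#'
#' For designs with a second between-subject factor (e.g. structural brain
#' abnormality presence, or epilepsy type) the band-wise layout is a two-way
#' between-subjects factorial; this runs `aov(value ~ group * factor2)`
#' separately for each band and returns the tidy effect table.
#'
#' @param data data frame with columns `subject`, `group`, `band`, `value`
#' @param factor2 vector (or column name in `data`) of the second factor
#' @return tibble with `band`, `effect`, `df_num`, `df_den`, `F`, `p`
#' @export
band_anova2 <- function(data, factor2) {
  if (is.character(factor2) && length(factor2) == 1) {
    factor2 <- data[[factor2]]
  }
  data$f2 <- factor(factor2)
  purrr::map_dfr(split(data, data$band), function(d) {
    fit <- stats::aov(value ~ group * f2, data = d)
    a <- as.data.frame(summary(fit)[[1]])
    tibble::tibble(
      band = d$band[1],
      effect = c("Group", "Factor2", "Group:Factor2"),
      df_num = a$Df[1:3], df_den = a$Df[4],
      F = a$`F value`[1:3], p = a$`Pr(>F)`[1:3]
    )
  })
}

#' Channel-wise permutation group test with FDR correction
#'
#' Runs a two-sample permutation test per channel (or per channel x band
#' when `values` carry one column per channel for each band) and corrects
#' across all tests with Benjamini-Hochberg.
#'
#' @param values subjects x channels numeric matrix (column names = channel
#'   labels)
#' @param groups binary group vector, one entry per subject
#' @param n_perm permutations per channel
#' @param seed RNG seed (one sub-seed per channel)
#' @param q FDR level
#' @return tibble with `channel`, `statistic`, `p`, `p_adj`, `rejected`
#' @export
channelwise_group_test <- function(values, groups, n_perm = 10000, seed = 1L,
                                   q = 0.05) {
  values <- as.matrix(values)
  if (ncol(values) == 0) {
    abort_netsig("No channels supplied.", "netsig_parameter_error")
  }
  if (nrow(values) != length(groups)) {
    abort_netsig("`groups` must have one entry per subject row.",
                 "netsig_parameter_error")
  }
  glev <- unique(groups)
  if (length(glev) != 2) {
    abort_netsig("Exactly two groups are required.", "netsig_parameter_error")
  }
  res <- purrr::map_dfr(seq_len(ncol(values)), function(j) {
    pt <- permutation_test(values[groups == glev[1], j],
                           values[groups == glev[2], j],
                           n_perm = n_perm, seed = derive_seed(seed, j))
    tibble::tibble(channel = colnames(values)[j] %||% as.character(j),
                   statistic = pt$statistic, p = pt$p)
  })
  fdr <- bh_fdr(res$p, q = q)
  res$p_adj <- fdr$p_adj
  res$rejected <- fdr$rejected
  res
}
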