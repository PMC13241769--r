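test_that("permutation test matches exhaustive enumeration on small samples", {
  x <- c(1, 2)
  y <- c(10, 11)
  ex <- permutation_test(x, y, exact = TRUE)
  expect_equal(ex$p, 2 / 6) # the two extreme splits of choose(4, 2)
  mc <- permutation_test(x, y, n_perm = 20000, seed = 3)
  expect_equal(mc$p, ex$p, tolerance = 0.02)
  # one-sided exhaustive: only the observed split is as extreme
  ex1 <- permutation_test(x, y, exact = TRUE, alternative = "less")
  expect_equal(ex1$p, 1 / 6)
  # larger exhaustive case against Monte Carlo
  set.seed(4)
  x2 <- rnorm(5); y2 <- rnorm(5) + 1
  ex2 <- permutation_test(x2, y2, exact = TRUE)
  mc2 <- permutation_test(x2, y2, n_perm = 50000, seed = 5)
  expect_equal(mc2$p, ex2$p, tolerance = 0.01)
})

test_that("permutation test handles degenerate and identical samples", {
  expect_warning(pt <- permutation_test(rep(1, 5), rep(1, 5), n_perm = 99),
                 class = "netsig_degenerate_sample")
  expect_equal(pt$p, 1)
  idp <- permutation_test(c(1, 2, 3), c(1, 2, 3), n_perm = 999, seed = 1)
  expect_equal(idp$statistic, 0)
  expect_equal(idp$p, 1)
  expect_error(permutation_test(1, c(1, 2)), class = "netsig_parameter_error")
})

test_that("permutation p-values are valid under the null", {
  # seeded type-I calibration at alpha = 0.05
  rej <- vapply(1:200, function(r) {
    set.seed(3000 + r)
    x <- rnorm(30)
    y <- rnorm(30)
    permutation_test(x, y, n_perm = 500, seed = 100 + r)$p <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
  # p >= 1/(n_perm + 1) always
  pt <- permutation_test(1:5, 101:105, n_perm = 199, seed = 1)
  expect_gte(pt$p, 1 / 200)
})

test_that("modal p-value stabilizes Monte-Carlo tests", {
  expect_equal(modal_p(function(s) 0.04, n_repeats = 10), 0.04)
  # mode of a seeded MC test equals the exact enumeration p
  x <- c(0.3, 1.1, 2.2, 0.4)
  y <- c(2.5, 3.0, 4.1, 2.8)
  ex <- permutation_test(x, y, exact = TRUE)$p
  mode_p <- modal_p(function(s) permutation_test(x, y, n_perm = 2000,
                                                 seed = s)$p,
                    n_repeats = 30, seed = 9)
  expect_lt(abs(mode_p - ex), 0.005)
})

test_that("chi-squared test matches the textbook formula", {
  even <- chi2_contingency(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p, 1)
  tab <- matrix(c(26, 10, 34, 50), 2) # structural-etiology style contrast
  res <- chi2_contingency(tab)
  expect_gt(res$statistic, 0)
  expect_lt(res$p, 0.05)
  # textbook sum over cells of (O - E)^2 / E
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_error(chi2_contingency(matrix(c(0, 0, 5, 5), 2)),
               class = "netsig_parameter_error")
  expect_error(chi2_contingency(matrix(c(1.5, 2, 3, 4), 2)),
               class = "netsig_parameter_error")
})

test_that("split-plot ANOVA matches first-principles sums of squares", {
  set.seed(6)
  d <- expand.grid(subject = paste0("s", 1:6),
                   band = c("delta", "theta", "alpha", "beta"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 3, "A", "B")
  d$value <- rnorm(nrow(d)) + (d$group == "A") * (d$band == "delta") * 2
  fit <- mixed_anova(d)
  o <- oracle_splitplot(d)
  eff <- tidy(fit)
  expect_equal(eff$F[eff$effect == "Group"], o$F_group, tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "Band"], o$F_band, tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "Group:Band"], o$F_int, tolerance = 1e-10)
  # SS decomposition is complete
  expect_equal(sum(o$ss[c("group", "subj", "band", "int", "err")]),
               o$ss[["total"]], tolerance = 1e-9)
})

test_that("identical groups produce zero group and interaction F", {
  set.seed(99)
  d <- expand.grid(subject = paste0("s", 1:8),
                   band = c("delta", "theta", "alpha", "beta"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 4, "A", "B")
  d$value <- rnorm(nrow(d))
  # make group B an exact copy of group A, subject by subject
  wide <- tidyr::pivot_wider(d, id_cols = c(subject, group),
                             names_from = band, values_from = value)
  bands <- c("delta", "theta", "alpha", "beta")
  wide[wide$group == "B", bands] <- wide[wide$group == "A", bands]
  d2 <- tidyr::pivot_longer(wide, dplyr::all_of(bands),
                            names_to = "band", values_to = "value")
  fit <- mixed_anova(d2)
  eff <- tidy(fit)
  expect_lt(abs(eff$F[eff$effect == "Group"]), 1e-10)
  expect_lt(abs(eff$F[eff$effect == "Group:Band"]), 1e-10)
})

test_that("sphericity diagnostics agree with the multivariate reference", {
  set.seed(7)
  n <- 40
  Y <- matrix(rnorm(n * 4), n, 4) %*% chol(diag(4) + 0.4)
  g <- rep(c("A", "B"), each = n / 2)
  d <- data.frame(subject = rep(paste0("s", 1:n), 4),
                  group = rep(g, 4),
                  band = rep(c("b1", "b2", "b3", "b4"), each = n),
                  value = as.vector(Y))
  fit <- mixed_anova(d)
  # reference route: stats::mauchly.test on the within-subject mlm
  ml <- stats::lm(Y ~ g)
  idata <- data.frame(band = factor(c("b1", "b2", "b3", "b4")))
  mt <- stats::mauchly.test(ml, X = ~1, idata = idata, M = ~band)
  expect_equal(fit$mauchly$W, unname(mt$statistic), tolerance = 1e-8)
  expect_equal(fit$mauchly$p, mt$p.value, tolerance = 1e-3)
  # GG epsilon from the same reference machinery (printed in the heading)
  av <- stats::anova(ml, X = ~1, idata = idata, M = ~band, test = "Spherical")
  hd <- grep("Greenhouse-Geisser", attr(av, "heading"), value = TRUE)
  eps_ref <- as.numeric(sub(".*:\\s*", "", hd))
  expect_equal(fit$eps_gg, eps_ref, tolerance = 1e-3)
})

test_that("compound-symmetric data give epsilon near one", {
  set.seed(8)
  n <- 200
  subj_eff <- rnorm(n, 0, 1)
  Y <- sweep(matrix(rnorm(n * 4, 0, 1), n, 4), 1, subj_eff, "+")
  d <- data.frame(subject = rep(paste0("s", 1:n), 4),
                  group = rep(rep(c("A", "B"), each = n / 2), 4),
                  band = rep(paste0("b", 1:4), each = n),
                  value = as.vector(Y))
  fit <- mixed_anova(d)
  expect_gt(fit$eps_gg, 0.95)
})

test_that("BH-FDR follows the step-up rule", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$rejected)) # max-rank test: 0.04 <= 4 * 0.05 / 4
  expect_equal(r$p_adj, c(0.04, 0.04, 0.04, 0.04))
  single <- bh_fdr(0.03)
  expect_equal(single$p_adj, 0.03)
  none <- bh_fdr(c(0.5, 0.6, 0.9))
  expect_false(any(none$rejected))
  # adjusted p monotone in raw-p rank, always >= raw
  set.seed(9)
  p <- runif(50)
  r2 <- bh_fdr(p)
  expect_true(all(r2$p_adj >= r2$p))
  expect_true(all(diff(r2$p_adj[order(r2$p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "netsig_parameter_error")
})

test_that("channel-wise mapping flags injected effects and controls FDR", {
  set.seed(10)
  n <- 40
  vals <- matrix(rnorm(n * 10), n, 10,
                 dimnames = list(NULL, paste0("ch", 1:10)))
  groups <- rep(0:1, each = n / 2)
  vals[groups == 1, 4] <- vals[groups == 1, 4] + 3 # large shift in one channel
  res <- channelwise_group_test(vals, groups, n_perm = 2000, seed = 11)
  expect_true(res$rejected[res$channel == "ch4"])
  expect_lte(sum(res$rejected[res$channel != "ch4"]), 1)
  # null simulation: empirical FDR stays at or below q
  fdr_hits <- vapply(1:20, function(r) {
    set.seed(500 + r)
    v0 <- matrix(rnorm(n * 10), n, 10)
    r0 <- channelwise_group_test(v0, groups, n_perm = 500,
                                 seed = derive_seed(99, r))
    mean(r0$rejected)
  }, numeric(1))
  expect_lte(mean(fdr_hits), 0.05)
  expect_error(channelwise_group_test(matrix(numeric(0), n, 0), groups),
               class = "netsig_parameter_error")
})

test_that("band-wise two-factor ANOVA recovers a planted interaction", {
  set.seed(12)
  n <- 80
  d <- expand.grid(subject = paste0("s", 1:n), band = c("delta", "alpha"),
                   stringsAsFactors = FALSE)
  d$group <- rep(rep(c("DRE", "nonDRE"), each = n / 2), 2)
  f2 <- rep(rep(c("pSBA", "aSBA"), n / 2), 2)
  d$value <- rnorm(nrow(d)) +
    (d$group == "DRE" & f2 == "aSBA" & d$band == "delta") * 1.5
  res <- band_anova2(d, f2)
  expect_equal(nrow(res), 6) # 3 effects x 2 bands
  p_int_delta <- res$p[res$band == "delta" & res$effect == "Group:Factor2"]
  expect_lt(p_int_delta, 0.05)
})
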