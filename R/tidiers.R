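#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the effect table of a split-plot ANOVA
#'
#' @param x a `netsig_anova`
#' @param ... unused
#' @return tibble with one row per effect (`Group`, `Band`, `Group:Band`)
#' @export
tidy.netsig_anova <- function(x, ...) {
  x$effects
}

#' One-row summary of a split-plot ANOVA
#'
#' @param x a `netsig_anova`
#' @param ... unused
#' @return tibble with sphericity and variance-homogeneity diagnostics
#' @export
glance.netsig_anova <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, k_bands = x$k_bands, eps_gg = x$eps_gg,
    mauchly_W = x$mauchly$W, mauchly_p = x$mauchly$p,
    bartlett_stat = x$bartlett$statistic, bartlett_p = x$bartlett$p
  )
}

#' Tidy coefficients of a logistic fit
#'
#' @param x a `netsig_logistic`
#' @param ... unused
#' @return tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`
#' @export
tidy.netsig_logistic <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = unname(x$se), statistic = unname(x$z),
                 p.value = unname(x$p))
}

#' Tidy the full-data coefficients of a cross-validated model
#'
#' @param x a `netsig_cv`
#' @param ... unused
#' @return tibble with `term`, `estimate` (standardized beta), `abs_beta`
#'   (salience), `p.value`
#' @export
tidy.netsig_cv <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 abs_beta = abs(unname(x$coef)),
                 std.error = unname(x$coef_se), p.value = unname(x$coef_p))
}

#' One-row cross-validation performance summary
#'
#' @param x a `netsig_cv`
#' @param ... unused
#' @return tibble with AUC (mean, sd, median) and the median threshold
#'   metrics
#' @export
glance.netsig_cv <- function(x, ...) {
  m <- x$metrics_median
  tibble::tibble(
    k = x$k, auc_mean = x$auc_mean, auc_sd = x$auc_sd,
    auc_median = x$auc_median,
    sens = m[["sens"]], spec = m[["spec"]], ppv = m[["ppv"]],
    npv = m[["npv"]], acc = m[["acc"]], f1 = m[["f1"]]
  )
}

#' One-row summary of a permutation test
#'
#' @param x a `netsig_perm`
#' @param ... unused
#' @export
glance.netsig_perm <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p, n_perm = x$n_perm)
}

#' One-row summary of a model comparison
#'
#' @param x a `netsig_model_comparison`
#' @param ... unused
#' @export
glance.netsig_model_comparison <- function(x, ...) {
  tibble::tibble(auc_base = x$auc_base, auc_full = x$auc_full,
                 delta_auc = x$delta_auc, p.value = x$p, n_perm = x$n_perm)
}

#' ROC curve of a cross-validated model
#'
#' Mean ROC (vertical averaging across folds) with the chance diagonal.
#'
#' @param object a `netsig_cv`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.netsig_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_line(linewidth = 0.9, color = "#2C7FB8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Mean ROC (%d-fold CV), AUC = %.3f +/- %.3f",
                      object$k, object$auc_mean, object$auc_sd)
    ) +
    ggplot2::theme_minimal()
}

#' Band-wise connectivity matrices as heatmaps
#'
#' @param object a `netsig_connectivity`
#' @param ... unused
#' @return a ggplot faceted by band
#' @export
autoplot.netsig_connectivity <- function(object, ...) {
  df <- purrr::imap_dfr(object$bands, function(m, band) {
    tibble::tibble(band = band,
                   from = rep(rownames(m), ncol(m)),
                   to = rep(colnames(m), each = nrow(m)),
                   wpli = as.vector(m))
  })
  df$from <- factor(df$from, levels = rownames(object$bands[[1]]))
  df$to <- factor(df$to, levels = rownames(object$bands[[1]]))
  df$band <- factor(df$band, levels = names(object$bands))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$wpli)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::facet_wrap(~band) +
    ggplot2::labs(x = NULL, y = NULL, fill = "wPLI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Channel power spectral densities
#'
#' @param object a `netsig_spectrum`
#' @param log10_power plot log10 PSD (default TRUE)
#' @param fmax upper frequency limit for display
#' @param ... unused
#' @return a ggplot, one line per channel
#' @export
autoplot.netsig_spectrum <- function(object, log10_power = TRUE, fmax = 40, ...) {
  df <- tibble::tibble(
    channel = rep(object$labels, each = length(object$freqs)),
    freq = rep(object$freqs, nrow(object$psd)),
    psd = as.vector(t(object$psd))
  ) |> dplyr::filter(.data$freq > 0, .data$freq <= fmax)
  if (log10_power) df$psd <- log10(df$psd)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$psd,
                                   group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = if (log10_power) "log10 PSD (uV²/Hz)" else "PSD (uV²/Hz)") +
    ggplot2::theme_minimal()
}

#' Group contrast plot for a tested feature table
#'
#' Dot-and-error display of the group mean differences with BH-significance
#' highlighting, from the `feature_tests` table of [run_stats()].
#'
#' @param stats a `netsig_stats`
#' @return a ggplot
#' @export
plot_feature_tests <- function(stats) {
  stopifnot(inherits(stats, "netsig_stats"))
  df <- stats$feature_tests |>
    dplyr::mutate(label = ifelse(is.na(.data$band), .data$metric,
                                 paste(.data$metric, .data$band, sep = "_")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic,
                                   y = stats::reorder(.data$label, .data$statistic),
                                   color = .data$rejected)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50", `TRUE` = "#D7301F")) +
    ggplot2::labs(x = "Group mean difference (DRE-like - responder)", y = NULL,
                  color = "BH significant") +
    ggplot2::theme_minimal()
}
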