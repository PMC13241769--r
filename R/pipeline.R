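#' Extract the full qEEG feature set from one recording
#'
#' Runs spectral, connectivity and graph analysis on an already-preprocessed
#' recording and returns the tidy feature rows: relative band power,
#' aperiodic exponent and offset (per channel and GLOBAL), global wPLI per
#' band, and the six graph metrics per band. This function never sees
#' outcome labels - extraction is blinded by construction.
#'
#' @param rec a [recording()]
#' @param epochs optional [epoch_set()]; default selects the leading
#'   `epoch_target` seconds
#' @param epoch_target,epoch_tol epoch selection targets in seconds
#' @param bands band table as from [band_definitions()]
#' @param density binarization edge density for graph metrics
#' @param n_null small-world-index null count
#' @param seed seed for graph null models
#' @return tidy tibble with columns `metric`, `band`, `scope`, `channel`,
#'   `value`
#' @export
extract_features <- function(rec, epochs = NULL, epoch_target = 180,
                             epoch_tol = 25, bands = band_definitions(),
                             density = 0.05, n_null = 20, seed = 1L) {
  stopifnot(inherits(rec, "netsig_recording"))
  if (is.null(epochs)) {
    epochs <- select_epochs(rec, target = min(epoch_target, n_samples(rec) / rec$fs),
                            tol = epoch_tol, strict = FALSE)
  }
  spec <- welch_psd(rec, epochs)
  bp <- band_relative_power(spec, bands)
  ap <- fit_aperiodic(spec)
  cs <- cross_spectra(rec, epochs)
  cm <- wpli(cs, bands)
  gw <- global_wpli(cm)
  gm <- graph_metrics(cm, density = density, n_null = n_null, seed = seed)
  scope_of <- function(channel) ifelse(channel == "GLOBAL", "GLOBAL", "channel")
  dplyr::bind_rows(
    bp |>
      dplyr::transmute(metric = "rel_power", band = as.character(.data$band),
                       scope = scope_of(.data$channel),
                       channel = .data$channel, value = .data$rel_power),
    ap |>
      tidyr::pivot_longer(c("exponent", "offset"), names_to = "metric") |>
      dplyr::transmute(metric = .data$metric, band = NA_character_,
                       scope = scope_of(.data$channel),
                       channel = .data$channel, value = .data$value),
    tibble::tibble(metric = "wpli_global", band = names(gw), scope = "GLOBAL",
                   channel = "GLOBAL", value = unname(gw)),
    gm |>
      tidyr::pivot_longer(c("Q", "swi", "btwc", "ge", "clustering", "lambda"),
                          names_to = "metric") |>
      dplyr::transmute(metric = .data$metric, band = .data$band,
                       scope = "GLOBAL", channel = "GLOBAL",
                       value = .data$value)
  )
}

#' Extract features for a whole cohort
#'
#' Accepts either a cohort list from [gen_cohort()] (with recordings kept),
#' a bare named list of recordings, or a [cohort_config()] - in the latter
#' case subjects are generated one at a time and discarded after feature
#' extraction, so arbitrarily large synthetic cohorts run in bounded
#' memory. Per-subject failures are logged and skipped; the run errors if
#' more than 20% of subjects fail.
#'
#' @param x cohort list, named list of recordings, or config
#' @param seed seed driving graph null models (per-subject sub-seeds)
#' @param progress print one line per subject
#' @param ... passed to [extract_features()]
#' @return tidy feature tibble with a leading `subject_id` column
#' @export
run_extract <- function(x, seed = 1L, progress = FALSE, ...) {
  jobs <- NULL
  if (inherits(x, "netsig_cohort_config")) {
    idx <- seq_len(2 * x$n_per_group)
    jobs <- purrr::map(idx, function(i) {
      force(i)
      function() gen_subject(x, if (i <= x$n_per_group) 1L else 2L, i)$recording
    })
    names(jobs) <- sprintf("S%03d", idx)
  } else {
    recs <- if (!is.null(x$recordings)) x$recordings else x
    if (!length(recs) || !all(purrr::map_lgl(recs, inherits, "netsig_recording"))) {
      abort_netsig("`x` must be recordings, a cohort, or a cohort config.",
                   "netsig_parameter_error")
    }
    jobs <- purrr::map(recs, function(r) function() r)
    names(jobs) <- names(recs) %||% sprintf("S%03d", seq_along(recs))
  }
  failed <- character(0)
  out <- purrr::imap(jobs, function(job, sid) {
    if (progress) message("extracting ", sid)
    tryCatch({
      rec <- job()
      ft <- extract_features(rec, seed = derive_seed(seed, match(sid, names(jobs))), ...)
      dplyr::mutate(ft, subject_id = sid, .before = 1)
    }, error = function(e) {
      message("subject ", sid, " skipped: ", conditionMessage(e))
      failed <<- c(failed, sid)
      NULL
    })
  })
  if (length(failed) > 0.2 * length(jobs)) {
    abort_netsig(sprintf("%d of %d subjects failed extraction.",
                         length(failed), length(jobs)), "netsig_run_error")
  }
  dplyr::bind_rows(out)
}

#' Default qEEG feature block for classification
#'
#' The realized feature list carried into the qEEG-augmented model: delta
#' and alpha relative power, aperiodic exponent and offset, delta and alpha
#' betweenness, delta small-world index and delta global efficiency (all
#' GLOBAL scope).
#' @return tibble with `metric`, `band`
#' @export
default_qeeg_features <- function() {
  tibble::tribble(
    ~metric, ~band,
    "rel_power", "delta",
    "rel_power", "alpha",
    "exponent", NA_character_,
    "offset", NA_character_,
    "btwc", "delta",
    "btwc", "alpha",
    "swi", "delta",
    "ge", "delta"
  )
}

#' Default clinical predictor columns for classification
#' @return character vector of column names
#' @export
default_clinical_predictors <- function() {
  c("sex_female", "age", "age_onset", "duration", "baseline_seizure_freq",
    "n_seizure_types", "focal", "structural_etiology",
    "neuroimaging_abnormal", "etle", "asm1_response")
}

feature_wide <- function(features, select = NULL, scope = "GLOBAL") {
  f <- dplyr::filter(features, .data$scope == !!scope)
  if (!is.null(select)) {
    f <- dplyr::inner_join(f, select, by = c("metric", "band"))
  }
  f |>
    dplyr::mutate(name = ifelse(is.na(.data$band), .data$metric,
                                paste(.data$metric, .data$band, sep = "_"))) |>
    dplyr::select("subject_id", "name", "value") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value")
}

#' Group statistics over an extracted feature table
#'
#' For every GLOBAL (metric, band) feature: a two-sample permutation test
#' between outcome groups, stabilized by the most-frequent-p procedure, with
#' Benjamini-Hochberg correction across all features. Band-resolved metric
#' families (relative power, global wPLI) additionally get the split-plot
#' band x group ANOVA with Greenhouse-Geisser, Mauchly and Bartlett
#' diagnostics.
#'
#' @param features tidy feature tibble from [run_extract()]
#' @param clinical clinical table sharing `subject_id` (supplies `outcome`)
#' @param n_perm permutations per test
#' @param n_repeats repeats for the modal-p stabilization
#' @param q FDR level
#' @param seed RNG seed
#' @return a `netsig_stats` list: `feature_tests` (tibble), `anova` (named
#'   list of `netsig_anova`), parameters
#' @export
run_stats <- function(features, clinical, n_perm = 10000, n_repeats = 100,
                      q = 0.05, seed = 1L) {
  if (nrow(features) == 0) {
    abort_netsig("Empty feature table.", "netsig_parameter_error")
  }
  miss <- setdiff(unique(features$subject_id), clinical$subject_id)
  if (length(miss)) {
    abort_netsig(paste("Subjects missing from the clinical table:",
                       paste(miss, collapse = ", ")), "netsig_parameter_error")
  }
  glob <- dplyr::filter(features, .data$scope == "GLOBAL") |>
    dplyr::left_join(dplyr::select(clinical, "subject_id", "outcome"),
                     by = "subject_id")
  keys <- dplyr::distinct(glob, .data$metric, .data$band)
  tests <- purrr::pmap_dfr(keys, function(metric, band) {
    d <- glob[glob$metric == metric &
                (is.na(band) | (!is.na(glob$band) & glob$band == band)), ]
    x <- d$value[d$outcome == 1]
    y <- d$value[d$outcome == 0]
    ok <- sum(is.finite(x)) >= 2 && sum(is.finite(y)) >= 2
    if (!ok) {
      return(tibble::tibble(metric = metric, band = band,
                            mean_dre = mean(x, na.rm = TRUE),
                            mean_ctrl = mean(y, na.rm = TRUE),
                            statistic = NA_real_, p = NA_real_))
    }
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    fseed <- derive_seed(seed, 1000 + nrow(keys) * 7 + match(paste(metric, band),
                                paste(keys$metric, keys$band)))
    p <- modal_p(function(s) permutation_test(x, y, n_perm = n_perm,
                                              seed = s)$p,
                 n_repeats = n_repeats, seed = fseed)
    tibble::tibble(metric = metric, band = band,
                   mean_dre = mean(x), mean_ctrl = mean(y),
                   statistic = mean(x) - mean(y), p = p)
  })
  fdr <- bh_fdr(tests$p, q = q)
  tests$p_adj <- fdr$p_adj
  tests$rejected <- fdr$rejected
  anovas <- list()
  for (m in c("rel_power", "wpli_global")) {
    d <- glob |>
      dplyr::filter(.data$metric == m, !is.na(.data$band)) |>
      dplyr::transmute(subject = .data$subject_id,
                       group = ifelse(.data$outcome == 1, "DRE", "nonDRE"),
                       band = .data$band, value = .data$value)
    if (nrow(d) > 0 && !anyNA(d$value)) {
      anovas[[m]] <- mixed_anova(d)
    }
  }
  structure(list(feature_tests = tests, anova = anovas,
                 n_perm = n_perm, n_repeats = n_repeats, q = q, seed = seed),
            class = "netsig_stats")
}

#' @export
print.netsig_stats <- function(x, ...) {
  cat(sprintf("<netsig_stats> %d features tested (%d significant after BH at q = %g)\n",
              nrow(x$feature_tests), sum(x$feature_tests$rejected, na.rm = TRUE),
              x$q))
  print(as.data.frame(dplyr::arrange(x$feature_tests, .data$p)), digits = 3)
  invisible(x)
}

#' Fit and compare the clinical-only and clinical+qEEG models
#'
#' Builds the clinical design from `predictors`, appends the qEEG block
#' (default: the realized feature list of [default_qeeg_features()], or the
#' features flagged significant in a supplied `netsig_stats`), runs
#' stratified cross-validated logistic ROC analysis for both models and the
#' permutation model comparison.
#'
#' @param features tidy feature tibble from [run_extract()]
#' @param clinical clinical table (supplies `outcome` and predictors)
#' @param predictors clinical predictor columns
#' @param qeeg_select tibble (`metric`, `band`) of qEEG features, a
#'   `netsig_stats` (uses its BH-rejected features), or `NULL` for the
#'   default list
#' @param k CV folds
#' @param n_perm permutations for the model comparison
#' @param seed RNG seed
#' @return a `netsig_classify` list: `cv_base`, `cv_full`, `comparison`,
#'   `salience` (tibble ordered by |beta|)
#' @export
run_classify <- function(features, clinical,
                         predictors = default_clinical_predictors(),
                         qeeg_select = NULL, k = 5, n_perm = 10000,
                         seed = 1L) {
  if (inherits(qeeg_select, "netsig_stats")) {
    qeeg_select <- qeeg_select$feature_tests |>
      dplyr::filter(.data$rejected,
                    .data$metric %in% c("rel_power", "exponent", "offset",
                                        "btwc", "swi", "ge", "clustering",
                                        "lambda", "Q", "wpli_global")) |>
      dplyr::select("metric", "band")
  }
  qeeg_select <- qeeg_select %||% default_qeeg_features()
  Xq_tbl <- feature_wide(features, qeeg_select)
  cl <- dplyr::semi_join(clinical, Xq_tbl, by = "subject_id") |>
    dplyr::arrange(match(.data$subject_id, Xq_tbl$subject_id))
  miss <- setdiff(Xq_tbl$subject_id, cl$subject_id)
  if (length(miss)) {
    abort_netsig(paste("Subjects missing from the clinical table:",
                       paste(miss, collapse = ", ")), "netsig_parameter_error")
  }
  X_clin <- as.matrix(cl[, predictors])
  X_qeeg <- as.matrix(Xq_tbl[, setdiff(names(Xq_tbl), "subject_id")])
  keep <- stats::complete.cases(X_qeeg)
  y <- cl$outcome
  cv_base <- crossval_roc(X_clin[keep, , drop = FALSE], y[keep], k = k,
                          seed = derive_seed(seed, 1))
  cv_full <- crossval_roc(cbind(X_clin, X_qeeg)[keep, , drop = FALSE], y[keep],
                          k = k, seed = derive_seed(seed, 1))
  cmp <- compare_models(X_clin[keep, , drop = FALSE],
                        X_qeeg[keep, , drop = FALSE], y[keep], k = k,
                        n_perm = n_perm, seed = derive_seed(seed, 2))
  sal <- tibble::tibble(
    feature = names(cv_full$coef)[-1],
    beta = unname(cv_full$coef[-1]),
    abs_beta = abs(unname(cv_full$coef[-1])),
    p = unname(cv_full$coef_p[-1])
  ) |> dplyr::arrange(dplyr::desc(.data$abs_beta))
  structure(list(cv_base = cv_base, cv_full = cv_full, comparison = cmp,
                 salience = sal, n_used = sum(keep), seed = seed),
            class = "netsig_classify")
}

#' @export
print.netsig_classify <- function(x, ...) {
  cat(sprintf("<netsig_classify> AUC clinical-only %.3f +/- %.3f | clinical+qEEG %.3f +/- %.3f | delta p = %.4g\n",
              x$cv_base$auc_mean, x$cv_base$auc_sd,
              x$cv_full$auc_mean, x$cv_full$auc_sd, x$comparison$p))
  cat("top saliences:\n")
  print(as.data.frame(utils::head(x$salience, 5)), digits = 3)
  invisible(x)
}

#' End-to-end pipeline on a synthetic cohort
#'
#' simulate -> extract -> stats -> classify, fully seeded. Statistical and
#' classification workloads are controlled by the `n_perm*` arguments so
#' validation runs can be scaled.
#'
#' @param cfg a [cohort_config()]
#' @param n_perm permutations for feature tests
#' @param n_repeats modal-p repeats
#' @param n_perm_cmp permutations for the model comparison
#' @param seed analysis-stage seed (cohort generation uses `cfg$seed`)
#' @return list with `features`, `clinical`, `truth`, `stats`, `classify`
#' @export
run_pipeline <- function(cfg = cohort_config(), n_perm = 10000,
                         n_repeats = 100, n_perm_cmp = 10000, seed = 1L) {
  clinical <- gen_clinical(cfg)
  truth <- purrr::map_dfr(seq_len(2 * cfg$n_per_group), function(i) {
    g <- if (i <= cfg$n_per_group) 1L else 2L
    gen_subject_truth(cfg, g, i)
  })
  features <- run_extract(cfg, seed = derive_seed(seed, 10))
  st <- run_stats(features, clinical, n_perm = n_perm, n_repeats = n_repeats,
                  seed = derive_seed(seed, 20))
  clf <- run_classify(features, clinical, qeeg_select = NULL,
                      n_perm = n_perm_cmp, seed = derive_seed(seed, 30))
  list(features = features, clinical = clinical, truth = truth,
       stats = st, classify = clf)
}

gen_subject_truth <- function(cfg, group, index) {
  gen_subject_params_only(cfg, group, index)
}

# parameter draw identical to gen_subject, without synthesizing the signal
gen_subject_params_only <- function(cfg, group, index) {
  sseed <- derive_seed(cfg$seed, index)
  sds <- cfg$subject_sd
  pars <- with_seed(derive_seed(sseed, 1), list(
    exponent = min(0, cfg$exponent[group] + stats::rnorm(1, 0, sds$exponent)),
    offset = cfg$offset[group] + stats::rnorm(1, 0, sds$offset),
    amp_delta = cfg$amp_delta[group] * exp(stats::rnorm(1, 0, sds$log_amp)),
    amp_alpha = cfg$amp_alpha[group] * exp(stats::rnorm(1, 0, sds$log_amp))
  ))
  tibble::tibble(
    subject_id = sprintf("S%03d", index), group = group,
    outcome = as.integer(group == 1),
    exponent = pars$exponent, offset = pars$offset,
    amp_delta = pars$amp_delta, amp_alpha = pars$amp_alpha,
    backbone = cfg$coupling$backbones[group],
    n_coupled = 9L, seed = sseed
  )
}
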