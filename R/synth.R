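#' Generate aperiodic (1/f-like) background noise
#'
#' Spectral-shaping construction: complex Gaussian coefficients are drawn in
#' the frequency domain with one-sided power spectral density
#' `10^offset * f^exponent` and inverse-transformed, so the expected Welch
#' PSD of the series follows the requested power law exactly (in
#' expectation) at every nonzero frequency.
#'
#' @param exponent spectral exponent chi <= 0 (slope of log10-power against
#'   log10-frequency; more negative = steeper decay)
#' @param offset log10 power at 1 Hz, in log10(uV^2/Hz)
#' @param duration length in seconds
#' @param fs sampling rate in Hz
#' @param seed RNG seed
#' @return numeric vector of `duration * fs` samples (uV)
#' @export
gen_aperiodic_noise <- function(exponent, offset, duration, fs, seed) {
  if (exponent > 0) {
    abort_netsig("`exponent` must be <= 0.", "netsig_parameter_error")
  }
  n <- round(duration * fs)
  nfreq <- n %/% 2 + 1
  f <- seq(0, nfreq - 1) * fs / n
  p <- c(0, 10^offset * f[-1]^exponent) # one-sided density target; no DC power
  with_seed(seed, {
    amp <- sqrt(n * fs * p / 2)
    re <- stats::rnorm(nfreq) / sqrt(2)
    im <- stats::rnorm(nfreq) / sqrt(2)
    X <- complex(real = amp * re, imaginary = amp * im)
    X[1] <- 0
    if (n %% 2 == 0) X[nfreq] <- complex(real = amp[nfreq] * re[nfreq] * sqrt(2), imaginary = 0)
    full <- c(X, Conj(rev(X[2:(nfreq - 1 + n %% 2)])))
    Re(stats::fft(full, inverse = TRUE)) / n
  })
}

#' Generate a narrowband oscillation
#'
#' Band-limited Gaussian process: white noise is shaped in the frequency
#' domain by a Gaussian envelope centered at `center` with spectral standard
#' deviation `bandwidth / 2`, then scaled to the requested RMS amplitude.
#' `phase_offset` rotates the analytic signal by a constant phase, so two
#' calls sharing a `seed` differ by exactly that phase lag at every moment.
#'
#' @param center center frequency, Hz (0 < center < fs/2)
#' @param bandwidth full spectral width parameter, Hz (> 0)
#' @param amplitude target RMS amplitude, uV (>= 0); 0 returns a zero series
#' @param duration length in seconds
#' @param fs sampling rate, Hz
#' @param seed RNG seed
#' @param phase_offset constant phase lag in radians
#' @return numeric vector of `duration * fs` samples
#' @export
gen_oscillation <- function(center, bandwidth, amplitude, duration, fs, seed,
                            phase_offset = 0) {
  if (center <= 0 || center >= fs / 2) {
    abort_netsig("`center` must lie in (0, fs/2).", "netsig_parameter_error")
  }
  if (bandwidth <= 0) {
    abort_netsig("`bandwidth` must be positive.", "netsig_parameter_error")
  }
  n <- round(duration * fs)
  if (amplitude == 0) {
    return(numeric(n))
  }
  w <- with_seed(seed, stats::rnorm(n))
  W <- stats::fft(w)
  f <- seq(0, n - 1) * fs / n
  f_fold <- pmin(f, fs - f)
  env <- exp(-(f_fold - center)^2 / (2 * (bandwidth / 2)^2))
  pos <- f > 0 & f < fs / 2
  neg <- f > fs / 2
  rot <- rep(complex(real = 1), n)
  rot[pos] <- exp(complex(imaginary = -phase_offset))
  rot[neg] <- exp(complex(imaginary = phase_offset))
  x <- Re(stats::fft(W * env * rot, inverse = TRUE)) / n
  x * amplitude / sqrt(mean(x^2))
}

#' Instantaneous (zero-lag) linear mixing
#'
#' Multiplies the channel matrix by a square nonsingular mixing matrix,
#' emulating volume conduction: a purely instantaneous mixture introduces
#' zero-lag correlations only, which the wPLI estimator is designed to
#' suppress.
#'
#' @param x channels x samples matrix, or a [recording()]
#' @param mixing square mixing matrix (channels x channels)
#' @return mixed object of the same type as `x`
#' @export
mix_zero_lag <- function(x, mixing) {
  m <- if (inherits(x, "netsig_recording")) x$data else x
  if (!is.matrix(mixing) || nrow(mixing) != ncol(mixing) ||
      nrow(mixing) != nrow(m)) {
    abort_netsig("`mixing` must be square with one row per channel.",
                 "netsig_parameter_error")
  }
  if (rcond(mixing) < 1e-12) {
    abort_netsig("`mixing` is singular or near-singular.", "netsig_parameter_error")
  }
  mixed <- mixing %*% m
  if (inherits(x, "netsig_recording")) {
    x$data <- mixed
    x$meta$mixed <- TRUE
    x
  } else {
    mixed
  }
}

#' Default exponential-falloff volume-conduction mixing matrix
#'
#' `M = I + spread * K`, `K_ij = exp(-|i-j|)` for neighboring channel
#' indices: a crude but nonsingular stand-in for scalp leakage, strongest
#' between adjacent electrodes.
#' @param n_channels number of channels
#' @param spread leakage strength (0 disables mixing)
#' @return n x n mixing matrix
#' @export
mixing_matrix <- function(n_channels, spread = 0.25) {
  d <- abs(outer(seq_len(n_channels), seq_len(n_channels), "-"))
  K <- exp(-d)
  diag(K) <- 0
  diag(n_channels) + spread * K
}

#' Coupling backbone graphs for the two cohort groups
#'
#' Nine-edge motifs whose binarized-graph metrics realize the drug-resistant
#' vs responder topology contrast at the pipeline's 5% edge density
#' (9 edges on 19 channels):
#' * `"segregated"` (DRE-like): a clustered triangle with two long pendant
#'   chains - an elongated, regular-leaning layout: lower global efficiency,
#'   higher betweenness, lower small-world index.
#' * `"integrated"` (non-DRE-like): a triangle with short interlinked
#'   branches - a compact, small-world-leaning layout: higher efficiency and
#'   small-world index, lower betweenness.
#' With probability `jitter_p` each edge is rewired to a random pair
#' (per-subject biological variability).
#'
#' @param type backbone type
#' @param n_channels total channel count (>= 8)
#' @param jitter_p per-edge rewiring probability
#' @param seed RNG seed for the jitter
#' @return integer edge matrix, columns `i`, `j` (i < j)
#' @export
coupling_backbone <- function(type = c("segregated", "integrated"),
                              n_channels = 19, jitter_p = 0.05, seed = 1L) {
  type <- match.arg(type)
  el <- switch(type,
    segregated = rbind(c(1, 5), c(5, 8), c(3, 8), c(3, 7), c(4, 7),
                         c(2, 4), c(4, 6), c(2, 6), c(2, 9)),
    integrated = rbind(c(1, 7), c(3, 7), c(4, 9), c(3, 5), c(5, 6),
                          c(2, 6), c(1, 3), c(4, 5), c(6, 8))
  )
  if (jitter_p > 0) {
    el <- with_seed(seed, {
      for (e in seq_len(nrow(el))) {
        if (stats::runif(1) < jitter_p) {
          for (try in 1:100) {
            anchor <- el[e, sample(2, 1)]
            cand <- sample(n_channels, 1)
            ne <- sort(c(anchor, cand))
            dup <- any(el[, 1] == ne[1] & el[, 2] == ne[2])
            if (cand != anchor && !dup) {
              el[e, ] <- ne
              break
            }
          }
        }
      }
      el
    })
  }
  colnames(el) <- c("i", "j")
  el
}

#' Cohort generator configuration
#'
#' Defaults encode the study conditions the pipeline is validated under:
#' two groups of 60 subjects, 19 channels at 256 Hz for 180 s, and a
#' DRE-like group with higher delta and lower alpha oscillation amplitude, a
#' more negative aperiodic exponent and offset, and a segregated, elongated
#' delta-band coupling topology against the responder group's compact
#' integrated topology. Amplitudes are in uV RMS; exponents are the
#' log-log PSD slopes of the aperiodic background.
#'
#' @param n_per_group subjects per group
#' @param n_channels,fs,duration recording geometry
#' @param exponent,offset,amp_delta,amp_alpha length-2 numeric vectors,
#'   `c(DRE-like, responder)` generative parameters
#' @param subject_sd list of per-subject jitter SDs for `exponent`, `offset`
#'   and (log-scale) amplitudes
#' @param coupling list: `band` = c(center, bandwidth) Hz of the coupled
#'   oscillation, `strength` in `[0,1]` (fraction of band variance shared),
#'   `lag` radians, `backbones` = types per group, `jitter_p`
#' @param mixing_spread zero-lag leakage strength (see [mixing_matrix()])
#' @param clinical list of group-wise clinical covariate parameters
#'   (Bernoulli rates and normal/log-normal moments per group, DRE-like
#'   first)
#' @param seed master seed; everything else derives from it
#' @return a `netsig_cohort_config` list
#' @export
cohort_config <- function(n_per_group = 60, n_channels = 19, fs = 256,
                          duration = 180,
                          exponent = c(-1.9, -1.5),
                          offset = c(0.7, 1.0),
                          amp_delta = c(6, 4),
                          amp_alpha = c(7, 10),
                          subject_sd = list(exponent = 0.1, offset = 0.1,
                                            log_amp = 0.1),
                          coupling = list(band = c(3, 1.5), strength = 0.9,
                                          lag = pi / 2,
                                          backbones = c("segregated",
                                                        "integrated"),
                                          jitter_p = 0.05),
                          mixing_spread = 0.25,
                          clinical = default_clinical_params(),
                          seed = 20260925) {
  stopifnot(n_per_group >= 1, n_channels >= 8, fs > 0, duration > 0)
  structure(
    list(n_per_group = n_per_group, n_channels = n_channels, fs = fs,
         duration = duration, exponent = exponent, offset = offset,
         amp_delta = amp_delta, amp_alpha = amp_alpha,
         subject_sd = subject_sd, coupling = coupling,
         mixing_spread = mixing_spread, clinical = clinical, seed = seed),
    class = "netsig_cohort_config"
  )
}

#' Group-wise clinical covariate parameters
#'
#' Bernoulli rates and continuous-moment pairs `c(DRE-like, responder)`
#' matching the contrasts reported for clinical predictors of drug
#' resistance (response to the first anti-seizure medication is the
#' strongest discriminant).
#' @return named list of length-2 parameter vectors
#' @export
default_clinical_params <- function() {
  list(
    sex_female = c(0.60, 0.45),
    age_mean = c(46.7, 50.6), age_sd = c(22.4, 18.9),
    onset_mean = c(33.3, 38.8), onset_sd = c(24.2, 20.6),
    duration_mean = c(13.5, 12.5), duration_sd = c(12.7, 11.5),
    seizfreq_meanlog = log(c(3, 2)), seizfreq_sdlog = c(1.1, 0.9),
    types_probs = list(c(0.6, 0.3, 0.1), c(0.75, 0.25, 0)),
    focal = c(0.90, 0.917),
    structural_etiology = c(0.433, 0.167),
    neuroimaging_abnormal = c(0.70, 0.567),
    etle = c(0.217, 0.267),
    asm1_response = c(0.183, 0.433)
  )
}

#' Generate one synthetic subject recording
#'
#' Assembles, per channel, the aperiodic 1/f background plus delta and alpha
#' narrowband oscillations; delta-band oscillations of coupled channel pairs
#' share a lagged common source (fraction `strength` of band variance),
#' after which the whole montage passes through the zero-lag mixing matrix.
#'
#' @param cfg a [cohort_config()]
#' @param group 1 (DRE-like) or 2 (responder)
#' @param index subject index within the cohort (drives sub-seeding)
#' @return list with `recording`, `truth` (one-row tibble), `backbone`
#' @export
gen_subject <- function(cfg, group, index) {
  sseed <- derive_seed(cfg$seed, index)
  nch <- cfg$n_channels
  n <- round(cfg$duration * cfg$fs)
  sds <- cfg$subject_sd
  pars <- with_seed(derive_seed(sseed, 1), list(
    exponent = min(0, cfg$exponent[group] + stats::rnorm(1, 0, sds$exponent)),
    offset = cfg$offset[group] + stats::rnorm(1, 0, sds$offset),
    amp_delta = cfg$amp_delta[group] * exp(stats::rnorm(1, 0, sds$log_amp)),
    amp_alpha = cfg$amp_alpha[group] * exp(stats::rnorm(1, 0, sds$log_amp))
  ))
  cp <- cfg$coupling
  el <- coupling_backbone(cp$backbones[group], nch, cp$jitter_p,
                          seed = derive_seed(sseed, 2))
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = nch)
  # equal variance share per coupled pair (strength split over the maximum
  # backbone degree) so every backbone edge is equally detectable by wPLI
  share <- cp$strength / max(deg, 1)
  X <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    ap <- gen_aperiodic_noise(pars$exponent, pars$offset, cfg$duration, cfg$fs,
                              seed = derive_seed(sseed, 10 + ch))
    own_delta_var <- max(0, 1 - deg[ch] * share)
    dl <- gen_oscillation(cp$band[1], cp$band[2],
                          pars$amp_delta * sqrt(own_delta_var),
                          cfg$duration, cfg$fs,
                          seed = derive_seed(sseed, 100 + ch))
    al <- gen_oscillation(10, 2.5, pars$amp_alpha, cfg$duration, cfg$fs,
                          seed = derive_seed(sseed, 200 + ch))
    X[ch, ] <- ap + dl + al
  }
  # lagged shared sources on the coupling backbone
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    eseed <- derive_seed(sseed, 300 + e)
    u_i <- gen_oscillation(cp$band[1], cp$band[2], 1, cfg$duration, cfg$fs,
                           seed = eseed, phase_offset = 0)
    u_j <- gen_oscillation(cp$band[1], cp$band[2], 1, cfg$duration, cfg$fs,
                           seed = eseed, phase_offset = cp$lag)
    X[i, ] <- X[i, ] + pars$amp_delta * sqrt(share) * u_i
    X[j, ] <- X[j, ] + pars$amp_delta * sqrt(share) * u_j
  }
  if (cfg$mixing_spread > 0) {
    X <- mix_zero_lag(X, mixing_matrix(nch, cfg$mixing_spread))
  }
  labels <- channel_labels(nch)
  rec <- recording(X, fs = cfg$fs, labels = labels,
                   meta = list(subject = index, group = group, seed = sseed))
  truth <- tibble::tibble(
    subject_id = sprintf("S%03d", index), group = group,
    outcome = as.integer(group == 1),
    exponent = pars$exponent, offset = pars$offset,
    amp_delta = pars$amp_delta, amp_alpha = pars$amp_alpha,
    backbone = cp$backbones[group], n_coupled = nrow(el), seed = sseed
  )
  list(recording = rec, truth = truth, backbone = el)
}

#' Standard 10-20 channel labels
#' @param n number of channels (up to 19 standard names, then generic)
#' @export
channel_labels <- function(n) {
  std <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
           "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  if (n <= length(std)) std[seq_len(n)] else c(std, paste0("ch", seq_len(n - length(std))))
}

#' Generate clinical covariates for a cohort
#'
#' @param cfg a [cohort_config()]
#' @return tibble, one row per subject (rows ordered DRE-like group first)
#' @export
gen_clinical <- function(cfg) {
  p <- cfg$clinical
  ng <- cfg$n_per_group
  with_seed(derive_seed(cfg$seed, 900001), {
    rows <- purrr::map_dfr(1:2, function(g) {
      idx <- seq_len(ng) + (g - 1) * ng
      age <- pmin(90, pmax(18, stats::rnorm(ng, p$age_mean[g], p$age_sd[g])))
      onset <- pmax(1, pmin(age - 0.5, stats::rnorm(ng, p$onset_mean[g], p$onset_sd[g])))
      tibble::tibble(
        subject_id = sprintf("S%03d", idx),
        outcome = as.integer(g == 1),
        sex_female = stats::rbinom(ng, 1, p$sex_female[g]),
        age = round(age, 1),
        age_onset = round(onset, 1),
        duration = round(pmax(0.5, stats::rnorm(ng, p$duration_mean[g], p$duration_sd[g])), 1),
        baseline_seizure_freq = pmax(1, round(stats::rlnorm(ng, p$seizfreq_meanlog[g], p$seizfreq_sdlog[g]))),
        n_seizure_types = sample(1:3, ng, replace = TRUE, prob = p$types_probs[[g]]),
        focal = stats::rbinom(ng, 1, p$focal[g]),
        structural_etiology = stats::rbinom(ng, 1, p$structural_etiology[g]),
        neuroimaging_abnormal = stats::rbinom(ng, 1, p$neuroimaging_abnormal[g]),
        etle = stats::rbinom(ng, 1, p$etle[g]),
        asm1_response = stats::rbinom(ng, 1, p$asm1_response[g])
      )
    })
    rows$sba <- rows$neuroimaging_abnormal # pSBA indicator
    validate_clinical(rows)
  })
}

#' Generate a full synthetic cohort
#'
#' DRE-like subjects first (indices 1..n_per_group), responders after.
#' Fully deterministic under the config's master seed via per-subject
#' sub-seeding.
#'
#' @param cfg a [cohort_config()]
#' @param keep_recordings if `FALSE`, recordings are dropped (use
#'   [gen_subject()] to regenerate on demand in streaming pipelines)
#' @return list with `recordings` (named list of [recording()]s or `NULL`),
#'   `clinical` (tibble) and `truth` (tibble)
#' @export
gen_cohort <- function(cfg, keep_recordings = TRUE) {
  stopifnot(inherits(cfg, "netsig_cohort_config"))
  subs <- purrr::map(seq_len(2 * cfg$n_per_group), function(i) {
    g <- if (i <= cfg$n_per_group) 1L else 2L
    gen_subject(cfg, g, i)
  })
  truth <- purrr::map_dfr(subs, "truth")
  recs <- NULL
  if (keep_recordings) {
    recs <- purrr::map(subs, "recording")
    names(recs) <- truth$subject_id
  }
  list(recordings = recs, clinical = gen_clinical(cfg), truth = truth)
}
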