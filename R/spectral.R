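#' Frequency band definitions
#'
#' Default analysis bands: delta (2-4 Hz), theta (5-7 Hz), alpha (8-12 Hz),
#' beta (13-29 Hz). Bands are closed intervals evaluated on the spectral
#' grid; with the default 0.5 Hz resolution the bins at 4.5, 7.5 and 12.5 Hz
#' fall between bands, so relative powers over the four bands sum to slightly
#' less than one by construction. Gamma is excluded: in clinical scalp EEG it
#' is dominated by muscle artifact.
#'
#' @return tibble with columns `band`, `lo`, `hi`
#' @export
band_definitions <- function() {
  tibble::tribble(
    ~band, ~lo, ~hi,
    "delta", 2, 4,
    "theta", 5, 7,
    "alpha", 8, 12,
    "beta", 13, 29
  )
}

#' Hann-tapered segment FFTs shared by PSD and cross-spectral estimation
#'
#' Segments never straddle epoch boundaries. Returns the one-sided FFTs with
#' the scaling factors needed for density normalization.
#' @noRd
segment_ffts <- function(rec, epochs = NULL, window = 2, overlap = 0.5) {
  fs <- rec$fs
  nper <- round(window * fs)
  step <- max(1, round(nper * (1 - overlap)))
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nper - 1) / nper)) # periodic Hann
  blocks <- epoch_data(rec, epochs)
  segs <- list()
  for (blk in blocks) {
    ns <- ncol(blk)
    if (ns < nper) next
    starts <- seq(1, ns - nper + 1, by = step)
    for (s in starts) {
      segs[[length(segs) + 1]] <- blk[, s:(s + nper - 1), drop = FALSE]
    }
  }
  if (length(segs) == 0) {
    abort_netsig("No segment of one full analysis window fits in the epochs.",
                 "netsig_insufficient_data")
  }
  nfreq <- nper %/% 2 + 1
  n_seg <- length(segs)
  nch <- n_channels(rec)
  Z <- array(complex(real = 0), dim = c(nfreq, nch, n_seg))
  for (k in seq_len(n_seg)) {
    X <- t(segs[[k]]) * w # nper x nch, tapered
    F <- stats::mvfft(X)
    Z[, , k] <- F[seq_len(nfreq), , drop = FALSE]
  }
  list(
    Z = Z,
    freqs = seq(0, nfreq - 1) * fs / nper,
    fs = fs, nper = nper, n_segments = n_seg,
    win_ss = sum(w^2), labels = rec$labels
  )
}

#' Welch power spectral density
#'
#' Average of Hann-tapered, 50%-overlapping modified periodograms, computed
#' only on segments that lie fully inside the supplied epochs. One-sided
#' density normalization in uV^2/Hz: the PSD integrated across frequency
#' (times the bin width) recovers the signal variance.
#'
#' @param rec a [recording()]
#' @param epochs optional [epoch_set()]; `NULL` uses the whole recording
#' @param window segment length in seconds (default 2, giving 0.5 Hz
#'   resolution at 256 Hz)
#' @param overlap fractional segment overlap (default 0.5)
#' @return a `netsig_spectrum`: list with `freqs` (Hz), `psd`
#'   (channels x freqs matrix, uV^2/Hz), `n_segments`, `labels`
#' @export
welch_psd <- function(rec, epochs = NULL, window = 2, overlap = 0.5) {
  sf <- segment_ffts(rec, epochs, window, overlap)
  scale <- 2 / (sf$fs * sf$win_ss)
  pxx <- apply(abs(sf$Z)^2, c(1, 2), mean) * scale # nfreq x nch
  # one-sided: DC and Nyquist bins are not doubled
  pxx[1, ] <- pxx[1, ] / 2
  if (sf$nper %% 2 == 0) pxx[nrow(pxx), ] <- pxx[nrow(pxx), ] / 2
  structure(
    list(freqs = sf$freqs, psd = t(pxx), n_segments = sf$n_segments,
         labels = sf$labels, window = window, overlap = overlap, fs = sf$fs),
    class = "netsig_spectrum"
  )
}

#' @export
print.netsig_spectrum <- function(x, ...) {
  cat(sprintf("<netsig_spectrum> %d channels, %d bins (%.2g-%g Hz), %d segments\n",
              nrow(x$psd), length(x$freqs), min(x$freqs), max(x$freqs),
              x$n_segments))
  invisible(x)
}

trapz_band <- function(freqs, y, lo, hi) {
  idx <- which(freqs >= lo - 1e-9 & freqs <= hi + 1e-9)
  if (length(idx) < 2) {
    abort_netsig("Band contains fewer than two spectral bins.",
                 "netsig_parameter_error")
  }
  f <- freqs[idx]
  v <- y[idx]
  sum(diff(f) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Relative band power
#'
#' Band power is the trapezoidal integral of the PSD over the closed band;
#' the denominator is the integral over `total_range` (default 2-29 Hz, the
#' union span of the analysis bands). Global values are the unweighted mean
#' across channels.
#'
#' @param spec a `netsig_spectrum` from [welch_psd()]
#' @param bands band table as from [band_definitions()]
#' @param total_range length-2 numeric, denominator range in Hz
#' @return tibble with columns `channel` (labels plus `"GLOBAL"`), `band`,
#'   `rel_power`
#' @export
band_relative_power <- function(spec, bands = band_definitions(),
                                total_range = c(2, 29)) {
  stopifnot(inherits(spec, "netsig_spectrum"))
  if (min(bands$lo) < min(spec$freqs) || max(bands$hi) > max(spec$freqs)) {
    abort_netsig("Bands fall outside the spectrum range.", "netsig_parameter_error")
  }
  nch <- nrow(spec$psd)
  per <- purrr::map_dfr(seq_len(nch), function(ch) {
    total <- trapz_band(spec$freqs, spec$psd[ch, ], total_range[1], total_range[2])
    if (total <= 0) {
      abort_netsig("Zero total power in the denominator range.",
                   "netsig_undefined_ratio")
    }
    tibble::tibble(
      channel = spec$labels[ch],
      band = bands$band,
      rel_power = purrr::map2_dbl(bands$lo, bands$hi,
                                  ~ trapz_band(spec$freqs, spec$psd[ch, ], .x, .y)) / total
    )
  })
  glob <- per |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(rel_power = mean(.data$rel_power), .groups = "drop") |>
    dplyr::mutate(channel = "GLOBAL") |>
    dplyr::select("channel", "band", "rel_power")
  out <- dplyr::bind_rows(per, glob)
  out$band <- factor(out$band, levels = bands$band)
  out
}

#' Aperiodic (1/f) exponent and offset of the PSD
#'
#' Robust straight-line fit of log10(PSD) against log10(frequency) over
#' `fit_range`, excluding the alpha-peak window so the oscillatory bump does
#' not bias the broadband slope. After an ordinary least-squares start,
#' `robust_iters` rounds of Tukey bisquare re-weighting down-weight residual
#' peak bins. The slope is the spectral exponent (more negative = steeper
#' spectral decay), the intercept the offset in log10(uV^2/Hz).
#'
#' @param spec a `netsig_spectrum`
#' @param fit_range frequencies used for the fit, Hz
#' @param exclude open interval excluded from the fit (alpha peak +-0.5 Hz)
#' @param robust_iters bisquare re-weighting iterations (0 = plain OLS)
#' @return tibble with columns `channel` (labels plus `"GLOBAL"`),
#'   `exponent`, `offset`, `resid_rms`; the GLOBAL row is the channel mean
#' @export
fit_aperiodic <- function(spec, fit_range = c(2, 29), exclude = c(7.5, 12.5),
                          robust_iters = 3) {
  stopifnot(inherits(spec, "netsig_spectrum"))
  sel <- spec$freqs >= fit_range[1] - 1e-9 & spec$freqs <= fit_range[2] + 1e-9
  if (!is.null(exclude)) {
    sel <- sel & !(spec$freqs > exclude[1] & spec$freqs < exclude[2])
  }
  per <- purrr::map_dfr(seq_len(nrow(spec$psd)), function(ch) {
    p <- spec$psd[ch, ]
    use <- sel & p > 0
    if (sum(use) < 10) {
      abort_netsig("Fewer than 10 usable bins for the aperiodic fit.",
                   "netsig_fit_error")
    }
    lx <- log10(spec$freqs[use])
    ly <- log10(p[use])
    wts <- rep(1, length(lx))
    for (it in seq_len(robust_iters + 1)) {
      fit <- stats::lm.wfit(cbind(1, lx), ly, w = wts)
      if (it > robust_iters) break
      r <- ly - cbind(1, lx) %*% fit$coefficients
      s <- stats::mad(r)
      if (s < 1e-12) break # exact power law: residuals are numerically zero
      u <- abs(r / (4.685 * s))
      wts <- as.numeric(ifelse(u < 1, (1 - u^2)^2, 0))
      if (sum(wts > 0) < 10) break
    }
    res <- ly - cbind(1, lx) %*% fit$coefficients
    tibble::tibble(channel = spec$labels[ch],
                   exponent = unname(fit$coefficients[2]),
                   offset = unname(fit$coefficients[1]),
                   resid_rms = sqrt(mean(res^2)))
  })
  glob <- tibble::tibble(channel = "GLOBAL",
                         exponent = mean(per$exponent),
                         offset = mean(per$offset),
                         resid_rms = mean(per$resid_rms))
  dplyr::bind_rows(per, glob)
}
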