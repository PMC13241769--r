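#' Multichannel EEG recording container
#'
#' A `netsig_recording` holds a channels-by-samples numeric matrix in
#' microvolts together with the sampling rate and ordered channel labels
#' (10-20 convention for scalp EEG). All pipeline functions accept and return
#' this container so preprocessing steps compose.
#'
#' @param data numeric matrix, channels x samples, in uV
#' @param fs sampling rate in Hz (> 0)
#' @param labels character vector of unique channel names; defaults to
#'   `"ch1"..."chN"`
#' @param meta optional named list of provenance information
#' @return an object of class `netsig_recording`
#' @examples
#' rec <- recording(matrix(rnorm(512), 2, 256), fs = 256, labels = c("Fp1", "Fp2"))
#' n_channels(rec)
#' @export
recording <- function(data, fs, labels = NULL, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort_netsig("`data` must be a numeric channels x samples matrix.", "netsig_format_error")
  }
  if (nrow(data) < 2) {
    abort_netsig("A recording needs at least 2 channels.", "netsig_format_error")
  }
  if (!all(is.finite(data))) {
    abort_netsig("All samples must be finite.", "netsig_format_error")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort_netsig("`fs` must be a single positive sampling rate in Hz.", "netsig_parameter_error")
  }
  labels <- labels %||% paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) {
    abort_netsig("`labels` length must equal the number of channels.", "netsig_format_error")
  }
  if (anyDuplicated(labels)) {
    abort_netsig("Channel labels must be unique.", "netsig_format_error")
  }
  structure(
    list(data = unname(data), fs = as.numeric(fs), labels = as.character(labels), meta = meta),
    class = "netsig_recording"
  )
}

#' @export
print.netsig_recording <- function(x, ...) {
  cat(sprintf(
    "<netsig_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @rdname recording
#' @param rec a `netsig_recording`
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, the
#' standard common-average reference for scalp EEG. Idempotent: the channel
#' mean of the output is zero at every sample.
#'
#' @param rec a `netsig_recording`
#' @return a re-referenced `netsig_recording`
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "netsig_recording"))
  avg <- colMeans(rec$data)
  out <- rec
  out$data <- sweep(rec$data, 2, avg)
  out$meta$reference <- "common_average"
  out
}

#' Design a linear-phase FIR filter kernel
#'
#' Windowed-sinc (Hamming) band-pass combined, when requested, with a narrow
#' band-stop notch. Returns the composite impulse response (odd length, type-I
#' linear phase).
#' @noRd
design_fir <- function(fs, band = c(0.5, 70), notch = 50, notch_width = 4,
                       transition = 0.25) {
  nyq <- fs / 2
  if (!is.null(band)) {
    if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2]) {
      abort_netsig("Band edges must satisfy 0 < lo < hi < fs/2.", "netsig_parameter_error")
    }
  }
  # Hamming transition width ~ 3.3 / N (normalized); sized for the stated
  # transition at the high-pass edge.
  n_bp <- ceiling(3.3 / (transition / fs))
  if (n_bp %% 2 == 1) n_bp <- n_bp + 1 # even order -> odd length, type I
  h <- signal::fir1(n_bp, band / nyq, type = "pass", window = signal::hamming(n_bp + 1))
  if (!is.null(notch) && !is.na(notch)) {
    if (notch <= band[1] || notch >= band[2]) {
      abort_netsig("Notch frequency must lie inside the pass band.", "netsig_parameter_error")
    }
    stop_band <- c(notch - notch_width / 2, notch + notch_width / 2)
    n_nt <- ceiling(3.3 / (1 / fs))
    if (n_nt %% 2 == 1) n_nt <- n_nt + 1
    h_nt <- signal::fir1(n_nt, stop_band / nyq, type = "stop", window = signal::hamming(n_nt + 1))
    h <- stats::convolve(h, rev(h_nt), type = "open")
  }
  as.numeric(h)
}

#' Zero-phase FIR convolution (group-delay compensated)
#'
#' Odd-length linear-phase kernel applied by FFT convolution; the integer
#' group delay (L-1)/2 is removed so features are not shifted in time.
#' Signal edges are reflection-padded to limit transients.
#' @noRd
apply_fir_zero_phase <- function(x, h) {
  L <- length(h)
  gd <- (L - 1) / 2
  n <- length(x)
  pad <- min(gd, n - 1)
  # reflect (without repeating the end samples)
  xp <- c(2 * x[1] - rev(x[seq(2, pad + 1)]), x, 2 * x[n] - rev(x[seq(n - pad, n - 1)]))
  y <- stats::convolve(xp, rev(h), type = "open")
  y[(pad + gd + 1):(pad + gd + n)]
}

#' FIR band-pass and notch filtering
#'
#' Applies a linear-phase windowed-sinc (Hamming) FIR band-pass plus an
#' optional narrow FIR notch, with group-delay compensation so the output is
#' effectively zero-phase. Defaults follow standard clinical resting-EEG
#' preprocessing: 0.5-70 Hz band-pass and a 50 Hz mains notch (48-52 Hz stop
#' band).
#'
#' @param rec a `netsig_recording`
#' @param band length-2 numeric, pass band in Hz (inside (0, fs/2))
#' @param notch mains frequency in Hz, or `NULL` to disable
#' @param notch_width full width of the stop band in Hz
#' @return the filtered `netsig_recording`
#' @export
filter_recording <- function(rec, band = c(0.5, 70), notch = 50, notch_width = 4) {
  stopifnot(inherits(rec, "netsig_recording"))
  h <- design_fir(rec$fs, band = band, notch = notch, notch_width = notch_width)
  out <- rec
  out$data <- t(apply(rec$data, 1, apply_fir_zero_phase, h = h))
  out$meta$filter <- list(band = band, notch = notch, notch_width = notch_width,
                          n_taps = length(h))
  out
}

#' Epoch sets: contiguous artifact-free intervals
#'
#' An `netsig_epochs` object is a list of half-open, 0-based sample intervals
#' `[start, end)` into a recording, plus the total selected duration in
#' seconds. Intervals are non-overlapping and each is at least one spectral
#' analysis window (2 s) long.
#'
#' @param intervals integer matrix with columns `start`, `end` (half-open,
#'   0-based) or a list of length-2 vectors
#' @param fs sampling rate of the parent recording
#' @return a `netsig_epochs` object
#' @export
epoch_set <- function(intervals, fs) {
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  intervals <- matrix(as.numeric(intervals), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
  intervals <- intervals[order(intervals[, 1]), , drop = FALSE]
  if (any(intervals[, 2] <= intervals[, 1])) {
    abort_netsig("Epoch intervals must satisfy start < end.", "netsig_parameter_error")
  }
  if (nrow(intervals) > 1 &&
      any(intervals[-1, 1] < intervals[-nrow(intervals), 2])) {
    abort_netsig("Epoch intervals must not overlap.", "netsig_parameter_error")
  }
  if (any((intervals[, 2] - intervals[, 1]) < 2 * fs)) {
    abort_netsig("Each epoch must be at least one 2 s analysis window long.",
                 "netsig_parameter_error")
  }
  structure(
    list(intervals = intervals,
         total_duration = sum(intervals[, 2] - intervals[, 1]) / fs,
         fs = fs),
    class = "netsig_epochs"
  )
}

#' @export
print.netsig_epochs <- function(x, ...) {
  cat(sprintf("<netsig_epochs> %d interval(s), %.1f s total\n",
              nrow(x$intervals), x$total_duration))
  invisible(x)
}

#' Select analysis epochs from a recording
#'
#' Selects approximately `target` seconds of artifact-free signal. With no
#' exclusion mask the earliest samples are taken (deterministic default).
#' With a logical `keep_mask` (one value per sample, `FALSE` = excluded),
#' usable runs are accumulated in temporal order until the target is reached;
#' runs shorter than one 2 s analysis window are skipped.
#'
#' @param rec a `netsig_recording`
#' @param keep_mask optional logical vector of length `n_samples(rec)`
#' @param target target total duration in seconds
#' @param tol tolerance in seconds; total duration should land in
#'   `[target - tol, target + tol]`
#' @param strict if `TRUE`, raise an error when less than `target - tol`
#'   usable signal exists; otherwise return what is available with a warning
#' @return a `netsig_epochs` object
#' @export
select_epochs <- function(rec, keep_mask = NULL, target = 180, tol = 25,
                          strict = TRUE) {
  stopifnot(inherits(rec, "netsig_recording"))
  fs <- rec$fs
  n <- n_samples(rec)
  min_len <- 2 * fs
  target_n <- round(target * fs)
  if (is.null(keep_mask)) keep_mask <- rep(TRUE, n)
  if (length(keep_mask) != n) {
    abort_netsig("`keep_mask` must have one value per sample.", "netsig_parameter_error")
  }
  r <- rle(keep_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths # 0-based starts
  runs <- cbind(start = starts[r$values], end = ends[r$values])
  runs <- runs[(runs[, 2] - runs[, 1]) >= min_len, , drop = FALSE]
  picked <- list()
  got <- 0
  for (i in seq_len(nrow(runs))) {
    if (got >= target_n) break
    take <- min(runs[i, 2] - runs[i, 1], target_n - got)
    if (take < min_len) take <- runs[i, 2] - runs[i, 1] # keep whole short tail? no: skip
    if (take < min_len) next
    picked[[length(picked) + 1]] <- c(runs[i, 1], runs[i, 1] + take)
    got <- got + take
  }
  if (got < (target - tol) * fs) {
    msg <- sprintf("Only %.1f s usable signal; target was %g +/- %g s.",
                   got / fs, target, tol)
    if (strict) abort_netsig(msg, "netsig_insufficient_data")
    warn_netsig(msg, "netsig_short_epochs")
  }
  if (length(picked) == 0) {
    abort_netsig("No usable epochs found.", "netsig_insufficient_data")
  }
  epoch_set(picked, fs)
}

#' Extract the samples covered by an epoch set
#'
#' @param rec a `netsig_recording`
#' @param epochs a `netsig_epochs`; `NULL` selects the whole recording
#' @return list of channels x samples matrices, one per epoch interval
#' @export
epoch_data <- function(rec, epochs = NULL) {
  if (is.null(epochs)) {
    return(list(rec$data))
  }
  stopifnot(inherits(epochs, "netsig_epochs"))
  apply_rows <- seq_len(nrow(epochs$intervals))
  lapply(apply_rows, function(i) {
    s <- epochs$intervals[i, 1]
    e <- epochs$intervals[i, 2]
    if (e > n_samples(rec)) {
      abort_netsig("Epoch interval exceeds the recording length.", "netsig_parameter_error")
    }
    rec$data[, (s + 1):e, drop = FALSE]
  })
}
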