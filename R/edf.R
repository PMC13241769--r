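#' Read a multichannel EEG recording from an EDF/EDF+ file
#'
#' Minimal reader for the European Data Format: 256-byte fixed header,
#' per-signal header block, then 16-bit little-endian data records scaled by
#' the per-signal physical/digital calibration. Annotation channels
#' ("EDF Annotations") are dropped. All retained signals must share one
#' sampling rate.
#'
#' @param path path to an EDF/EDF+ file
#' @return a [recording()]
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) {
    abort_netsig(sprintf("File not found: %s", path), "netsig_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 256)
  if (length(hdr_raw) < 256) {
    abort_netsig("Truncated EDF header.", "netsig_format_error")
  }
  fld <- function(raw, from, len) {
    trimws(rawToChar(raw[from:(from + len - 1)]))
  }
  version <- fld(hdr_raw, 1, 8)
  n_records <- suppressWarnings(as.integer(fld(hdr_raw, 237, 8)))
  rec_dur <- suppressWarnings(as.numeric(fld(hdr_raw, 245, 8)))
  ns <- suppressWarnings(as.integer(fld(hdr_raw, 253, 4)))
  if (is.na(ns) || ns < 1 || is.na(n_records) || is.na(rec_dur) || rec_dur <= 0) {
    abort_netsig("Malformed EDF header.", "netsig_format_error")
  }
  sig_raw <- readBin(con, "raw", n = ns * 256)
  if (length(sig_raw) < ns * 256) {
    abort_netsig("Truncated EDF signal header.", "netsig_format_error")
  }
  # field layout (stored field-by-field across all ns signals):
  # label(16) transducer(80) dim(8) phys_min(8) phys_max(8)
  # dig_min(8) dig_max(8) prefilter(80) n_samp(8) reserved(32)
  labels <- vapply(seq_len(ns), function(i) {
    from <- (i - 1) * 16 + 1
    trimws(rawToChar(sig_raw[from:(from + 15)]))
  }, character(1))
  num_fld <- function(byte_offset, width = 8) {
    vapply(seq_len(ns), function(i) {
      from <- byte_offset * ns + (i - 1) * width + 1
      suppressWarnings(as.numeric(trimws(rawToChar(sig_raw[from:(from + width - 1)]))))
    }, numeric(1))
  }
  pmin <- num_fld(104)
  pmax <- num_fld(112)
  dmin <- num_fld(120)
  dmax <- num_fld(128)
  nsamp <- num_fld(216)
  if (any(is.na(c(pmin, pmax, dmin, dmax, nsamp))) || any(nsamp < 1) ||
      any(dmax <= dmin)) {
    abort_netsig("Malformed EDF signal header fields.", "netsig_format_error")
  }
  keep <- labels != "EDF Annotations"
  if (sum(keep) < 1) {
    abort_netsig("EDF file contains no signal channels.", "netsig_format_error")
  }
  fs_all <- nsamp[keep] / rec_dur
  if (length(unique(fs_all)) != 1) {
    abort_netsig("Signals with heterogeneous sampling rates are not supported.",
                 "netsig_unsupported_input")
  }
  total_per_rec <- sum(nsamp)
  vals <- readBin(con, "integer", n = n_records * total_per_rec, size = 2,
                  signed = TRUE, endian = "little")
  if (length(vals) < n_records * total_per_rec) {
    abort_netsig("Truncated EDF data records.", "netsig_format_error")
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  offs <- pmin - dmin * gain
  idx_end <- cumsum(nsamp)
  idx_start <- idx_end - nsamp + 1
  out <- matrix(NA_real_, nrow = sum(keep), ncol = n_records * nsamp[keep][1])
  row_i <- 0
  for (s in seq_len(ns)) {
    if (!keep[s]) next
    row_i <- row_i + 1
    block <- vapply(seq_len(n_records), function(r) {
      base <- (r - 1) * total_per_rec
      vals[(base + idx_start[s]):(base + idx_end[s])]
    }, numeric(nsamp[s]))
    out[row_i, ] <- as.numeric(block) * gain[s] + offs[s]
  }
  recording(out, fs = fs_all[1], labels = labels[keep],
            meta = list(source = path, format = "edf", version = version))
}

#' Write a recording to a minimal EDF file
#'
#' Companion writer used for round-trip tests and cohort export. Data are
#' quantized to the format's 16-bit range using a symmetric physical range
#' covering the observed amplitudes; the quantization step is
#' `2 * phys_max / 65535` uV. One-second data records are used when the
#' sample count divides evenly by `fs`, otherwise a single record holds the
#' whole recording.
#'
#' @param rec a [recording()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "netsig_recording"))
  nc <- n_channels(rec)
  ns <- n_samples(rec)
  fs <- rec$fs
  if (ns %% fs == 0 && fs == round(fs)) {
    n_records <- ns / fs
    rec_dur <- 1
    nsamp <- fs
  } else {
    n_records <- 1
    rec_dur <- ns / fs
    nsamp <- ns
  }
  pmax <- max(1e-6, max(abs(rec$data)))
  dmax <- 32767
  dmin <- -32767 # symmetric digital range so the calibration offset is zero
  gain <- (2 * pmax) / (dmax - dmin)
  dig <- round(rec$data / gain)
  dig[dig > dmax] <- dmax
  dig[dig < dmin] <- dmin
  pad <- function(x, width) {
    x <- substr(as.character(x), 1, width)
    formatC(x, width = width, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("netsig synthetic", 80), pad("netsig export", 80),
    pad("01.01.26", 8), pad("09.00.00", 8), pad(256 + nc * 256, 8), pad("", 44),
    pad(n_records, 8), pad(format(rec_dur, digits = 7), 8), pad(nc, 4)
  ), con, eos = NULL)
  sig_field <- function(values, width) {
    writeChar(paste(vapply(values, pad, character(1), width = width),
                    collapse = ""), con, eos = NULL)
  }
  sig_field(rec$labels, 16)
  sig_field(rep("", nc), 80)
  sig_field(rep("uV", nc), 8)
  sig_field(rep(format(-pmax, digits = 7), nc), 8)
  sig_field(rep(format(pmax, digits = 7), nc), 8)
  sig_field(rep(dmin, nc), 8)
  sig_field(rep(dmax, nc), 8)
  sig_field(rep("", nc), 80)
  sig_field(rep(nsamp, nc), 8)
  sig_field(rep("", nc), 32)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * nsamp + 1):(r * nsamp)
    for (ch in seq_len(nc)) {
      writeBin(as.integer(dig[ch, cols]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
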