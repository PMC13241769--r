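#' Segment-wise cross-spectra
#'
#' Hann-tapered FFT outer products on the same segmentation as [welch_psd()]
#' (2 s windows, 50% overlap, segments confined to epochs). The heavy
#' n_segments x channels x channels x freqs tensor is not materialized;
#' per-segment channel FFTs are stored and pair products formed on demand
#' (see [cs_tensor()] for the explicit tensor on small problems).
#'
#' @param rec a [recording()]
#' @param epochs optional [epoch_set()]
#' @param window,overlap Welch segmentation parameters
#' @return a `netsig_cross_spectra` object
#' @export
cross_spectra <- function(rec, epochs = NULL, window = 2, overlap = 0.5) {
  sf <- segment_ffts(rec, epochs, window, overlap)
  sf$scale <- 2 / (sf$fs * sf$win_ss)
  class(sf) <- "netsig_cross_spectra"
  sf
}

#' @export
print.netsig_cross_spectra <- function(x, ...) {
  cat(sprintf("<netsig_cross_spectra> %d channels, %d bins, %d segments\n",
              dim(x$Z)[2], dim(x$Z)[1], x$n_segments))
  invisible(x)
}

#' Materialize the cross-spectral tensor
#'
#' Explicit `[segment, i, j, freq]` complex tensor
#' `S_ij = scale * Z_i * Conj(Z_j)`; Hermitian in (i, j) with the
#' per-segment periodogram on the diagonal. Intended for small validation
#' problems - memory grows as segments x channels^2 x freqs.
#'
#' @param cs a `netsig_cross_spectra`
#' @return complex array `[n_segments, n_channels, n_channels, n_freqs]`
#' @export
cs_tensor <- function(cs) {
  stopifnot(inherits(cs, "netsig_cross_spectra"))
  d <- dim(cs$Z) # nfreq x nch x nseg
  out <- array(complex(real = 0), dim = c(d[3], d[2], d[2], d[1]))
  for (s in seq_len(d[3])) {
    for (f in seq_len(d[1])) {
      z <- cs$Z[f, , s]
      out[s, , , f] <- cs$scale * (z %o% Conj(z))
    }
  }
  out
}

#' Weighted phase lag index
#'
#' For every frequency bin k in a band and channel pair (i, j):
#' `wPLI_k = |mean_s Im(S_ij)| / mean_s |Im(S_ij)|` across segments s, with
#' 0/0 defined as 0; the band value is the unweighted mean across the band's
#' bins. The imaginary cross-spectrum vanishes for zero-lag (volume
#' conducted) coupling, which is why wPLI is used for scalp EEG. A debiased
#' squared variant is available behind `debias`.
#'
#' @param cs a `netsig_cross_spectra` from [cross_spectra()]
#' @param bands band table as from [band_definitions()], or a single row
#' @param debias if `TRUE`, compute the debiased squared wPLI estimator
#' @return a `netsig_connectivity`: list of symmetric channels x channels
#'   matrices in `[0,1]` (diagonal 0), one per band
#' @export
wpli <- function(cs, bands = band_definitions(), debias = FALSE) {
  stopifnot(inherits(cs, "netsig_cross_spectra"))
  if (cs$n_segments < 2) {
    abort_netsig("wPLI needs at least 2 segments.", "netsig_estimator_error")
  }
  nch <- dim(cs$Z)[2]
  mats <- vector("list", nrow(bands))
  names(mats) <- bands$band
  for (b in seq_len(nrow(bands))) {
    bins <- which(cs$freqs >= bands$lo[b] - 1e-9 & cs$freqs <= bands$hi[b] + 1e-9)
    if (length(bins) == 0) {
      abort_netsig("Band has no spectral bins.", "netsig_parameter_error")
    }
    acc <- matrix(0, nch, nch)
    for (k in bins) {
      Zk <- t(cs$Z[k, , ]) # nseg x nch
      X <- Re(Zk); Y <- Im(Zk)
      # Im(z_i conj(z_j)) summed over segments = (Y'X - X'Y)_{ij}
      num_s <- crossprod(Y, X)
      num <- num_s - t(num_s)
      den <- matrix(0, nch, nch)
      sq <- matrix(0, nch, nch)
      for (s in seq_len(nrow(Zk))) {
        I <- tcrossprod(Y[s, ], X[s, ]) - tcrossprod(X[s, ], Y[s, ])
        den <- den + abs(I)
        if (debias) sq <- sq + I^2
      }
      if (debias) {
        numer <- num^2 - sq
        denom <- den^2 - sq
        v <- ifelse(denom > 0, numer / denom, 0)
        v[v < 0] <- 0
      } else {
        v <- ifelse(den > 0, abs(num) / den, 0)
      }
      acc <- acc + v
    }
    m <- acc / length(bins)
    m <- (m + t(m)) / 2 # enforce exact symmetry
    diag(m) <- 0
    dimnames(m) <- list(cs$labels, cs$labels)
    mats[[b]] <- m
  }
  structure(list(bands = mats, band_table = bands, n_segments = cs$n_segments,
                 debias = debias),
            class = "netsig_connectivity")
}

#' @export
print.netsig_connectivity <- function(x, ...) {
  g <- global_wpli(x)
  cat("<netsig_connectivity> global wPLI:",
      paste(sprintf("%s=%.3f", names(g), g), collapse = ", "), "\n")
  invisible(x)
}

#' Global connectivity per band
#'
#' Mean of the strictly-upper-triangle entries of each band's wPLI matrix
#' (equivalent, up to a constant factor, to averaging per-channel node
#' strengths).
#'
#' @param cm a `netsig_connectivity`
#' @return named numeric vector, one value per band
#' @export
global_wpli <- function(cm) {
  stopifnot(inherits(cm, "netsig_connectivity"))
  vapply(cm$bands, function(m) mean(m[upper.tri(m)]), numeric(1))
}
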