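# Independent brute-force oracles used to validate the package's
# implementations on small instances. These deliberately share no code with
# the package internals.

# --- graph oracles (adjacency matrix in, scalars out) ------------------------

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    d <- length(nb)
    if (d < 2) {
      cc[i] <- 0
    } else {
      links <- 0
      for (a in seq_along(nb)) {
        for (b in seq_len(a - 1)) {
          links <- links + A[nb[a], nb[b]]
        }
      }
      cc[i] <- links / (d * (d - 1) / 2)
    }
  }
  list(per_node = cc, C = mean(cc))
}

oracle_lambda <- function(A) {
  D <- oracle_distances(A)
  v <- D[upper.tri(D)]
  v <- v[is.finite(v) & v > 0]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

oracle_ge <- function(A) {
  D <- oracle_distances(A)
  v <- D[upper.tri(D)]
  mean(ifelse(is.finite(v) & v > 0, 1 / v, 0))
}

# path-counting betweenness via recursive enumeration of all geodesics
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  btw <- numeric(n)
  # count geodesics from s to t passing through v (v != s, t)
  n_paths <- function(s, t) {
    if (s == t) return(1)
    if (!is.finite(D[s, t])) return(0)
    tot <- 0
    for (w in which(A[s, ] == 1)) {
      if (D[w, t] == D[s, t] - 1) tot <- tot + n_paths(w, t)
    }
    tot
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      tot <- n_paths(s, t)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          btw[v] <- btw[v] + n_paths(s, v) * n_paths(v, t) / tot
        }
      }
    }
  }
  norm <- (n - 1) * (n - 2) / 2
  list(per_node = btw / norm, BtwC = mean(btw / norm))
}

oracle_modularity <- function(A, membership) {
  m <- sum(A) / 2
  deg <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_c <- sum(A[idx, idx]) / 2
    d_c <- sum(deg[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# --- wPLI oracle from raw tapered FFTs ---------------------------------------

# direct evaluation of the defining ratio from a recording's raw segments
oracle_wpli <- function(rec, lo, hi, window = 2, overlap = 0.5) {
  fs <- rec$fs
  nper <- round(window * fs)
  step <- round(nper * (1 - overlap))
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nper - 1) / nper))
  starts <- seq(1, ncol(rec$data) - nper + 1, by = step)
  nch <- nrow(rec$data)
  freqs <- seq(0, nper %/% 2) * fs / nper
  bins <- which(freqs >= lo & freqs <= hi)
  out <- matrix(0, nch, nch)
  for (i in seq_len(nch - 1)) {
    for (j in (i + 1):nch) {
      acc <- 0
      for (k in bins) {
        ims <- vapply(starts, function(s) {
          zi <- fft(rec$data[i, s:(s + nper - 1)] * w)[k]
          zj <- fft(rec$data[j, s:(s + nper - 1)] * w)[k]
          Im(zi * Conj(zj))
        }, numeric(1))
        num <- abs(mean(ims))
        den <- mean(abs(ims))
        acc <- acc + if (den > 0) num / den else 0
      }
      out[i, j] <- out[j, i] <- acc / length(bins)
    }
  }
  out
}

# --- split-plot ANOVA sums of squares from first principles ------------------

oracle_splitplot <- function(d) {
  # d: subject, group, band, value; balanced cell structure assumed
  gm <- mean(d$value)
  k <- length(unique(d$band))
  subj_mean <- tapply(d$value, d$subject, mean)
  subj_group <- tapply(as.character(d$group), d$subject, function(v) v[1])
  grp_mean <- tapply(d$value, d$group, mean)
  band_mean <- tapply(d$value, d$band, mean)
  cell_mean <- tapply(d$value, list(d$group, d$band), mean)
  n_g <- table(subj_group)
  ss_group <- k * sum(n_g * (grp_mean[names(n_g)] - gm)^2)
  ss_subj_within <- k * sum((subj_mean - grp_mean[subj_group])^2)
  n_tot <- length(subj_mean)
  ss_band <- n_tot * sum((band_mean - gm)^2)
  ss_int <- 0
  for (g in rownames(cell_mean)) {
    for (b in colnames(cell_mean)) {
      ss_int <- ss_int + n_g[[g]] *
        (cell_mean[g, b] - grp_mean[[g]] - band_mean[[b]] + gm)^2
    }
  }
  ss_tot <- sum((d$value - gm)^2)
  ss_err <- ss_tot - ss_group - ss_subj_within - ss_band - ss_int
  g_lev <- length(unique(d$group))
  df <- list(group = g_lev - 1, subj = n_tot - g_lev, band = k - 1,
             int = (g_lev - 1) * (k - 1), err = (n_tot - g_lev) * (k - 1))
  list(
    F_group = (ss_group / df$group) / (ss_subj_within / df$subj),
    F_band = (ss_band / df$band) / (ss_err / df$err),
    F_int = (ss_int / df$int) / (ss_err / df$err),
    ss = c(group = ss_group, subj = ss_subj_within, band = ss_band,
           int = ss_int, err = ss_err, total = ss_tot)
  )
}

# --- misc --------------------------------------------------------------------

# analytic-signal instantaneous phase (Hilbert via FFT)
oracle_phase <- function(v) {
  n <- length(v)
  H <- rep(0, n)
  H[1] <- 1
  H[2:(n %/% 2)] <- 2
  H[n %/% 2 + 1] <- 1
  Arg(fft(fft(v) * H, inverse = TRUE) / n)
}
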