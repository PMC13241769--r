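test_that("Welch PSD satisfies Parseval and white-noise density checks", {
  fs <- 256
  t <- seq(0, 180 - 1 / fs, by = 1 / fs)
  set.seed(11)
  rec <- recording(rbind(sin(2 * pi * 10 * t), rnorm(length(t), sd = 2)), fs)
  sp <- welch_psd(rec)
  df <- sp$freqs[2] - sp$freqs[1]
  expect_equal(sp$freqs[which.max(sp$psd[1, ])], 10)
  expect_equal(sum(sp$psd[1, ]) * df, 0.5, tolerance = 0.02) # sinusoid variance
  flat <- mean(sp$psd[2, sp$freqs > 5 & sp$freqs < 100])
  expect_equal(flat, 4 / (fs / 2), tolerance = 0.05) # sigma^2 / (fs/2)
  zero <- welch_psd(recording(matrix(0, 2, 2048), fs))
  expect_true(all(zero$psd == 0))
  expect_error(welch_psd(recording(matrix(rnorm(2 * 100), 2), fs)),
               class = "netsig_insufficient_data")
})

test_that("PSD scales quadratically and relative power is scale-invariant", {
  fs <- 256
  set.seed(12)
  rec <- recording(matrix(rnorm(2 * 60 * fs), 2), fs)
  rec3 <- rec
  rec3$data <- 3 * rec$data
  sp1 <- welch_psd(rec)
  sp3 <- welch_psd(rec3)
  expect_equal(sp3$psd, 9 * sp1$psd, tolerance = 1e-12)
  expect_equal(band_relative_power(sp1), band_relative_power(sp3),
               tolerance = 1e-12)
})

test_that("relative band power isolates narrowband content", {
  fs <- 256
  t <- seq(0, 180 - 1 / fs, by = 1 / fs)
  pure <- recording(rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t)), fs)
  bp <- band_relative_power(welch_psd(pure))
  ch1 <- bp[bp$channel == "ch1", ]
  expect_gte(ch1$rel_power[ch1$band == "alpha"], 0.95)
  expect_true(all(ch1$rel_power[ch1$band != "alpha"] <= 0.02))
  # equal-amplitude 3 Hz + 10 Hz: alpha/delta ratio = 1
  two <- recording(rbind(sin(2 * pi * 3 * t) + sin(2 * pi * 10 * t),
                         sin(2 * pi * 3 * t) + sin(2 * pi * 10 * t)), fs)
  bp2 <- band_relative_power(welch_psd(two))
  ch <- bp2[bp2$channel == "ch1", ]
  expect_equal(ch$rel_power[ch$band == "alpha"] / ch$rel_power[ch$band == "delta"],
               1, tolerance = 0.05)
  # GLOBAL rows are channel means
  glob <- bp2[bp2$channel == "GLOBAL", ]
  per <- bp2[bp2$channel != "GLOBAL", ]
  expect_equal(glob$rel_power,
               tapply(per$rel_power, per$band, mean)[as.character(glob$band)],
               ignore_attr = TRUE)
  # zero power in the denominator range -> undefined ratio
  hf <- welch_psd(recording(rbind(sin(2 * pi * 60 * t), sin(2 * pi * 60 * t)), fs))
  hf$psd[, hf$freqs >= 2 & hf$freqs <= 29] <- 0
  expect_error(band_relative_power(hf), class = "netsig_undefined_ratio")
})

test_that("aperiodic fit is exact on noiseless power laws", {
  freqs <- seq(0, 128, by = 0.5)
  psd <- rbind(10^(-1) * pmax(freqs, 0.25)^(-2), rep(3, length(freqs)))
  spec <- structure(list(freqs = freqs, psd = psd, n_segments = 1,
                         labels = c("pl", "flat"), window = 2, overlap = 0.5,
                         fs = 256), class = "netsig_spectrum")
  fit <- fit_aperiodic(spec)
  expect_equal(fit$exponent[1], -2, tolerance = 1e-6)
  expect_equal(fit$offset[1], -1, tolerance = 1e-6)
  expect_equal(fit$exponent[2], 0, tolerance = 1e-6)
  expect_lt(fit$resid_rms[1], 1e-9)
})

test_that("alpha exclusion protects the exponent from oscillatory peaks", {
  fs <- 256
  ap <- gen_aperiodic_noise(-1.5, 1, 120, fs, 21)
  osc <- gen_oscillation(10, 2, 2 * sqrt(mean(ap^2)), 120, fs, 22)
  rec <- recording(rbind(ap, ap + osc), fs, labels = c("plain", "peaked"))
  fit <- fit_aperiodic(welch_psd(rec))
  expect_lt(abs(fit$exponent[2] - fit$exponent[1]), 0.1)
})

test_that("steeper exponents match steeper spectral decay ratios", {
  freqs <- seq(0, 128, by = 0.5)
  chis <- c(-0.5, -1, -2, -3)
  psd <- do.call(rbind, lapply(chis, function(ch) pmax(freqs, 0.25)^ch))
  spec <- structure(list(freqs = freqs, psd = psd, n_segments = 1,
                         labels = paste0("c", seq_along(chis)), window = 2,
                         overlap = 0.5, fs = 256), class = "netsig_spectrum")
  fit <- fit_aperiodic(spec)
  decay <- psd[, freqs == 29] / psd[, freqs == 2]
  expect_equal(order(fit$exponent[seq_along(chis)]), order(decay))
})

test_that("welch segments never straddle epoch boundaries", {
  fs <- 256
  set.seed(31)
  rec <- recording(matrix(rnorm(2 * 20 * fs), 2), fs)
  ep <- epoch_set(list(c(0, 5 * fs), c(10 * fs, 15 * fs)), fs)
  sp <- welch_psd(rec, ep)
  # 5 s epochs with 2 s windows, 1 s step: 4 segments each
  expect_equal(sp$n_segments, 8)
})
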