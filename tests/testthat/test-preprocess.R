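make_rec <- function(eeg, veog = NULL, heog = NULL, fs = 250) {
  n <- ncol(eeg)
  labels <- eeg_montage()[seq_len(nrow(eeg))]
  if (is.null(veog)) veog <- numeric(n)
  if (is.null(heog)) heog <- numeric(n)
  # pad unused montage rows so the channel set is always the full montage
  full <- matrix(stats::rnorm(length(eeg_montage()) * n, sd = 1e-3),
                 length(eeg_montage()), n)
  full[seq_len(nrow(eeg)), ] <- eeg
  recording("s1", fs, rbind(full, veog, heog),
            c(eeg_montage(), eog_labels()))
}

test_that("EOG regression recovers a known propagation coefficient", {
  set.seed(7)
  n <- 5000
  veog <- as.numeric(stats::arima.sim(list(ar = 0.95), n))
  heog <- as.numeric(stats::arima.sim(list(ar = 0.95), n))
  clean <- matrix(stats::rnorm(2 * n), 2, n)
  contaminated <- clean +
    rbind(0.30 * veog + 0.10 * heog, 0.05 * veog - 0.20 * heog)
  rec <- make_rec(contaminated, veog, heog)
  out <- correct_eog(rec)
  # the removed component must match the least-squares oracle fitted on the
  # construction (EOG terms only; the mean is preserved)
  oracle <- stats::coef(stats::lm(contaminated[1, ] ~ veog + heog))
  expect_lt(max(abs(
    out$samples["Fp1", ] -
      (contaminated[1, ] - oracle[["veog"]] * veog - oracle[["heog"]] * heog)
  )) / stats::sd(clean[1, ]), 1e-8)
  recovered_beta <- stats::coef(stats::lm(
    (contaminated[1, ] - out$samples["Fp1", ]) ~ veog + heog))
  expect_lt(abs(recovered_beta[["veog"]] - oracle[["veog"]]) /
              oracle[["veog"]], 0.01)
  # and the oracle itself sits close to the planted coefficient
  expect_lt(abs(oracle[["veog"]] - 0.30) / 0.30, 0.05)
  # EOG channels pass through unmodified
  expect_identical(out$samples["VEOG", ], rec$samples["VEOG", ])
  # channel count and order preserved
  expect_identical(out$channel_labels, rec$channel_labels)
})

test_that("zero EOG channels leave the EEG unchanged and missing EOG errors", {
  rec <- make_rec(matrix(stats::rnorm(2 * 1000), 2, 1000))
  out <- correct_eog(rec)
  expect_equal(out$samples, rec$samples)
  no_eog <- recording("s1", 250, matrix(0, 29, 500), eeg_montage())
  expect_error(correct_eog(no_eog), "VEOG")
})

test_that("epoching counts, rejection and baseline correction follow the rule", {
  fs <- 250
  rec <- make_rec(matrix(stats::rnorm(29 * 120 * fs, sd = 30), 29, 120 * fs),
                  fs = fs)
  ep <- epoch_and_reject(rec, preprocess_config())
  expect_equal(dim(ep$data), c(60, 29, 2 * fs))   # 120 s / 2 s epochs
  # a 30 uV RMS Gaussian exceeds 150 uV (5 sigma) only very rarely
  expect_lt(sum(ep$rejected_mask), 10)
  # plant excursions in epochs 3, 17, 40
  rec2 <- rec
  for (e in c(3, 17, 40)) rec2$samples["Cz", (e - 1) * 500 + 10] <- 400
  ep2 <- epoch_and_reject(rec2, preprocess_config())
  expect_true(all(ep2$rejected_mask[c(3, 17, 40)]))
  expect_identical(ep2$rejected_mask[-c(3, 17, 40)],
                   ep$rejected_mask[-c(3, 17, 40)])
  # retained epochs are baseline-corrected: zero mean per channel
  expect_lt(max(abs(apply(ep$data, c(1, 2), mean))), 1e-9)
  # all-rejected input is an explicit error
  hot <- make_rec(matrix(500, 2, 1000))
  expect_error(epoch_and_reject(hot, preprocess_config()), "all epochs rejected")
})

test_that("decimation preserves the dominant frequency and sample bookkeeping", {
  fs <- 1000
  t <- seq_len(20 * fs) / fs
  x <- matrix(rep(30 * sin(2 * pi * 10 * t), each = 29), 29, byrow = FALSE)
  x <- x + stats::rnorm(length(x))
  rec <- make_rec(x[, seq_len(20 * fs)], fs = fs)
  cfg <- preprocess_config()
  ep <- epoch_and_reject(rec, cfg)
  dn <- downsample_epochs(ep, cfg)
  expect_equal(dim(dn$data)[3], 500)        # 2000 samples / factor 4
  expect_equal(dn$fs, 250)
  spec <- Mod(stats::fft(dn$data[1, 1, ]))[2:250]
  freqs <- (1:249) * 250 / 500
  expect_equal(freqs[which.max(spec)], 10)  # FFT peak survives decimation
  bad <- preprocess_config(target_fs = 300)
  expect_error(downsample_epochs(ep, bad), "integer multiple")
})

test_that("ten retained epochs give the 5000-sample analysis segment", {
  spec <- tiny_cohort_spec(n_patients = 1, n_controls = 0, duration = 24,
                           fs = 1000)
  rec <- generate_cohort(spec)$recordings[[1]]
  eps <- preprocess_recording(rec, preprocess_config(), bands = "alpha")
  expect_equal(dim(eps$alpha$data), c(10, 29, 500))
  expect_equal(prod(dim(eps$alpha$data)[c(1, 3)]), 5000)
})

test_that("band filters pass their band and stop the others", {
  fs <- 250
  cfg <- preprocess_config()
  t <- seq_len(20 * fs) / fs
  sine10 <- matrix(rep(sin(2 * pi * 10 * t), each = 2), 2, byrow = FALSE)
  rec <- make_rec(sine10, fs = fs)
  ep <- epoch_and_reject(rec, preprocess_config(epoch_seconds = 20))
  mid <- 1000:4000
  rms <- function(v) sqrt(mean(v^2))
  alpha <- bandpass_epochs(ep, "alpha", cfg)
  expect_lt(abs(rms(alpha$data[1, 1, mid]) / rms(ep$data[1, 1, mid]) - 1),
            0.05)
  expect_equal(alpha$band, "alpha")
  delta <- bandpass_epochs(ep, "delta", cfg)
  expect_lt(rms(delta$data[1, 1, mid]) / rms(ep$data[1, 1, mid]), 0.10)
  # all five bands are available per subject
  expect_named(cfg$bands, c("delta", "theta", "alpha", "beta", "gamma"))
  # Nyquist violation is an error
  slow <- epoch_and_reject(make_rec(sine10[, 1:400], fs = 80),
                           preprocess_config(epoch_seconds = 5))
  expect_error(bandpass_epochs(slow, "gamma", cfg), "Nyquist")
  expect_error(bandpass_epochs(ep, "mu", cfg), "unknown band")
})

test_that("band filtering is nearly idempotent in-band", {
  fs <- 250
  cfg <- preprocess_config()
  set.seed(2)
  x <- matrix(stats::rnorm(2 * 20 * fs), 2, 20 * fs)
  ep <- epoch_and_reject(make_rec(x, fs = fs),
                         preprocess_config(epoch_seconds = 20))
  once <- bandpass_epochs(ep, "alpha", cfg)
  twice <- bandpass_epochs(once, "alpha", cfg)
  # compare spectral power strictly inside the band (9-11 Hz): a second
  # pass may only reshape the filter's own roll-off at the 8/12 Hz edges
  inband_rms <- function(v) {
    n <- length(v)
    f <- (seq_len(n) - 1) * fs / n
    sqrt(sum(Mod(stats::fft(v))[f >= 9 & f <= 11]^2)) / n
  }
  r1 <- inband_rms(once$data[1, 1, ])
  r2 <- inband_rms(twice$data[1, 1, ])
  expect_lt(abs(r2 / r1 - 1), 0.01)
})

test_that("epoch selection keeps the first clean epochs in order", {
  data <- array(stats::rnorm(20 * 2 * 100), c(20, 2, 100))
  ep <- slnet:::new_epoch_set(data, 250, c("Cz", "Pz"),
                              rejected_mask = rep(FALSE, 20))
  sel <- select_epochs(ep, 10)
  expect_equal(sel$data, data[1:10, , , drop = FALSE])
  ep$rejected_mask[c(2, 5)] <- TRUE
  sel2 <- select_epochs(ep, 10)
  expect_equal(sel2$data, data[c(1, 3, 4, 6:12), , , drop = FALSE])
  ep$rejected_mask[1:15] <- TRUE
  expect_error(select_epochs(ep, 10), "5 artifact-free")
})
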