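test_that("Welch grid has 0.5 Hz resolution with 2 s segments", {
  x <- rnorm(20000)
  psd <- welch_psd(x, fs = 2000)
  expect_equal(diff(psd$freq)[1], 0.5)
  psd2 <- welch_psd(rnorm(80000), fs = 20000)
  expect_equal(diff(psd2$freq)[1], 0.5)
  expect_error(welch_psd(rnorm(100), fs = 2000), "shorter")
})

test_that("pure tones and noise produce the expected spectra", {
  fs <- 1000
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 20 * t)
  psd <- welch_psd(x, fs)
  expect_equal(psd$freq[which.max(psd$power)], 20)
  # white noise: flat spectrum; with ~39 averaged segments the per-bin
  # power is tightly concentrated around the common level, and the lower
  # and upper halves of the band carry equal mean power
  set.seed(2)
  pn <- welch_psd(rnorm(fs * 40), fs)
  p <- pn$power[pn$freq > 5 & pn$freq < 495]
  expect_lt(sd(p) / mean(p), 0.5)
  lo <- mean(p[seq_len(length(p) %/% 2)])
  hi <- mean(p[-seq_len(length(p) %/% 2)])
  expect_equal(lo / hi, 1, tolerance = 0.05)
})

test_that("population PSD averages per-cell spectra", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  tr <- cbind(sin(2 * pi * 15 * t), sin(2 * pi * 15 * t + 1))
  psd <- population_psd(tr, fs)
  expect_s3_class(psd, "stngpe_psd")
  expect_equal(dominant_frequency(psd, c(5, 30)), 15)
  one <- welch_psd(tr[, 1], fs)
  expect_equal(psd$power[psd$freq == 15],
               (one$power[one$freq == 15] +
                  welch_psd(tr[, 2], fs)$power[one$freq == 15]) / 2)
})

test_that("dominant frequency and band power read the right bins", {
  psd <- structure(list(freq = seq(0, 100, by = 0.5),
                        power = rep(1, 201)), class = "stngpe_psd")
  psd$power[psd$freq == 21] <- 10
  expect_equal(dominant_frequency(psd), 21)
  expect_true(dominant_frequency(psd) >= 13 && dominant_frequency(psd) <= 30)
  expect_gt(band_power(psd, 21, 5), band_power(psd, 40, 5))
})

test_that("instantaneous phase advances linearly for a sinusoid", {
  fs <- 1000
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  x <- 3 * sin(2 * pi * 18 * t)
  ph <- instantaneous_phase(x, fs, center = 18)
  sel <- ph$t > 1000 & ph$t < 5000  # avoid filter edges
  slope <- unname(coef(lm(ph$phase[sel] ~ ph$t[sel]))[2])  # rad per ms
  expect_equal(slope * 1000 / (2 * pi), 18, tolerance = 0.01)
  # amplitude scaling leaves phase unchanged
  ph2 <- instantaneous_phase(10 * x, fs, center = 18)
  expect_equal(ph$phase[sel], ph2$phase[sel], tolerance = 1e-6)
  # two sinusoids 90 degrees apart keep a constant difference
  y <- sin(2 * pi * 18 * t + pi / 2)
  phy <- instantaneous_phase(y, fs, center = 18)
  d <- (phy$phase[sel] - ph$phase[sel]) * 180 / pi
  expect_equal(mean(d), 90, tolerance = 1)
  expect_lt(sd(d), 2)
  expect_error(instantaneous_phase(x, fs, center = 3), "band")
})

test_that("phase vectors recover construction and the uniform null", {
  fs <- 1000
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  ph <- instantaneous_phase(sin(2 * pi * 20 * t), fs, center = 20)
  # all spikes at a fixed phase: per-cell and population length 1
  cycles <- seq(500, 7500, by = 50)
  locked <- phase_vectors(list(cycles, cycles + 50), ph)
  expect_gt(min(locked$length), 0.99)
  expect_gt(locked$pop_length, 0.99)
  # uniform spikes: expected resultant ~ sqrt(pi / (4 n))
  set.seed(4)
  n <- 400
  unif <- lapply(1:30, function(i) sort(runif(n, 500, 7500)))
  u <- phase_vectors(unif, ph)
  expect_lt(u$pop_length, 0.2)
  expect_equal(mean(u$length), sqrt(pi / (4 * n)), tolerance = 0.4)
  # commanded 45 degree offset appears in the population angle
  base <- phase_vectors(list(cycles), ph)
  shift <- phase_vectors(list(cycles + 45 / 360 * 50), ph)
  expect_equal(circular_diff(shift$pop_angle, base$pop_angle), 45,
               tolerance = 3)
  # cells below the spike threshold are excluded and counted
  mixed <- phase_vectors(list(cycles, cycles[1:3]), ph)
  expect_equal(mixed$n_excluded, 1L)
})

test_that("phase pipeline recovers von-Mises resultant lengths", {
  fs <- 1000
  f <- 18
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  ph <- instantaneous_phase(sin(2 * pi * f * t), fs, center = f)
  set.seed(9)
  for (kappa in c(0.5, 2, 8)) {
    trains <- lapply(1:50, function(i) {
      th <- rvonmises(100, mu = 0, kappa = kappa) %% (2 * pi)
      cyc <- sample(20:(f * 58), 100, replace = TRUE)
      sort((cyc + th / (2 * pi)) * 1000 / f)
    })
    vec <- phase_vectors(trains, ph)
    expected <- besselI(kappa, 1) / besselI(kappa, 0)
    expect_equal(mean(vec$length), expected, tolerance = 0.025,
                 label = paste("kappa", kappa))
  }
})

test_that("burst detection follows the ISI and count definition", {
  b <- detect_bursts(seq(0, 40, by = 10))
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_spikes, 5L)
  expect_equal(b$intra_rate, 100)
  # the 20 ms bound is inclusive
  b20 <- detect_bursts(seq(0, 60, by = 20))
  expect_equal(nrow(b20), 1L)
  expect_equal(b20$n_spikes, 4L)
  # three spikes never form a burst
  expect_equal(nrow(detect_bursts(c(0, 5, 10))), 0L)
  # bursts separated by long gaps are independent; extra sparse spikes
  # between bursts do not change detections
  train <- c(seq(0, 30, 10), 200, seq(400, 430, 10))
  b2 <- detect_bursts(train)
  expect_equal(nrow(b2), 2L)
  expect_equal(b2, detect_bursts(sort(c(train, 100, 300))))
})

test_that("rate and CV metrics handle periodic, Poisson and sparse trains", {
  expect_equal(rate_and_cv(list(seq(0, 3999, by = 50)), 4000)$rate, 20)
  expect_equal(rate_and_cv(list(seq(0, 1000, by = 10)), 1000)$cv_isi, 0)
  set.seed(5)
  pois <- poisson_trains(1, 30, 2e5)[[1]]
  expect_equal(rate_and_cv(list(pois), 2e5)$cv_isi, 1, tolerance = 0.05)
  expect_true(is.na(rate_and_cv(list(c(1, 2)), 100)$cv_isi))
  # 80 spikes in 4000 ms is 20 Hz
  expect_equal(rate_and_cv(list(seq_len(80) * 10), 4000)$rate, 20)
})

test_that("burst metrics summarize per-cell distributions", {
  trains <- list(seq(0, 30, 10), seq(0, 990, 100))  # one burster, one tonic
  m <- burst_metrics(trains, window = 1000)
  expect_equal(sort(m$per_cell$burst_rate), c(0, 1))
  expect_equal(m$per_cell$intra_rate[1], 100)
})

test_that("pseudo-voltage conversion embeds spikes as waveforms", {
  pv <- pseudo_voltage(list(numeric(0)), duration = 100, dt = 0.05)
  expect_true(all(pv == 0))
  one <- pseudo_voltage(list(50), duration = 100, dt = 0.05)
  w <- ap_waveform(0.05)
  expect_equal(max(one), max(w))
  expect_equal(which.max(one[, 1]), 1000 + which.max(w))
  # periodic 20 Hz train has its PSD peak at 20 Hz
  train <- list(seq(0, 3950, by = 50))
  tr <- pseudo_voltage(train, duration = 4000, dt = 0.5)
  psd <- welch_psd(tr[, 1] - mean(tr[, 1]), fs = 2000)
  expect_equal(dominant_frequency(psd, c(5, 35)), 20)
  # phase results are insensitive to the template choice
  fs <- 1000
  alt <- ifelse(seq(0, 2, by = 1 / fs * 1000) <= 1, 50, -5)
  for (wf in list(ap_waveform(1), alt)) {
    tr2 <- pseudo_voltage(train, duration = 4000, dt = 1, waveform = wf)
    ph <- instantaneous_phase(tr2[, 1], fs = 1000, center = 20)
    slope <- unname(coef(lm(ph$phase[1000:3000] ~ ph$t[1000:3000]))[2])
    expect_equal(slope * 1000 / (2 * pi), 20, tolerance = 0.02)
  }
})
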