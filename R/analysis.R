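#' Signal analyses for network records
#'
#' Population spectra (Welch), instantaneous beta phase (zero-phase
#' Butterworth band-pass + analytic signal), spike phase-locking vectors,
#' burst detection, rate/regularity metrics, and the pseudo-voltage
#' conversion that lets generator populations enter the same phase pipeline.
#'
#' @name analysis
NULL

#' Welch power spectral density
#'
#' Overlapping 2 s Hann-windowed segments with 50% overlap, averaged over
#' segments; at any sampling rate the 2 s segment length gives a 0.5 Hz
#' frequency resolution. Each trace is de-meaned per segment.
#'
#' @param x numeric vector (a single trace).
#' @param fs sampling rate, Hz.
#' @param segment_s segment length, seconds (default 2).
#' @return list with `freq` (Hz) and `power` (density units).
#' @export
welch_psd <- function(x, fs, segment_s = 2) {
  nper <- round(segment_s * fs)
  if (length(x) < nper)
    stop("trace shorter than one Welch segment (", segment_s, " s)")
  step <- nper %/% 2
  nseg <- 1 + (length(x) - nper) %/% step
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))  # Hann
  scale <- fs * sum(w^2)
  nf <- nper %/% 2 + 1
  acc <- numeric(nf)
  for (s in seq_len(nseg)) {
    seg <- x[(s - 1) * step + seq_len(nper)]
    seg <- (seg - mean(seg)) * w
    sp <- stats::fft(seg)[seq_len(nf)]
    p <- Mod(sp)^2 / scale
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
    acc <- acc + p
  }
  list(freq = seq(0, fs / 2, length.out = nf), power = acc / nseg)
}

#' Population PSD: mean Welch PSD over somatic voltage traces
#'
#' @param traces matrix, one column per cell.
#' @param fs sampling rate, Hz.
#' @param segment_s Welch segment length, seconds.
#' @return list with `freq` and `power` (mean over cells), class
#'   `stngpe_psd`.
#' @export
population_psd <- function(traces, fs, segment_s = 2) {
  traces <- as.matrix(traces)
  psds <- apply(traces, 2, welch_psd, fs = fs, segment_s = segment_s,
                simplify = FALSE)
  structure(list(freq = psds[[1]]$freq,
                 power = rowMeans(vapply(psds, `[[`, psds[[1]]$power,
                                         "power"))),
            class = "stngpe_psd")
}

#' @export
plot.stngpe_psd <- function(x, fmax = 60, ...) {
  sel <- x$freq <= fmax & x$freq > 0
  plot(x$freq[sel], x$power[sel], type = "l", xlab = "frequency (Hz)",
       ylab = "power density", ...)
  invisible(x)
}

#' Frequency of maximum power within a band
#' @param psd a `stngpe_psd` (or list with freq/power).
#' @param band numeric length-2 band, Hz (default beta, 13-30 Hz).
#' @return frequency of the maximal bin strictly inside the band, Hz.
#' @export
dominant_frequency <- function(psd, band = c(13, 30)) {
  sel <- which(psd$freq >= band[1] & psd$freq <= band[2])
  psd$freq[sel[which.max(psd$power[sel])]]
}

#' Power-weighted mean frequency within a band
#'
#' The spectral centroid of the band: a more stable estimator of where the
#' band's power is concentrated than the argmax bin at short record lengths.
#' @param psd a `stngpe_psd`.
#' @param band numeric length-2 band, Hz.
#' @return weighted mean frequency, Hz.
#' @export
spectral_centroid <- function(psd, band = c(13, 30)) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  sum(psd$freq[sel] * psd$power[sel]) / sum(psd$power[sel])
}

#' Band power around a centre frequency
#' @param psd a `stngpe_psd`.
#' @param center centre frequency, Hz.
#' @param width full band width, Hz (default 5).
#' @return mean power density over the band.
#' @export
band_power <- function(psd, center, width = 5) {
  sel <- psd$freq >= center - width / 2 & psd$freq <= center + width / 2
  mean(psd$power[sel])
}

# analytic signal via FFT (Marple construction)
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a reference trace
#'
#' Band-pass filters the trace with a zero-phase (forward-backward) 4th-order
#' Butterworth filter in an 8 Hz band around `center`, then takes the
#' analytic-signal angle. To keep the normalized band well-conditioned the
#' trace is first decimated to about 1 kHz.
#'
#' @param x reference trace (e.g. population mean voltage).
#' @param fs sampling rate of `x`, Hz.
#' @param center band centre, Hz; must exceed half the band width.
#' @param width band width, Hz (default 8).
#' @return list with `phase` (unwrapped, radians), `t` (ms), `fs_out`.
#' @export
instantaneous_phase <- function(x, fs, center, width = 8) {
  if (center - width / 2 <= 0) stop("band centre too low for the band width")
  dec <- max(1L, floor(fs / 1000))
  if (dec > 1L) {
    x <- signal::decimate(x, dec)
    fs <- fs / dec
  }
  if (length(x) < 3 * fs / center)
    stop("trace too short to resolve the band centre")
  bf <- signal::butter(4, c(center - width / 2, center + width / 2) / (fs / 2),
                       type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))
  ph <- Arg(.analytic_signal(xf))
  dph <- diff(ph)
  dph <- dph - 2 * pi * round(dph / (2 * pi))
  list(phase = cumsum(c(ph[1], dph)), t = (seq_along(xf) - 1) * 1000 / fs,
       fs_out = fs)
}

#' Spike phase-locking vectors
#'
#' Maps each spike to the reference phase at its time, computes per-cell mean
#' resultant vectors of the unit phasors, and the population vector as the
#' vector mean of the per-cell vectors (cells first, then population, so
#' strongly locked sparse cells are not swamped by dense ones). Cells with
#' fewer than `min_spikes` spikes are excluded and counted.
#'
#' @param trains list of spike-time vectors, ms (same time base as `phase$t`).
#' @param phase result of [instantaneous_phase()].
#' @param min_spikes exclusion threshold (default 5).
#' @return object of class `phase_vectors`: per-cell `length`/`angle`
#'   (degrees), population `pop_length`/`pop_angle`, `n_excluded`.
#' @export
phase_vectors <- function(trains, phase, min_spikes = 5L) {
  t0 <- phase$t[1]; t1 <- phase$t[length(phase$t)]
  per_cell <- lapply(trains, function(sp) {
    sp <- sp[sp >= t0 & sp <= t1]
    if (length(sp) < min_spikes) return(NULL)
    ph <- stats::approx(phase$t, phase$phase, xout = sp)$y
    mean(exp(1i * ph))
  })
  keep <- !vapply(per_cell, is.null, TRUE)
  z <- unlist(per_cell[keep])
  if (!length(z)) stop("no cell passed the minimum-spike criterion")
  pop <- mean(z)
  structure(list(length = Mod(z), angle = (Arg(z) * 180 / pi) %% 360,
                 pop_length = Mod(pop),
                 pop_angle = (Arg(pop) * 180 / pi) %% 360,
                 n_cells = sum(keep), n_excluded = sum(!keep)),
            class = "phase_vectors")
}

#' @export
print.phase_vectors <- function(x, ...) {
  cat(sprintf("<phase_vectors> %d cells (%d excluded): population length %.3f, angle %.1f deg\n",
              x$n_cells, x$n_excluded, x$pop_length, x$pop_angle))
  invisible(x)
}

#' Circular difference between two angles
#' @param a,b angles in degrees.
#' @return signed difference `a - b` wrapped to (-180, 180].
#' @export
circular_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Detect bursts in a spike train
#'
#' A burst is a maximal run of at least `min_spikes` spikes whose
#' inter-spike intervals are all `<= max_isi` (boundary inclusive).
#'
#' @param spikes sorted spike times, ms.
#' @param max_isi ISI bound, ms (default 20).
#' @param min_spikes minimum spikes per burst (default 4).
#' @return data frame with one row per burst: `start`, `n_spikes`,
#'   `duration` (ms), `intra_rate` (Hz).
#' @export
detect_bursts <- function(spikes, max_isi = 20, min_spikes = 4L) {
  n <- length(spikes)
  empty <- data.frame(start = numeric(0), n_spikes = integer(0),
                      duration = numeric(0), intra_rate = numeric(0))
  if (n < min_spikes) return(empty)
  short <- diff(spikes) <= max_isi
  r <- rle(short)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rows <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < min_spikes - 1L) next
    i1 <- starts[i]; i2 <- ends[i] + 1L  # spike indices
    dur <- spikes[i2] - spikes[i1]
    k <- i2 - i1 + 1L
    rows[[length(rows) + 1]] <- data.frame(
      start = spikes[i1], n_spikes = k, duration = dur,
      intra_rate = (k - 1) / dur * 1000)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Burst metrics across a population
#'
#' @param trains list of spike-time vectors, ms.
#' @param window analysis window length, ms (for burst rate).
#' @return list with population medians of per-cell burst rate (bursts/s),
#'   intra-burst rate (Hz) and CV of ISIs, plus the per-cell table.
#' @export
burst_metrics <- function(trains, window) {
  per_cell <- do.call(rbind, lapply(seq_along(trains), function(i) {
    sp <- trains[[i]]
    b <- detect_bursts(sp)
    isi <- diff(sp)
    data.frame(cell = i,
               burst_rate = nrow(b) / (window / 1000),
               intra_rate = if (nrow(b)) stats::median(b$intra_rate) else NA,
               cv_isi = if (length(isi) >= 2)
                 stats::sd(isi) / mean(isi) else NA)
  }))
  list(median_burst_rate = stats::median(per_cell$burst_rate, na.rm = TRUE),
       median_intra_rate = stats::median(per_cell$intra_rate, na.rm = TRUE),
       median_cv_isi = stats::median(per_cell$cv_isi, na.rm = TRUE),
       per_cell = per_cell)
}

#' Mean rate and ISI coefficient of variation per cell
#'
#' @param trains list of spike-time vectors, ms.
#' @param window window length, ms.
#' @return data frame with `rate` (Hz) and `cv_isi` (NA below 3 spikes).
#' @export
rate_and_cv <- function(trains, window) {
  do.call(rbind, lapply(seq_along(trains), function(i) {
    sp <- trains[[i]]
    isi <- diff(sp)
    data.frame(cell = i, rate = length(sp) / (window / 1000),
               cv_isi = if (length(sp) >= 3) stats::sd(isi) / mean(isi)
                        else NA_real_)
  }))
}

#' Default action-potential template for pseudo-voltage traces
#'
#' A 2 ms biphasic waveform: 1 ms depolarizing lobe (+100 mV peak) and 1 ms
#' after-hyperpolarization (-20 mV). Phase results are insensitive to the
#' template choice (tested); it only matters that spikes become finite-width
#' pulses.
#' @param dt sampling period, ms.
#' @return numeric waveform.
#' @export
ap_waveform <- function(dt = 0.05) {
  t <- seq(0, 2, by = dt)
  ifelse(t <= 1, 100 * sin(pi * t), -20 * sin(pi * (t - 1)))
}

#' Convolve spike trains with an action-potential waveform
#'
#' Produces voltage-like traces so generator populations (cortex, striatum)
#' can be analysed with the same spectral and phase pipeline as biophysical
#' cells.
#'
#' @param trains list of spike-time vectors, ms.
#' @param duration trace length, ms.
#' @param dt sampling period, ms.
#' @param waveform template sampled at `dt` (default [ap_waveform()]).
#' @return matrix, one column per train.
#' @export
pseudo_voltage <- function(trains, duration, dt = 0.05,
                           waveform = ap_waveform(dt)) {
  n <- ceiling(duration / dt)
  out <- matrix(0, n, length(trains))
  lw <- length(waveform)
  for (j in seq_along(trains)) {
    for (sp in trains[[j]]) {
      i0 <- floor(sp / dt) + 1L
      idx <- i0:min(i0 + lw - 1L, n)
      if (i0 > n || i0 < 1) next
      out[idx, j] <- out[idx, j] + waveform[seq_along(idx)]
    }
  }
  out
}

#' Summarize a simulation's oscillation and firing metrics
#'
#' One-call analysis used by the experiment runners: population PSDs,
#' dominant beta frequency of the reference population, instantaneous phase,
#' phase vectors for STN and GPe, rates and burst metrics.
#'
#' @param sim a `stngpe_sim`.
#' @param reference population whose trace defines the instantaneous phase
#'   (default `"GPe"`).
#' @param center optional band centre, Hz; defaults to the reference
#'   population's 13-30 Hz PSD argmax (use the input frequency when an
#'   exogenous oscillation is applied).
#' @param segment_s Welch segment length, s.
#' @return list of analysis results.
#' @export
analyze_sim <- function(sim, reference = "GPe", center = NULL,
                        segment_s = 2) {
  res <- list()
  for (p in c("STN", "GPe")) {
    res$psd[[p]] <- population_psd(
      sim$v_soma[, sim$cellpop == p, drop = FALSE], sim$fs,
      segment_s = segment_s)
    res$rates[[p]] <- population_rates(sim, p)
    res$bursts[[p]] <- burst_metrics(sim$spikes[sim$cellpop == p],
                                     sim$duration)
  }
  if (is.null(center)) center <- dominant_frequency(res$psd[[reference]])
  res$center <- center
  ref_trace <- population_trace(sim, reference)
  res$phase <- tryCatch(instantaneous_phase(ref_trace, sim$fs, center),
                        error = function(e) NULL)
  if (!is.null(res$phase)) {
    for (p in c("STN", "GPe"))
      res$vectors[[p]] <- tryCatch(
        phase_vectors(sim$spikes[sim$cellpop == p], res$phase),
        error = function(e) NULL)
  }
  res
}
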