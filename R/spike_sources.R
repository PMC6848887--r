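#' Surrogate spike-train generation
#'
#' Cortical and striatal afferent populations, and a fraction of the STN and
#' GPe populations themselves, are represented by statistically specified
#' spike generators rather than biophysical cells: homogeneous Poisson
#' processes for the non-oscillatory condition, and an oscillatory-bursting
#' process for synchronous beta-band input.
#'
#' The oscillatory process works per cycle of a regular oscillation at
#' `osc_frequency`: in every cycle a fresh random subset of
#' `round(burst_fraction * population_size)` generators emits a burst with a
#' common onset time, a variable spike count, and intra-burst inter-spike
#' intervals drawn uniformly from `intraburst_isi_range`. Background Poisson
#' spikes falling inside a deletion window centred on each burst are removed
#' so the train does not carry implausibly short intervals next to the burst.
#'
#' @name spike_sources
NULL

#' Homogeneous Poisson spike trains
#'
#' @param n number of independent trains.
#' @param rate mean rate, Hz (>= 0).
#' @param duration train length, ms.
#' @param seed optional integer seed (uses the current RNG stream if NULL).
#' @return list of numeric vectors of spike times in ms, sorted.
#' @export
poisson_trains <- function(n, rate, duration, seed = NULL) {
  stopifnot(rate >= 0, duration > 0, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(rep(list(numeric(0)), n))
  lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, rate * duration / 1000)
    sort(stats::runif(k, 0, duration))
  })
}

#' Oscillatory-bursting spike-train specification
#'
#' @param population_size number of generators.
#' @param background_rate Poisson background rate, Hz.
#' @param osc_frequency oscillation frequency, Hz (> 0).
#' @param burst_fraction fraction of generators bursting per cycle, in (0, 1].
#' @param intraburst_isi_range ms interval the intra-burst ISIs are drawn
#'   from.
#' @param spikes_per_burst integer range of spikes per burst.
#' @param deletion_window width in ms of the background-deletion window
#'   centred on the burst midpoint; default 1.5 x the maximal burst duration.
#' @param onset_jitter_sd per-burst jitter (ms) applied to onset and spike
#'   times; 0 disables it.
#' @return object of class `osc_burst_spec`.
#' @export
osc_burst_spec <- function(population_size, background_rate = 10,
                           osc_frequency = 20, burst_fraction = 0.1,
                           intraburst_isi_range = c(5, 6),
                           spikes_per_burst = c(4L, 7L),
                           deletion_window = NULL, onset_jitter_sd = 0) {
  stopifnot(burst_fraction > 0, burst_fraction <= 1, osc_frequency > 0,
            diff(intraburst_isi_range) >= 0, spikes_per_burst[1] >= 2)
  max_burst <- (spikes_per_burst[2] - 1) * intraburst_isi_range[2]
  if (is.null(deletion_window)) deletion_window <- 1.5 * max_burst
  structure(list(population_size = population_size,
                 background_rate = background_rate,
                 osc_frequency = osc_frequency,
                 burst_fraction = burst_fraction,
                 intraburst_isi_range = intraburst_isi_range,
                 spikes_per_burst = as.integer(spikes_per_burst),
                 deletion_window = deletion_window,
                 onset_jitter_sd = onset_jitter_sd),
            class = "osc_burst_spec")
}

#' Generate oscillatory-bursting spike trains
#'
#' @param spec an [osc_burst_spec()].
#' @param duration ms.
#' @param seed optional integer seed.
#' @param offset_ms shift of burst onsets relative to the oscillation's
#'   zero-phase instants, ms (used by [phase_offset_trains()]).
#' @return list of spike-time vectors (ms, sorted), one per generator.
#' @export
oscillatory_burst_trains <- function(spec, duration, seed = NULL,
                                     offset_ms = 0) {
  stopifnot(inherits(spec, "osc_burst_spec"))
  if (!is.null(seed)) set.seed(seed)
  period <- 1000 / spec$osc_frequency
  max_burst <- (spec$spikes_per_burst[2] - 1) * spec$intraburst_isi_range[2]
  if (period < max_burst)
    stop("oscillation period (", round(period, 2),
         " ms) is shorter than the maximal burst duration (", max_burst,
         " ms); reduce spikes_per_burst")
  n <- spec$population_size
  trains <- poisson_trains(n, spec$background_rate, duration)
  n_burst <- round(spec$burst_fraction * n)
  onsets <- seq(0, duration, by = period) + offset_ms
  onsets <- onsets[onsets >= 0 & onsets < duration]
  for (on in onsets) {
    sel <- sample.int(n, n_burst)
    jit_on <- if (spec$onset_jitter_sd > 0)
      stats::rnorm(1, 0, spec$onset_jitter_sd) else 0
    for (cell in sel) {
      k <- sample(seq(spec$spikes_per_burst[1], spec$spikes_per_burst[2]), 1)
      isis <- stats::runif(k - 1, spec$intraburst_isi_range[1],
                           spec$intraburst_isi_range[2])
      spk <- on + jit_on + c(0, cumsum(isis))
      if (spec$onset_jitter_sd > 0)
        spk <- spk + stats::rnorm(k, 0, spec$onset_jitter_sd)
      burst_mid <- on + (spk[k] - spk[1]) / 2
      keep <- abs(trains[[cell]] - burst_mid) > spec$deletion_window / 2
      trains[[cell]] <- sort(c(trains[[cell]][keep],
                               spk[spk >= 0 & spk < duration]))
    }
  }
  trains
}

#' Oscillatory trains with a commanded phase offset
#'
#' Identical generative process to [oscillatory_burst_trains()] with burst
#' onsets delayed by `offset_degrees / 360` of the oscillation period
#' relative to the reference oscillation's zero phase.
#'
#' @inheritParams oscillatory_burst_trains
#' @param offset_degrees phase offset in `[0, 360)`.
#' @export
phase_offset_trains <- function(spec, duration, offset_degrees, seed = NULL) {
  stopifnot(offset_degrees >= 0, offset_degrees < 360)
  offset_ms <- offset_degrees / 360 * 1000 / spec$osc_frequency
  oscillatory_burst_trains(spec, duration, seed = seed, offset_ms = offset_ms)
}

#' Pooled empirical rate of a set of spike trains
#' @param trains list of spike-time vectors, ms.
#' @param duration ms.
#' @return mean rate per train, Hz.
#' @export
pooled_rate <- function(trains, duration) {
  sum(lengths(trains)) / length(trains) / (duration / 1000)
}

#' Write spike trains as a two-column text file
#'
#' Plain-text `cell_id time_ms` rows, one per spike.
#' @param trains list of spike-time vectors.
#' @param path output file.
#' @export
write_spike_trains <- function(trains, path) {
  ids <- rep(seq_along(trains), lengths(trains))
  utils::write.table(data.frame(cell_id = ids, time_ms = unlist(trains)),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike trains written by [write_spike_trains()]
#' @param path file path.
#' @param n number of trains (defaults to the maximum cell id present).
#' @return list of spike-time vectors.
#' @export
read_spike_trains <- function(path, n = NULL) {
  tab <- utils::read.table(path, header = TRUE)
  if (is.null(n)) n <- max(tab$cell_id)
  out <- rep(list(numeric(0)), n)
  sp <- split(tab$time_ms, factor(tab$cell_id, levels = seq_len(n)))
  for (i in seq_len(n)) out[[i]] <- sort(sp[[i]])
  out
}
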