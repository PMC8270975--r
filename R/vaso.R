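#' Average bandpower of a baseline trace
#'
#' Power of the mean-removed signal within a frequency band, computed from a
#' rectangular-window periodogram: the per-ordinate one-sided powers
#' `2 |X_k|^2 / N^2` are summed over ordinates falling in `[band1, band2]`
#' Hz. For a pure in-band sinusoid of amplitude `A` this converges to the
#' mean-square power `A^2 / 2`. Used on the baseline of percent-change
#' diameter traces to quantify spontaneous vasomotion (default band
#' 0.02-1 Hz).
#'
#' @param x Numeric vector (a baseline segment), uniformly sampled.
#' @param fs Sampling rate in Hz; must exceed twice the upper band edge.
#' @param band Length-2 numeric band in Hz (default `c(0.02, 1)`).
#' @return Band power (squared signal units).
#' @export
bandpower <- function(x, fs, band = c(0.02, 1)) {
  stopifnot(is.numeric(x), length(x) >= 4)
  if (fs <= 2 * band[2])
    stop("sampling rate too low to resolve the band", call. = FALSE)
  x <- x - mean(x)
  n <- length(x)
  X <- stats::fft(x)
  k <- seq_len(floor(n / 2))  # positive-frequency ordinates
  f <- k / n * fs
  pow <- 2 * Mod(X[k + 1])^2 / n^2
  if (n %% 2 == 0) pow[length(pow)] <- pow[length(pow)] / 2  # Nyquist once
  sum(pow[f >= band[1] & f <= band[2]])
}

#' Zero-phase lowpass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth lowpass with unit DC
#' gain. The contract is defined by its pass/stop behaviour: a passband
#' sinusoid well below the cutoff is preserved, and attenuation at twice the
#' cutoff exceeds 20 dB.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (default 0.2); must be below Nyquist.
#' @return Filtered vector, same length.
#' @export
lowpass <- function(x, fs, cutoff = 0.2) {
  if (cutoff >= fs / 2)
    stop("`cutoff` must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  n <- length(x)
  # mean removal + odd-reflection padding suppress the filter's edge
  # transients; a constant trace passes through exactly unchanged
  mu <- mean(x)
  x <- x - mu
  np <- min(n - 1, ceiling(10 * fs / cutoff))
  xp <- c(2 * x[1] - x[np:1 + 1], x, 2 * x[n] - x[n - seq_len(np)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[np + seq_len(n)] + mu
}

#' Classify the vasomotion phase at stimulus onset
#'
#' The percent-change trace is lowpass filtered (0.2 Hz) and inspected in a
#' 2.5 s window ending at stimulus onset — a quarter cycle at the ~0.1 Hz
#' vasomotion frequency. The trial is classified by whether the filtered
#' window mean lies above or below the mean of the filtered baseline, and
#' whether the filtered trace is ascending or descending across the window:
#' above/ascending = 1, above/descending = 2, below/descending = 3,
#' below/ascending = 4. Exact ties go to the lower phase number and are
#' flagged.
#'
#' @param trace A percent-change [trial_trace()] (or tibble with `time_s`,
#'   `value` plus `stim_onset` given explicitly).
#' @param stim_onset Stimulus onset in seconds; defaults to the trace's.
#' @param window_s Length of the pre-stimulus window (default 2.5 s).
#' @param cutoff Lowpass cutoff in Hz (default 0.2).
#' @param baseline_mean `"filtered"` (default) compares against the mean of
#'   the filtered baseline; `"raw"` uses the unfiltered baseline mean.
#' @return A one-row tibble: `phase` (integer 1-4), `above`, `ascending`,
#'   `tie` (flag).
#' @export
classify_phase <- function(trace, stim_onset = NULL, window_s = 2.5,
                           cutoff = 0.2,
                           baseline_mean = c("filtered", "raw")) {
  baseline_mean <- match.arg(baseline_mean)
  stopifnot(is.data.frame(trace))
  if (is.null(stim_onset)) {
    if (!inherits(trace, "nvc_trace"))
      stop("`stim_onset` required for plain tibbles", call. = FALSE)
    stim_onset <- trace_meta(trace)$stim_onset
  }
  t <- trace$time_s
  fs <- 1 / mean(diff(t))
  if (stim_onset - window_s < t[1] - 1e-9)
    stop("incomplete pre-stimulus window: need ", window_s,
         " s before stimulus onset", call. = FALSE)
  v <- trace_fill(trace$value, t)
  base_idx <- t < stim_onset - 1e-9
  filt <- lowpass(v[base_idx], fs, cutoff)
  tb <- t[base_idx]
  win <- tb >= stim_onset - window_s - 1e-9
  ref <- if (baseline_mean == "filtered") mean(filt) else mean(v[base_idx])
  wmean <- mean(filt[win])
  trend <- filt[win][sum(win)] - filt[win][1]
  tie <- wmean == ref || trend == 0
  above <- wmean > ref || (wmean == ref)  # tie resolved toward lower phase
  ascending <- trend > 0 || (trend == 0 && above)
  # mapping: 1 above/asc, 2 above/desc, 3 below/desc, 4 below/asc
  phase <- if (above && ascending) 1L else if (above) 2L else
    if (!ascending) 3L else 4L
  tibble::tibble(phase = phase, above = above, ascending = ascending,
                 tie = tie)
}

#' Vasomotion profile of a trial
#'
#' Convenience wrapper combining baseline [bandpower()] (0.02-1 Hz, on the
#' percent-change baseline) with [classify_phase()].
#'
#' @param trace A percent-change [trial_trace()].
#' @param band Bandpower band in Hz.
#' @param cutoff Lowpass cutoff for phase classification.
#' @return One-row tibble: `bandpower`, `phase`, `tie`.
#' @export
vasomotion_profile <- function(trace, band = c(0.02, 1), cutoff = 0.2) {
  stopifnot(inherits(trace, "nvc_trace"))
  fs <- 1 / trace_dt(trace)
  bp <- bandpower(baseline_values(trace), fs, band)
  ph <- classify_phase(trace, cutoff = cutoff)
  tibble::tibble(bandpower = bp, phase = ph$phase, tie = ph$tie)
}

#' Correlate vasomotion power with response metrics
#'
#' Pearson correlation between per-trial baseline bandpower and a matched
#' response metric (amplitude or onset), with the sample size and the
#' correlation test p-value.
#'
#' @param bandpower Numeric vector of per-trial band powers.
#' @param response Matched numeric vector of response metrics.
#' @return One-row tibble: `r`, `n`, `p_value`.
#' @export
power_response_correlation <- function(bandpower, response) {
  stopifnot(length(bandpower) == length(response))
  ok <- is.finite(bandpower) & is.finite(response)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(bandpower[ok]) == 0 || stats::sd(response[ok]) == 0)
    stop("zero variance in one of the vectors", call. = FALSE)
  ct <- stats::cor.test(bandpower[ok], response[ok])
  tibble::tibble(r = unname(ct$estimate), n = n, p_value = ct$p.value)
}
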