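#' Baseline-subtracted signal (delta-F)
#'
#' Subtracts the mean of the baseline window from the whole trace:
#' `dF = F - F0`, with `F0` the baseline mean. Missing samples are excluded
#' from the baseline statistic and left missing in the output.
#'
#' @param trace A [trial_trace()].
#' @return A trace of the same class with centred values.
#' @export
delta_f <- function(trace) {
  stopifnot(inherits(trace, "nvc_trace"))
  f0 <- mean(baseline_values(trace))
  trace_update(trace, trace$value - f0)
}

#' Percent change from baseline
#'
#' `100 * (F - F0) / F0` with `F0` the baseline mean. The baseline mean must
#' be non-zero: a zero baseline signals an unusable trace (e.g. an empty
#' measurement), and the function errors rather than emitting NaN.
#'
#' @param trace A [trial_trace()].
#' @return A trace in percent-change units.
#' @export
percent_change <- function(trace) {
  stopifnot(inherits(trace, "nvc_trace"))
  f0 <- mean(baseline_values(trace))
  if (abs(f0) < .Machine$double.eps * 100)
    stop("baseline mean is zero; percent change undefined", call. = FALSE)
  trace_update(trace, 100 * (trace$value - f0) / f0)
}

#' Baseline z-score of a single trial
#'
#' `z(t) = (F(t) - mean_baseline) / sd_baseline`, with the sample SD
#' (`n - 1` denominator) of the baseline window. Normalizing each trial by
#' its own baseline SD down-weights trials with large spontaneous vasomotion
#' before averaging. Requires at least two baseline samples with non-zero SD.
#'
#' @param trace A [trial_trace()].
#' @return A `nvc_ztrace` (a trace whose values are z units) carrying
#'   `baseline_mean` and `baseline_sd` attributes.
#' @export
zscore_trial <- function(trace) {
  stopifnot(inherits(trace, "nvc_trace"))
  b <- baseline_values(trace)
  if (length(b) < 2)
    stop("baseline needs at least 2 samples to z-score", call. = FALSE)
  s <- stats::sd(b)
  if (s == 0)
    stop("baseline SD is zero; flat trace cannot be z-scored", call. = FALSE)
  m <- mean(b)
  trace_update(trace, (trace$value - m) / s, class = "nvc_ztrace",
               baseline_mean = m, baseline_sd = s)
}

#' Average trials pointwise
#'
#' Pointwise mean and SEM (`sd / sqrt(n)`) across trials sharing a time base
#' and stimulus timing. Missing samples are linearly interpolated per trial
#' before averaging.
#'
#' @param trials List of traces (typically z-scored) on a common time base.
#' @return A trace of pointwise means carrying a `sem` column alongside
#'   `time_s` and `value`, plus the shared metadata.
#' @export
average_trials <- function(trials) {
  stopifnot(is.list(trials), length(trials) >= 1)
  t0 <- trials[[1]]$time_s
  for (tr in trials) {
    if (length(tr$time_s) != length(t0) || max(abs(tr$time_s - t0)) > 1e-9)
      stop("trials must share the same time base", call. = FALSE)
    m1 <- trace_meta(trials[[1]]); m2 <- trace_meta(tr)
    if (abs(m1$stim_onset - m2$stim_onset) > 1e-9 ||
        abs(m1$stim_duration - m2$stim_duration) > 1e-9)
      stop("trials must share stimulus timing", call. = FALSE)
  }
  vals <- vapply(trials, function(tr) trace_fill(tr$value, tr$time_s),
                 numeric(length(t0)))
  vals <- matrix(vals, nrow = length(t0))
  n <- length(trials)
  mu <- rowMeans(vals)
  sem <- if (n > 1) apply(vals, 1, stats::sd) / sqrt(n) else rep(0, length(t0))
  out <- trace_update(trials[[1]], mu)
  out$sem <- sem
  attr(out, "n_trials") <- n
  out
}

# per-trial response amplitude: max of the (filled) trace inside the window
trial_amplitude <- function(trace, window = NULL) {
  if (is.null(window)) window <- response_window(trace)
  v <- trace_fill(trace$value, trace$time_s)
  idx <- trace$time_s >= window[1] - 1e-9 & trace$time_s < window[2] + 1e-9
  if (!any(idx)) stop("response window contains no samples", call. = FALSE)
  max(v[idx])
}

#' Inter-trial variability of response amplitudes
#'
#' The response amplitude of each trial is the maximum of its trace within
#' the response window (stimulus onset to offset + 2 s by default); the
#' statistic is the sample SD of these amplitudes across trials.
#'
#' @param trials List of at least two traces (typically z-scored).
#' @param response_window Length-2 numeric window in seconds; default from
#'   the first trial's stimulus timing.
#' @return A one-row tibble: `sd_amplitude`, `mean_amplitude`, `n`.
#' @export
intertrial_variability <- function(trials, response_window = NULL) {
  stopifnot(is.list(trials))
  if (length(trials) < 2)
    stop("need at least 2 trials to measure variability", call. = FALSE)
  amps <- vapply(trials, trial_amplitude, numeric(1), window = response_window)
  tibble::tibble(sd_amplitude = stats::sd(amps),
                 mean_amplitude = mean(amps), n = length(amps))
}

#' Response amplitudes of the first trials (adaptation check)
#'
#' Returns the per-trial response amplitudes of the first `k` trials in
#' presentation order, for assessing trial-to-trial adaptation.
#'
#' @param trials Ordered list of traces.
#' @param k Number of leading trials (default 3).
#' @param response_window As in [intertrial_variability()].
#' @return A tibble `trial`, `amplitude` with `k` rows.
#' @export
adaptation_check <- function(trials, k = 3, response_window = NULL) {
  stopifnot(is.list(trials))
  if (length(trials) < k)
    stop("need at least ", k, " trials", call. = FALSE)
  amps <- vapply(trials[seq_len(k)], trial_amplitude, numeric(1),
                 window = response_window)
  tibble::tibble(trial = seq_len(k), amplitude = amps)
}
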