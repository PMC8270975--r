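#' Construct a trial trace
#'
#' A trial trace is the basic record of the package: one uniformly sampled
#' signal (neuronal calcium, vessel diameter, or RBC velocity) from one
#' stimulation trial, together with the stimulus timing and the baseline
#' window used for normalization. It is a tibble with columns `time_s` and
#' `value` and carries its metadata as attributes, so it pipes through the
#' normalization verbs ([delta_f()], [percent_change()], [zscore_trial()]).
#'
#' @param time_s Numeric vector of sample times in seconds, uniformly spaced.
#' @param value Numeric vector of signal values, same length as `time_s`.
#' @param stim_onset Stimulus onset time in seconds.
#' @param stim_duration Stimulus duration in seconds.
#' @param baseline_window Length-2 numeric, `(start, end)` of the baseline
#'   period in seconds; must end at or before `stim_onset`. Defaults to
#'   everything before the stimulus.
#' @param modality One of `"calcium"`, `"diameter"`, `"velocity"`.
#' @param compartment Vascular compartment label (e.g. `"pial"`,
#'   `"penetrating"`, `"first_order"`, `"capillary_ge4"`); free-form.
#' @param arbor_id Identifier of the vascular arbor / network.
#' @param quality Optional per-sample confidence in `[0, 1]`; samples with
#'   quality 0 are treated as missing.
#'
#' @return A `nvc_trace` object (tibble subclass).
#' @export
#' @examples
#' tr <- trial_trace(seq(0, 20, by = 0.1), rnorm(201), stim_onset = 10,
#'                   stim_duration = 5, modality = "diameter")
#' tr
trial_trace <- function(time_s, value, stim_onset, stim_duration,
                        baseline_window = NULL,
                        modality = c("calcium", "diameter", "velocity"),
                        compartment = NA_character_, arbor_id = NA_character_,
                        quality = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.numeric(time_s), is.numeric(value),
            length(time_s) == length(value), length(time_s) >= 2)
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("`time_s` must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("`time_s` must be uniformly sampled", call. = FALSE)
  if (is.null(baseline_window)) baseline_window <- c(time_s[1], stim_onset)
  baseline_window <- as.numeric(baseline_window)
  if (length(baseline_window) != 2 || baseline_window[2] > stim_onset + 1e-9)
    stop("`baseline_window` must be (start, end) with end <= stim_onset",
         call. = FALSE)
  if (!is.null(quality)) {
    stopifnot(length(quality) == length(value))
    value[quality <= 0] <- NA_real_
  }
  new_nvc_trace(tibble::tibble(time_s = time_s, value = value),
                stim_onset = stim_onset, stim_duration = stim_duration,
                baseline_window = baseline_window, modality = modality,
                compartment = compartment, arbor_id = arbor_id)
}

new_nvc_trace <- function(df, ..., class = character()) {
  meta <- list(...)
  out <- tibble::new_tibble(df, nrow = nrow(df),
                            class = c(class, "nvc_trace"))
  for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  out
}

#' @export
print.nvc_trace <- function(x, ...) {
  cat(sprintf("<nvc_trace: %s | stim %.3g s + %.3g s | baseline [%.3g, %.3g] s | %d samples>\n",
              trace_meta(x)$modality, trace_meta(x)$stim_onset,
              trace_meta(x)$stim_duration, trace_meta(x)$baseline_window[1],
              trace_meta(x)$baseline_window[2], nrow(x)))
  NextMethod()
}

#' Trace metadata as a list
#'
#' @param trace A [trial_trace()] object.
#' @return A named list with `stim_onset`, `stim_duration`, `baseline_window`,
#'   `modality`, `compartment`, `arbor_id` (and, for z-scored traces,
#'   `baseline_mean` and `baseline_sd`).
#' @export
trace_meta <- function(trace) {
  nm <- c("stim_onset", "stim_duration", "baseline_window", "modality",
          "compartment", "arbor_id", "baseline_mean", "baseline_sd")
  out <- lapply(nm, function(n) attr(trace, n, exact = TRUE))
  names(out) <- nm
  out[!vapply(out, is.null, logical(1))]
}

# rebuild a trace with new values, preserving metadata (optionally overriding)
trace_update <- function(trace, value, ..., class = character()) {
  meta <- utils::modifyList(trace_meta(trace), list(...))
  df <- tibble::tibble(time_s = trace$time_s, value = value)
  do.call(new_nvc_trace, c(list(df = df, class = class), meta))
}

trace_dt <- function(trace) {
  (trace$time_s[length(trace$time_s)] - trace$time_s[1]) /
    (length(trace$time_s) - 1)
}

# logical index of baseline samples, window half-open [start, end)
baseline_idx <- function(trace) {
  bw <- trace_meta(trace)$baseline_window
  trace$time_s >= bw[1] - 1e-9 & trace$time_s < bw[2] - 1e-9
}

# baseline values with missing (quality-0) samples dropped
baseline_values <- function(trace) {
  v <- trace$value[baseline_idx(trace)]
  v <- v[is.finite(v)]
  if (length(v) == 0)
    stop("baseline window contains no usable samples", call. = FALSE)
  v
}

# linear interpolation across missing samples for trace-wide operations
trace_fill <- function(value, time_s) {
  if (!anyNA(value)) return(value)
  ok <- is.finite(value)
  if (sum(ok) < 2) stop("too few finite samples to interpolate", call. = FALSE)
  stats::approx(time_s[ok], value[ok], xout = time_s, rule = 2)$y
}

#' Default response window of a trace
#'
#' Stimulus onset to stimulus offset plus two seconds, the window in which
#' evoked response amplitudes are measured.
#'
#' @param trace A [trial_trace()] object.
#' @param tail_s Seconds after stimulus offset to include (default 2).
#' @return Length-2 numeric `(start, end)` in seconds.
#' @export
response_window <- function(trace, tail_s = 2) {
  m <- trace_meta(trace)
  c(m$stim_onset, m$stim_onset + m$stim_duration + tail_s)
}
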