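#' Ground truth for the synthetic-data generator
#'
#' Bundles everything the generator needs to produce trials with known truth:
#' the coupling kernel, the calcium response shape, vasomotion, and noise.
#' Identical ground truth (including `seed`) produces bit-identical data.
#'
#' Defaults are the study conditions the analysis is validated under:
#' vascular traces are in percent-change-from-baseline units, the kernel has
#' the shape/rate/delay of a slow (anesthetized-like) coupling kernel with
#' its gain set so a unit-amplitude calcium response evokes a ~5% dilation,
#' vasomotion is a single ~0.1 Hz sinusoid of 1% amplitude, calcium kinetics
#' are GCaMP6-like double exponentials, and measurement noise is 0.2%.
#'
#' @param tf_params Length-4 numeric `(p1, p2, p3, p4)` of the generative
#'   coupling kernel; see [transfer_function()] for units and constraints.
#' @param ca_onset Latency of the calcium rise after stimulus onset, seconds.
#' @param ca_peak_amplitude Peak amplitude of the noiseless calcium response
#'   (signal units).
#' @param tau_rise,tau_decay Calcium rise / decay time constants, seconds.
#' @param vasomotion_amplitude Amplitude of the vasomotion sinusoid added to
#'   vascular traces, in percent of baseline.
#' @param vasomotion_freq Vasomotion frequency in Hz, within (0.02, 1).
#' @param vasomotion_phase Vasomotion phase at `t = 0`, radians.
#' @param noise_sd SD of the additive i.i.d. Gaussian noise (signal units).
#' @param seed Integer seed for all randomness derived from this truth.
#' @return A list of class `nvc_truth`.
#' @export
#' @examples
#' gt <- ground_truth(noise_sd = 0.05, seed = 7)
#' ca <- make_calcium_trace(stim_onset = 10, stim_duration = 5, rate = 10,
#'                          truth = gt)
ground_truth <- function(tf_params = c(1.3, 0.5, 0.27, 6),
                         ca_onset = 0.05, ca_peak_amplitude = 1,
                         tau_rise = 0.2, tau_decay = 1.0,
                         vasomotion_amplitude = 1, vasomotion_freq = 0.1,
                         vasomotion_phase = 0, noise_sd = 0.2, seed = 1L) {
  stopifnot(length(tf_params) == 4)
  if (tf_params[1] <= 1) stop("tf shape p1 must be > 1", call. = FALSE)
  if (tf_params[2] <= 0) stop("tf rate p2 must be > 0", call. = FALSE)
  if (tf_params[3] < 0) stop("tf delay p3 must be >= 0", call. = FALSE)
  if (tf_params[4] <= 0) stop("tf gain p4 must be > 0", call. = FALSE)
  if (vasomotion_freq <= 0.02 || vasomotion_freq >= 1)
    stop("`vasomotion_freq` must lie in (0.02, 1) Hz", call. = FALSE)
  structure(list(tf_params = as.numeric(tf_params), ca_onset = ca_onset,
                 ca_peak_amplitude = ca_peak_amplitude,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 vasomotion_amplitude = vasomotion_amplitude,
                 vasomotion_freq = vasomotion_freq,
                 vasomotion_phase = vasomotion_phase,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "nvc_truth")
}

#' The generative transfer function of a ground truth
#' @param truth A [ground_truth()].
#' @param grid_dt Sampling interval for discretization, seconds.
#' @return A [transfer_function()].
#' @export
truth_tf <- function(truth, grid_dt = 0.1) {
  p <- truth$tf_params
  transfer_function(p[1], p[2], p[3], p[4], grid_dt = grid_dt)
}

#' Simulate a stimulus-locked calcium trace
#'
#' Baseline is zero-mean (plus noise); after `stim_onset + ca_onset` the
#' trace follows a double-exponential waveform, `(1 - exp(-u/tau_rise))`
#' rising during the stimulus and decaying with `tau_decay` after stimulus
#' offset, normalized so the noiseless peak equals `ca_peak_amplitude`.
#'
#' @param stim_onset Stimulus onset, seconds; must leave a baseline before it.
#' @param stim_duration Stimulus duration, seconds, positive.
#' @param rate Sampling rate in Hz, positive.
#' @param truth A [ground_truth()].
#' @param duration Total trace duration in seconds (default: onset +
#'   stimulus + 15 s of recovery).
#' @param baseline_window Baseline window; default the full pre-stimulus
#'   period.
#' @param stream Integer offset added to the truth seed so multiple trials
#'   from one truth draw independent noise.
#' @return A calcium [trial_trace()].
#' @export
make_calcium_trace <- function(stim_onset, stim_duration, rate, truth,
                               duration = stim_onset + stim_duration + 15,
                               baseline_window = NULL, stream = 0L) {
  if (!is.numeric(rate) || rate <= 0)
    stop("`rate` must be a positive sampling rate in Hz", call. = FALSE)
  if (stim_duration <= 0) stop("`stim_duration` must be > 0", call. = FALSE)
  if (stim_onset < 0) stop("`stim_onset` must be >= 0", call. = FALSE)
  t <- seq(0, duration, by = 1 / rate)
  u <- t - stim_onset - truth$ca_onset
  w <- numeric(length(t))
  on <- u > 0
  w[on] <- (1 - exp(-u[on] / truth$tau_rise)) *
    exp(-pmax(0, u[on] - stim_duration) / truth$tau_decay)
  pk <- max(w)
  value <- if (pk > 0) truth$ca_peak_amplitude * w / pk else w
  value <- value + synth_noise(length(t), truth, stream)
  trial_trace(t, value, stim_onset = stim_onset,
              stim_duration = stim_duration,
              baseline_window = baseline_window, modality = "calcium")
}

# i.i.d. gaussian noise, deterministic in (truth$seed, stream)
synth_noise <- function(n, truth, stream = 0L) {
  if (truth$noise_sd <= 0) return(numeric(n))
  withr::with_seed(truth$seed + 1000L * as.integer(stream),
                   stats::rnorm(n, 0, truth$noise_sd))
}

#' Simulate a vascular trace from a calcium trace
#'
#' The vascular response is the causal convolution of the calcium trace with
#' the ground-truth kernel (scaled by the sample interval), plus a vasomotion
#' sinusoid `A sin(2 pi f t + phase)` and additive Gaussian noise.
#'
#' @param ca A calcium [trial_trace()] from [make_calcium_trace()].
#' @param truth A [ground_truth()].
#' @param modality `"diameter"` or `"velocity"` label for the output trace.
#' @param stream Integer noise-stream offset (see [make_calcium_trace()]).
#' @return A vascular [trial_trace()] on the same time base.
#' @export
make_vascular_trace <- function(ca, truth,
                                modality = c("diameter", "velocity"),
                                stream = 1L) {
  modality <- match.arg(modality)
  stopifnot(inherits(ca, "nvc_trace"))
  dt <- trace_dt(ca)
  tf <- truth_tf(truth, grid_dt = dt)
  evoked <- tf_convolve(ca$value, tf, dt)
  vaso <- truth$vasomotion_amplitude *
    sin(2 * pi * truth$vasomotion_freq * ca$time_s + truth$vasomotion_phase)
  value <- evoked + vaso + synth_noise(length(evoked), truth, stream)
  trace_update(ca, value, modality = modality)
}

#' Simulate a set of trials with shared ground truth
#'
#' Generates `n_trials` paired calcium/vascular trials; each trial draws an
#' independent noise stream and (optionally) an independent vasomotion phase,
#' while the kernel and response shape are shared — the structure the
#' trial-averaging analysis assumes.
#'
#' @param n_trials Number of trials, at least 1.
#' @param truth A [ground_truth()].
#' @param stim_onset,stim_duration,rate,duration As [make_calcium_trace()].
#' @param modality Vascular modality label.
#' @param randomize_phase Draw a fresh vasomotion phase per trial (default
#'   TRUE, as in recordings where stimulation is not locked to vasomotion).
#' @param amplitude_jitter_sd SD of multiplicative per-trial jitter of the
#'   calcium response amplitude (0 = identical responses).
#' @return A list of class `nvc_trial_set` with elements `calcium`,
#'   `vascular` (lists of traces), and `truth`.
#' @export
simulate_trial_set <- function(n_trials, truth, stim_onset = 10,
                               stim_duration = 5, rate = 10,
                               duration = stim_onset + stim_duration + 15,
                               modality = c("diameter", "velocity"),
                               randomize_phase = TRUE,
                               amplitude_jitter_sd = 0) {
  modality <- match.arg(modality)
  stopifnot(n_trials >= 1)
  phases <- withr::with_seed(truth$seed,
    if (randomize_phase) stats::runif(n_trials, 0, 2 * pi)
    else rep(truth$vasomotion_phase, n_trials))
  jitters <- withr::with_seed(truth$seed + 1L,
    if (amplitude_jitter_sd > 0)
      pmax(0.05, stats::rnorm(n_trials, 1, amplitude_jitter_sd))
    else rep(1, n_trials))
  ca_list <- vector("list", n_trials)
  va_list <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tr_i <- truth
    tr_i$vasomotion_phase <- phases[i]
    tr_i$ca_peak_amplitude <- truth$ca_peak_amplitude * jitters[i]
    ca_list[[i]] <- make_calcium_trace(stim_onset, stim_duration, rate, tr_i,
                                       duration = duration,
                                       stream = 2L * i)
    va_list[[i]] <- make_vascular_trace(ca_list[[i]], tr_i,
                                        modality = modality,
                                        stream = 2L * i + 1L)
  }
  structure(list(calcium = ca_list, vascular = va_list, truth = truth,
                 modality = modality),
            class = "nvc_trial_set")
}

#' Write a trial set to CSV with a JSON sidecar
#'
#' The CSV is long format (`trial_id`, `time_s`, `value`) per modality; the
#' sidecar stores the ground truth and stimulus metadata.
#'
#' @param set A `nvc_trial_set` from [simulate_trial_set()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_trial_set <- function(set, dir, prefix = "trials") {
  stopifnot(inherits(set, "nvc_trial_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- function(traces) {
    dplyr::bind_rows(purrr::imap(traces, function(tr, i)
      tibble::tibble(trial_id = i, time_s = tr$time_s, value = tr$value)))
  }
  utils::write.csv(long(set$calcium),
                   file.path(dir, paste0(prefix, "_calcium.csv")),
                   row.names = FALSE)
  utils::write.csv(long(set$vascular),
                   file.path(dir, paste0(prefix, "_", set$modality, ".csv")),
                   row.names = FALSE)
  m <- trace_meta(set$calcium[[1]])
  side <- list(truth = unclass(set$truth), modality = set$modality,
               stim_onset = m$stim_onset, stim_duration = m$stim_duration,
               baseline_window = m$baseline_window,
               rate_hz = 1 / trace_dt(set$calcium[[1]]))
  jsonlite::write_json(side, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trial set written by [write_trial_set()]
#'
#' @param dir Directory containing the CSVs and sidecar.
#' @param prefix File-name prefix used at write time.
#' @return A `nvc_trial_set`.
#' @export
read_trial_set <- function(dir, prefix = "trials") {
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  truth <- do.call(ground_truth, side$truth[names(side$truth) != "seed"] |>
                     c(list(seed = side$truth$seed)))
  load_traces <- function(path, modality) {
    df <- utils::read.csv(path)
    lapply(split(df, df$trial_id), function(d)
      trial_trace(d$time_s, d$value, stim_onset = side$stim_onset,
                  stim_duration = side$stim_duration,
                  baseline_window = side$baseline_window,
                  modality = modality))
  }
  structure(list(
    calcium = load_traces(file.path(dir, paste0(prefix, "_calcium.csv")),
                          "calcium"),
    vascular = load_traces(
      file.path(dir, paste0(prefix, "_", side$modality, ".csv")),
      side$modality),
    truth = truth, modality = side$modality), class = "nvc_trial_set")
}
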