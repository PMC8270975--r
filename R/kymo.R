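#' Construct a kymograph
#'
#' A kymograph is the time-by-position image produced by repeatedly scanning
#' one line: rows are scan lines (time), columns are pixels along the line.
#' In diameter mode the line crosses the vessel perpendicular to its axis; in
#' velocity mode it runs along the vessel axis and unlabeled RBCs appear as
#' dark streaks in the fluorescent plasma whose slope encodes velocity.
#'
#' @param image Numeric matrix, lines x pixels.
#' @param dt_line Time per scan line in seconds, positive.
#' @param dx Pixel size along the line in micrometers, positive.
#' @param mode `"diameter"` or `"velocity"`.
#' @return A `nvc_kymograph` object.
#' @export
kymograph <- function(image, dt_line, dx, mode = c("diameter", "velocity")) {
  mode <- match.arg(mode)
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0)
    stop("`image` must be a nonempty numeric matrix", call. = FALSE)
  if (!is.numeric(dt_line) || dt_line <= 0)
    stop("`dt_line` must be > 0", call. = FALSE)
  if (!is.numeric(dx) || dx <= 0) stop("`dx` must be > 0", call. = FALSE)
  structure(list(image = image, dt_line = dt_line, dx = dx, mode = mode),
            class = "nvc_kymograph")
}

#' @export
print.nvc_kymograph <- function(x, ...) {
  cat(sprintf("<nvc_kymograph (%s): %d lines x %d px | dt_line %.3g ms | dx %.3g um>\n",
              x$mode, nrow(x$image), ncol(x$image), 1e3 * x$dt_line, x$dx))
  invisible(x)
}

#' Render a synthetic kymograph with known ground truth
#'
#' Diameter mode draws, per scan line, a bright plateau of the instantaneous
#' lumen width on a dark background, with Gaussian-blurred edges whose
#' half-maximum points fall exactly at the true boundaries. Velocity mode
#' draws a uniformly bright plasma line interrupted by moving Gaussian RBC
#' shadows whose displacement per line is the instantaneous velocity times
#' `dt_line`. Intensities lie in `[0, 1]` before noise.
#'
#' @param diameter_t Diameter time series in micrometers: a [trial_trace()]
#'   or tibble with `time_s`, `value` (used in diameter mode).
#' @param velocity_t Velocity time series in mm/s (used in velocity mode).
#' @param dx Pixel size in micrometers, positive.
#' @param dt_line Line period in seconds, positive.
#' @param truth A [ground_truth()] (supplies noise SD and the seed).
#' @param mode `"diameter"` or `"velocity"`.
#' @param scan_len_um Length of the scanned line in micrometers.
#' @param edge_blur_um SD of the Gaussian edge blur (diameter mode).
#' @param shadow_spacing_um Mean RBC spacing along the vessel (velocity mode).
#' @param shadow_sigma_um SD of each Gaussian RBC shadow (velocity mode).
#' @param stream Integer noise-stream offset.
#' @return A [kymograph()].
#' @export
render_kymograph <- function(diameter_t = NULL, velocity_t = NULL, dx, dt_line,
                             truth, mode = c("diameter", "velocity"),
                             scan_len_um = if (mode == "diameter") 40 else 80,
                             edge_blur_um = 0.3, shadow_spacing_um = 8,
                             shadow_sigma_um = 1.2, stream = 10L) {
  mode <- match.arg(mode)
  if (dx <= 0 || dt_line <= 0)
    stop("`dx` and `dt_line` must be > 0", call. = FALSE)
  src <- if (mode == "diameter") diameter_t else velocity_t
  if (is.null(src)) stop("missing input series for mode ", mode, call. = FALSE)
  n_px <- ceiling(scan_len_um / dx)
  x <- (seq_len(n_px) - 0.5) * dx  # pixel centres, um
  t_end <- max(src$time_s)
  lines_t <- seq(0, t_end, by = dt_line)
  vals <- stats::approx(src$time_s, src$value, xout = lines_t, rule = 2)$y
  n_ln <- length(lines_t)

  if (mode == "diameter") {
    if (any(vals >= scan_len_um))
      stop("diameter exceeds the scanned line length", call. = FALSE)
    centre <- scan_len_um / 2
    left <- centre - vals / 2
    right <- centre + vals / 2
    # smooth plateau: product of two error-function edges; half-max exactly
    # at the true boundaries
    img <- stats::pnorm(outer(-left, x, `+`), sd = edge_blur_um) *
      stats::pnorm(outer(right, -x, `+`), sd = edge_blur_um)
  } else {
    # plasma line along the vessel axis, shadows advected by the velocity
    disp_um <- cumsum(vals * 1e3) * dt_line  # mm/s -> um/s
    spacing <- shadow_spacing_um
    n_sh <- ceiling(3 * scan_len_um / spacing)
    offs <- withr::with_seed(truth$seed + 1000L * stream,
      sort(stats::runif(n_sh, -scan_len_um, 2 * scan_len_um)))
    img <- matrix(0.9, n_ln, n_px)
    period <- 3 * scan_len_um
    for (k in seq_len(n_sh)) {
      # wrap positions so shadows recirculate through the field of view
      pos <- (offs[k] + disp_um + scan_len_um) %% period - scan_len_um
      d2 <- (outer(-pos, x, `+`) / shadow_sigma_um)^2
      img <- img * (1 - 0.75 * exp(-0.5 * d2))
    }
  }
  img <- pmin(pmax(img, 0), 1)
  if (truth$noise_sd > 0)
    img <- img + matrix(synth_noise(length(img), truth, stream), n_ln, n_px)
  kymograph(img, dt_line = dt_line, dx = dx, mode = mode)
}

#' Extract vessel diameter from a kymograph
#'
#' Per scan line, the lumen diameter is the distance between the two
#' half-maximum crossings of the intensity profile, with linear interpolation
#' between pixels for sub-pixel boundaries. A causal (preceding-time) moving
#' mean of `filter_ms` is applied to the image before boundary detection, so
#' the value at time t depends only on lines at times <= t. The half-maximum
#' level is midway between a background estimate (lower decile) and the peak
#' estimate (upper decile), making the measurement invariant to intensity
#' scaling and offset.
#'
#' @param k A [kymograph()] in diameter mode.
#' @param filter_ms Length of the causal mean filter in milliseconds
#'   (default 200).
#' @param min_contrast Minimum (peak - background) / (|peak| + |background|)
#'   contrast for a line to be measurable.
#' @return A tibble `time_s`, `value` (micrometers), `quality`; lines where
#'   no crossing exists have `value = NA` and `quality = 0`.
#' @export
extract_diameter <- function(k, filter_ms = 200, min_contrast = 0.05) {
  stopifnot(inherits(k, "nvc_kymograph"))
  if (k$mode != "diameter")
    stop("kymograph is not in diameter mode", call. = FALSE)
  img <- causal_mean_filter(k$image, max(1L, round(filter_ms / 1e3 / k$dt_line)))
  n_ln <- nrow(img)
  x <- (seq_len(ncol(img)) - 0.5) * k$dx
  value <- rep(NA_real_, n_ln)
  quality <- numeric(n_ln)
  for (i in seq_len(n_ln)) {
    p <- img[i, ]
    bg <- mean(p[p <= stats::quantile(p, 0.1)])
    pk <- max(p)  # robust to vessel width; noise is tamed by the mean filter
    contrast <- (pk - bg) / (abs(pk) + abs(bg) + .Machine$double.eps)
    if (!is.finite(contrast) || contrast < min_contrast) next
    half <- (pk + bg) / 2
    above <- p > half
    if (!any(above)) next
    iL <- which(above)[1]
    iR <- which(above)[length(which(above))]
    xl <- if (iL == 1) x[1] else
      x[iL - 1] + (half - p[iL - 1]) / (p[iL] - p[iL - 1]) * k$dx
    xr <- if (iR == ncol(img)) x[ncol(img)] else
      x[iR] + (half - p[iR]) / (p[iR + 1] - p[iR]) * k$dx
    value[i] <- xr - xl
    quality[i] <- min(1, contrast)
  }
  tibble::tibble(time_s = (seq_len(n_ln) - 1) * k$dt_line,
                 value = value, quality = quality)
}

# causal moving mean over the preceding `w` lines (including the current)
causal_mean_filter <- function(img, w) {
  if (w <= 1) return(img)
  cs <- apply(img, 2, cumsum)
  n <- nrow(img)
  lag <- rbind(matrix(0, min(w, n), ncol(img)),
               cs[seq_len(max(0, n - w)), , drop = FALSE])
  counts <- pmin(seq_len(n), w)
  (cs - lag) / counts
}

#' Extract RBC velocity from a kymograph
#'
#' Over sliding windows, estimates the dominant streak angle of the RBC
#' shadows by a Radon-style search: the image window is mean-subtracted and
#' projected along candidate streak directions; the direction maximizing the
#' variance explained by the projection is the streak angle, refined by
#' parabolic interpolation. Velocity is `tan(angle) * dx / dt_line`; its sign
#' gives the flow direction. Quality is the explained-variance fraction of
#' the best projection; windows below `min_contrast` are returned missing.
#'
#' @param k A [kymograph()] in velocity mode.
#' @param window_ms Window length in milliseconds (default 50); must cover at
#'   least 8 lines.
#' @param overlap Fractional window overlap (default 0.75).
#' @param v_max Largest searchable speed, mm/s.
#' @param min_contrast Quality threshold below which a window is missing.
#' @return A tibble `time_s` (window centre), `value` (mm/s), `quality`.
#' @export
extract_velocity <- function(k, window_ms = 50, overlap = 0.75, v_max = 30,
                             min_contrast = 0.05) {
  stopifnot(inherits(k, "nvc_kymograph"))
  if (k$mode != "velocity")
    stop("kymograph is not in velocity mode", call. = FALSE)
  w <- round(window_ms / 1e3 / k$dt_line)
  if (w < 8) stop("window must cover at least 8 lines", call. = FALSE)
  step <- max(1L, round(w * (1 - overlap)))
  n_ln <- nrow(k$image)
  starts <- seq(1L, max(1L, n_ln - w + 1L), by = step)
  # slope grid in px/line: 0 and log-spaced magnitudes up to the v_max slope
  s_max <- v_max * 1e3 * k$dt_line / k$dx
  s_coarse <- exp(seq(log(0.02), log(s_max), length.out = 40))
  slopes <- sort(c(-s_coarse, 0, s_coarse))
  res <- purrr::map(starts, function(s0) {
    win <- k$image[s0:min(n_ln, s0 + w - 1L), , drop = FALSE]
    est <- streak_slope(win, slopes)
    tibble::tibble(
      time_s = (s0 - 1 + nrow(win) / 2) * k$dt_line,
      value = est$slope * k$dx / k$dt_line / 1e3,  # px/line -> mm/s
      quality = est$quality)
  })
  out <- dplyr::bind_rows(res)
  bad <- out$quality < min_contrast
  out$value[bad] <- NA_real_
  out$quality[bad] <- 0
  out
}

# dominant streak slope (px per line) of a window by projection-variance
# search over a slope grid, with local refinement + parabolic interpolation
streak_slope <- function(win, slopes) {
  win <- win - mean(win)
  tot <- sum(win^2)
  if (tot <= .Machine$double.eps) return(list(slope = 0, quality = 0))
  sc <- vapply(slopes, function(s) projection_score(win, s), numeric(1))
  i0 <- which.max(sc)
  # refine on a fine local grid in angle space around the coarse maximum
  th0 <- atan(slopes[max(1L, i0 - 1L)])
  th1 <- atan(slopes[min(length(slopes), i0 + 1L)])
  th <- seq(th0, th1, length.out = 15)
  scf <- vapply(tan(th), function(s) projection_score(win, s), numeric(1))
  j <- which.max(scf)
  if (j > 1 && j < length(th)) {
    # parabolic vertex through the three points around the maximum
    y1 <- scf[j - 1]; y2 <- scf[j]; y3 <- scf[j + 1]
    denom <- (y1 - 2 * y2 + y3)
    delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    delta <- max(-1, min(1, delta))
    th_hat <- th[j] + delta * (th[2] - th[1])
  } else th_hat <- th[j]
  list(slope = tan(th_hat), quality = max(scf) / tot)
}

# variance explained by binning pixel values on u = x - slope * line
projection_score <- function(win, s) {
  n_ln <- nrow(win); n_px <- ncol(win)
  i <- rep(seq_len(n_ln), times = n_px)
  j <- rep(seq_len(n_px), each = n_ln)
  u <- j - s * i
  b <- floor(u - min(u)) + 1L
  v <- as.vector(win)
  sums <- rowsum(v, b)  # sorted by bin index, matching the counts below
  counts <- tabulate(b, nbins = max(b))
  counts <- counts[counts > 0]
  sum(sums^2 / counts)
}

#' Thresholded activation map from a widefield stack
#'
#' Per pixel, the activation score is the summed change in fluorescence over
#' the stimulation window relative to the mean baseline fluorescence, clipped
#' at zero; the mask keeps pixels whose score reaches `threshold_frac` of the
#' maximum score. Windows are half-open `[start, end)` in seconds.
#'
#' @param stack 3-D numeric array, `height x width x frames`.
#' @param frame_times Frame times in seconds, one per frame.
#' @param stim_window,baseline_window Length-2 numeric windows in seconds;
#'   both must contain at least one frame.
#' @param threshold_frac Fraction of the maximum score, in (0, 1).
#' @return A list with `score` (matrix) and `mask` (logical matrix).
#' @export
activation_map <- function(stack, frame_times, stim_window, baseline_window,
                           threshold_frac = 0.75) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  if (length(frame_times) != dim(stack)[3])
    stop("`frame_times` must match the number of frames", call. = FALSE)
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("`threshold_frac` must lie in (0, 1)", call. = FALSE)
  in_win <- function(w) frame_times >= w[1] & frame_times < w[2]
  bi <- in_win(baseline_window)
  si <- in_win(stim_window)
  if (!any(bi) || !any(si))
    stop("stimulus/baseline window contains no frames", call. = FALSE)
  base <- apply(stack[, , bi, drop = FALSE], c(1, 2), mean)
  score <- apply(stack[, , si, drop = FALSE], c(1, 2), sum) - sum(si) * base
  score <- pmax(score, 0)
  mx <- max(score)
  mask <- if (mx > 0) score >= threshold_frac * mx
          else matrix(FALSE, nrow(score), ncol(score))
  list(score = score, mask = mask)
}

#' Convert a kymograph measurement into a trial trace
#'
#' Attaches stimulus metadata to an extracted diameter/velocity series so it
#' can enter the normalization verbs. Missing (quality-0) samples stay
#' missing; they are excluded from baseline statistics and interpolated by
#' the trace operations that need complete series.
#'
#' @param meas Tibble from [extract_diameter()] / [extract_velocity()].
#' @param stim_onset,stim_duration,baseline_window,modality,compartment,arbor_id
#'   Metadata; see [trial_trace()].
#' @return A [trial_trace()].
#' @export
measurement_to_trace <- function(meas, stim_onset, stim_duration,
                                 baseline_window = NULL,
                                 modality = c("diameter", "velocity"),
                                 compartment = NA_character_,
                                 arbor_id = NA_character_) {
  modality <- match.arg(modality)
  trial_trace(meas$time_s, meas$value, stim_onset = stim_onset,
              stim_duration = stim_duration,
              baseline_window = baseline_window, modality = modality,
              compartment = compartment, arbor_id = arbor_id,
              quality = meas$quality)
}
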