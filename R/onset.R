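#' Fit the four-parameter sigmoid to an averaged z-score trace
#'
#' Least-squares fit of
#' \deqn{s(x) = A + B / (1 + e^{-(-x - C) D})}
#' over the fit window. `A` is one asymptote, `B` the span, `C` the (negated)
#' midpoint and `D` the slope parameter. As printed, the formula produces a
#' rising curve for `D < 0` when `B > 0`; the parameterization is degenerate
#' under `(A, B, C, D) -> (A + B, -B, C, -D)`, and fits are canonicalized to
#' `B > 0` so the lower asymptote is always `A` and the upper `A + B`.
#'
#' Fitting uses a deterministic multi-start grid (midpoints across the
#' window, `|D|` in `{0.5, 1, 2, 5}` per second, both signs) with
#' Levenberg-Marquardt refinement from each start; the minimum-RSS fit is
#' returned.
#'
#' @param trace A trace (tibble with `time_s` and `value`; a `value` column
#'   named `z` is also accepted).
#' @param fit_window Length-2 numeric window in seconds; defaults to the
#'   trace's baseline start through stimulus offset + 5 s when the trace
#'   carries metadata, otherwise the full extent. Must contain >= 8 samples.
#' @param d_grid Magnitudes of the slope starts (1/s).
#' @return A `nvc_sigmoid` object: parameters `A`, `B`, `C`, `D`, `rss`,
#'   `fit_window`, `flat` (TRUE when the response is degenerate/flat) and the
#'   fitted data window.
#' @export
fit_sigmoid <- function(trace, fit_window = NULL, d_grid = c(0.5, 1, 2, 5)) {
  stopifnot(is.data.frame(trace))
  val <- if ("value" %in% names(trace)) trace$value else trace$z
  if (is.null(val)) stop("trace needs a `value` (or `z`) column", call. = FALSE)
  if (is.null(fit_window)) {
    if (inherits(trace, "nvc_trace")) {
      m <- trace_meta(trace)
      fit_window <- c(m$baseline_window[1],
                      m$stim_onset + m$stim_duration + 5)
    } else fit_window <- range(trace$time_s)
  }
  keep <- trace$time_s >= fit_window[1] - 1e-9 &
    trace$time_s <= fit_window[2] + 1e-9 & is.finite(val)
  x <- trace$time_s[keep]
  y <- val[keep]
  if (length(x) < 8)
    stop("fit window must contain at least 8 samples", call. = FALSE)

  rng <- diff(range(y))
  if (rng < .Machine$double.eps * 100) {
    # flat trace: degenerate fit, slope unidentifiable
    fit <- list(A = mean(y), B = 0, C = -mean(x), D = NA_real_,
                rss = sum((y - mean(y))^2), fit_window = fit_window,
                flat = TRUE, data = tibble::tibble(time_s = x, value = y))
    class(fit) <- "nvc_sigmoid"
    return(fit)
  }

  sig <- function(x, A, B, C, D) A + B / (1 + exp(-(-x - C) * D))
  best <- NULL
  c_starts <- -stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  for (C0 in c_starts) for (Dm in d_grid) for (Ds in c(-1, 1)) {
    start <- list(A = stats::quantile(y, 0.05, names = FALSE), B = rng,
                  C = C0, D = Ds * Dm)
    fit_try <- tryCatch(
      minpack.lm::nlsLM(y ~ A + B / (1 + exp(-(-x - C) * D)),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit_try)) next
    rss <- sum(stats::residuals(fit_try)^2)
    if (is.null(best) || rss < best$rss)
      best <- c(as.list(stats::coef(fit_try)), list(rss = rss))
  }
  if (is.null(best))
    stop("sigmoid fit failed to converge from all starts", call. = FALSE)
  # canonicalize to B > 0 via (A, B, C, D) <-> (A + B, -B, C, -D)
  if (best$B < 0) {
    best$A <- best$A + best$B
    best$B <- -best$B
    best$D <- -best$D
  }
  fit <- list(A = best$A, B = best$B, C = best$C, D = best$D, rss = best$rss,
              fit_window = fit_window, flat = FALSE,
              data = tibble::tibble(time_s = x, value = y))
  class(fit) <- "nvc_sigmoid"
  fit
}

#' Evaluate a fitted sigmoid
#'
#' @param object A `nvc_sigmoid` from [fit_sigmoid()].
#' @param time_s Times at which to evaluate; defaults to the fitted window.
#' @param ... Unused.
#' @return Tibble `time_s`, `value`.
#' @export
predict.nvc_sigmoid <- function(object, time_s = NULL, ...) {
  if (is.null(time_s)) time_s <- object$data$time_s
  v <- if (object$flat) rep(object$A, length(time_s)) else
    object$A + object$B / (1 + exp(-(-time_s - object$C) * object$D))
  tibble::tibble(time_s = time_s, value = v)
}

#' @export
print.nvc_sigmoid <- function(x, ...) {
  if (x$flat) {
    cat(sprintf("<sigmoid fit: flat trace, A = %.4g (B ~ 0, D unidentifiable)>\n",
                x$A))
  } else {
    cat(sprintf(
      "<sigmoid fit: A = %.4g, B = %.4g, C = %.4g s, D = %.4g /s | rss %.4g>\n",
      x$A, x$B, x$C, x$D, x$rss))
  }
  invisible(x)
}

#' Onset times from a sigmoid fit
#'
#' The peak is the upper asymptote of the fit above `baseline_level`; the
#' onset `tXX` is the earliest time where the fit reaches `XX%` of that peak
#' above baseline, solved in closed form from the sigmoid inverse:
#' `t = log(B / (L - A) - 1) / D - C` at level `L`. Onsets are reported
#' relative to `stim_onset`.
#'
#' @param fit A `nvc_sigmoid` from [fit_sigmoid()].
#' @param baseline_level Baseline in z units; default the fitted lower
#'   asymptote `A`. Pass the empirical baseline mean to measure from the
#'   dotted-line convention instead.
#' @param stim_onset Stimulus onset in seconds (0 keeps absolute times).
#' @param levels Percent-of-peak levels (default 10, 25, 50).
#' @return A one-row tibble: `t10`, `t25`, `t50` (seconds, relative to
#'   `stim_onset`), `peak` (z units), `slope` (the `D` parameter), `ok`.
#'   A non-rising fit returns `ok = FALSE` with missing onsets.
#' @export
onset_times <- function(fit, baseline_level = NULL, stim_onset = 0,
                        levels = c(10, 25, 50)) {
  stopifnot(inherits(fit, "nvc_sigmoid"))
  empty <- tibble::tibble(
    !!!stats::setNames(as.list(rep(NA_real_, length(levels))),
                       paste0("t", levels)),
    peak = NA_real_, slope = if (fit$flat) NA_real_ else fit$D, ok = FALSE)
  if (fit$flat) return(empty)
  if (is.null(baseline_level)) baseline_level <- fit$A
  upper <- fit$A + fit$B  # canonical B > 0
  peak <- upper - baseline_level
  if (peak <= 0 || fit$D >= 0) return(empty)  # D < 0 is the rising branch
  ts <- vapply(levels / 100, function(frac) {
    L <- baseline_level + frac * peak
    if (L <= fit$A || L >= upper) return(NA_real_)
    log(fit$B / (L - fit$A) - 1) / fit$D - fit$C
  }, numeric(1))
  tibble::tibble(
    !!!stats::setNames(as.list(ts - stim_onset), paste0("t", levels)),
    peak = peak, slope = fit$D, ok = TRUE)
}

#' Rising slope of a fit
#'
#' The slope is defined as the `D` parameter of the four-parameter sigmoid.
#' Under the canonical `B > 0` convention a rising response has `D < 0`;
#' steeper responses have larger `|D|`. Flat fits return `NA` (the slope is
#' unidentifiable).
#'
#' @param fit A `nvc_sigmoid`.
#' @return The signed `D` parameter (1/s).
#' @export
rising_slope <- function(fit) {
  stopifnot(inherits(fit, "nvc_sigmoid"))
  if (fit$flat) return(NA_real_)
  fit$D
}

#' @export
tidy.nvc_sigmoid <- function(x, ...) {
  tibble::tibble(term = c("A", "B", "C", "D"),
                 estimate = c(x$A, x$B, x$C, x$D),
                 unit = c("z", "z", "s", "1/s"))
}

#' @export
glance.nvc_sigmoid <- function(x, ...) {
  tibble::tibble(A = x$A, B = x$B, C = x$C, D = x$D, rss = x$rss,
                 flat = x$flat, n = nrow(x$data))
}
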