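# Inlet volumetric flow waveforms Q(t). The waveform is the single
# time-varying boundary input of the pipeline: it drives the parabolic inlet
# profile and the 0D Windkessel pressure response.

#' Construct a periodic flow waveform
#'
#' @param times Sample times in seconds, strictly increasing, first sample 0.
#' @param flows Volumetric flow in mL/s, same length as `times`.
#' @param period Cardiac period in seconds; `max(times)` must not exceed it.
#'   The waveform is treated as periodic with this period.
#' @return An object of class `flow_waveform` with fields `times`, `flows`,
#'   `period`.
#' @export
flow_waveform <- function(times, flows, period) {
  if (!is.numeric(times) || !is.numeric(flows) || length(times) != length(flows))
    stop("`times` and `flows` must be numeric vectors of equal length", call. = FALSE)
  if (length(times) < 4L)
    stop("waveform needs at least 4 samples", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(flows)))
    stop("waveform samples must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (abs(times[1L]) > 1e-12)
    stop("first sample time must be 0", call. = FALSE)
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("`period` must be a single positive number", call. = FALSE)
  if (max(times) > period + 1e-12)
    stop("last sample time must not exceed the period", call. = FALSE)
  structure(list(times = as.numeric(times), flows = as.numeric(flows),
                 period = as.numeric(period)),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("Flow waveform: %d samples, period %.3g s, mean %.3g mL/s, peak %.3g mL/s\n",
              length(x$times), x$period, waveform_mean_flow(x), max(x$flows)))
  invisible(x)
}

#' Periodic interpolant of a waveform
#'
#' Returns a function Q(t) (mL/s) valid for any real t, by linear
#' interpolation with periodic wrap-around (the sample at t = period is the
#' sample at t = 0).
#'
#' @param wf A [flow_waveform()].
#' @return A function of one numeric argument.
#' @export
waveform_function <- function(wf) {
  stopifnot(inherits(wf, "flow_waveform"))
  tt <- c(wf$times, wf$period)
  qq <- c(wf$flows, wf$flows[1L])
  f <- stats::approxfun(tt, qq, rule = 2)
  period <- wf$period
  function(t) f(t %% period)
}

#' Time-averaged flow of a waveform
#'
#' Mean of Q(t) over one period by the periodic trapezoidal rule (the wrap
#' segment from the last sample back to t = 0 is included).
#'
#' @param wf A [flow_waveform()].
#' @return Mean flow, mL/s.
#' @export
waveform_mean_flow <- function(wf) {
  stopifnot(inherits(wf, "flow_waveform"))
  tt <- c(wf$times, wf$period)
  qq <- c(wf$flows, wf$flows[1L])
  sum(diff(tt) * (utils::head(qq, -1L) + utils::tail(qq, -1L)) / 2) / wf$period
}

#' Read a flow waveform from CSV
#'
#' The CSV must have header columns `time_s` and `flow_mL_s`. Times are
#' shifted so that the first sample is at 0; flows are unchanged.
#'
#' @param path CSV file path.
#' @param period Cardiac period, s.
#' @return A [flow_waveform()].
#' @export
read_waveform <- function(path, period) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "flow_mL_s") %in% names(df)))
    stop("waveform CSV must have columns `time_s` and `flow_mL_s`", call. = FALSE)
  if (nrow(df) < 4L)
    stop("waveform CSV has fewer than 4 rows", call. = FALSE)
  if (any(diff(df$time_s) <= 0))
    stop("waveform times must be strictly increasing (duplicate or reversed time)", call. = FALSE)
  flow_waveform(df$time_s - df$time_s[1L], df$flow_mL_s, period)
}

#' Write a flow waveform to CSV
#'
#' @param wf A [flow_waveform()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(wf, path) {
  stopifnot(inherits(wf, "flow_waveform"))
  utils::write.csv(data.frame(time_s = wf$times, flow_mL_s = wf$flows),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthesize a carotid-like inlet waveform
#'
#' Two-Gaussian-bump-plus-baseline shape: a sharp systolic peak followed by a
#' smaller dicrotic bump and diastolic decay, rescaled so the discrete time
#' average equals `mean_flow` and the maximum equals `peak_flow` exactly.
#'
#' @param period Cardiac period, s (default 0.9, the typical carotid value).
#' @param mean_flow Cycle-averaged flow, mL/s.
#' @param peak_flow Systolic peak flow, mL/s; must exceed `mean_flow`.
#' @param n_samples Number of uniformly spaced samples over one period.
#' @return A [flow_waveform()], strictly positive.
#' @export
make_carotid_waveform <- function(period = 0.9, mean_flow = 6, peak_flow = 18,
                                  n_samples = 40) {
  if (peak_flow <= mean_flow)
    stop("`peak_flow` must exceed `mean_flow`", call. = FALSE)
  stopifnot(mean_flow > 0, n_samples >= 8)
  tt <- period * (seq_len(n_samples) - 1L) / n_samples
  u <- tt / period
  # systolic bump at 15% of the cycle, dicrotic bump at 45%
  s <- exp(-((u - 0.15) / 0.07)^2) + 0.35 * exp(-((u - 0.45) / 0.12)^2)
  sm <- mean(s)
  # affine map a + b*s with discrete mean = mean_flow and max = peak_flow
  b <- (peak_flow - mean_flow) / (max(s) - sm)
  a <- mean_flow - b * sm
  q <- a + b * s
  if (min(q) <= 0)
    stop("requested (mean, peak) pair yields a non-positive waveform; reduce peak_flow",
         call. = FALSE)
  flow_waveform(tt, q, period)
}
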