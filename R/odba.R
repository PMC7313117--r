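# Overall dynamic body acceleration (ODBA) from tri-axial accelerometry.
# The static (postural/gravitational) component is a centred running mean
# over a 1-s window; the dynamic component is the residual, and per-sample
# ODBA is the sum of its absolute values across the three axes.

# centred running mean with shrinking windows at the edges (exact, O(n))
running_mean <- function(x, window) {
  n <- length(x)
  h <- floor(window / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1)
  hi <- pmin(i + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Split an acceleration stream into static and dynamic components
#'
#' The static component of each axis is the centred running mean over a
#' window of `window_s` seconds (shrinking at the stream edges); the dynamic
#' component is the raw signal minus the static one, so the two sum to the
#' raw stream exactly.
#'
#' @param acc Data frame with columns `ax`, `ay`, `az` (acceleration in g)
#'   sampled uniformly at `rate_hz`.
#' @param rate_hz Sampling rate (Hz).
#' @param window_s Smoothing window (seconds).
#' @return A list with data frames `static` and `dynamic`.
#' @export
static_dynamic_split <- function(acc, rate_hz = 25, window_s = 1) {
  window <- round(window_s * rate_hz)
  if (window > nrow(acc)) stop("smoothing window exceeds stream length", call. = FALSE)
  static <- data.frame(ax = running_mean(acc$ax, window),
                       ay = running_mean(acc$ay, window),
                       az = running_mean(acc$az, window))
  dynamic <- data.frame(ax = acc$ax - static$ax,
                        ay = acc$ay - static$ay,
                        az = acc$az - static$az)
  list(static = static, dynamic = dynamic)
}

#' Per-sample overall dynamic body acceleration
#'
#' @param dynamic Data frame of dynamic-component accelerations (`ax`, `ay`,
#'   `az`, in g), as returned by [static_dynamic_split()].
#' @return Numeric vector of per-sample ODBA (g).
#' @export
odba <- function(dynamic) {
  abs(dynamic$ax) + abs(dynamic$ay) + abs(dynamic$az)
}

#' Trip-level ODBA
#'
#' Mean per-sample ODBA over the samples whose timestamps fall within the
#' trip window, the per-trip energy-expenditure proxy.
#'
#' @param odba_t Numeric vector of per-sample ODBA.
#' @param t Sample timestamps (same length, `POSIXct` or numeric).
#' @param start_t,end_t Trip window (inclusive).
#' @return Mean ODBA in g, or `NA` (with a warning) when no sample falls in
#'   the window.
#' @export
trip_odba <- function(odba_t, t, start_t, end_t) {
  keep <- t >= start_t & t <= end_t
  if (!any(keep)) {
    warning("no acceleration samples within the trip window")
    return(NA_real_)
  }
  mean(odba_t[keep])
}
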