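#' Timecourse container
#'
#' A minimal container for one output trace: strictly increasing times (s)
#' and values (nM bound effector for simulations, background-subtracted AU
#' for bead data).
#'
#' @param times numeric, strictly increasing, length >= 2.
#' @param values numeric, same length, no missing values.
#' @return An object of class `timecourse`.
#' @export
timecourse <- function(times, values) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 2) stop("a timecourse needs at least 2 points")
  if (anyNA(times) || anyNA(values)) stop("missing values not allowed")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %d points over [%g, %g] s; peak %.4g, final %.4g\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              max(x$values), x$values[length(x$values)]))
  invisible(x)
}

#' Normalize a trace to its maximum
#'
#' Dividing by the peak keeps only the shape of the response (the absolute
#' response carries amplitude and shape; the normalized one shape only).
#' Idempotent.
#'
#' @param tc a [timecourse()].
#' @return A `timecourse` with maximum value 1.
#' @export
normalize_to_max <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  m <- max(tc$values)
  if (m <= 0) stop("cannot normalize: maximum value is not positive")
  timecourse(tc$times, tc$values / m)
}

#' Integrated signal of a trace
#'
#' Trapezoidal integral of the values over the full time span (units x s).
#'
#' @param tc a [timecourse()].
#' @return Scalar integral.
#' @export
integrated_signal <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  pracma::trapz(tc$times, tc$values)
}

#' Initial rate of activation
#'
#' Slope of the least-squares line through the early part of the trace: all
#' points up to the first time the value reaches `onset_frac` of the peak
#' (at least 3 points).
#'
#' @param tc a [timecourse()].
#' @param onset_frac fraction of peak defining the early window.
#' @return Slope in units/s (0 for a flat zero trace).
#' @export
initial_rate <- function(tc, onset_frac = 0.1) {
  stopifnot(inherits(tc, "timecourse"))
  if (length(tc$times) < 3) stop("initial_rate needs at least 3 points")
  pk <- max(tc$values)
  if (pk <= 0) return(0)
  i10 <- which(tc$values >= onset_frac * pk)[1]
  n <- max(i10, 3)
  stats::coef(stats::lm(tc$values[1:n] ~ tc$times[1:n]))[[2]]
}

final_value <- function(tc, n_tail = 3) {
  v <- tc$values
  mean(v[seq(max(1, length(v) - n_tail + 1), length(v))])
}

#' Transient (overshoot) score of a trace
#'
#' `(peak - final) / peak`, clipped to [0, 1], where `final` is the mean of
#' the last `n_tail` sample points (robust to per-point noise on
#' experimental-style traces). 0 for a monotone rise to plateau; ~1 for a
#' pulse that decays back to baseline.
#'
#' @param tc a [timecourse()].
#' @param n_tail number of trailing points averaged into the final value.
#' @return Scalar in [0, 1].
#' @export
transient_score <- function(tc, n_tail = 3) {
  stopifnot(inherits(tc, "timecourse"))
  pk <- max(tc$values)
  if (pk <= 0) stop("transient_score requires a positive peak")
  min(max((pk - final_value(tc, n_tail)) / pk, 0), 1)
}

#' Width of the pulse above half-prominence
#'
#' Total time spent above `(peak + final) / 2`, with linear interpolation of
#' the crossing times.
#'
#' @inheritParams transient_score
#' @return Width in seconds.
#' @export
pulse_width <- function(tc, n_tail = 3) {
  stopifnot(inherits(tc, "timecourse"))
  thr <- (max(tc$values) + final_value(tc, n_tail)) / 2
  t <- tc$times; v <- tc$values
  above <- v >= thr
  w <- 0
  for (i in seq_len(length(t) - 1)) {
    if (above[i] && above[i + 1]) {
      w <- w + (t[i + 1] - t[i])
    } else if (xor(above[i], above[i + 1])) {
      frac <- (thr - v[i]) / (v[i + 1] - v[i])
      tc_cross <- t[i] + frac * (t[i + 1] - t[i])
      w <- w + if (above[i]) tc_cross - t[i] else t[i + 1] - tc_cross
    }
  }
  w
}

#' All scalar features of a trace
#'
#' @inheritParams transient_score
#' @param onset_frac passed to [initial_rate()].
#' @return One-row data.frame: `integrated_signal`, `initial_rate`,
#'   `peak_value`, `peak_time`, `final_value`, `pulse_width_s`,
#'   `transient_score`.
#' @export
feature_set <- function(tc, n_tail = 3, onset_frac = 0.1) {
  stopifnot(inherits(tc, "timecourse"))
  i_pk <- which.max(tc$values)
  data.frame(integrated_signal = integrated_signal(tc),
             initial_rate = initial_rate(tc, onset_frac),
             peak_value = tc$values[i_pk],
             peak_time = tc$times[i_pk],
             final_value = final_value(tc, n_tail),
             pulse_width_s = pulse_width(tc, n_tail),
             transient_score = if (max(tc$values) > 0)
               transient_score(tc, n_tail) else 0)
}

#' Mutant distortion score
#'
#' Fold-change in integrated signal of a mutant system relative to wild
#' type under identical input: `integrated_signal(mutant) /
#' integrated_signal(wt)`.
#'
#' @param mutant,wt [timecourse()] objects on the same time grid.
#' @return Scalar fold-change.
#' @export
distortion_score <- function(mutant, wt) {
  stopifnot(inherits(mutant, "timecourse"), inherits(wt, "timecourse"))
  if (!isTRUE(all.equal(mutant$times, wt$times)))
    stop("traces must share the same time grid")
  denom <- integrated_signal(wt)
  if (denom <= 0) stop("wild-type integrated signal must be positive")
  integrated_signal(mutant) / denom
}

#' Feedback gain
#'
#' Ratio of the integrated signal of a feedback system to the matching
#' constitutive (non-feedback) system.
#'
#' @param fb,base [timecourse()] objects on the same time grid.
#' @return Scalar gain.
#' @export
feedback_gain <- function(fb, base) {
  distortion_score(fb, base)
}
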