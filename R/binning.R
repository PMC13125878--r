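# Retrospective cardiac/respiratory sorting of acquisition time points
# from surrogate signals (trigger times + respiratory amplitude).

#' Assign cardiac phase bins from trigger times
#'
#' Phase-based cardiac binning: each time point inside the trigger range
#' is mapped to `floor(n_bins * (t - t_k) / (t_{k+1} - t_k))` for its
#' enclosing RR interval, clamped to `n_bins - 1`. A time exactly at a
#' trigger starts a new beat (bin 0); this includes the final trigger.
#' Times outside `[first, last]` trigger are unassigned (`NA`) and their
#' count is attached as attribute `n_excluded`.
#'
#' @param times numeric vector of times, seconds.
#' @param triggers a [generate_cardiac_triggers()] object or a numeric
#'   vector of strictly increasing trigger times.
#' @param n_bins number of cardiac bins (default 10).
#' @return Integer vector of 0-based bin indices (`NA` outside range)
#'   with attribute `n_excluded`.
#' @export
assign_cardiac_phase <- function(times, triggers, n_bins = 10) {
  tt <- if (inherits(triggers, "cardiac_triggers")) triggers$trigger_times
        else as.numeric(triggers)
  if (length(tt) < 2L || any(diff(tt) <= 0))
    stop("triggers must be >= 2 strictly increasing times", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  bin <- rep(NA_integer_, length(times))
  inside <- times >= tt[1] & times <= tt[length(tt)]
  k <- findInterval(times[inside], tt, rightmost.closed = FALSE)
  # a time equal to the final trigger starts a (virtual) new beat: bin 0
  at_end <- k == length(tt)
  frac <- numeric(length(k))
  ok <- !at_end
  frac[ok] <- (times[inside][ok] - tt[k[ok]]) / (tt[k[ok] + 1] - tt[k[ok]])
  b <- pmin(as.integer(floor(n_bins * frac)), n_bins - 1L)
  b[at_end] <- 0L
  bin[inside] <- b
  attr(bin, "n_excluded") <- sum(!inside)
  bin
}

# centered moving average with shrinking windows at the record edges
moving_average <- function(x, half_width) {
  n <- length(x)
  if (half_width < 1L) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_width, 1L)
  hi <- pmin(seq_len(n) + half_width, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Assign respiratory states from waveform amplitude
#'
#' Amplitude-based respiratory sorting into four states: end-inhale (EI,
#' amplitude at or above the upper percentile threshold), end-exhale
#' (EE, at or below the lower threshold), and active inhale/exhale
#' (AIn/AEx) for the remaining middle band split by breathing direction.
#' Thresholds are sample percentiles (default 10th/90th, i.e. a
#' 10%/80%/10% amplitude split) of the baseline-corrected waveform;
#' baseline correction subtracts a centered moving average with a window
#' of two respiratory periods so that slow bellows drift does not skew
#' the thresholds. The breathing direction is the central-difference
#' slope of a lightly smoothed copy of the signal (moving average,
#' `slope_window` seconds): positive slope gives AIn, negative AEx, and
#' an exactly zero slope is tie-broken to AEx (end of the exhale
#' plateau).
#'
#' @param waveform a `resp_waveform` from
#'   [generate_respiratory_waveform()], or a numeric amplitude vector
#'   (then `dt` and `period` must be supplied).
#' @param lower,upper percentile thresholds in \[0,1\] (default 0.10 /
#'   0.90).
#' @param detrend logical; subtract the moving-average baseline before
#'   computing thresholds (default `TRUE`).
#' @param baseline_window baseline moving-average window, seconds
#'   (default two respiratory periods).
#' @param slope_window smoothing window for the slope estimate, seconds
#'   (default 0.5 s).
#' @param dt,period sampling step and respiratory period, seconds; taken
#'   from the waveform object when given.
#' @return Factor vector with levels `EE, AEx, AIn, EI`.
#' @export
assign_respiratory_state <- function(waveform, lower = 0.10, upper = 0.90,
                                     detrend = TRUE, baseline_window = NULL,
                                     slope_window = 0.5, dt = NULL,
                                     period = NULL) {
  if (inherits(waveform, "resp_waveform")) {
    amp <- waveform$amplitudes
    dt <- waveform$dt
    period <- waveform$period
  } else {
    amp <- as.numeric(waveform)
    if (is.null(dt)) stop("dt must be supplied for a bare amplitude vector",
                          call. = FALSE)
  }
  if (diff(range(amp)) < .Machine$double.eps * max(1, abs(amp[1])) * 8)
    stop("degenerate signal: constant waveform, percentile thresholds coincide",
         call. = FALSE)
  x <- amp
  if (detrend) {
    if (is.null(baseline_window)) {
      if (is.null(period))
        stop("period (or baseline_window) needed for baseline correction",
             call. = FALSE)
      baseline_window <- 2 * period
    }
    hw <- max(1L, round(baseline_window / (2 * dt)))
    x <- amp - moving_average(amp, hw)
  }
  q <- quantile(x, c(lower, upper), names = FALSE, type = 7)
  if (q[2] - q[1] <= 0)
    stop("degenerate signal: percentile thresholds coincide", call. = FALSE)
  sm <- moving_average(amp, max(1L, round(slope_window / (2 * dt))))
  n <- length(sm)
  slope <- c(sm[2] - sm[1], (sm[3:n] - sm[1:(n - 2)]) / 2, sm[n] - sm[n - 1])
  state <- ifelse(x >= q[2], "EI",
           ifelse(x <= q[1], "EE",
           ifelse(slope > 0, "AIn", "AEx")))
  factor(state, levels = RESP_STATES)
}

#' Joint cardiac/respiratory bin assignment
#'
#' Combines [assign_cardiac_phase()] and [assign_respiratory_state()]
#' on the respiratory waveform's time grid. Samples outside the cardiac
#' trigger range are excluded (not extrapolated); the excluded count is
#' attached as attribute `n_excluded`.
#'
#' @param waveform a `resp_waveform`.
#' @param triggers a `cardiac_triggers` object or numeric trigger times.
#' @param n_cardiac number of cardiac bins (default 10).
#' @param ... passed to [assign_respiratory_state()].
#' @return data.frame with columns `time` (s), `cardiac_bin` (0-based),
#'   `resp_state` (factor EE/AEx/AIn/EI), restricted to assigned
#'   samples; attribute `n_excluded` counts dropped samples.
#' @export
bin_signals <- function(waveform, triggers, n_cardiac = 10, ...) {
  stopifnot(inherits(waveform, "resp_waveform"))
  cb <- assign_cardiac_phase(waveform$times, triggers, n_cardiac)
  rs <- assign_respiratory_state(waveform, ...)
  keep <- !is.na(cb)
  out <- data.frame(time = waveform$times[keep],
                    cardiac_bin = cb[keep],
                    resp_state = rs[keep])
  attr(out, "n_excluded") <- attr(cb, "n_excluded")
  out
}

#' Bin occupancy summary
#'
#' Tabulates sample counts and fractions per (cardiac bin, respiratory
#' state), plus the marginal fractions. Fractions are over assigned
#' samples and sum to 1.
#'
#' @param assignment data.frame from [bin_signals()].
#' @return List with `joint` (counts matrix, cardiac bins x respiratory
#'   states), `cardiac_fraction`, `resp_fraction`, `n`.
#' @export
summarize_bins <- function(assignment) {
  if (nrow(assignment) == 0L) stop("empty assignment", call. = FALSE)
  joint <- table(cardiac_bin = assignment$cardiac_bin,
                 resp_state = assignment$resp_state)
  n <- sum(joint)
  list(joint = joint,
       cardiac_fraction = rowSums(joint) / n,
       resp_fraction = colSums(joint) / n,
       n = n)
}
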