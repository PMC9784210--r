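# Pulse-train representation: the applied voltage is piecewise constant in
# time; segments() exposes the exact on/off timeline the solvers step over.

#' Define a PEF pulse train
#'
#' A monopolar train of rectangular voltage pulses followed by a latency
#' observation window. Defaults are the study protocol: 10 pulses of 1000 V,
#' 100 us wide, separated by 100 us, observed for 10 ms after the last pulse.
#'
#' @param n_pulses number of pulses (>= 1).
#' @param amplitude pulse amplitude, V (zero is allowed for sham runs).
#' @param pulse_width pulse width, microseconds.
#' @param interval inter-pulse interval, microseconds (100 or 10 in the study).
#' @param latency_window post-train observation window, milliseconds.
#' @return an object of class `pef_pulse_train`.
#' @export
pulse_train <- function(n_pulses = 10, amplitude = 1000, pulse_width = 100,
                        interval = 100, latency_window = 10) {
  stopifnot(n_pulses >= 1, amplitude >= 0, pulse_width > 0, interval > 0,
            latency_window > 0)
  structure(list(n_pulses = as.integer(n_pulses), amplitude = amplitude,
                 pulse_width = pulse_width, interval = interval,
                 latency_window = latency_window),
            class = "pef_pulse_train")
}

#' Applied voltage at a given time
#'
#' Pulse k (k = 0 .. n-1) is on for t in
#' [k (width + interval), k (width + interval) + width); the voltage is zero
#' in the intervals and after the last pulse. Vectorised over `t_us`.
#'
#' @param train a [pulse_train()].
#' @param t_us time since the start of the train, microseconds (>= 0).
#' @return voltage in V.
#' @export
voltage_at <- function(train, t_us) {
  if (any(t_us < 0)) stop("t_us must be non-negative")
  period <- train$pulse_width + train$interval
  k <- floor(t_us / period)
  phase <- t_us - k * period
  on <- k < train$n_pulses & phase < train$pulse_width
  ifelse(on, train$amplitude, 0)
}

#' End of the last pulse, in microseconds
#'
#' @param train a [pulse_train()].
#' @return time of the falling edge of pulse n, us.
#' @export
train_end_us <- function(train) {
  (train$n_pulses - 1) * (train$pulse_width + train$interval) + train$pulse_width
}

#' Piecewise-constant timeline of the train
#'
#' Contiguous, non-overlapping segments covering `[0, end-of-last-pulse +
#' latency]`: n on-segments, n-1 off-intervals, and one final latency segment.
#'
#' @param train a [pulse_train()].
#' @return data.frame with columns `t_start_us`, `t_end_us`, `on` (logical)
#'   and `kind` ("pulse", "interval", "latency").
#' @export
segments <- function(train) {
  period <- train$pulse_width + train$interval
  n <- train$n_pulses
  starts <- ends <- numeric(0)
  kind <- character(0)
  for (k in seq_len(n) - 1) {
    starts <- c(starts, k * period)
    ends <- c(ends, k * period + train$pulse_width)
    kind <- c(kind, "pulse")
    if (k < n - 1) {
      starts <- c(starts, k * period + train$pulse_width)
      ends <- c(ends, (k + 1) * period)
      kind <- c(kind, "interval")
    }
  }
  starts <- c(starts, train_end_us(train))
  ends <- c(ends, train_end_us(train) + train$latency_window * 1000)
  kind <- c(kind, "latency")
  data.frame(t_start_us = starts, t_end_us = ends, on = kind == "pulse",
             kind = kind, stringsAsFactors = FALSE)
}
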