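# Zero-phase Butterworth filtering with reflective padding.
#
# "4th-order zero-phase" is read as a 4th-order design applied forward and
# backward (effective 8th-order magnitude response); set order = 2 for the
# alternative reading. Reflective padding of 3x the filter settling length
# keeps edge transients away from the analysed samples.
.zero_phase_filter <- function(x, rate, cutoff, type, order = 4) {
  nyq <- rate / 2
  if (any(cutoff >= nyq)) stop("filter cutoff at or above Nyquist frequency")
  if (any(cutoff <= 0)) stop("filter cutoff must be positive")
  bf <- signal::butter(order, cutoff / nyq, type = type)
  if (type == "low") {
    # at very low normalised cutoffs the designed coefficients lose the unit
    # DC gain to cancellation error; restore it explicitly
    g0 <- sum(bf$b) / sum(bf$a)
    bf$b <- bf$b / g0
  }
  # IIR transients decay over ~1/cutoff seconds; pad generously so the
  # zero-initial-condition transients of the forward and backward passes
  # never reach the analysed samples
  npad <- ceiling(6 * rate / min(cutoff))
  if (length(x) <= npad)
    stop("series shorter than 3x the filter settling length (needs > ",
         npad, " samples at this cutoff)")
  # even (mirror) reflection: preserves the local mean at the edges, which
  # matters for the non-negative rectified signal fed to the low-pass
  head_pad <- x[(npad + 1):2]
  tail_pad <- x[(length(x) - 1):(length(x) - npad)]
  padded <- c(head_pad, x, tail_pad)
  y <- signal::filtfilt(bf, padded)
  y[(npad + 1):(npad + length(x))]
}

#' Linear-envelope extraction from raw EMG
#'
#' The standard surface-EMG envelope pipeline: 4th-order zero-phase
#' Butterworth high-pass at 40 Hz, demean, full-wave rectify, then 4th-order
#' zero-phase Butterworth low-pass at a gait-cycle-dependent cutoff of
#' 3.5 / cycle_period Hz. Small negative ripple left by the low-pass is
#' clamped to zero (envelopes are physically non-negative).
#'
#' @param raw numeric vector of raw EMG samples.
#' @param rate sample rate (Hz), must exceed twice the 40 Hz high-pass cutoff.
#' @param cycle_period gait-cycle period (s), > 0; sets the low-pass cutoff.
#' @param highpass high-pass cutoff (Hz, default 40).
#' @param order Butterworth design order applied forward-backward (default 4).
#' @return non-negative envelope series, same length as \code{raw}.
#' @export
emg_envelope <- function(raw, rate, cycle_period, highpass = 40, order = 4) {
  if (cycle_period <= 0) stop("cycle_period must be positive")
  if (rate <= 2 * highpass) stop("sample rate must exceed twice the high-pass cutoff")
  hp <- .zero_phase_filter(raw, rate, highpass, "high", order)
  hp <- hp - mean(hp)
  rect <- abs(hp)
  env <- .zero_phase_filter(rect, rate, 3.5 / cycle_period, "low", order)
  pmax(env, 0)
}

#' Shift a continuous record by an electromechanical delay
#'
#' Output sample at time t equals the input at t - delay (linear
#' interpolation for non-integer sample shifts). The leading gap is held at
#' the record's first value, so analysed cycles should start at least one
#' delay-length after the record starts; output length is preserved.
#'
#' @param x numeric series.
#' @param rate sample rate (Hz).
#' @param delay delay in milliseconds, >= 0 and shorter than the record.
#' @return shifted series, same length as \code{x}.
#' @export
delay_shift <- function(x, rate, delay) {
  if (delay < 0) stop("delay must be non-negative")
  n <- length(x)
  shift <- delay / 1000 * rate
  if (shift >= n) stop("delay longer than the record")
  if (shift == 0) return(x)
  idx <- seq_len(n) - shift
  stats::approx(seq_len(n), x, xout = pmax(idx, 1), rule = 2)$y
}

# Resample one heel-strike-to-heel-strike interval to the 101-point
# percent-of-cycle grid by linear interpolation (no normalisation).
.resample_cycle <- function(x, rate, t0, t1, n_points = 101L) {
  times <- seq(t0, t1, length.out = n_points)
  src_t <- (seq_along(x) - 1) / rate
  stats::approx(src_t, x, xout = times, rule = 2)$y
}

#' Resample a continuous series into per-cycle 101-point series
#'
#' Utility used for kinematics and activations: each heel-strike interval is
#' linearly resampled onto the 0-100\% gait-cycle grid. No amplitude
#' normalisation is applied.
#'
#' @param x numeric series starting at time 0.
#' @param rate sample rate (Hz).
#' @param heel_strikes ordered heel-strike event times (s), >= 2 of them.
#' @param n_points points per cycle (default 101).
#' @return list of numeric vectors, one per cycle.
#' @export
resample_cycles <- function(x, rate, heel_strikes, n_points = 101L) {
  if (length(heel_strikes) < 2L) stop("need at least two heel strikes")
  lapply(seq_len(length(heel_strikes) - 1L), function(c) {
    .resample_cycle(x, rate, heel_strikes[c], heel_strikes[c + 1L], n_points)
  })
}

#' Segment an envelope into normalised per-cycle series
#'
#' Each heel-strike interval is resampled to 101 points, offset by its own
#' minimum (per-cycle minimum becomes exactly 0), and all cycles are then
#' divided by the maximum over the analysed cycles (global maximum becomes
#' exactly 1). An all-zero envelope is returned as all-zero cycles with a
#' warning (no division).
#'
#' @inheritParams resample_cycles
#' @return list with \code{cycles} (list of 101-point vectors) and
#'   \code{trial_max} (the pre-normalisation maximum, for provenance).
#' @export
segment_normalize <- function(x, rate, heel_strikes, n_points = 101L) {
  cycles <- resample_cycles(x, rate, heel_strikes, n_points)
  cycles <- lapply(cycles, function(c) c - min(c))
  m <- max(vapply(cycles, max, numeric(1)))
  if (m == 0) {
    warning("all-zero envelope: returning unnormalised zero cycles")
    return(list(cycles = cycles, trial_max = 0))
  }
  list(cycles = lapply(cycles, function(c) c / m), trial_max = m)
}

#' Per-muscle EMG cycle set
#'
#' Container for the per-cycle 101-point envelopes of one muscle in one of
#' the four signal variants.
#'
#' @param muscle muscle label.
#' @param variant one of \code{"basic"}, \code{"scaled"}, \code{"delayed"},
#'   \code{"calibrated"}.
#' @param cycles list of equal-length non-negative numeric vectors.
#' @param provenance named list of processing parameters.
#' @return an object of class \code{emg_cycle_set}.
#' @export
emg_cycle_set <- function(muscle, variant, cycles, provenance = list()) {
  variant <- match.arg(variant, c("basic", "scaled", "delayed", "calibrated"))
  lens <- vapply(cycles, length, integer(1))
  if (length(unique(lens)) != 1L) stop("all cycles must have equal length")
  if (any(vapply(cycles, function(c) any(c < 0), logical(1))))
    stop("envelope cycles must be non-negative")
  structure(list(muscle = muscle, variant = variant, cycles = cycles,
                 provenance = provenance),
            class = "emg_cycle_set")
}

#' Build the four EMG signal variants for one muscle
#'
#' From one continuous raw EMG record: \code{basic} is the
#' envelope -> segment -> normalise pipeline on the undelayed record;
#' \code{delayed} is the same pipeline applied to the record shifted by the
#' leg's electromechanical delay; \code{scaled} = basic x scale and
#' \code{calibrated} = delayed x scale pointwise, so that
#' calibrated / scale = delayed by construction.
#'
#' @param raw numeric vector of raw EMG samples starting at time 0.
#' @param rate sample rate (Hz).
#' @param cycle_period nominal gait-cycle period (s) for the low-pass cutoff.
#' @param heel_strikes ordered heel-strike times (s).
#' @param scale muscle-specific EMG scale factor in (0, 1].
#' @param delay electromechanical delay (ms), >= 0.
#' @param muscle muscle label stored in the result.
#' @return named list of four \code{\link{emg_cycle_set}} objects
#'   (\code{basic}, \code{scaled}, \code{delayed}, \code{calibrated}).
#' @export
make_variants <- function(raw, rate, cycle_period, heel_strikes,
                          scale, delay, muscle = "muscle") {
  if (scale <= 0 || scale > 1) stop("scale must lie in (0, 1]")
  if (delay < 0) stop("delay must be non-negative")
  env <- emg_envelope(raw, rate, cycle_period)
  basic <- segment_normalize(env, rate, heel_strikes)
  env_d <- delay_shift(env, rate, delay)
  delayed <- segment_normalize(env_d, rate, heel_strikes)
  prov <- list(rate = rate, cycle_period = cycle_period,
               scale = scale, delay_ms = delay)
  list(
    basic = emg_cycle_set(muscle, "basic", basic$cycles, prov),
    scaled = emg_cycle_set(muscle, "scaled",
                           lapply(basic$cycles, `*`, scale), prov),
    delayed = emg_cycle_set(muscle, "delayed", delayed$cycles, prov),
    calibrated = emg_cycle_set(muscle, "calibrated",
                               lapply(delayed$cycles, `*`, scale), prov))
}

#' Estimate a delay between two continuous records by cross-correlation
#'
#' Returns the lag (ms) at which the cross-correlation between the reference
#' and the delayed record peaks; used to verify electromechanical-delay
#' handling.
#'
#' @param reference,delayed numeric series of equal length.
#' @param rate sample rate (Hz).
#' @param max_lag_ms largest lag searched (ms).
#' @return estimated delay in milliseconds.
#' @export
estimate_delay <- function(reference, delayed, rate, max_lag_ms = 200) {
  max_lag <- round(max_lag_ms / 1000 * rate)
  n <- length(reference)
  if (length(delayed) != n) stop("series lengths differ")
  x <- reference - mean(reference)
  y <- delayed - mean(delayed)
  # overlap-normalised cross-correlation: dividing by the overlap length
  # avoids the 1/n taper that biases broad peaks toward zero lag
  cc <- vapply(0:max_lag, function(k)
    sum(x[seq_len(n - k)] * y[seq_len(n - k) + k]) / (n - k), numeric(1))
  (which.max(cc) - 1L) / rate * 1000
}
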