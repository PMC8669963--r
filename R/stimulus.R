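#' DBS stimulus specification
#'
#' Describes the rectangular pulse train used as DBS input: a train of
#' pulses at `frequency_hz` whose value during a pulse is `amplitude`
#' (added to the phase velocity of every targeted oscillator) and zero
#' between pulses. One iteration corresponds to `iteration_duration_ms`
#' simulated milliseconds (default 1 ms, so 130 Hz yields a pulse roughly
#' every 7.7 iterations).
#'
#' @param frequency_hz Pulse rate in Hz, `> 0`. Default 130.
#' @param amplitude Phase-velocity increment during a pulse, dimensionless.
#'   Default 3.0.
#' @param pulse_width_iterations Integer `>= 1`, iterations a pulse lasts.
#'   Default 1.
#' @param iteration_duration_ms Simulated milliseconds per iteration, `> 0`.
#'   Default 1.0.
#' @param targets Integer indices of the oscillators receiving input, or
#'   `NULL` (default) for all oscillators.
#' @return An object of class `stimulus_spec`.
#' @export
#' @examples
#' stimulus_spec()  # the default 130 Hz / 3.0 train
stimulus_spec <- function(frequency_hz = 130, amplitude = 3.0,
                          pulse_width_iterations = 1L,
                          iteration_duration_ms = 1.0,
                          targets = NULL) {
  stopifnot(is.numeric(frequency_hz), length(frequency_hz) == 1L,
            is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(pulse_width_iterations), length(pulse_width_iterations) == 1L,
            is.numeric(iteration_duration_ms), length(iteration_duration_ms) == 1L)
  if (frequency_hz <= 0) stop("invalid stimulus: frequency_hz must be > 0")
  if (!is.finite(amplitude)) stop("invalid stimulus: amplitude must be finite")
  if (pulse_width_iterations < 1 ||
      pulse_width_iterations != round(pulse_width_iterations)) {
    stop("invalid stimulus: pulse_width_iterations must be an integer >= 1")
  }
  if (iteration_duration_ms <= 0) {
    stop("invalid stimulus: iteration_duration_ms must be > 0")
  }
  # consecutive pulse onsets must not overlap
  if (pulse_width_iterations * frequency_hz * iteration_duration_ms / 1000 >= 1) {
    stop("invalid stimulus: pulses overlap ",
         "(pulse_width_iterations * frequency_hz * iteration_duration_ms/1000 must be < 1)")
  }
  if (!is.null(targets)) {
    if (!is.numeric(targets) || any(targets < 1) ||
        any(targets != round(targets))) {
      stop("invalid stimulus: targets must be positive integer indices or NULL")
    }
    targets <- as.integer(sort(unique(targets)))
  }
  structure(
    list(frequency_hz = frequency_hz, amplitude = amplitude,
         pulse_width_iterations = as.integer(pulse_width_iterations),
         iteration_duration_ms = iteration_duration_ms,
         targets = targets),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "DBS stimulus: %g Hz, amplitude %g, pulse width %d it, %g ms/it, targets: %s\n",
    x$frequency_hz, x$amplitude, x$pulse_width_iterations,
    x$iteration_duration_ms,
    if (is.null(x$targets)) "all" else paste(x$targets, collapse = ",")))
  invisible(x)
}

# TRUE at iterations where a new pulse begins. A pulse starts at t = 0 and at
# every t where floor(t*delta*f) exceeds floor((t-1)*delta*f), with delta the
# iteration duration in seconds.
pulse_onset <- function(spec, iteration) {
  delta <- spec$iteration_duration_ms / 1000
  f <- spec$frequency_hz
  iteration == 0 |
    (iteration > 0 &
       floor(iteration * delta * f) > floor((iteration - 1) * delta * f))
}

# 0/1 indicator that iteration t falls inside a pulse (an onset occurred at
# t, t-1, ..., t-width+1). Vectorised over `iterations`.
pulse_indicator <- function(spec, iterations) {
  w <- spec$pulse_width_iterations
  if (w == 1L) return(as.numeric(pulse_onset(spec, iterations)))
  inside <- rep(FALSE, length(iterations))
  for (k in 0:(w - 1L)) {
    s <- iterations - k
    inside <- inside | (s >= 0 & pulse_onset(spec, s))
  }
  as.numeric(inside)
}

#' DBS drive value at an iteration
#'
#' Returns the instantaneous drive of the rectangular pulse train: 0 when
#' `dbs_on` is `FALSE` or between pulses, and `spec$amplitude` during a
#' pulse. The pulse clock runs on the global iteration counter, so
#' consecutive schedule blocks share one continuous train.
#'
#' @param spec A [stimulus_spec()].
#' @param iteration Non-negative integer iteration index (vectorised).
#' @param dbs_on Logical flag: is stimulation switched on?
#' @return Numeric drive value(s), same length as `iteration`.
#' @export
#' @examples
#' dbs_waveform(stimulus_spec(), 0:10, dbs_on = TRUE)
dbs_waveform <- function(spec, iteration, dbs_on) {
  stopifnot(inherits(spec, "stimulus_spec"), is.logical(dbs_on),
            length(dbs_on) == 1L)
  if (any(iteration < 0)) stop("dbs_waveform: iteration must be >= 0")
  if (!dbs_on) return(rep(0, length(iteration)))
  spec$amplitude * pulse_indicator(spec, iteration)
}

#' Count pulse onsets over a block of iterations
#'
#' Convenience for checking pulse accounting: the number of pulse onsets in
#' the half-open global-iteration window `[start, start + n_iterations)`.
#'
#' @param spec A [stimulus_spec()].
#' @param n_iterations Block length in iterations.
#' @param start First global iteration of the block (default 0).
#' @return Integer onset count.
#' @export
count_pulse_onsets <- function(spec, n_iterations, start = 0L) {
  stopifnot(n_iterations >= 1)
  its <- seq.int(start, start + n_iterations - 1L)
  sum(pulse_onset(spec, its))
}
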