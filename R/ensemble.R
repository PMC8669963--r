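#' Draw natural frequencies for an oscillator ensemble
#'
#' Natural frequencies omega_i are independent uniform draws on the open
#' interval (0, 1), in radians per iteration.
#'
#' @param n Oscillator count, `>= 2`.
#' @param seed Optional integer; if given, `set.seed(seed)` is called first.
#' @return Numeric vector of length `n`, each element strictly inside (0, 1).
#' @export
#' @examples
#' draw_natural_frequencies(5, seed = 1)
draw_natural_frequencies <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("invalid network: n must be an integer >= 2")
  }
  if (!is.null(seed)) set.seed(seed)
  omega <- stats::runif(n)
  # runif can in principle return an endpoint; redraw (probability ~ 0)
  while (any(bad <- (omega <= 0 | omega >= 1))) omega[bad] <- stats::runif(sum(bad))
  omega
}

#' Draw initial phases for an oscillator ensemble
#'
#' Initial phases are uniform on (0, 2*pi), one per oscillator.
#'
#' @inheritParams draw_natural_frequencies
#' @return Numeric vector of length `n` of radians.
#' @export
draw_initial_phases <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("invalid network: n must be an integer >= 2")
  }
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n, 0, 2 * pi)
}

#' Construct an oscillator ensemble
#'
#' Bundles the per-oscillator natural frequencies and current (unwrapped)
#' phases. Phases are stored unwrapped — they are never reduced modulo
#' 2*pi during integration; only phase differences enter the dynamics and
#' the synchronization metrics, for which wrapping is immaterial.
#'
#' @param natural_frequencies Length-n numeric, each in (0, 1).
#' @param phases Length-n numeric, radians (unwrapped).
#' @return An object of class `oscillator_ensemble` with fields `n`,
#'   `natural_frequencies`, `phases`.
#' @export
oscillator_ensemble <- function(natural_frequencies, phases) {
  stopifnot(is.numeric(natural_frequencies), is.numeric(phases))
  n <- length(natural_frequencies)
  if (n < 2) stop("invalid network: need at least 2 oscillators")
  if (length(phases) != n) {
    stop("configuration error: natural_frequencies and phases differ in length")
  }
  if (any(natural_frequencies <= 0 | natural_frequencies >= 1)) {
    stop("invalid network: natural frequencies must lie in (0, 1)")
  }
  if (any(!is.finite(phases))) stop("invalid network: phases must be finite")
  structure(
    list(n = n,
         natural_frequencies = as.numeric(natural_frequencies),
         phases = as.numeric(phases)),
    class = "oscillator_ensemble"
  )
}

#' Construct a simulation state
#'
#' The simulation state carries the ensemble, the global iteration counter
#' (which clocks the DBS pulse train across consecutive schedule blocks) and
#' the seed that generated the run, for provenance.
#'
#' @param ensemble An [oscillator_ensemble()].
#' @param iteration Integer step counter `>= 0` (default 0).
#' @param rng_seed Integer seed recorded for provenance (default `NA`).
#' @return An object of class `simulation_state`.
#' @export
simulation_state <- function(ensemble, iteration = 0L, rng_seed = NA_integer_) {
  stopifnot(inherits(ensemble, "oscillator_ensemble"))
  if (iteration < 0 || iteration != round(iteration)) {
    stop("configuration error: iteration must be a non-negative integer")
  }
  structure(
    list(ensemble = ensemble,
         iteration = as.integer(iteration),
         rng_seed = rng_seed),
    class = "simulation_state"
  )
}
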