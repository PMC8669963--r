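# One explicit-Euler update of the phase vector.
#
# The coupling term (1/N) * sum_j K_ij * sin(phi_j - phi_i) is evaluated via
# the identity sin(phi_j - phi_i) = sin(phi_j)cos(phi_i) - cos(phi_j)sin(phi_i),
# i.e. two matrix-vector products, so a step is O(n^2) BLAS work. Under the
# "repulsive" convention the sign of the coupling term is flipped, matching
# the literal printed form sin(phi_i - phi_j).
advance_phases <- function(phases, omega, K, n, drive, dt,
                           sign_convention = "attractive") {
  s <- sin(phases)
  c <- cos(phases)
  coup <- (c * as.vector(K %*% s) - s * as.vector(K %*% c)) / n
  if (sign_convention == "repulsive") coup <- -coup
  phases + dt * (omega + coup + drive)
}

# Maximum |phase| before the run is declared numerically unstable.
PHASE_OVERFLOW_BOUND <- 1e9

check_phases_finite <- function(phases, iteration) {
  if (any(!is.finite(phases)) || max(abs(phases)) > PHASE_OVERFLOW_BOUND) {
    stop(sprintf(
      "numerical overflow: non-finite or runaway phase at iteration %d (|phi| > %g); unstable dt/K combination",
      iteration, PHASE_OVERFLOW_BOUND))
  }
  invisible(TRUE)
}

#' Advance the simulation by one explicit-Euler step
#'
#' Applies one step of
#' `phi_i <- phi_i + dt * (omega_i + (1/N) * sum_j K_ij sin(phi_j - phi_i) + I_i)`
#' and increments the iteration counter. Phases are kept unwrapped.
#'
#' @param state A [simulation_state()].
#' @param coupling A [build_coupling_matrix()] result with `coupling$n`
#'   equal to the ensemble size.
#' @param drive Per-oscillator drive values: a scalar (recycled) or a
#'   length-n numeric vector.
#' @param dt Time step in iteration units, `> 0` (default 1).
#' @param sign_convention `"attractive"` (default, `sin(phi_j - phi_i)`) or
#'   `"repulsive"` (the literal printed `sin(phi_i - phi_j)`).
#' @return The advanced [simulation_state()].
#' @export
euler_step <- function(state, coupling, drive, dt = 1,
                       sign_convention = c("attractive", "repulsive")) {
  stopifnot(inherits(state, "simulation_state"),
            inherits(coupling, "coupling_matrix"))
  sign_convention <- match.arg(sign_convention)
  ens <- state$ensemble
  if (coupling$n != ens$n) {
    stop("configuration error: coupling matrix size does not match ensemble size")
  }
  if (length(drive) == 1L) drive <- rep(as.numeric(drive), ens$n)
  if (length(drive) != ens$n) {
    stop("configuration error: drive length does not match ensemble size")
  }
  if (dt <= 0) stop("configuration error: dt must be > 0")
  phases <- advance_phases(ens$phases, ens$natural_frequencies,
                           coupling$strengths, ens$n, drive, dt,
                           sign_convention)
  check_phases_finite(phases, state$iteration + 1L)
  state$ensemble$phases <- phases
  state$iteration <- state$iteration + 1L
  state
}

#' Construct a phase trajectory
#'
#' @param phases T x n numeric matrix of unwrapped phases (radians), one row
#'   per recorded iteration.
#' @param block_label Text label of the schedule block (default "").
#' @param iteration_offset Global iteration index of the first recorded row
#'   minus one, i.e. the state's counter when the block started (default 0).
#' @return An object of class `phase_trajectory`.
#' @export
phase_trajectory <- function(phases, block_label = "", iteration_offset = 0L) {
  phases <- as.matrix(phases)
  if (nrow(phases) < 1 || ncol(phases) < 2) {
    stop("invalid trajectory: need T >= 1 iterations and n >= 2 oscillators")
  }
  if (any(!is.finite(phases))) stop("invalid trajectory: non-finite phases")
  structure(
    list(phases = phases, block_label = as.character(block_label),
         iteration_offset = as.integer(iteration_offset)),
    class = "phase_trajectory"
  )
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("Phase trajectory '%s': %d iterations x %d oscillators (offset %d)\n",
              x$block_label, nrow(x$phases), ncol(x$phases), x$iteration_offset))
  invisible(x)
}

#' Integrate one schedule block
#'
#' Runs `n_iterations` explicit-Euler steps with [dbs_waveform()] supplying
#' the drive (gated by `dbs_on`), recording the phase vector after every
#' step. The returned state carries the final phases and the advanced global
#' iteration counter, so consecutive blocks form one continuous simulation:
#' chaining two blocks is bit-identical to one block of the combined length.
#'
#' @param state A [simulation_state()].
#' @param coupling A `coupling_matrix`; held fixed for the whole block
#'   (static plasticity).
#' @param spec A [stimulus_spec()].
#' @param dbs_on Logical: is DBS switched on during this block?
#' @param n_iterations Block length, `>= 1`.
#' @param dt Time step in iteration units (default 1).
#' @param sign_convention See [euler_step()].
#' @param block_label Label stored on the trajectory (default from `dbs_on`).
#' @return A list with elements `trajectory` (a [phase_trajectory()], one row
#'   per iteration) and `state` (the final [simulation_state()]).
#' @export
integrate_block <- function(state, coupling, spec, dbs_on, n_iterations,
                            dt = 1,
                            sign_convention = c("attractive", "repulsive"),
                            block_label = NULL) {
  stopifnot(inherits(state, "simulation_state"),
            inherits(coupling, "coupling_matrix"),
            inherits(spec, "stimulus_spec"),
            is.logical(dbs_on), length(dbs_on) == 1L)
  sign_convention <- match.arg(sign_convention)
  if (n_iterations < 1 || n_iterations != round(n_iterations)) {
    stop("configuration error: n_iterations must be an integer >= 1")
  }
  n_iterations <- as.integer(n_iterations)
  ens <- state$ensemble
  n <- ens$n
  if (coupling$n != n) {
    stop("configuration error: coupling matrix size does not match ensemble size")
  }
  if (is.null(block_label)) block_label <- if (dbs_on) "DBS ON" else "DBS OFF"

  it0 <- state$iteration
  # drive evaluated at the iteration the step starts from, on the global clock
  step_iters <- seq.int(it0, it0 + n_iterations - 1L)
  drive_scalar <- dbs_waveform(spec, step_iters, dbs_on)
  target_mask <- if (is.null(spec$targets)) rep(1, n) else {
    if (max(spec$targets) > n) {
      stop("configuration error: stimulus targets exceed ensemble size")
    }
    mask <- numeric(n); mask[spec$targets] <- 1; mask
  }

  phases <- ens$phases
  omega <- ens$natural_frequencies
  K <- coupling$strengths
  traj <- matrix(NA_real_, n_iterations, n)
  for (k in seq_len(n_iterations)) {
    phases <- advance_phases(phases, omega, K, n,
                             drive_scalar[k] * target_mask, dt,
                             sign_convention)
    traj[k, ] <- phases
  }
  check_phases_finite(phases, it0 + n_iterations)

  state$ensemble$phases <- phases
  state$iteration <- it0 + n_iterations
  list(trajectory = phase_trajectory(traj, block_label, it0),
       state = state)
}
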