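#' Plasticity signature of a virtual patient
#'
#' A plasticity signature is the quadruple (alpha_p, alpha_d, tau_p, tau_d)
#' that fixes the coupling strength of every oscillator pair for the lifetime
#' of a simulation: alpha_p scales the potentiation (LTP-like) contribution,
#' alpha_d the depotentiation (LTD-like) contribution, and tau_p / tau_d are
#' the damping parameters entering the exponents (both 0.5 by default).
#'
#' @param alpha_p Potentiation rate, dimensionless, `>= 0`.
#' @param alpha_d Depotentiation rate, dimensionless, `>= 0`.
#' @param tau_p Potentiation damping parameter, `> 0`. Default 0.5.
#' @param tau_d Depotentiation damping parameter, `> 0`. Default 0.5.
#' @param label Optional free-text condition name; defaults to
#'   `"alpha_p=<x>, alpha_d=<y>"`.
#' @return An object of class `plasticity_signature`.
#' @seealso [coupling_strength()], [build_coupling_matrix()],
#'   [condition_bank()] for the seven built-in conditions.
#' @export
#' @examples
#' plasticity_signature(8.0, 0.001)
plasticity_signature <- function(alpha_p, alpha_d, tau_p = 0.5, tau_d = 0.5,
                                 label = NULL) {
  stopifnot(is.numeric(alpha_p), length(alpha_p) == 1L, is.finite(alpha_p),
            is.numeric(alpha_d), length(alpha_d) == 1L, is.finite(alpha_d),
            is.numeric(tau_p), length(tau_p) == 1L, is.finite(tau_p),
            is.numeric(tau_d), length(tau_d) == 1L, is.finite(tau_d))
  if (alpha_p < 0) stop("invalid plasticity signature: alpha_p must be >= 0")
  if (alpha_d < 0) stop("invalid plasticity signature: alpha_d must be >= 0")
  if (tau_p <= 0) stop("invalid plasticity signature: tau_p must be > 0")
  if (tau_d <= 0) stop("invalid plasticity signature: tau_d must be > 0")
  if (is.null(label)) {
    label <- sprintf("alpha_p=%g, alpha_d=%g", alpha_p, alpha_d)
  }
  structure(
    list(alpha_p = alpha_p, alpha_d = alpha_d,
         tau_p = tau_p, tau_d = tau_d, label = as.character(label)),
    class = "plasticity_signature"
  )
}

#' @export
print.plasticity_signature <- function(x, ...) {
  cat(sprintf(
    "Plasticity signature '%s': alpha_p = %g, alpha_d = %g, tau_p = %g, tau_d = %g\n",
    x$label, x$alpha_p, x$alpha_d, x$tau_p, x$tau_d))
  invisible(x)
}

#' Coupling strength of one oscillator pair
#'
#' Evaluates the static plasticity-determined coupling
#' `K = alpha_p * exp(r1 * tau_p) - alpha_d * exp(r2 * tau_d)`.
#' The sign may be negative when the depotentiation term dominates. The
#' exponent is the literal form `exp(r * tau)`; see the methods vignette for
#' the discussion of this choice.
#'
#' @param sig A [plasticity_signature()].
#' @param r1,r2 Pair-specific random draws in the open interval (0, 1).
#'   Vectorised: `r1` and `r2` may be equal-length vectors.
#' @return Numeric vector of coupling strengths.
#' @export
#' @examples
#' sig <- plasticity_signature(8.0, 0.001)
#' coupling_strength(sig, 0.5, 0.2)
coupling_strength <- function(sig, r1, r2) {
  stopifnot(inherits(sig, "plasticity_signature"),
            is.numeric(r1), is.numeric(r2), length(r1) == length(r2))
  if (any(r1 <= 0 | r1 >= 1) || any(r2 <= 0 | r2 >= 1)) {
    stop("coupling_strength: r1 and r2 must lie in the open interval (0, 1)")
  }
  sig$alpha_p * exp(r1 * sig$tau_p) - sig$alpha_d * exp(r2 * sig$tau_d)
}

#' Build the static coupling matrix of a network
#'
#' Draws, for each unordered oscillator pair, one (r1, r2) pair of uniform
#' variates on (0, 1) (r2 is redrawn on the probability-zero event r1 == r2)
#' and fills a symmetric coupling matrix with zero diagonal whose entries are
#' [coupling_strength()] evaluated at those draws. The matrix is static: it
#' never changes during a simulation run.
#'
#' @param sig A [plasticity_signature()].
#' @param n Oscillator count, `>= 2`.
#' @param seed Optional integer; if given, `set.seed(seed)` is called first
#'   so the matrix is reproducible. If `NULL` the current RNG state is used.
#' @return An object of class `coupling_matrix` with fields `n`, `strengths`
#'   (n x n symmetric, zero diagonal), `draws_r1`, `draws_r2` (the generating
#'   variates, symmetric, `NA` on the diagonal) and `signature`.
#' @export
#' @examples
#' cm <- build_coupling_matrix(plasticity_signature(8.0, 0.001), n = 10, seed = 1)
#' isSymmetric(cm$strengths)
build_coupling_matrix <- function(sig, n, seed = NULL) {
  stopifnot(inherits(sig, "plasticity_signature"))
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("invalid network: n must be an integer >= 2")
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  m <- n * (n - 1L) / 2L
  r1 <- stats::runif(m)
  r2 <- stats::runif(m)
  # r1 == r2 has probability zero for continuous draws; guard anyway
  while (any(bad <- (r2 == r1))) r2[bad] <- stats::runif(sum(bad))
  k <- sig$alpha_p * exp(r1 * sig$tau_p) - sig$alpha_d * exp(r2 * sig$tau_d)

  fill_sym <- function(v, diag_value) {
    mat <- matrix(diag_value, n, n)
    mat[lower.tri(mat)] <- v
    tmat <- t(mat)
    mat[upper.tri(mat)] <- tmat[upper.tri(tmat)]
    mat
  }
  structure(
    list(n = n,
         strengths = fill_sym(k, 0),
         draws_r1 = fill_sym(r1, NA_real_),
         draws_r2 = fill_sym(r2, NA_real_),
         signature = sig),
    class = "coupling_matrix"
  )
}

#' @export
print.coupling_matrix <- function(x, ...) {
  rng <- range(x$strengths[upper.tri(x$strengths)])
  cat(sprintf("Coupling matrix: %d oscillators, K in [%.4g, %.4g] ('%s')\n",
              x$n, rng[1], rng[2], x$signature$label))
  invisible(x)
}
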