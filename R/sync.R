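#' Pairwise phase-locking value
#'
#' The PLV of a pair of phase time series is the modulus of the time average
#' of the complex exponential of their phase difference,
#' `|mean(exp(-1i * (phi_i - phi_j)))|`, over the recorded iterations. It
#' ranges from 0 (no consistent phase relation) to 1 (perfectly locked), is
#' invariant to adding a common offset to both series and to shifting any
#' entry by multiples of 2*pi.
#'
#' @param phases_i,phases_j Equal-length numeric vectors of radians, T >= 1.
#' @return A scalar in \[0, 1\].
#' @export
#' @examples
#' t <- 1:100
#' plv_pair(0.3 * t, 0.3 * t + 0.7)  # constant difference -> 1
plv_pair <- function(phases_i, phases_j) {
  if (!is.numeric(phases_i) || !is.numeric(phases_j)) {
    stop("invalid input: phases must be numeric")
  }
  if (length(phases_i) != length(phases_j)) {
    stop("invalid input: phase sequences differ in length")
  }
  if (length(phases_i) == 0L) stop("invalid input: empty phase sequences")
  if (any(!is.finite(phases_i)) || any(!is.finite(phases_j))) {
    stop("invalid input: non-finite phases")
  }
  Mod(mean(exp(-1i * (phases_i - phases_j))))
}

#' All pairwise phase-locking values of a trajectory
#'
#' Computes the full n x n matrix of pairwise PLVs in one complex
#' cross-product, `|t(Conj(Z)) Z| / T` with `Z = exp(1i * phases)`.
#'
#' @param traj A [phase_trajectory()] or a T x n numeric matrix of radians.
#' @return Symmetric n x n matrix of PLVs with unit diagonal.
#' @export
plv_matrix <- function(traj) {
  phases <- if (inherits(traj, "phase_trajectory")) traj$phases else as.matrix(traj)
  if (nrow(phases) < 1 || ncol(phases) < 2) {
    stop("invalid input: need T >= 1 iterations and n >= 2 oscillators")
  }
  if (any(!is.finite(phases))) stop("invalid input: non-finite phases")
  z <- exp(1i * phases)
  Mod(crossprod(Conj(z), z)) / nrow(phases)
}

#' Grand-average phase-locking value
#'
#' The arithmetic mean of the pairwise PLV over all `n*(n-1)/2` unordered
#' oscillator pairs (i != j, without repetition): the global network
#' synchronization index for one schedule block.
#'
#' @inheritParams plv_matrix
#' @param burn_in Fraction of the block's leading iterations to exclude
#'   before computing the PLVs (default 0: the full block is used).
#' @return A scalar in \[0, 1\].
#' @export
grand_plv <- function(traj, burn_in = 0) {
  phases <- if (inherits(traj, "phase_trajectory")) traj$phases else as.matrix(traj)
  stopifnot(burn_in >= 0, burn_in < 1)
  if (burn_in > 0) {
    drop_n <- floor(burn_in * nrow(phases))
    if (drop_n >= nrow(phases)) stop("invalid input: burn_in removes every iteration")
    if (drop_n > 0) phases <- phases[-seq_len(drop_n), , drop = FALSE]
  }
  pm <- plv_matrix(phases)
  mean(pm[upper.tri(pm)])
}

#' Baseline-normalized percentage change
#'
#' Expresses each block's value as a percentage of the baseline block:
#' `100 * value_b / value_baseline`. The baseline block maps to exactly 100.
#'
#' @param block_values Non-empty numeric vector of per-block values.
#' @param baseline_index 1-based index of the baseline block (default 1).
#' @return Numeric vector of percentages, same length and names as
#'   `block_values`.
#' @export
#' @examples
#' percent_change(c(0.4, 0.5, 0.4))  # 100, 125, 100
percent_change <- function(block_values, baseline_index = 1L) {
  if (!is.numeric(block_values) || length(block_values) == 0L) {
    stop("invalid input: block_values must be a non-empty numeric vector")
  }
  if (baseline_index < 1 || baseline_index > length(block_values) ||
      baseline_index != round(baseline_index)) {
    stop("invalid input: baseline_index out of range")
  }
  base <- block_values[baseline_index]
  if (!is.finite(base) || base <= 0) {
    stop("degenerate baseline: baseline block value must be > 0")
  }
  out <- 100 * block_values / base
  out[baseline_index] <- 100
  out
}

#' Summarize replicate grand PLVs per block
#'
#' Computes the per-block mean and sample standard deviation of the
#' grand-average PLV across replicate runs, plus the percentage change of
#' the per-block means relative to the protocol baseline. Per-replicate
#' percentages are also returned for transparency.
#'
#' @param per_replicate_block_values R x B numeric matrix: one row per
#'   replicate, one column per schedule block.
#' @param baseline_index 1-based baseline block index (default 1).
#' @param block_labels Optional length-B character vector of block names.
#' @return An object of class `sync_summary` with fields `block_labels`,
#'   `grand_plv_mean`, `grand_plv_sd`, `percent_change` (of the means),
#'   `percent_change_replicates` (R x B), `n_replicates`, `baseline_index`.
#' @export
summarize_replicates <- function(per_replicate_block_values,
                                 baseline_index = 1L, block_labels = NULL) {
  x <- as.matrix(per_replicate_block_values)
  if (!is.numeric(x) || nrow(x) < 1 || ncol(x) < 1) {
    stop("invalid input: need an R x B numeric matrix with R >= 1, B >= 1")
  }
  R <- nrow(x); B <- ncol(x)
  if (is.null(block_labels)) {
    block_labels <- colnames(x)
    if (is.null(block_labels)) block_labels <- paste0("block", seq_len(B))
  }
  if (length(block_labels) != B) {
    stop("invalid input: block_labels length does not match block count")
  }
  means <- colMeans(x)
  if (R == 1L) {
    warning("single replicate: standard deviations reported as 0")
    sds <- rep(0, B)
  } else {
    sds <- apply(x, 2, stats::sd)
  }
  pct_reps <- t(apply(x, 1, percent_change, baseline_index = baseline_index))
  if (B == 1L) pct_reps <- matrix(pct_reps, nrow = R, ncol = 1L)
  structure(
    list(block_labels = as.character(block_labels),
         grand_plv_mean = stats::setNames(means, block_labels),
         grand_plv_sd = stats::setNames(sds, block_labels),
         percent_change = stats::setNames(
           percent_change(means, baseline_index), block_labels),
         percent_change_replicates = pct_reps,
         n_replicates = R,
         baseline_index = as.integer(baseline_index)),
    class = "sync_summary"
  )
}

#' @export
print.sync_summary <- function(x, ...) {
  cat(sprintf("Synchronization summary (%d replicate%s):\n", x$n_replicates,
              if (x$n_replicates == 1) "" else "s"))
  df <- data.frame(block = x$block_labels,
                   grand_plv_mean = round(x$grand_plv_mean, 4),
                   grand_plv_sd = round(x$grand_plv_sd, 4),
                   percent_change = round(x$percent_change, 2),
                   row.names = NULL)
  print(df)
  invisible(x)
}
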