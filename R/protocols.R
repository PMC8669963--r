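#' Schedule block
#'
#' One block of a stimulation schedule: a label, a DBS ON/OFF flag and a
#' duration in iterations.
#'
#' @param label Block name, e.g. `"DBS ON"` or `"DBS OFF2"`.
#' @param dbs_on Logical flag.
#' @param n_iterations Duration in iterations, `>= 1`.
#' @return An object of class `schedule_block`.
#' @export
schedule_block <- function(label, dbs_on, n_iterations) {
  stopifnot(is.character(label), length(label) == 1L,
            is.logical(dbs_on), length(dbs_on) == 1L)
  if (n_iterations < 1 || n_iterations != round(n_iterations)) {
    stop("invalid schedule block: n_iterations must be an integer >= 1")
  }
  structure(list(label = label, dbs_on = dbs_on,
                 n_iterations = as.integer(n_iterations)),
            class = "schedule_block")
}

#' Stimulation protocol
#'
#' An ordered sequence of [schedule_block()]s plus the index of the block
#' whose grand PLV defines the 100% baseline for percentage change.
#'
#' @param name Protocol name.
#' @param blocks List of [schedule_block()]s.
#' @param baseline_block_index 1-based baseline index (default 1).
#' @return An object of class `dbs_protocol`.
#' @export
dbs_protocol <- function(name, blocks, baseline_block_index = 1L) {
  stopifnot(is.character(name), length(name) == 1L, is.list(blocks),
            length(blocks) >= 1L,
            all(vapply(blocks, inherits, logical(1), "schedule_block")))
  if (baseline_block_index < 1 || baseline_block_index > length(blocks)) {
    stop("invalid protocol: baseline_block_index out of range")
  }
  structure(list(name = name, blocks = blocks,
                 baseline_block_index = as.integer(baseline_block_index)),
            class = "dbs_protocol")
}

#' @export
print.dbs_protocol <- function(x, ...) {
  cat(sprintf("Protocol '%s' (%d blocks, baseline block %d):\n",
              x$name, length(x$blocks), x$baseline_block_index))
  for (b in x$blocks) {
    cat(sprintf("  %-9s %s, %d iterations\n", b$label,
                if (b$dbs_on) "ON " else "OFF", b$n_iterations))
  }
  invisible(x)
}

#' The seven built-in plasticity conditions
#'
#' The condition bank covers the plasticity signatures studied for the
#' stimulation protocols: (1) high potentiation / low depotentiation
#' (8.0, 0.001); (2) low / high (0.001, 8.0); (3) equally high (8.0, 8.0);
#' (4) equally medium (4.0, 4.0); (5)-(7) equally low (0.7, 0.7),
#' (0.1, 0.1), (0.001, 0.001). All use tau_p = tau_d = 0.5.
#'
#' @return Named list of 7 [plasticity_signature()]s, names `"1"`..`"7"`.
#' @export
#' @examples
#' condition_bank()[["1"]]
condition_bank <- function() {
  alphas <- list(
    c(8.0, 0.001), c(0.001, 8.0), c(8.0, 8.0), c(4.0, 4.0),
    c(0.7, 0.7), c(0.1, 0.1), c(0.001, 0.001))
  descr <- c(
    "high potentiation, low depotentiation",
    "low potentiation, high depotentiation",
    "equally high potentiation and depotentiation",
    "equally medium potentiation and depotentiation",
    "equally low potentiation and depotentiation (0.7)",
    "equally low potentiation and depotentiation (0.1)",
    "equally low potentiation and depotentiation (0.001)")
  out <- lapply(seq_along(alphas), function(i) {
    plasticity_signature(alphas[[i]][1], alphas[[i]][2],
                         label = sprintf("condition %d: %s", i, descr[i]))
  })
  names(out) <- as.character(seq_along(alphas))
  out
}

#' Chronic withdrawal/renewal protocol
#'
#' Five blocks alternating DBS ON and OFF starting ON — DBS ON, DBS OFF,
#' DBS ON2, DBS OFF2, DBS ON3 — simulating repeated cessation and restart
#' of stimulation in a chronic "patient". The first ON block is the 100%
#' baseline.
#'
#' @param block_iterations Iterations per block (default 2000).
#' @return A [dbs_protocol()].
#' @export
withdrawal_renewal_protocol <- function(block_iterations = 2000L) {
  labels <- c("DBS ON", "DBS OFF", "DBS ON2", "DBS OFF2", "DBS ON3")
  on <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  dbs_protocol("withdrawal_renewal",
               mapply(schedule_block, labels, on,
                      MoreArgs = list(n_iterations = block_iterations),
                      SIMPLIFY = FALSE, USE.NAMES = FALSE),
               baseline_block_index = 1L)
}

#' De novo insertion protocol
#'
#' Two equal-length blocks, DBS OFF then DBS ON, simulating a stimulation-
#' naive "patient" receiving a first treatment period. The initial OFF block
#' is the 100% baseline. Durations of 500, 1000 and 2000 iterations are the
#' ones studied; any length `>= 1` is accepted.
#'
#' @param block_iterations Iterations per block (default 2000).
#' @return A [dbs_protocol()].
#' @export
de_novo_protocol <- function(block_iterations = 2000L) {
  dbs_protocol("de_novo",
               list(schedule_block("DBS OFF", FALSE, block_iterations),
                    schedule_block("DBS ON", TRUE, block_iterations)),
               baseline_block_index = 1L)
}

#' Deterministic child seed
#'
#' Derives the replicate-level seed from a master seed and an index:
#' `(master_seed * 10007 + index * 1000003) mod (2^31 - 1)`, computed
#' exactly in double precision, so replicate streams are stable across
#' platforms and independent of how many replicates are requested.
#'
#' @param master_seed Integer master seed.
#' @param index Positive integer replicate (or experiment) index.
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(index), all(index >= 1))
  as.integer((abs(as.double(master_seed)) * 10007 + as.double(index) * 1000003) %%
               2147483647)
}

#' Run one protocol under one plasticity condition
#'
#' For each replicate, a child seed is derived with [child_seed()]; natural
#' frequencies, the coupling matrix and initial phases (uniform on
#' `(0, 2*pi)`) are drawn once; the protocol's blocks are then integrated in
#' sequence with phases and the global pulse clock carried across blocks
#' (one "patient" is one continuous system), and the grand-average PLV is
#' computed per block. The coupling matrix is never rebuilt between blocks.
#'
#' @param protocol A [dbs_protocol()].
#' @param condition A [plasticity_signature()] or an integer 1..7 indexing
#'   [condition_bank()].
#' @param n Oscillator count (default 100).
#' @param spec A [stimulus_spec()] (default: 130 Hz, amplitude 3.0).
#' @param n_replicates Number of independent replicates (default 10).
#' @param master_seed Integer master seed (default 1).
#' @param sign_convention See [euler_step()].
#' @param burn_in Burn-in fraction passed to [grand_plv()] (default 0).
#' @return An object of class `experiment_result` with fields `protocol`,
#'   `condition`, `per_replicate_block_plv` (R x B), `summary` (a
#'   [summarize_replicates()] result), `seeds`, `config_echo`.
#' @export
run_experiment <- function(protocol, condition, n = 100L,
                           spec = stimulus_spec(), n_replicates = 10L,
                           master_seed = 1L,
                           sign_convention = c("attractive", "repulsive"),
                           burn_in = 0) {
  stopifnot(inherits(protocol, "dbs_protocol"), inherits(spec, "stimulus_spec"))
  sign_convention <- match.arg(sign_convention)
  if (is.numeric(condition) && length(condition) == 1L) {
    condition <- condition_bank()[[as.character(condition)]]
    if (is.null(condition)) stop("unknown built-in condition id")
  }
  stopifnot(inherits(condition, "plasticity_signature"))
  if (n_replicates < 1) stop("configuration error: n_replicates must be >= 1")

  B <- length(protocol$blocks)
  labels <- vapply(protocol$blocks, `[[`, character(1), "label")
  seeds <- child_seed(master_seed, seq_len(n_replicates))
  plv <- matrix(NA_real_, n_replicates, B,
                dimnames = list(NULL, labels))

  for (r in seq_len(n_replicates)) {
    set.seed(seeds[r])
    omega <- draw_natural_frequencies(n)
    coupling <- build_coupling_matrix(condition, n)
    phases0 <- draw_initial_phases(n)
    state <- simulation_state(oscillator_ensemble(omega, phases0),
                              rng_seed = seeds[r])
    for (b in seq_len(B)) {
      blk <- protocol$blocks[[b]]
      res <- tryCatch(
        integrate_block(state, coupling, spec, blk$dbs_on, blk$n_iterations,
                        sign_convention = sign_convention,
                        block_label = blk$label),
        error = function(e) {
          stop(sprintf("replicate %d, block '%s': %s", r, blk$label,
                       conditionMessage(e)), call. = FALSE)
        })
      state <- res$state
      plv[r, b] <- grand_plv(res$trajectory, burn_in = burn_in)
    }
  }

  summary <- summarize_replicates(plv, protocol$baseline_block_index, labels)
  config_echo <- list(
    protocol = protocol$name,
    block_iterations = vapply(protocol$blocks, `[[`, integer(1), "n_iterations"),
    baseline_block_index = protocol$baseline_block_index,
    condition = list(alpha_p = condition$alpha_p, alpha_d = condition$alpha_d,
                     tau_p = condition$tau_p, tau_d = condition$tau_d,
                     label = condition$label),
    network = list(n = as.integer(n), master_seed = as.integer(master_seed)),
    stimulus = list(frequency_hz = spec$frequency_hz, amplitude = spec$amplitude,
                    pulse_width_iterations = spec$pulse_width_iterations,
                    iteration_duration_ms = spec$iteration_duration_ms,
                    coupling_sign_convention = sign_convention),
    n_replicates = as.integer(n_replicates),
    burn_in = burn_in)
  structure(
    list(protocol = protocol, condition = condition,
         per_replicate_block_plv = plv, summary = summary,
         seeds = seeds, config_echo = config_echo),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment: protocol '%s', %s\n", x$protocol$name,
              x$condition$label))
  print(x$summary)
  invisible(x)
}

#' Run the full protocol-by-condition study
#'
#' Runs the chronic withdrawal/renewal protocol under all seven built-in
#' plasticity conditions, plus the de novo protocol at each duration in
#' `de_novo_iterations` under the conditions in `de_novo_conditions`
#' (default 1, 2, 3, 4, 7 — the panels studied; set `all_de_novo = TRUE`
#' for all seven). Each experiment receives its own deterministic seed
#' derived from `master_seed`; de novo runs at different durations are
#' independent draws.
#'
#' @param n_replicates Replicates per experiment (default 10).
#' @param master_seed Integer master seed (default 1).
#' @param n Oscillator count (default 100).
#' @param block_iterations Withdrawal/renewal block length (default 2000).
#' @param de_novo_iterations De novo block lengths (default
#'   `c(500, 1000, 2000)`).
#' @param de_novo_conditions Condition ids for the de novo arm.
#' @param all_de_novo If `TRUE`, run the de novo arm for all 7 conditions.
#' @param spec A [stimulus_spec()].
#' @param sign_convention See [euler_step()].
#' @return An object of class `study_result`: a list with `results` (list of
#'   [run_experiment()] outputs) and `table` (the combined summary
#'   data.frame, one row per protocol/condition/block/duration).
#' @export
run_full_study <- function(n_replicates = 10L, master_seed = 1L, n = 100L,
                           block_iterations = 2000L,
                           de_novo_iterations = c(500L, 1000L, 2000L),
                           de_novo_conditions = c(1L, 2L, 3L, 4L, 7L),
                           all_de_novo = FALSE,
                           spec = stimulus_spec(),
                           sign_convention = c("attractive", "repulsive")) {
  sign_convention <- match.arg(sign_convention)
  if (all_de_novo) de_novo_conditions <- 1:7
  bank <- condition_bank()

  plan <- list()
  for (cond in 1:7) {
    plan[[length(plan) + 1L]] <- list(
      protocol = withdrawal_renewal_protocol(block_iterations), cond = cond)
  }
  for (cond in de_novo_conditions) {
    for (dur in de_novo_iterations) {
      plan[[length(plan) + 1L]] <- list(
        protocol = de_novo_protocol(dur), cond = cond)
    }
  }

  results <- vector("list", length(plan))
  for (e in seq_along(plan)) {
    p <- plan[[e]]
    exp_seed <- child_seed(master_seed, e)
    results[[e]] <- tryCatch(
      run_experiment(p$protocol, bank[[as.character(p$cond)]], n = n,
                     spec = spec, n_replicates = n_replicates,
                     master_seed = exp_seed,
                     sign_convention = sign_convention),
      error = function(err) {
        warning(sprintf("experiment %d (protocol %s, condition %d) failed: %s",
                        e, p$protocol$name, p$cond, conditionMessage(err)))
        NULL
      })
  }
  names(results) <- vapply(seq_along(plan), function(e) {
    sprintf("%s_cond%d_it%d", plan[[e]]$protocol$name, plan[[e]]$cond,
            plan[[e]]$protocol$blocks[[1]]$n_iterations)
  }, character(1))

  structure(list(results = results, table = summary_table(results)),
            class = "study_result")
}

#' Combined summary table of experiment results
#'
#' @param results A single `experiment_result`, a list of them (`NULL`
#'   entries from failed experiments are skipped), or a `study_result`.
#' @return A data.frame with one row per protocol/condition/block, columns
#'   `protocol`, `condition_label`, `block_label`, `n_iterations`,
#'   `grand_plv_mean`, `grand_plv_sd`, `percent_change`, `n_replicates`,
#'   `seed`.
#' @export
summary_table <- function(results) {
  if (inherits(results, "study_result")) results <- results$results
  if (inherits(results, "experiment_result")) results <- list(results)
  results <- Filter(Negate(is.null), results)
  rows <- lapply(results, function(res) {
    s <- res$summary
    data.frame(
      protocol = res$protocol$name,
      condition_label = res$condition$label,
      block_label = s$block_labels,
      n_iterations = vapply(res$protocol$blocks, `[[`, integer(1),
                            "n_iterations"),
      grand_plv_mean = as.numeric(s$grand_plv_mean),
      grand_plv_sd = as.numeric(s$grand_plv_sd),
      percent_change = as.numeric(s$percent_change),
      n_replicates = s$n_replicates,
      seed = res$config_echo$network$master_seed,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Full study: %d experiments, %d summary rows\n",
              length(x$results), nrow(x$table)))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("...\n")
  invisible(x)
}
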