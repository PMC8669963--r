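# Schema of the run configuration: defaults plus the set of allowed keys.
# Unknown keys are a hard error (fail loud) so parameter provenance in a
# reproducibility tool is protected.
default_config_list <- function() {
  list(
    network = list(n = 100L, master_seed = 1L),
    # condition 1 (high potentiation, low depotentiation) is the default
    plasticity = list(condition = 1L, alpha_p = NULL, alpha_d = NULL,
                      tau_p = 0.5, tau_d = 0.5),
    stimulus = list(frequency_hz = 130, amplitude = 3.0,
                    pulse_width_iterations = 1L, iteration_duration_ms = 1.0,
                    coupling_sign_convention = "attractive"),
    protocol = list(name = "withdrawal_renewal", block_iterations = 2000L),
    replicates = 10L,
    output = list(dir = NULL, export_trajectories = FALSE)
  )
}

check_unknown_keys <- function(doc, schema, path = "") {
  extra <- setdiff(names(doc), names(schema))
  if (length(extra) > 0) {
    stop(sprintf("configuration error: unknown key%s '%s'%s",
                 if (length(extra) > 1) "s" else "",
                 paste0(path, extra, collapse = "', '"),
                 ""))
  }
  for (k in names(doc)) {
    if (is.list(schema[[k]]) && !is.null(names(schema[[k]]))) {
      if (!is.list(doc[[k]])) {
        stop(sprintf("configuration error: key '%s%s' must be a mapping", path, k))
      }
      check_unknown_keys(doc[[k]], schema[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(defaults, doc) {
  for (k in names(doc)) {
    if (is.null(doc[[k]])) next  # explicit null keeps the default
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(doc[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], doc[[k]])
    } else {
      defaults[[k]] <- doc[[k]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a JSON (or, if the `yaml` package is installed, YAML) document —
#' or takes an equivalent named list — validates it against the
#' configuration schema, fills defaults, and resolves a named built-in
#' plasticity condition to its rates. Unknown keys are an error. An empty
#' document yields the all-defaults configuration (n = 100, 130 Hz,
#' amplitude 3.0, tau = 0.5, withdrawal/renewal protocol at 2000
#' iterations, 10 replicates).
#'
#' @param config A file path, a JSON string, or a named list. `NULL` (the
#'   default) gives the all-defaults configuration.
#' @return An object of class `run_config`: the fully resolved nested list.
#' @export
#' @examples
#' load_config(list(plasticity = list(condition = 3)))$plasticity$alpha_p
load_config <- function(config = NULL) {
  doc <- if (is.null(config)) {
    list()
  } else if (is.list(config)) {
    config
  } else if (is.character(config) && length(config) == 1L) {
    if (file.exists(config)) {
      if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
        if (!requireNamespace("yaml", quietly = TRUE)) {
          stop("configuration error: YAML input requires the 'yaml' package; use JSON")
        }
        yaml::read_yaml(config)
      } else {
        jsonlite::fromJSON(config, simplifyVector = TRUE)
      }
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  } else {
    stop("configuration error: config must be a path, JSON string, or named list")
  }
  if (length(doc) > 0 && is.null(names(doc))) {
    stop("configuration error: configuration document must be a mapping")
  }

  defaults <- default_config_list()
  check_unknown_keys(doc, defaults)
  cfg <- merge_config(defaults, doc)

  # --- validation, naming the offending key ---
  if (!is.numeric(cfg$network$n) || cfg$network$n < 2 ||
      cfg$network$n != round(cfg$network$n)) {
    stop("configuration error: network.n must be an integer >= 2")
  }
  cfg$network$n <- as.integer(cfg$network$n)
  if (!is.numeric(cfg$network$master_seed) ||
      cfg$network$master_seed != round(cfg$network$master_seed)) {
    stop("configuration error: network.master_seed must be an integer")
  }
  cfg$network$master_seed <- as.integer(cfg$network$master_seed)
  if (!is.numeric(cfg$replicates) || cfg$replicates < 1 ||
      cfg$replicates != round(cfg$replicates)) {
    stop("configuration error: replicates must be an integer >= 1")
  }
  cfg$replicates <- as.integer(cfg$replicates)

  # plasticity: a built-in condition id, or explicit rates (which drop the
  # default condition id); a resolved echo may carry both if they agree
  pl <- cfg$plasticity
  user_pl <- if (is.list(doc$plasticity)) doc$plasticity else list()
  gave_alphas <- !is.null(user_pl$alpha_p) || !is.null(user_pl$alpha_d)
  gave_condition <- !is.null(user_pl$condition)
  if (gave_alphas && !gave_condition) pl$condition <- NULL
  if (!is.null(pl$condition)) {
    if (!(as.character(pl$condition) %in% names(condition_bank()))) {
      stop("configuration error: plasticity.condition must be 1..7")
    }
    sig <- condition_bank()[[as.character(pl$condition)]]
    if (gave_alphas && gave_condition &&
        (!identical(as.numeric(user_pl$alpha_p), sig$alpha_p) ||
         !identical(as.numeric(user_pl$alpha_d), sig$alpha_d))) {
      stop("configuration error: give plasticity.condition or explicit alpha_p/alpha_d, not both")
    }
    cfg$plasticity <- list(condition = as.integer(pl$condition),
                           alpha_p = sig$alpha_p, alpha_d = sig$alpha_d,
                           tau_p = sig$tau_p, tau_d = sig$tau_d)
  } else {
    if (is.null(pl$alpha_p) || is.null(pl$alpha_d)) {
      stop("configuration error: plasticity needs a condition id or both alpha_p and alpha_d")
    }
    if (pl$alpha_p < 0) stop("configuration error: plasticity.alpha_p must be >= 0")
    if (pl$alpha_d < 0) stop("configuration error: plasticity.alpha_d must be >= 0")
    if (pl$tau_p <= 0) stop("configuration error: plasticity.tau_p must be > 0")
    if (pl$tau_d <= 0) stop("configuration error: plasticity.tau_d must be > 0")
    cfg$plasticity <- list(alpha_p = as.numeric(pl$alpha_p),
                           alpha_d = as.numeric(pl$alpha_d),
                           tau_p = as.numeric(pl$tau_p),
                           tau_d = as.numeric(pl$tau_d))
  }

  st <- cfg$stimulus
  if (!st$coupling_sign_convention %in% c("attractive", "repulsive")) {
    stop("configuration error: stimulus.coupling_sign_convention must be 'attractive' or 'repulsive'")
  }
  # constructor re-validates the numeric stimulus fields
  tryCatch(
    stimulus_spec(st$frequency_hz, st$amplitude, st$pulse_width_iterations,
                  st$iteration_duration_ms),
    error = function(e) stop("configuration error: stimulus: ",
                             conditionMessage(e), call. = FALSE))
  cfg$stimulus$pulse_width_iterations <- as.integer(st$pulse_width_iterations)

  if (!cfg$protocol$name %in% c("withdrawal_renewal", "de_novo")) {
    stop("configuration error: protocol.name must be 'withdrawal_renewal' or 'de_novo'")
  }
  if (!is.numeric(cfg$protocol$block_iterations) ||
      any(cfg$protocol$block_iterations < 1)) {
    stop("configuration error: protocol.block_iterations must be >= 1")
  }
  cfg$protocol$block_iterations <- as.integer(cfg$protocol$block_iterations)

  structure(cfg, class = c("run_config", "list"))
}

#' Serialize a run configuration to JSON
#'
#' Writes (or returns) the configuration as pretty-printed JSON at full
#' numeric precision. `load_config(save_config(cfg))` returns an identical
#' configuration (round-trip contract).
#'
#' @param config A `run_config` (or compatible named list).
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to `path`.
#' @export
save_config <- function(config, path = NULL) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(as.character(json))
}

#' Run a simulation experiment from a configuration
#'
#' Resolves the configuration (via [load_config()] if needed), builds the
#' protocol and stimulus, and calls [run_experiment()].
#'
#' @param config A `run_config`, or anything [load_config()] accepts.
#' @return An `experiment_result` (see [run_experiment()]).
#' @export
run_from_config <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  spec <- stimulus_spec(cfg$stimulus$frequency_hz, cfg$stimulus$amplitude,
                        cfg$stimulus$pulse_width_iterations,
                        cfg$stimulus$iteration_duration_ms)
  protocol <- switch(cfg$protocol$name,
    withdrawal_renewal = withdrawal_renewal_protocol(cfg$protocol$block_iterations),
    de_novo = de_novo_protocol(cfg$protocol$block_iterations))
  condition <- plasticity_signature(
    cfg$plasticity$alpha_p, cfg$plasticity$alpha_d,
    cfg$plasticity$tau_p, cfg$plasticity$tau_d,
    label = if (!is.null(cfg$plasticity$condition)) {
      condition_bank()[[as.character(cfg$plasticity$condition)]]$label
    } else NULL)
  res <- run_experiment(protocol, condition, n = cfg$network$n, spec = spec,
                        n_replicates = cfg$replicates,
                        master_seed = cfg$network$master_seed,
                        sign_convention = cfg$stimulus$coupling_sign_convention)
  res$config_echo$run_config <- unclass(cfg)
  res
}
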