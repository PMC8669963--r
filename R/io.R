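# Fixed 6-significant-digit formatting for CSV output; full-precision values
# live in the JSON sidecar. Deterministic formatting keeps files byte-stable.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

write_summary_csv <- function(tab, path) {
  num_cols <- c("grand_plv_mean", "grand_plv_sd", "percent_change")
  out <- tab
  for (cn in num_cols) out[[cn]] <- fmt_num(tab[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
}

#' Write experiment results to disk
#'
#' Writes, into `out_dir`: `summary.csv` (one row per
#' protocol/condition/block, numeric columns at 6 significant digits),
#' `config.json` (the full-precision configuration echo of every
#' experiment), and `seeds.csv` (the per-replicate seed log). Files are
#' byte-stable given identical results. On failure, partially written files
#' are removed.
#'
#' @param results An `experiment_result`, a list of them, or a
#'   `study_result`.
#' @param out_dir Output directory; created if absent.
#' @return Invisibly, the manifest: a named character vector of written
#'   file paths.
#' @export
write_results <- function(results, out_dir) {
  if (inherits(results, "study_result")) results <- results$results
  if (inherits(results, "experiment_result")) results <- list(results)
  results <- Filter(Negate(is.null), results)
  if (length(results) == 0L) stop("write_results: no results to write")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  paths <- c(summary = file.path(out_dir, "summary.csv"),
             config = file.path(out_dir, "config.json"),
             seeds = file.path(out_dir, "seeds.csv"))
  written <- character(0)
  on_fail_cleanup <- function(e) {
    unlink(written)
    stop(sprintf("write_results: I/O failure for '%s': %s",
                 out_dir, conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    tab <- summary_table(results)
    write_summary_csv(tab, paths[["summary"]])
    written <- c(written, paths[["summary"]])

    echoes <- lapply(results, `[[`, "config_echo")
    if (!is.null(names(results))) names(echoes) <- names(results)
    writeLines(as.character(jsonlite::toJSON(
      echoes, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)),
      paths[["config"]])
    written <- c(written, paths[["config"]])

    seed_rows <- do.call(rbind, lapply(seq_along(results), function(e) {
      res <- results[[e]]
      data.frame(experiment = e, protocol = res$protocol$name,
                 condition_label = res$condition$label,
                 replicate = seq_along(res$seeds), seed = res$seeds,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(seed_rows, paths[["seeds"]], row.names = FALSE,
                     quote = TRUE)
    written <- c(written, paths[["seeds"]])
  }, error = on_fail_cleanup)
  invisible(paths)
}

#' Export a phase trajectory as CSV
#'
#' Long-format per-iteration dump with columns `iteration` (global index),
#' `oscillator_index`, `phase_rad`. A `.gz` suffix on `path` writes a
#' gzip-compressed file.
#'
#' @param traj A [phase_trajectory()].
#' @param path Output file path (`.csv` or `.csv.gz`).
#' @return Invisibly, `path`.
#' @export
export_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "phase_trajectory"))
  T_ <- nrow(traj$phases); n <- ncol(traj$phases)
  df <- data.frame(
    iteration = rep(traj$iteration_offset + seq_len(T_), times = n),
    oscillator_index = rep(seq_len(n), each = T_),
    phase_rad = as.vector(traj$phases))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
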