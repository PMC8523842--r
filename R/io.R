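#' Write an epoch set in the package container format
#'
#' The container is a plain-text pair: `<stem>.csv` holds the data array
#' flattened column-major to a `(trials * channels) x samples` matrix, and
#' `<stem>.json` is the sidecar with dimensions, labels, sampling rate,
#' montage, and any extra metadata.
#'
#' @param epochs An [epoch_set()].
#' @param stem Output path without extension.
#' @return Invisibly, the CSV path.
#' @export
write_epochs <- function(epochs, stem) {
  d <- dim(epochs$data)
  mat <- matrix(epochs$data, nrow = d[1L] * d[2L])
  data.table::fwrite(data.table::as.data.table(mat),
                     paste0(stem, ".csv"), col.names = FALSE)
  sidecar <- list(n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
                  fs = epochs$fs, labels = epochs$labels,
                  channel_names = epochs$channel_names,
                  extra = epochs$extra)
  jsonlite::write_json(sidecar, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paste0(stem, ".csv"))
}

#' Read an epoch set from the package container format
#'
#' Validates the sidecar against the data file and raises a distinct
#' diagnostic for a missing sidecar, a shape mismatch, or inconsistent
#' montage/label lengths.
#'
#' @param stem Path without extension (expects `<stem>.csv` and
#'   `<stem>.json`).
#' @return An [epoch_set()].
#' @export
read_epochs <- function(stem) {
  csv <- paste0(stem, ".csv"); side <- paste0(stem, ".json")
  if (!file.exists(side)) stop("missing sidecar: ", side)
  if (!file.exists(csv)) stop("missing data file: ", csv)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  need <- c("n_trials", "n_channels", "n_samples", "fs", "labels",
            "channel_names")
  missing <- setdiff(need, names(meta))
  if (length(missing)) stop("sidecar lacks fields: ",
                            paste(missing, collapse = ", "))
  mat <- as.matrix(data.table::fread(csv, header = FALSE))
  if (nrow(mat) != meta$n_trials * meta$n_channels ||
      ncol(mat) != meta$n_samples) {
    stop("shape mismatch: data is ", nrow(mat), " x ", ncol(mat),
         " but sidecar declares ", meta$n_trials, " trials x ",
         meta$n_channels, " channels x ", meta$n_samples, " samples")
  }
  if (length(meta$channel_names) != meta$n_channels) {
    stop("sidecar declares ", meta$n_channels, " channels but lists ",
         length(meta$channel_names), " channel names")
  }
  data <- array(as.numeric(mat),
                dim = c(meta$n_trials, meta$n_channels, meta$n_samples))
  extra <- if (is.null(meta$extra)) list() else meta$extra
  epoch_set(data, meta$labels, meta$fs, meta$channel_names, extra)
}

#' Run the full two-stage channel-selection pipeline
#'
#' Builds the objective backend, runs the multitasking stage over its
#' evaluation allotment, then the analysis/local-search stage, and returns
#' the two task archives, the final three-objective Pareto set, the variable
#' groups, and the evaluation ledger summary. All randomness is governed by
#' `seed`.
#'
#' @param mi_epochs Two-class MI [epoch_set()] (raw).
#' @param ssvep_epochs SSVEP [epoch_set()] labelled by stimulus index.
#' @param stim A [stimulus_spec()].
#' @param config An [ea_config()].
#' @param seed Integer seed for the whole run.
#' @param verbose Emit per-generation progress.
#' @return List of class `emmoa_result`.
#' @export
run_emmoa <- function(mi_epochs, ssvep_epochs, stim, config = ea_config(),
                      seed = 1L, verbose = FALSE) {
  t0 <- Sys.time()
  set.seed(seed)
  backend <- objective_backend(mi_epochs, ssvep_epochs, stim,
                               budget = config$budget,
                               cv_folds = config$cv_folds, cv_seed = seed)
  s1 <- run_stage1(backend, config, verbose = verbose)
  t1 <- Sys.time()
  s2 <- run_stage2(s1, backend, config)
  t2 <- Sys.time()
  structure(list(final = s2$final, ps_mi = s1$ps_mi, ps_ssvep = s1$ps_ssvep,
                 groups = s2$groups, progress = s1$progress,
                 generations = s1$generations,
                 ledger = ledger_summary(backend$ledger),
                 config = config, seed = seed,
                 channel_names = mi_epochs$channel_names,
                 timings = c(stage1 = as.numeric(difftime(t1, t0, units = "secs")),
                             stage2 = as.numeric(difftime(t2, t1, units = "secs")))),
            class = "emmoa_result")
}

#' @export
print.emmoa_result <- function(x, ...) {
  cat("Two-stage multitasking channel selection\n")
  cat("  evaluations used: ", x$ledger$evaluations, " / ",
      x$ledger$budget, "\n", sep = "")
  cat("  stage-1 generations: ", x$generations, "\n", sep = "")
  cat("  |PS_MI| = ", length(x$ps_mi$members),
      ", |PS_SSVEP| = ", length(x$ps_ssvep$members),
      ", |final PS| = ", length(x$final$members), "\n", sep = "")
  df <- summarize_result(x)
  cat("  final Pareto set (MAR, SAR, channels):\n")
  print(df[, c("MAR", "SAR", "n_channels", "channels")], row.names = FALSE)
  invisible(x)
}

#' Accuracy-vs-channel-count table for a finished run
#'
#' One row per final Pareto solution: MAR, SAR, and number of selected
#' channels, sorted by channel count then accuracy.
#'
#' @param result An `emmoa_result` from [run_emmoa()].
#' @return data.frame with columns channels, mask, MAR, SAR, NC, n_channels.
#' @export
summarize_result <- function(result) {
  df <- as.data.frame(result$final, channel_names = result$channel_names)
  df$n_channels <- result$config$n_channels - df$NC
  df[order(df$n_channels, -df$MAR, -df$SAR), , drop = FALSE]
}

#' Write a run directory: archives, groups, manifest
#'
#' Persists PS_MI, PS_SSVEP, and the final three-objective Pareto set as
#' CSV + JSON pairs, the variable groups, the per-generation progress log,
#' and a run manifest sufficient to re-launch an identical run.
#'
#' @param result An `emmoa_result`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_emmoa_run <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chn <- result$channel_names
  meta <- list(seed = result$seed)
  write_archive(result$ps_mi, file.path(out_dir, "ps_mi"), chn, meta)
  write_archive(result$ps_ssvep, file.path(out_dir, "ps_ssvep"), chn, meta)
  write_archive(result$final, file.path(out_dir, "final_ps"), chn, meta)
  data.table::fwrite(summarize_result(result),
                     file.path(out_dir, "summary.csv"))
  if (!is.null(result$progress)) {
    data.table::fwrite(result$progress, file.path(out_dir, "progress.csv"))
  }
  groups <- result$groups
  manifest <- list(
    package_version = as.character(utils::packageVersion("emmoa")),
    seed = result$seed,
    config = unclass(result$config),
    ledger = result$ledger,
    generations = result$generations,
    timings_sec = as.list(result$timings),
    channel_names = chn,
    variable_groups = if (!is.null(groups)) list(
      add_group = groups$add_group, delete_group = groups$delete_group,
      invalid_group = groups$invalid_group) else NULL,
    files = list(ps_mi = "ps_mi.csv", ps_ssvep = "ps_ssvep.csv",
                 final_ps = "final_ps.csv", summary = "summary.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
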