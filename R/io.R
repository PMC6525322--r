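#' Export an activity trace as tidy CSV
#'
#' Columns: `run_id`, `trial`, `step`, `unit_type`, `unit_index`, `rate`.
#'
#' @param trace A `wm_trace`.
#' @param path Output file.
#' @param run_id,trial Identifiers stamped on every row.
#' @param every Keep every `every`-th step (1 = all steps).
#' @param digits Significant digits written.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, run_id = "run", trial = 1L,
                            every = 1L, digits = 10L) {
  td <- tidy_trace(trace)
  if (every > 1L) {
    steps <- sort(unique(td$step))
    td <- dplyr::filter(td, .data$step %in% steps[seq(1, length(steps),
                                                      by = every)])
  }
  td <- dplyr::mutate(td, run_id = run_id, trial = trial,
                      rate = signif(.data$rate, digits), .before = 1)
  utils::write.csv(td, path, row.names = FALSE)
  invisible(path)
}

#' Export a weight matrix as labeled CSV
#'
#' @param w Weight matrix (e.g. `state$W_fc`).
#' @param path Output file.
#' @param row_prefix,col_prefix Label prefixes for rows and columns.
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(w, path, row_prefix = "post",
                              col_prefix = "pre") {
  df <- as.data.frame(signif(unclass(w), 12))
  colnames(df) <- paste0(col_prefix, seq_len(ncol(df)))
  df <- cbind(unit = paste0(row_prefix, seq_len(nrow(df))), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an experiment table with its configuration echo and log
#'
#' Emits `<name>.csv` (the tidy table), `<name>_config.json` (full
#' configuration echo with seed and config hash) and `<name>.log` into
#' `dir`.
#'
#' @param tab A `wm_experiment` tibble.
#' @param dir Output directory (created if missing).
#' @param params The `wm_params` used.
#' @param name Base file name (default: the experiment name).
#' @return The CSV path, invisibly.
#' @export
write_experiment <- function(tab, dir, params, name = NULL) {
  name <- name %||% attr(tab, "experiment")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(tab), csv, row.names = FALSE)
  cfg <- unclass(params)
  cfg$variant_code <- NULL
  jsonlite::write_json(
    list(experiment = name, seed = attr(tab, "seed"),
         config_hash = attr(tab, "config_hash"), params = cfg),
    file.path(dir, paste0(name, "_config.json")),
    auto_unbox = TRUE, digits = NA)
  writeLines(
    c(sprintf("experiment: %s", name),
      sprintf("seed: %s", attr(tab, "seed")),
      sprintf("config_hash: %s", attr(tab, "config_hash")),
      sprintf("rows: %d", nrow(tab)),
      sprintf("written: %s", csv)),
    file.path(dir, paste0(name, ".log")))
  invisible(csv)
}

#' Read an experiment table written by [write_experiment()]
#'
#' @param csv Path to the CSV.
#' @return A `wm_experiment` tibble (attributes restored from the config
#'   echo when present).
#' @export
read_experiment <- function(csv) {
  if (!file.exists(csv)) stop("file not found: ", csv, call. = FALSE)
  tab <- tibble::as_tibble(utils::read.csv(csv, stringsAsFactors = FALSE))
  cfgp <- sub("\\.csv$", "_config.json", csv)
  if (file.exists(cfgp)) {
    cfg <- jsonlite::read_json(cfgp, simplifyVector = TRUE)
    attr(tab, "seed") <- cfg$seed
    attr(tab, "config_hash") <- cfg$config_hash
    attr(tab, "experiment") <- cfg$experiment
  } else {
    attr(tab, "experiment") <- tab$experiment[1]
  }
  class(tab) <- c("wm_experiment", class(tab))
  tab
}
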