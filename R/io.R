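#' Read and validate the trace table
#'
#' Expects a comma-separated file (header row, '.' decimal) with columns
#' `cell_id`, `time_min`, `frame_id`, `raw_intensity`.  Snapshot times
#' must be strictly increasing within each cell; duplicate (cell, time)
#' pairs are rejected.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_traces <- function(path) {
  df <- read_table_checked(path, c("cell_id", "time_min", "frame_id",
                                   "raw_intensity"))
  df$time_min <- as.numeric(df$time_min)
  df$raw_intensity <- as.numeric(df$raw_intensity)
  if (anyNA(df$time_min) || anyNA(df$raw_intensity))
    stop("non-numeric time_min/raw_intensity in ", path, call. = FALSE)
  for (cell in unique(df$cell_id)) {
    t <- df$time_min[df$cell_id == cell]
    if (anyDuplicated(t))
      stop("duplicate snapshot times for cell ", cell, call. = FALSE)
    if (is.unsorted(t, strictly = TRUE))
      stop("snapshot times not strictly increasing for cell ", cell,
           call. = FALSE)
  }
  message(sprintf("read %d snapshots for %d cells from %s", nrow(df),
                  length(unique(df$cell_id)), path))
  df
}

#' Read and validate the division-time table
#'
#' Columns `cell_id`, `division_time_min`; boundaries must be strictly
#' increasing within each cell, with at least two per cell (one
#' generation).
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_divisions <- function(path) {
  df <- read_table_checked(path, c("cell_id", "division_time_min"))
  df$division_time_min <- as.numeric(df$division_time_min)
  if (anyNA(df$division_time_min))
    stop("non-numeric division_time_min in ", path, call. = FALSE)
  for (cell in unique(df$cell_id)) {
    b <- df$division_time_min[df$cell_id == cell]
    if (length(b) < 2)
      stop("cell ", cell, " has fewer than two division boundaries",
           call. = FALSE)
    if (is.unsorted(b, strictly = TRUE))
      stop("division times not strictly increasing for cell ", cell,
           call. = FALSE)
  }
  message(sprintf("read %d division boundaries for %d cells from %s",
                  nrow(df), length(unique(df$cell_id)), path))
  df
}

#' Read and validate the frame-pixel table
#'
#' Long form: columns `frame_id`, `pixel_intensity` (non-negative).
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_pixels <- function(path) {
  df <- read_table_checked(path, c("frame_id", "pixel_intensity"))
  df$pixel_intensity <- as.numeric(df$pixel_intensity)
  if (anyNA(df$pixel_intensity) || any(df$pixel_intensity < 0))
    stop("pixel intensities must be non-negative numbers in ", path,
         call. = FALSE)
  message(sprintf("read %d pixels over %d frames from %s", nrow(df),
                  length(unique(df$frame_id)), path))
  df
}

read_table_checked <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$cell_id <- if ("cell_id" %in% names(df)) as.character(df$cell_id)
  df
}

default_run_config <- function() {
  list(
    model = list(r_on = 0.0229, r_off = 0.0348, k_m = 1, gamma_m = 0.05,
                 k_p = 2, gamma_p = log(2) / 90, t_end = NULL,
                 sample_interval = 10, n_reps = 2000),
    pipeline = unclass(pipeline_config()),
    seed = 1
  )
}

#' Load a run configuration from YAML or JSON
#'
#' Missing keys are filled from the documented defaults (the analysis
#' protocol's values: ON threshold 1000 a.u., two-generation windows,
#' last-4-generation exclusion, minimum lifespan 10, bottom-10th-percentile
#' background, ensembles of 2000 replicates, 10-minute sampling); unknown
#' keys are rejected with the offending name.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.  `NULL` returns
#'   the defaults.
#' @return A list of class `run_config` with elements `model`, `pipeline`,
#'   `seed`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    bad <- setdiff(names(user), names(cfg))
    if (length(bad) > 0)
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (section in intersect(names(user), c("model", "pipeline"))) {
      bad <- setdiff(names(user[[section]]), names(cfg[[section]]))
      if (length(bad) > 0)
        stop("unknown config key(s) in '", section, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      for (k in names(user[[section]])) {
        v <- user[[section]][[k]]
        if (is.null(v)) next            # e.g. t_end: use the default rule
        if (!is.numeric(v) || length(v) != 1)
          stop("config key '", section, ".", k, "' must be a single number",
               call. = FALSE)
        cfg[[section]][[k]] <- v
      }
    }
    if (!is.null(user$seed)) cfg$seed <- user$seed
  }
  # validation through the typed constructors
  do.call(pipeline_config, cfg$pipeline)
  promoter_rates(cfg$model$r_on, cfg$model$r_off)
  kinetic_rates(cfg$model$k_m, cfg$model$gamma_m, cfg$model$k_p,
                cfg$model$gamma_p)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration as YAML
#'
#' `load_config(save_config(cfg, path))` restores an identical
#' configuration.
#'
#' @param config A `run_config` list.
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Write all pipeline outputs to a directory
#'
#' Writes `windowed_summary.csv`, `catastrophe_summary.csv`,
#' `durations.csv`, `rls.csv`, `correlations.csv`, `exclusions.json`, the
#' resolved pipeline configuration (`config.yaml`) and the package version
#' (`VERSION`).
#'
#' @param result An `aging_analysis` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_results <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(as.data.frame(df), file.path(outdir, name),
                     row.names = FALSE, quote = FALSE)
  wcsv(result$summary, "windowed_summary.csv")
  wcsv(result$catastrophe$windows, "catastrophe_summary.csv")
  wcsv(result$catastrophe$durations, "durations.csv")
  wcsv(result$rls$viability, "rls.csv")
  wcsv(result$correlations, "correlations.csv")
  jsonlite::write_json(result$exclusions,
                       file.path(outdir, "exclusions.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(result$config), file.path(outdir, "config.yaml"))
  writeLines(as.character(utils::packageVersion("agenoise")),
             file.path(outdir, "VERSION"))
  invisible(outdir)
}
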