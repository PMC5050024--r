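#' Read and write the ECS trace CSV dialect
#'
#' Columns `time_s, a505, a520, a535, irradiance_umol, phase`
#' (phase in `light`/`dark`), mandatory header, '.' decimal, UTF-8.
#'
#' @param path File path.
#' @param trace An `ecs_trace` (or compatible data frame) to write.
#' @param chl_per_area Optional chlorophyll normalisation to attach on
#'   read.
#' @return `read_ecs_trace` returns an `ecs_trace`;
#'   `write_ecs_trace` returns `path` invisibly.
#' @export
read_ecs_trace <- function(path, chl_per_area = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "a505", "a520", "a535", "irradiance_umol", "phase")
  if (!all(need %in% names(df))) {
    stop("ECS trace CSV must contain columns: ", paste(need, collapse = ", "))
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("time_s must be strictly increasing")
  }
  structure(df[, need], chl_per_area = chl_per_area,
            class = c("ecs_trace", "data.frame"))
}

#' @rdname read_ecs_trace
#' @export
write_ecs_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("time_s", "a505", "a520",
                                            "a535", "irradiance_umol",
                                            "phase")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the fluorescence trace CSV dialect
#'
#' Columns `time_s, fluor, event` with
#' `event` in `none`/`pulse_start`/`pulse_end`/`dark_start`.
#'
#' @param path File path.
#' @param trace A `fluor_trace` to write.
#' @return `read_fluor_trace` returns a `fluor_trace`.
#' @export
read_fluor_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "fluor", "event")
  if (!all(need %in% names(df))) {
    stop("fluorescence trace CSV must contain columns: ",
         paste(need, collapse = ", "))
  }
  ok <- c("none", "pulse_start", "pulse_end", "dark_start")
  if (!all(df$event %in% ok)) stop("unknown event markers in trace")
  structure(df[, need], class = c("fluor_trace", "data.frame"))
}

#' @rdname read_fluor_trace
#' @export
write_fluor_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("time_s", "fluor", "event")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write light-schedule CSV files
#'
#' Columns `start_s, irradiance_umol`.
#'
#' @param path File path.
#' @param schedule A `light_schedule` to write.
#' @param photoperiod_h,day_type Metadata attached on read.
#' @return `read_schedule` returns a `light_schedule`.
#' @export
read_schedule <- function(path, photoperiod_h = NULL, day_type = "custom") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("start_s", "irradiance_umol") %in% names(df))) {
    stop("schedule CSV must contain start_s and irradiance_umol")
  }
  if (is.null(photoperiod_h)) {
    photoperiod_h <- (max(df$start_s) + 1800) / 3600
  }
  new_light_schedule(df[, c("start_s", "irradiance_umol")],
                     photoperiod_h, day_type)
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule)[, c("start_s",
                                               "irradiance_umol")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load plant parameters from a YAML/key-value config file
#'
#' Every [plant_params()] field is addressable by name; unknown keys are
#' an error. A `seed` key and a `noise_sd` key are passed through in the
#' result's attributes.
#'
#' @param path Path to a YAML file.
#' @return A [plant_params()] object.
#' @export
read_plant_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  seed <- cfg$seed; noise_sd <- cfg$noise_sd
  cfg$seed <- NULL; cfg$noise_sd <- NULL
  known <- names(formals(plant_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  p <- do.call(plant_params, cfg)
  attr(p, "seed") <- seed
  attr(p, "noise_sd") <- noise_sd
  p
}

#' Write a results table as TSV with provenance header lines
#'
#' Metadata lines are prefixed with `#` (key: value), followed by a
#' header row and tab-separated values.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param meta Named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  }
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_results_tsv()]
#'
#' @param path File path.
#' @return Data frame, with the metadata in attribute `meta`.
#' @export
read_results_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*:\\s*", "", kv)
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}
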