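#' Write a scenario configuration to a YAML file
#'
#' The file holds the preset-independent description of a scenario: domain,
#' rectangle layout, region parameter table, biology constants, boundary
#' conditions, wind schedule, initial condition and run control. A `preset`
#' key may replace most of it; explicit keys override the preset's values.
#'
#' @param config An `aedes_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "aedes_scenario"))
  x <- list(
    name = config$name,
    description = config$description,
    domain = list(Lx = config$Lx, Ly = config$Ly, dx = config$dx),
    layout = list(background = config$layout$background,
                  provenance = config$layout$provenance,
                  rectangles = lapply(seq_len(nrow(config$layout$rectangles)),
                                      function(i) as.list(config$layout$rectangles[i, ]))),
    regions = lapply(seq_len(nrow(config$region_table)),
                     function(i) as.list(config$region_table[i, ])),
    biology = unclass(config$biology),
    boundary = list(sides = config$bc$sides, values = config$bc$values),
    wind = list(mode = config$wind$mode,
                day_start_h = config$wind$day_start_h,
                day_end_h = config$wind$day_end_h,
                speeds = if (is.null(config$wind$speeds)) NULL else
                  lapply(seq_len(nrow(config$wind$speeds)),
                         function(i) as.list(config$wind$speeds[i, ]))),
    initial = config$initial,
    duration_days = config$duration_days,
    snapshot_days = config$snapshot_days,
    options = config$options
  )
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

config_keys <- c("preset", "name", "description", "domain", "layout",
                 "regions", "biology", "boundary", "wind", "initial",
                 "duration_days", "snapshot_days", "options")

#' Load and validate a scenario configuration
#'
#' Reads a YAML scenario file (see [write_scenario_config()]). A `preset`
#' key loads the named preset first; any other keys then override the
#' preset's fields. Unknown top-level keys are rejected; biology constants
#' omitted from the file keep their defaults; all scenario invariants are
#' validated before returning.
#'
#' @param path Path to the YAML config.
#' @return An `aedes_scenario`.
#' @export
load_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), config_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows_to_tibble <- function(rows) dplyr::bind_rows(lapply(rows, tibble::as_tibble))

  if (!is.null(x$preset)) {
    dx <- x$domain$dx %||% 2
    cfg <- scenario_preset(x$preset, dx = dx)
  } else {
    need <- c("domain", "layout", "regions", "initial", "duration_days")
    miss <- setdiff(need, names(x))
    if (length(miss) > 0) {
      stop("config missing key(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    cfg <- NULL
  }

  biology <- do.call(biology_defaults, (x$biology %||% list()))
  bc <- if (!is.null(x$boundary)) {
    do.call(boundary_spec, c(x$boundary$sides,
                             list(values = x$boundary$values %||% list())))
  } else if (!is.null(cfg)) cfg$bc else boundary_spec()
  wind <- if (!is.null(x$wind)) {
    wind_schedule(x$wind$mode %||% "constant",
                  speeds = if (is.null(x$wind$speeds)) NULL else rows_to_tibble(x$wind$speeds),
                  day_start_h = x$wind$day_start_h %||% 6,
                  day_end_h = x$wind$day_end_h %||% 18)
  } else if (!is.null(cfg)) cfg$wind else wind_schedule("constant")

  if (is.null(cfg)) {
    new_scenario(
      name = x$name %||% "custom",
      description = x$description %||% "",
      Lx = x$domain$Lx, Ly = x$domain$Ly, dx = x$domain$dx %||% 2,
      layout = list(background = x$layout$background %||% "street",
                    rectangles = rows_to_tibble(x$layout$rectangles),
                    provenance = x$layout$provenance %||% ""),
      region_table = rows_to_tibble(x$regions),
      biology = biology, bc = bc, wind = wind,
      initial = list(type = x$initial$type, region = x$initial$region,
                     rect = unlist(x$initial$rect),
                     M0 = x$initial$M0 %||% biology$k1,
                     A0 = x$initial$A0 %||% biology$k2),
      duration_days = x$duration_days,
      snapshot_days = x$snapshot_days %||% c(0, 21, 42),
      options = x$options %||% list()
    )
  } else {
    if (!is.null(x$biology)) cfg$biology <- biology
    if (!is.null(x$boundary)) cfg$bc <- bc
    if (!is.null(x$wind)) cfg$wind <- wind
    if (!is.null(x$regions)) cfg$region_table <- rows_to_tibble(x$regions)
    if (!is.null(x$layout)) {
      cfg$layout <- list(background = x$layout$background %||% cfg$layout$background,
                         rectangles = rows_to_tibble(x$layout$rectangles),
                         provenance = x$layout$provenance %||% cfg$layout$provenance)
    }
    if (!is.null(x$initial)) {
      cfg$initial <- list(type = x$initial$type, region = x$initial$region,
                          rect = unlist(x$initial$rect),
                          M0 = x$initial$M0 %||% cfg$biology$k1,
                          A0 = x$initial$A0 %||% cfg$biology$k2)
    }
    if (!is.null(x$duration_days)) cfg$duration_days <- x$duration_days
    if (!is.null(x$snapshot_days)) cfg$snapshot_days <- x$snapshot_days
    if (!is.null(x$options)) cfg$options[names(x$options)] <- x$options
    if (!is.null(x$name)) cfg$name <- x$name
    if (!is.null(x$description)) cfg$description <- x$description
    validate_scenario(cfg)
  }
}

#' Write a run manifest
#'
#' JSON record of a completed run: config hash (MD5 of the written config
#' file), package version, wall-clock start/end and output paths.
#'
#' @param config The `aedes_scenario` that was run.
#' @param outputs Character vector of output paths.
#' @param started,finished POSIXct wall times.
#' @param path Manifest output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, outputs, started, finished, path) {
  tmp <- tempfile(fileext = ".yaml")
  write_scenario_config(config, tmp)
  manifest <- list(
    scenario = config$name,
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("aedesfvm")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
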