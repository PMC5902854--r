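#' Wind forcing schedule
#'
#' Either a constant per-region wind (taken from the scenario's region
#' table) or a day/night periodic schedule: two windows tiling 24 h exactly,
#' each with its own per-region `(vx, vy)`. The switch times default to
#' 06:00 and 18:00.
#'
#' @param mode `"constant"` or `"periodic"`.
#' @param speeds For periodic mode, a tibble with columns `label`, `window`
#'   (`"day"` / `"night"`), `vx`, `vy` covering every region label.
#' @param day_start_h,day_end_h Daytime window bounds in hours (0-24).
#' @return Object of class `wind_schedule`.
#' @export
wind_schedule <- function(mode = c("constant", "periodic"), speeds = NULL,
                          day_start_h = 6, day_end_h = 18) {
  mode <- match.arg(mode)
  if (mode == "periodic") {
    if (is.null(speeds) ||
        !all(c("label", "window", "vx", "vy") %in% names(speeds))) {
      stop("periodic schedule needs a speeds table with label, window, vx, vy",
           call. = FALSE)
    }
    if (!all(speeds$window %in% c("day", "night"))) {
      stop("window must be 'day' or 'night'", call. = FALSE)
    }
    if (!(day_start_h >= 0 && day_start_h < day_end_h && day_end_h <= 24)) {
      stop("need 0 <= day_start_h < day_end_h <= 24 so windows tile 24 h",
           call. = FALSE)
    }
    speeds <- tibble::as_tibble(speeds)
  }
  structure(list(mode = mode, speeds = speeds,
                 day_start_h = day_start_h, day_end_h = day_end_h),
            class = "wind_schedule")
}

#' Wind fields at a time instant
#'
#' Piecewise-constant-in-time per-cell wind velocity fields. In constant
#' mode the scenario region table's `vx`, `vy` columns are expanded; in
#' periodic mode the day or night window speeds are selected by the time of
#' day.
#'
#' @param schedule A [wind_schedule()].
#' @param t_days Simulation time in days (time of day = fractional part).
#' @param regions A [region_map()].
#' @param region_table The scenario's region table (used in constant mode).
#' @return List with matrices `vx` and `vy` (m/s).
#' @export
wind_at <- function(schedule, t_days, regions, region_table = NULL) {
  stopifnot(inherits(schedule, "wind_schedule"), inherits(regions, "region_map"))
  grid <- regions$grid
  if (schedule$mode == "constant") {
    if (is.null(region_table)) stop("constant mode needs region_table", call. = FALSE)
    idx <- match(regions$labels, region_table$label)
    return(list(
      vx = matrix(region_table$vx[idx], nrow = grid$nx),
      vy = matrix(region_table$vy[idx], nrow = grid$nx)
    ))
  }
  hour <- (t_days %% 1) * 24
  win <- if (hour >= schedule$day_start_h && hour < schedule$day_end_h) "day" else "night"
  tab <- schedule$speeds[schedule$speeds$window == win, ]
  missing <- setdiff(unique(as.vector(regions$labels)), tab$label)
  if (length(missing) > 0) {
    stop("wind schedule missing label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(regions$labels, tab$label)
  list(vx = matrix(tab$vx[idx], nrow = grid$nx),
       vy = matrix(tab$vy[idx], nrow = grid$nx))
}

# Wind switch times (days) within [0, duration] for segment construction.
wind_switch_times <- function(schedule, duration_days) {
  if (schedule$mode == "constant") return(numeric(0))
  per_day <- sort(unique(c(schedule$day_start_h, schedule$day_end_h) / 24))
  tt <- as.vector(outer(per_day, seq_len(ceiling(duration_days) + 1) - 1, "+"))
  tt[tt > 0 & tt < duration_days]
}

new_scenario <- function(name, description, Lx, Ly, dx, layout, region_table,
                         biology, bc, wind, initial, duration_days,
                         snapshot_days, options = list()) {
  opts <- list(face_diffusion = "harmonic", dt_cap = 600)
  opts[names(options)] <- options
  cfg <- structure(
    list(name = name, description = description, Lx = Lx, Ly = Ly, dx = dx,
         layout = layout, region_table = tibble::as_tibble(region_table),
         biology = biology, bc = bc, wind = wind, initial = initial,
         duration_days = duration_days, snapshot_days = snapshot_days,
         options = opts),
    class = "aedes_scenario")
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks grid, layout, region table coverage, parameter invariants, wind
#' schedule and initial-condition spec; errors on the first violation.
#'
#' @param config An `aedes_scenario`.
#' @return `config`, invisibly.
#' @export
validate_scenario <- function(config) {
  stopifnot(inherits(config, "aedes_scenario"))
  if (config$duration_days <= 0) stop("duration must be positive", call. = FALSE)
  if (config$dx <= 0) stop("dx must be positive", call. = FALSE)
  grid <- scenario_grid(config)
  regions <- scenario_regions(config)
  build_parameter_fields(regions, config$region_table, config$biology)
  stopifnot(inherits(config$bc, "boundary_spec"),
            inherits(config$wind, "wind_schedule"))
  init <- config$initial
  if (!init$type %in% c("region", "rect")) {
    stop("initial$type must be 'region' or 'rect'", call. = FALSE)
  }
  if (init$type == "region" &&
      !init$region %in% unique(as.vector(regions$labels))) {
    stop("initial region label not present in the raster: ", init$region,
         call. = FALSE)
  }
  if (init$M0 < 0 || init$A0 < 0) stop("seed amplitudes must be >= 0", call. = FALSE)
  if (any(config$snapshot_days < 0) ||
      any(config$snapshot_days > config$duration_days)) {
    stop("snapshot days must lie in [0, duration]", call. = FALSE)
  }
  if (config$wind$mode == "periodic") {
    wind_at(config$wind, 0, regions)  # coverage check
  }
  invisible(config)
}

#' @export
print.aedes_scenario <- function(x, ...) {
  cat(sprintf("<aedes_scenario> %s: %g x %g m at dx = %g m, %g days\n",
              x$name, x$Lx, x$Ly, x$dx, x$duration_days))
  cat(" ", x$description, "\n")
  invisible(x)
}

#' Grid and region raster of a scenario
#'
#' @param config An `aedes_scenario`.
#' @return `scenario_grid()` returns the [fv_grid()]; `scenario_regions()`
#'   rasterizes the rectangle layout into a [region_map()].
#' @export
scenario_grid <- function(config) {
  fv_grid(round(config$Lx / config$dx), round(config$Ly / config$dx),
          config$Lx, config$Ly)
}

#' @rdname scenario_grid
#' @export
scenario_regions <- function(config) {
  rasterize_blocks(scenario_grid(config), config$layout$rectangles,
                   background = config$layout$background,
                   provenance = config$layout$provenance)
}

#' Initial state of a scenario
#'
#' Seeds `M = M0`, `A = A0` inside the configured seed area (a region label
#' or an explicit rectangle) and zero elsewhere.
#'
#' @param config An `aedes_scenario`.
#' @return An [fv_state()] at `t = 0`.
#' @export
initial_state <- function(config) {
  grid <- scenario_grid(config)
  regions <- scenario_regions(config)
  mask <- if (config$initial$type == "region") {
    regions$labels == config$initial$region
  } else {
    r <- config$initial$rect
    cc <- cell_centers(grid)
    matrix(cc$x >= r[1] & cc$x < r[3] & cc$y >= r[2] & cc$y < r[4],
           nrow = grid$nx)
  }
  fv_state(M = mask * config$initial$M0, A = mask * config$initial$A0, grid)
}

# ---- Presets --------------------------------------------------------------
# Block layouts are approximate reconstructions of the studied neighbourhoods
# (regular street grids with the documented block counts); exact block
# coordinates are not published.

grid_rectangles <- function(label, ncol_b, nrow_b, Lx, Ly, street_w,
                            x_off = 0, width = Lx - x_off) {
  bw <- (width - (ncol_b + 1) * street_w) / ncol_b
  bh <- (Ly - (nrow_b + 1) * street_w) / nrow_b
  g <- expand.grid(i = seq_len(ncol_b), j = seq_len(nrow_b))
  tibble::tibble(
    label = label,
    x0 = x_off + street_w + (g$i - 1) * (bw + street_w),
    y0 = street_w + (g$j - 1) * (bh + street_w),
    x1 = x_off + street_w + (g$i - 1) * (bw + street_w) + bw,
    y1 = street_w + (g$j - 1) * (bh + street_w) + bh
  )
}

#' Scenario presets
#'
#' Ready-to-run configurations of the four studied settings:
#'
#' * `scenario_example1()`: generic 200 x 200 m city quarter, 3 x 3 building
#'   blocks separated by streets; constant wind along the streets with the
#'   y-component larger than the x-component; populations seeded in the
#'   lower-left corner; closed (zero-gradient) boundaries.
#' * `scenario_example2()`: 500 x 500 m Juiz de Fora city-centre
#'   reconstruction, 17 building blocks plus one park in a regular street
#'   grid; populations seeded in the park; no insecticide.
#' * `scenario_example3(variant)`: same domain with adulticide either
#'   concentrated on one street corridor (`h1 = 7.6`/day) or spread along
#'   all streets (`h1 = 0.928`/day); `h2 = 0` everywhere (adulticiding does
#'   not touch the aquatic phase).
#' * `scenario_example4()`: 400 x 400 m Copacabana beach front, 12 blocks,
#'   streets and a beach strip along the sea side; day/night periodic wind
#'   (beach speeds twice the street speeds), Dirichlet zero winged density on
#'   the sea-facing side; populations seeded in a small interior park area.
#'
#' @param dx Cell size in metres (default 2).
#' @param seed_M0,seed_A0 Seed amplitudes for the winged / aquatic phase
#'   (defaults: the carrying capacities `k1`, `k2`).
#' @param biology A [biology_defaults()] list.
#' @return An `aedes_scenario`.
#' @examples
#' cfg <- scenario_example1(dx = 10)
#' @export
scenario_example1 <- function(dx = 2, seed_M0 = NULL, seed_A0 = NULL,
                              biology = biology_defaults()) {
  rect <- grid_rectangles("block", 3, 3, 200, 200, street_w = 12.5)
  new_scenario(
    name = "example1",
    description = "Generic city quarter: 3x3 building blocks and streets, 200 x 200 m",
    Lx = 200, Ly = 200, dx = dx,
    layout = list(background = "street", rectangles = rect,
                  provenance = "approximate reconstruction of a generic square quarter"),
    region_table = tibble::tibble(
      label = c("block", "street"),
      psi = c(1, 0.3),
      vx = c(0, 5.0e-2), vy = c(0, 1.5e-1),
      Dx = c(3.75e-3, 1.25e-2), Dy = c(3.75e-3, 1.25e-2),
      h1 = c(0, 0), h2 = c(0, 0)),
    biology = biology,
    bc = boundary_spec(),
    wind = wind_schedule("constant"),
    initial = list(type = "rect", rect = c(0, 0, 30, 30),
                   M0 = seed_M0 %||% biology$k1, A0 = seed_A0 %||% biology$k2),
    duration_days = 42, snapshot_days = c(0, 21, 42)
  )
}

juiz_layout <- function() {
  # 6 x 3 slots in a regular street grid; the central slot of the middle row
  # is the park, the remaining 17 are building blocks.
  rect <- grid_rectangles("block", 6, 3, 500, 500, street_w = 10)
  park_slot <- which(rect$x0 < 250 & rect$x1 > 200 & rect$y0 < 250 & rect$y1 > 250)
  if (length(park_slot) != 1) {  # pick the slot containing the domain centre row, col 3
    park_slot <- 3 + 6  # col 3, row 2 in column-major expand.grid order
  }
  rect$label[park_slot] <- "park"
  list(background = "street", rectangles = rect,
       provenance = "approximate reconstruction of the Juiz de Fora city centre (17 blocks + park)")
}

juiz_region_table <- function() {
  tibble::tibble(
    label = c("block", "street", "park"),
    psi = c(1, 0.3, 0.8),
    vx = c(0, -1.0e-1, -5.0e-2), vy = c(0, 5e-2, 2.5e-2),
    Dx = c(3.75e-3, 1.25e-2, 1.25e-2), Dy = c(3.75e-3, 1.25e-2, 1.25e-2),
    h1 = c(0, 0, 0), h2 = c(0, 0, 0))
}

#' @rdname scenario_example1
#' @export
scenario_example2 <- function(dx = 2, seed_M0 = NULL, seed_A0 = NULL,
                              biology = biology_defaults()) {
  new_scenario(
    name = "example2",
    description = "Juiz de Fora city centre: 17 blocks + park, 500 x 500 m, no insecticide",
    Lx = 500, Ly = 500, dx = dx,
    layout = juiz_layout(),
    region_table = juiz_region_table(),
    biology = biology,
    bc = boundary_spec(),
    wind = wind_schedule("constant"),
    initial = list(type = "region", region = "park",
                   M0 = seed_M0 %||% biology$k1, A0 = seed_A0 %||% biology$k2),
    duration_days = 42, snapshot_days = c(0, 21, 42)
  )
}

#' @rdname scenario_example1
#' @param variant `"one_street"` (adulticide concentrated on a single street
#'   corridor at 7.6/day) or `"all_streets"` (0.928/day on every street).
#' @export
scenario_example3 <- function(variant = c("one_street", "all_streets"), dx = 2,
                              seed_M0 = NULL, seed_A0 = NULL,
                              biology = biology_defaults()) {
  variant <- match.arg(variant)
  cfg <- scenario_example2(dx = dx, seed_M0 = seed_M0, seed_A0 = seed_A0,
                           biology = biology)
  if (variant == "all_streets") {
    cfg$region_table$h1[cfg$region_table$label == "street"] <- 0.928
    cfg$description <- "Juiz de Fora with adulticide along all streets (h1 = 0.928/day)"
  } else {
    # Treated corridor: the vertical street immediately west of the park
    # column, full domain height; transport parameters identical to streets.
    rect <- cfg$layout$rectangles
    park <- rect[rect$label == "park", ]
    corridor <- tibble::tibble(label = "treated_street",
                               x0 = park$x0 - 10, y0 = 0,
                               x1 = park$x0, y1 = 500)
    cfg$layout$rectangles <- dplyr::bind_rows(rect, corridor)
    street <- cfg$region_table[cfg$region_table$label == "street", ]
    street$label <- "treated_street"
    street$h1 <- 7.6
    cfg$region_table <- dplyr::bind_rows(cfg$region_table, street)
    cfg$description <- "Juiz de Fora with adulticide along one street corridor (h1 = 7.6/day)"
  }
  cfg$name <- paste0("example3_", variant)
  validate_scenario(cfg)
}

#' @rdname scenario_example1
#' @export
scenario_example4 <- function(dx = 2, seed_M0 = NULL, seed_A0 = NULL,
                              biology = biology_defaults()) {
  # Beach strip along the sea-facing (right) side; 3 x 4 blocks on the
  # city side; daytime wind blows from the sea towards the city (vx < 0).
  beach_w <- 50
  rect <- dplyr::bind_rows(
    grid_rectangles("block", 3, 4, 400, 400, street_w = 10,
                    x_off = 0, width = 400 - beach_w),
    tibble::tibble(label = "beach", x0 = 400 - beach_w, y0 = 0, x1 = 400, y1 = 400)
  )
  speeds <- tibble::tibble(
    label = rep(c("block", "street", "beach"), 2),
    window = rep(c("day", "night"), each = 3),
    vx = c(0, -0.2, -0.4, 0, 0, 0),
    vy = c(0, 0.15, 0.3, 0, -0.25, -0.5))
  new_scenario(
    name = "example4",
    description = "Copacabana beach front: 12 blocks, streets and beach, periodic day/night wind",
    Lx = 400, Ly = 400, dx = dx,
    layout = list(background = "street", rectangles = rect,
                  provenance = "approximate reconstruction of the Copacabana beach front (12 blocks + beach strip)"),
    region_table = tibble::tibble(
      label = c("block", "street", "beach"),
      psi = c(1, 0.3, 0.8),
      vx = c(0, -0.2, -0.4), vy = c(0, 0.15, 0.3),  # daytime values; schedule overrides
      Dx = c(3.75e-3, 1.25e-2, 1.25e-2), Dy = c(3.75e-3, 1.25e-2, 1.25e-2),
      h1 = c(0, 0, 0), h2 = c(0, 0, 0)),
    biology = biology,
    bc = boundary_spec(right = "dirichlet"),
    wind = wind_schedule("periodic", speeds = speeds),
    initial = list(type = "rect", rect = c(180, 180, 220, 220),
                   M0 = seed_M0 %||% biology$k1, A0 = seed_A0 %||% biology$k2),
    duration_days = 42, snapshot_days = c(0, 21, 42)
  )
}

#' List the built-in presets
#'
#' @return Tibble with `preset` and `description`.
#' @export
scenario_presets <- function() {
  tibble::tibble(
    preset = c("example1", "example2", "example3:one_street",
               "example3:all_streets", "example4"),
    description = c(
      "Generic city quarter (blocks + streets)",
      "Juiz de Fora city centre, no insecticide",
      "Juiz de Fora, adulticide on one street corridor (h1 = 7.6/day)",
      "Juiz de Fora, adulticide on all streets (h1 = 0.928/day)",
      "Copacabana beach front, periodic day/night wind"))
}

#' Build a preset by name
#'
#' @param preset One of the names from [scenario_presets()] (`"example3"`
#'   accepts the `"example3:variant"` form).
#' @param ... Passed to the preset constructor (e.g. `dx`).
#' @return An `aedes_scenario`.
#' @export
scenario_preset <- function(preset, ...) {
  parts <- strsplit(preset, ":", fixed = TRUE)[[1]]
  switch(parts[1],
    example1 = scenario_example1(...),
    example2 = scenario_example2(...),
    example3 = scenario_example3(variant = if (length(parts) > 1) parts[2] else "one_street", ...),
    example4 = scenario_example4(...),
    stop("unknown preset: ", preset, call. = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
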