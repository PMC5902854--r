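#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the total-population time series of a run
#'
#' @param x An `aedes_sim`.
#' @param ... Unused.
#' @return Long tibble `(t_day, phase, total)`.
#' @export
tidy.aedes_sim <- function(x, ...) {
  tidyr::pivot_longer(x$totals, c("winged", "aquatic"),
                      names_to = "phase", values_to = "total")
}

#' One-row summary of a run
#'
#' @param x An `aedes_sim`.
#' @param ... Unused.
#' @return Tibble with scenario name, duration, step counts, stability
#'   indicators and final totals.
#' @export
glance.aedes_sim <- function(x, ...) {
  fin <- dplyr::slice_tail(x$totals, n = 1)
  tibble::tibble(
    scenario = x$config$name,
    duration_days = x$config$duration_days,
    n_steps = sum(x$reports$n_steps),
    dt_min_s = min(x$reports$dt_s),
    max_cfl = max(x$reports$max_cfl),
    min_density = min(x$reports$min_M, x$reports$min_A),
    final_winged = fin$winged,
    final_aquatic = fin$aquatic
  )
}

field_to_tibble <- function(field, grid) {
  cc <- cell_centers(grid)
  cc$value <- as.vector(field)
  cc
}

#' Plot a snapshot as a raster map
#'
#' @param object An `aedes_sim`.
#' @param day Snapshot day (default: the last configured snapshot).
#' @param phase `"winged"` or `"aquatic"`.
#' @param quantity `"support_weighted"` (the mapped quantity `psi * U`) or
#'   `"density"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aedes_sim <- function(object, day = max(object$config$snapshot_days),
                               phase = c("winged", "aquatic"),
                               quantity = c("support_weighted", "density"),
                               ...) {
  phase <- match.arg(phase)
  quantity <- match.arg(quantity)
  df <- field_to_tibble(snapshot_field(object, day, phase, quantity),
                        object$grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (quantity == "support_weighted")
      expression(psi %*% U) else "density") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, %s phase, day %g",
                                  object$config$name, phase, day),
                  x = "x (m)", y = "y (m)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot total-population trajectories of one or more runs
#'
#' @param ... Named `aedes_sim` objects (names become the legend labels).
#' @return A ggplot object with one panel per phase.
#' @export
plot_totals <- function(...) {
  runs <- list(...)
  if (is.null(names(runs)) || any(!nzchar(names(runs)))) {
    names(runs) <- vapply(runs, function(r) r$config$name, character(1))
  }
  df <- dplyr::bind_rows(lapply(runs, tidy), .id = "run")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_day, y = .data$total,
                                   colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~phase, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "domain total")
}

#' Write run outputs as CSV
#'
#' Writes the totals time series (`totals.csv`), one CSV field grid per
#' snapshot and phase (`snapshot_d<day>_<phase>.csv`, rows = y, columns = x,
#' support-weighted), and the region label grid.
#'
#' @param result An `aedes_sim`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_result_csv <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "totals.csv")
  utils::write.csv(result$totals, paths[1], row.names = FALSE)
  for (key in names(result$snapshots)) {
    for (ph in c("winged", "aquatic")) {
      f <- snapshot_field(result, as.numeric(key), ph)
      pth <- file.path(dir, sprintf("snapshot_d%s_%s.csv", key, ph))
      utils::write.table(t(f), pth, sep = ",", row.names = FALSE,
                         col.names = FALSE)
      paths <- c(paths, pth)
    }
  }
  rg <- file.path(dir, "regions.csv")
  write_region_csv(result$regions, rg)
  invisible(c(paths, rg))
}
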