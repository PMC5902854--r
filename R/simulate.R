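#' Run a scenario
#'
#' Integrates the coupled winged/aquatic system over the scenario duration
#' with forward-Euler steps at the [stable_dt()] bound. Time is split into
#' segments at wind-schedule switches and snapshot times; within a segment
#' the step is constant and chosen so the segment length is an exact
#' multiple. Fully deterministic: identical configurations produce identical
#' results.
#'
#' @param config An `aedes_scenario` (see [scenario_preset()]).
#' @param safety CFL safety fraction in (0, 1] passed to [stable_dt()].
#' @param record_dt_days Cadence (days) of the domain-total time series.
#' @param verbose Print per-segment progress lines.
#' @return Object of class `aedes_sim`: list with
#'   * `totals`: tibble `(t_day, winged, aquatic)` of
#'     \eqn{\int \psi M \, d\Omega} and \eqn{\int \psi A \, d\Omega};
#'   * `snapshots`: named list (by day) of `psiM` / `psiA` field matrices
#'     (the support-weighted populations) plus raw `M`, `A`;
#'   * `reports`: per-segment tibble (`t0_day`, `t1_day`, `dt_s`, `n_steps`,
#'     `max_cfl`, `min_M`, `min_A`);
#'   * `config`, `grid`, `regions`.
#' @examples
#' \donttest{
#' res <- simulate_scenario(scenario_example1(dx = 10))
#' dplyr::last(res$totals)
#' }
#' @export
simulate_scenario <- function(config, safety = 0.9, record_dt_days = 0.25,
                              verbose = FALSE) {
  validate_scenario(config)
  grid <- scenario_grid(config)
  regions <- scenario_regions(config)
  p <- build_parameter_fields(regions, config$region_table, config$biology)
  fd <- config$options$face_diffusion
  state <- initial_state(config)

  breaks <- sort(unique(c(0, config$duration_days, config$snapshot_days,
                          wind_switch_times(config$wind, config$duration_days))))
  snapshots <- list()
  grab <- function(day) {
    snapshots[[sprintf("%g", day)]] <<- list(
      t_day = day, psiM = p$psi * state$M, psiA = p$psi * state$A,
      M = state$M, A = state$A)
  }
  if (0 %in% config$snapshot_days) grab(0)

  totals_t <- 0
  b <- bc_codes(config$bc)
  tm0 <- sum(p$psi * state$M) * grid$dx * grid$dy
  ta0 <- sum(p$psi * state$A) * grid$dx * grid$dy
  totals_m <- tm0; totals_a <- ta0
  reports <- vector("list", length(breaks) - 1)

  for (s in seq_len(length(breaks) - 1)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1]
    w <- wind_at(config$wind, (t0 + t1) / 2, regions, config$region_table)
    p$vx <- w$vx; p$vy <- w$vy
    dt_bound <- stable_dt(p, grid, safety = safety, cap = config$options$dt_cap,
                          face_diffusion = fd)
    seg_s <- (t1 - t0) * 86400
    nsteps <- max(1L, ceiling(seg_s / dt_bound))
    dt <- seg_s / nsteps
    record_every <- max(1L, round(record_dt_days * 86400 / dt))
    out <- run_kernel(state$M, state$A, p, grid, config$bc, dt, nsteps,
                      t0_s = t0 * 86400, record_every = record_every,
                      face_diffusion = fd)
    state <- fv_state(pmax(out$M, 0), pmax(out$A, 0), grid, t = t1)
    keep <- -1L  # drop the duplicated segment-start sample
    totals_t <- c(totals_t, out$rec_t[keep] / 86400)
    totals_m <- c(totals_m, out$rec_winged[keep])
    totals_a <- c(totals_a, out$rec_aquatic[keep])
    reports[[s]] <- tibble::tibble(
      t0_day = t0, t1_day = t1, dt_s = dt, n_steps = nsteps,
      max_cfl = max(dt * cfl_denominator(p, grid, fd) / p$psi),
      min_M = out$min_M, min_A = out$min_A)
    if (t1 %in% config$snapshot_days) grab(t1)
    if (verbose) {
      message(sprintf("segment %d: t = %.2f..%.2f d, dt = %.2f s, %d steps, total winged = %.4g",
                      s, t0, t1, dt, nsteps, dplyr::last(totals_m)))
    }
  }

  structure(
    list(totals = tibble::tibble(t_day = totals_t, winged = totals_m,
                                 aquatic = totals_a),
         snapshots = snapshots,
         reports = dplyr::bind_rows(reports),
         config = config, grid = grid, regions = regions),
    class = "aedes_sim")
}

#' @export
print.aedes_sim <- function(x, ...) {
  fin <- dplyr::slice_tail(x$totals, n = 1)
  cat(sprintf("<aedes_sim> %s: %g days, %d steps, final totals winged = %.4g, aquatic = %.4g\n",
              x$config$name, x$config$duration_days, sum(x$reports$n_steps),
              fin$winged, fin$aquatic))
  invisible(x)
}

#' Extract a snapshot field
#'
#' @param result An `aedes_sim`.
#' @param day Snapshot day (must be one of the configured snapshot days).
#' @param phase `"winged"` or `"aquatic"`.
#' @param quantity `"support_weighted"` for the plotted quantity
#'   \eqn{\psi U} or `"density"` for the raw density `U`.
#' @return Field matrix.
#' @export
snapshot_field <- function(result, day, phase = c("winged", "aquatic"),
                           quantity = c("support_weighted", "density")) {
  phase <- match.arg(phase)
  quantity <- match.arg(quantity)
  key <- sprintf("%g", day)
  if (!key %in% names(result$snapshots)) {
    stop("no snapshot at day ", day, "; available: ",
         paste(names(result$snapshots), collapse = ", "), call. = FALSE)
  }
  s <- result$snapshots[[key]]
  if (quantity == "support_weighted") {
    if (phase == "winged") s$psiM else s$psiA
  } else {
    if (phase == "winged") s$M else s$A
  }
}
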