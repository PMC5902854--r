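#' Domain-integrated population total
#'
#' Midpoint-quadrature integral \eqn{\int_\Omega \psi U \, d\Omega =
#' \sum_{cells} \psi U \, \Delta x \Delta y} of a support-weighted density
#' field — the quantity whose time series the strategy comparison is based
#' on.
#'
#' @param field Density field matrix `U`.
#' @param psi Area-support field matrix.
#' @param grid An [fv_grid()].
#' @return Scalar total.
#' @examples
#' g <- fv_grid(10, 10, 200, 200)
#' total_population(const_field(1, g), const_field(0.3, g), g)  # 12000
#' @export
total_population <- function(field, psi, grid) {
  check_field(field, grid, "field")
  check_field(psi, grid, "psi")
  sum(psi * field) * grid$dx * grid$dy
}

#' Percent reduction of a treated run against a baseline
#'
#' `100 * (1 - treated(t) / baseline(t))` for both phases, evaluated at the
#' requested day(s) by linear interpolation of the recorded total-population
#' series. Invariant to a common rescaling of both series, so the result is
#' insensitive to the seed amplitude once the comparison pair shares it. A
#' treated total above the baseline gives a negative (flagged) percentage; a
#' zero baseline gives `NA`.
#'
#' @param baseline,treated `aedes_sim` objects or their `totals` tibbles
#'   (`t_day`, `winged`, `aquatic`).
#' @param t_days Evaluation day(s); default 42 (the end of the six-week run).
#' @return Tibble `(t_day, phase, baseline, treated, reduction_pct,
#'   increased)`.
#' @export
reduction_percentage <- function(baseline, treated, t_days = 42) {
  get_tot <- function(x) if (inherits(x, "aedes_sim")) x$totals else tibble::as_tibble(x)
  b <- get_tot(baseline); tr <- get_tot(treated)
  interp <- function(tab, col, t) stats::approx(tab$t_day, tab[[col]], xout = t)$y
  res <- tidyr::expand_grid(t_day = t_days, phase = c("winged", "aquatic"))
  res$baseline <- ifelse(res$phase == "winged",
                         interp(b, "winged", res$t_day),
                         interp(b, "aquatic", res$t_day))
  res$treated <- ifelse(res$phase == "winged",
                        interp(tr, "winged", res$t_day),
                        interp(tr, "aquatic", res$t_day))
  res$reduction_pct <- ifelse(res$baseline == 0, NA_real_,
                              100 * (1 - res$treated / res$baseline))
  res$increased <- !is.na(res$reduction_pct) & res$reduction_pct < 0
  res
}

#' Solver-health summary of a completed run
#'
#' Collects the stability and sanity indicators of a run: the largest CFL
#' number accepted, the most negative density encountered (should be no
#' smaller than round-off), whether both domain totals grew monotonically,
#' and the relative mass imbalance of a transport-only twin (reactions and
#' wind off, diffusion only, closed boundaries) restarted from the final
#' state — a discrete-conservation check of the flux telescoping.
#'
#' @param result An `aedes_sim`.
#' @param twin_steps Number of steps of the conservation twin run.
#' @return A one-row tibble with the indicators and a logical `all_ok`.
#' @export
health_report <- function(result, twin_steps = 200) {
  stopifnot(inherits(result, "aedes_sim"))
  cfg <- result$config
  grid <- result$grid
  p <- build_parameter_fields(result$regions, cfg$region_table, cfg$biology)

  # transport-only twin: zero reactions, zero wind, closed boundaries
  p0 <- p
  p0$vx[] <- 0; p0$vy[] <- 0
  p0$gamma <- 0; p0$r <- 0; p0$mu1 <- 0; p0$mu2 <- 0
  p0$k1 <- max(p$k1, 1); p0$k2 <- max(p$k2, 1)
  p0$h1[] <- 0; p0$h2[] <- 0
  last_day <- sprintf("%g", max(cfg$snapshot_days))
  M <- result$snapshots[[last_day]]$M
  dt <- stable_dt(p0, grid, safety = 0.9, cap = cfg$options$dt_cap)
  out <- run_kernel(M, M, p0, grid, boundary_spec(), dt, twin_steps,
                    record_every = twin_steps)
  m0 <- out$rec_winged[1]
  mass_residual <- if (m0 > 0) abs(dplyr::last(out$rec_winged) - m0) / m0 else 0

  tot <- result$totals
  tibble::tibble(
    max_cfl = max(result$reports$max_cfl),
    min_density = min(result$reports$min_M, result$reports$min_A),
    mass_residual = mass_residual,
    monotone_winged = !is.unsorted(tot$winged),
    monotone_aquatic = !is.unsorted(tot$aquatic),
    cfl_ok = max_cfl <= 1,
    positivity_ok = min_density >= -1e-10 * max(1, result$config$biology$k2),
    conservation_ok = mass_residual <= 1e-10,
    all_ok = cfl_ok & positivity_ok & conservation_ok
  )
}

#' Mean density by region label
#'
#' @param result An `aedes_sim`.
#' @param day Snapshot day.
#' @param phase `"winged"` or `"aquatic"`.
#' @return Tibble `(label, mean_density)` of the raw (not support-weighted)
#'   density averaged over each region's cells.
#' @export
region_mean_density <- function(result, day, phase = c("winged", "aquatic")) {
  phase <- match.arg(phase)
  f <- snapshot_field(result, day, phase, quantity = "density")
  labs <- result$regions$labels
  tibble::tibble(
    label = sort(unique(as.vector(labs))),
    mean_density = vapply(sort(unique(as.vector(labs))),
                          function(l) mean(f[labs == l]), numeric(1))
  )
}
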