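#' Baseline biological rate constants
#'
#' Default vital rates of the two-phase mosquito model, shared by every
#' scenario: maturation of the aquatic phase into winged adults
#' (`gamma`, day^-1), oviposition (`r`, day^-1), logistic capacity scales of
#' the winged and aquatic densities (`k1`, `k2`), and natural mortalities
#' (`mu1`, `mu2`, day^-1).
#'
#' @param gamma,r,k1,k2,mu1,mu2 Override individual constants.
#' @return Named list of class `biology_params`.
#' @examples
#' biology_defaults()$r
#' @export
biology_defaults <- function(gamma = 0.2, r = 30, k1 = 25, k2 = 100,
                             mu1 = 4.0e-2, mu2 = 1.0e-2) {
  p <- list(gamma = gamma, r = r, k1 = k1, k2 = k2, mu1 = mu1, mu2 = mu2)
  for (nm in c("gamma", "r", "k1", "k2", "mu1", "mu2")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0) {
      stop(nm, " must be a positive scalar", call. = FALSE)
    }
  }
  structure(p, class = "biology_params")
}

# Smallest admissible area-support coefficient: the discrete update divides
# by psi, so psi = 0 is excluded even though the support coefficient is
# conceptually in [0, 1].
PSI_MIN <- 1e-6

check_psi <- function(psi) {
  if (any(psi > 1) || any(psi < PSI_MIN)) {
    stop(sprintf("psi must lie in [%g, 1]", PSI_MIN), call. = FALSE)
  }
  invisible(psi)
}

#' Map region labels to per-cell coefficient fields
#'
#' Expands a per-region coefficient table into piecewise-constant per-cell
#' fields on the raster: area support `psi` (dimensionless, in (0, 1]), wind
#' velocity `vx`, `vy` (m/s), diffusion `Dx`, `Dy` (m^2/s) and insecticide
#' kill rates `h1`, `h2` (day^-1), plus the scalar biology constants. The
#' expansion is idempotent and independent of the row order of the table.
#'
#' @param regions A [region_map()].
#' @param region_table Tibble with one row per label present in `regions` and
#'   columns `label`, `psi`, `vx`, `vy`, `Dx`, `Dy`, `h1`, `h2` (missing
#'   `h1`/`h2` columns default to 0).
#' @param biology A [biology_defaults()] list.
#' @return Object of class `parameter_fields`: per-cell matrices plus the
#'   biology constants and the source grid.
#' @examples
#' g <- fv_grid(4, 4, 200, 200)
#' rm <- rasterize_blocks(g)
#' tab <- tibble::tibble(label = "street", psi = 0.3, vx = 0.05, vy = 0.15,
#'                       Dx = 1.25e-2, Dy = 1.25e-2)
#' p <- build_parameter_fields(rm, tab)
#' @export
build_parameter_fields <- function(regions, region_table,
                                   biology = biology_defaults()) {
  stopifnot(inherits(regions, "region_map"))
  if (!inherits(biology, "biology_params")) biology <- do.call(biology_defaults, biology)
  region_table <- tibble::as_tibble(region_table)
  if (!"h1" %in% names(region_table)) region_table$h1 <- 0
  if (!"h2" %in% names(region_table)) region_table$h2 <- 0
  need <- c("label", "psi", "vx", "vy", "Dx", "Dy", "h1", "h2")
  if (!all(need %in% names(region_table))) {
    stop("region_table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(region_table$label)) {
    stop("duplicate labels in region_table", call. = FALSE)
  }
  present <- unique(as.vector(regions$labels))
  missing <- setdiff(present, region_table$label)
  if (length(missing) > 0) {
    stop("region_table is missing label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_psi(region_table$psi)
  if (any(region_table$Dx < 0) || any(region_table$Dy < 0)) {
    stop("diffusion coefficients must be non-negative", call. = FALSE)
  }
  if (any(region_table$h1 < 0) || any(region_table$h2 < 0)) {
    stop("killing rates must be non-negative", call. = FALSE)
  }

  idx <- match(regions$labels, region_table$label)
  grid <- regions$grid
  field_of <- function(col) {
    matrix(region_table[[col]][idx], nrow = grid$nx, ncol = grid$ny)
  }
  structure(
    list(psi = field_of("psi"), vx = field_of("vx"), vy = field_of("vy"),
         Dx = field_of("Dx"), Dy = field_of("Dy"),
         h1 = field_of("h1"), h2 = field_of("h2"),
         gamma = biology$gamma, r = biology$r, k1 = biology$k1,
         k2 = biology$k2, mu1 = biology$mu1, mu2 = biology$mu2,
         grid = grid),
    class = "parameter_fields"
  )
}

#' @export
print.parameter_fields <- function(x, ...) {
  cat(sprintf(
    "<parameter_fields> %d x %d cells; psi in [%g, %g]; max |v| = %g m/s; max h1 = %g /day\n",
    x$grid$nx, x$grid$ny, min(x$psi), max(x$psi),
    max(abs(x$vx), abs(x$vy)), max(x$h1)))
  invisible(x)
}
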