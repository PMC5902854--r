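#' Deterministic verification fixtures
#'
#' Small configurations with known analytic or independently computable
#' references, used by the numerical test surface:
#'
#' * `"1d_advection"`: a top-hat profile on an `n`-cell line with uniform
#'   positive wind and no diffusion; reference = the exactly translated
#'   profile.
#' * `"1d_diffusion"`: a narrow Gaussian with uniform diffusion and no wind;
#'   reference = the analytic heat kernel.
#' * `"two_region"`: a tiny two-label (block/street) scenario exercising a
#'   coefficient discontinuity.
#' * `"equilibrium"`: a uniform one-region scenario seeded everywhere at the
#'   positive homogeneous equilibrium; reference = [homogeneous_equilibrium()].
#'
#' @param kind Fixture kind.
#' @param n Problem size (cells per direction).
#' @return A list with the fields needed by the fixture kind; 1-D kinds
#'   return `M0`, transport coefficients, grid spacing and a `reference`
#'   function of time (seconds); scenario kinds return a `config` and a
#'   `reference`.
#' @export
make_fixture <- function(kind = c("1d_advection", "1d_diffusion",
                                  "two_region", "equilibrium"), n = 64) {
  kind <- match.arg(kind)
  switch(kind,
    "1d_advection" = {
      L <- 100
      dx <- L / n
      x <- (seq_len(n) - 0.5) * dx
      top_hat <- function(x) as.numeric(x >= 20 & x <= 40)
      list(kind = kind, n = n, L = L, dx = dx, x = x,
           M0 = top_hat(x), v = 0.05, D = 0,
           reference = function(t_s) top_hat(x - 0.05 * t_s))
    },
    "1d_diffusion" = {
      L <- 100
      dx <- L / n
      x <- (seq_len(n) - 0.5) * dx
      D <- 1.25e-2
      s0 <- 4  # initial Gaussian standard deviation (m)
      g <- function(x, s) exp(-(x - L / 2)^2 / (2 * s^2)) / sqrt(2 * pi * s^2)
      list(kind = kind, n = n, L = L, dx = dx, x = x,
           M0 = g(x, s0), v = 0, D = D,
           reference = function(t_s) g(x, sqrt(s0^2 + 2 * D * t_s)))
    },
    "two_region" = {
      g <- fv_grid(n, n, 100, 100)
      rect <- tibble::tibble(label = "block", x0 = 25, y0 = 25, x1 = 75, y1 = 75)
      cfg <- new_scenario(
        name = "two_region_fixture",
        description = "one block inside streets, for interface tests",
        Lx = 100, Ly = 100, dx = 100 / n,
        layout = list(background = "street", rectangles = rect,
                      provenance = "synthetic fixture"),
        region_table = tibble::tibble(
          label = c("block", "street"), psi = c(1, 0.3),
          vx = c(0, 5e-2), vy = c(0, 5e-2),
          Dx = c(3.75e-3, 1.25e-2), Dy = c(3.75e-3, 1.25e-2),
          h1 = 0, h2 = 0),
        biology = biology_defaults(),
        bc = boundary_spec(), wind = wind_schedule("constant"),
        initial = list(type = "region", region = "block", M0 = 25, A0 = 100),
        duration_days = 1, snapshot_days = c(0, 1))
      list(kind = kind, config = cfg, reference = c(labels = 2))
    },
    "equilibrium" = {
      eq <- homogeneous_equilibrium()
      cfg <- new_scenario(
        name = "equilibrium_fixture",
        description = "uniform field at the positive homogeneous equilibrium",
        Lx = 100, Ly = 100, dx = 100 / n,
        layout = list(background = "street", rectangles = NULL,
                      provenance = "synthetic fixture"),
        region_table = tibble::tibble(
          label = "street", psi = 0.3, vx = 0, vy = 0,
          Dx = 1.25e-2, Dy = 1.25e-2, h1 = 0, h2 = 0),
        biology = biology_defaults(),
        bc = boundary_spec(), wind = wind_schedule("constant"),
        initial = list(type = "region", region = "street",
                       M0 = eq$M, A0 = eq$A),
        duration_days = 1, snapshot_days = c(0, 1))
      list(kind = kind, config = cfg, reference = eq)
    })
}
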