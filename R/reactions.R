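#' Local reaction terms of the two-phase model
#'
#' `winged_reaction()` evaluates the non-spatial source/sink of the winged
#' phase, `gamma * A * (1 - M / k1) - (mu1 + h1) * M`: maturation out of the
#' aquatic pool throttled by the winged carrying capacity, minus natural and
#' insecticide-induced mortality. `aquatic_reaction()` evaluates
#' `r * M * (1 - A / k2) - (mu2 + h2 + gamma) * A`: oviposition by winged
#' females regulated by breeder occupation, minus mortality, larvicide and
#' maturation losses. Both are elementwise (no spatial coupling) and return
#' rates in day^-1 times density units.
#'
#' @param M,A Density field matrices (or scalars) of matching shape.
#' @param p A [build_parameter_fields()] object, or a plain list providing
#'   the needed constants (`gamma`, `k1`, `mu1`, `h1` / `r`, `k2`, `mu2`,
#'   `h2`, `gamma`); `h1`, `h2` may be scalars or fields.
#' @return Rate field of the same shape as `M`.
#' @examples
#' b <- biology_defaults()
#' winged_reaction(0, 10, c(b, h1 = 0))   # = gamma * 10 = 2
#' aquatic_reaction(0, 10, c(b, h2 = 0))  # = -(mu2 + gamma) * 10
#' @export
winged_reaction <- function(M, A, p) {
  if (!identical(dim(M), dim(A)) || length(M) != length(A)) {
    stop("M and A must have the same shape", call. = FALSE)
  }
  h1 <- if (is.null(p$h1)) 0 else p$h1
  p$gamma * A * (1 - M / p$k1) - (p$mu1 + h1) * M
}

#' @rdname winged_reaction
#' @export
aquatic_reaction <- function(M, A, p) {
  if (!identical(dim(M), dim(A)) || length(M) != length(A)) {
    stop("M and A must have the same shape", call. = FALSE)
  }
  h2 <- if (is.null(p$h2)) 0 else p$h2
  p$r * M * (1 - A / p$k2) - (p$mu2 + h2 + p$gamma) * A
}

#' Spatially homogeneous equilibria of the two-phase model
#'
#' With uniform parameters, no insecticide and all spatial terms zero, the
#' model reduces to a planar ODE with the extinction state (0, 0) and, when
#' `gamma * r > mu1 * (mu2 + gamma)`, one positive equilibrium `(M*, A*)`
#' solving `gamma * A (1 - M/k1) = mu1 * M` and
#' `r * M (1 - A/k2) = (mu2 + gamma) * A`. The positive root is located
#' numerically (bisection on the scalar reduction in `M`) to a relative
#' tolerance of 1e-10.
#'
#' @param biology A [biology_defaults()] list.
#' @return A list with `M`, `A` (the positive equilibrium, or `NULL` when
#'   only extinction exists), `trivial = c(M = 0, A = 0)`, and
#'   `extinction_only` flag.
#' @examples
#' homogeneous_equilibrium()  # approx (23.776, 97.140)
#' @export
homogeneous_equilibrium <- function(biology = biology_defaults()) {
  b <- if (inherits(biology, "biology_params")) biology else do.call(biology_defaults, biology)
  trivial <- c(M = 0, A = 0)
  if (b$gamma * b$r <= b$mu1 * (b$mu2 + b$gamma)) {
    return(list(M = NULL, A = NULL, trivial = trivial, extinction_only = TRUE))
  }
  # A as a function of M from the aquatic balance, substituted into the
  # winged balance; the root of f on (0, k1) is the positive equilibrium.
  A_of_M <- function(M) b$r * M * b$k2 / ((b$mu2 + b$gamma) * b$k2 + b$r * M)
  f <- function(M) b$gamma * A_of_M(M) * (1 - M / b$k1) - b$mu1 * M
  root <- stats::uniroot(f, lower = 1e-12 * b$k1, upper = b$k1 * (1 - 1e-12),
                         tol = 1e-10 * b$k1)$root
  list(M = root, A = A_of_M(root), trivial = trivial, extinction_only = FALSE)
}
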