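#' Boundary conditions for the winged phase
#'
#' One condition per domain side. `"neumann"` is the zero-gradient /
#' zero-net-influx condition: no diffusive flux through the side, advective
#' outflow carried with the boundary-cell value, zero advective inflow.
#' `"dirichlet"` fixes the boundary density (default 0, used for a sea-facing
#' side) via a ghost value entering both the upwind advective and the central
#' diffusive flux. The aquatic phase has no transport terms and therefore
#' needs no boundary condition.
#'
#' @param left,right,bottom,top `"neumann"` or `"dirichlet"`.
#' @param values Named list of Dirichlet boundary densities per side.
#' @return Object of class `boundary_spec`.
#' @examples
#' boundary_spec(right = "dirichlet")
#' @export
boundary_spec <- function(left = "neumann", right = "neumann",
                          bottom = "neumann", top = "neumann",
                          values = list(left = 0, right = 0, bottom = 0, top = 0)) {
  sides <- list(left = left, right = right, bottom = bottom, top = top)
  for (s in names(sides)) {
    sides[[s]] <- match.arg(sides[[s]], c("neumann", "dirichlet"))
  }
  vals <- list(left = 0, right = 0, bottom = 0, top = 0)
  vals[names(values)] <- values
  structure(list(sides = sides, values = vals), class = "boundary_spec")
}

bc_codes <- function(bc) {
  stopifnot(inherits(bc, "boundary_spec"))
  ord <- c("left", "right", "bottom", "top")
  list(
    code = as.integer(unlist(bc$sides[ord]) == "dirichlet"),
    value = as.numeric(unlist(bc$values[ord]))
  )
}

#' First-order upwind face value
#'
#' Returns the upstream cell value for an advective face: the left
#' (lower-index) cell when the face velocity is positive, the right cell when
#' it is negative, and the arithmetic mean at a zero-velocity face (a pure
#' tie-break; the advective flux vanishes there anyway).
#'
#' @param left_cell,right_cell Densities in the two cells sharing the face.
#' @param face_velocity Face-normal velocity (m/s), positive from left to
#'   right. All arguments recycle elementwise.
#' @return Upstream density value(s).
#' @examples
#' upwind_face_value(2, 4, 0.1)   # 2
#' upwind_face_value(2, 4, -0.1)  # 4
#' @export
upwind_face_value <- function(left_cell, right_cell, face_velocity) {
  ifelse(face_velocity > 0, left_cell,
         ifelse(face_velocity < 0, right_cell, (left_cell + right_cell) / 2))
}

#' Net flux divergence of the winged-phase transport operator
#'
#' Per-cell net divergence of the combined advective (first-order upwind) and
#' diffusive (two-point central) fluxes,
#' `[G(x+) - G(x-)]/dx + [G(y+) - G(y-)]/dy` with
#' `G = -v_f * M_upwind + D_f * dM/dn`, in density per second. Face
#' velocities are arithmetic means of the adjacent cells; face diffusivities
#' default to the harmonic mean (flux-continuous across region interfaces
#' with discontinuous D), with the arithmetic mean as an option.
#'
#' @param M Winged density field matrix.
#' @param p A [build_parameter_fields()] object (uses `vx`, `vy`, `Dx`, `Dy`).
#' @param grid An [fv_grid()].
#' @param bc A [boundary_spec()].
#' @param face_diffusion `"harmonic"` or `"arithmetic"`.
#' @return Rate field matrix (per second; not divided by psi).
#' @export
flux_divergence <- function(M, p, grid, bc = boundary_spec(),
                            face_diffusion = c("harmonic", "arithmetic")) {
  face_diffusion <- match.arg(face_diffusion)
  check_field(M, grid, "M")
  check_field(p$vx, grid, "vx")
  b <- bc_codes(bc)
  fvm_flux_div_cpp(M, p$vx, p$vy, p$Dx, p$Dy, grid$dx, grid$dy,
                   b$code, b$value, face_diffusion == "harmonic")
}

# Per-cell face-aware explicit-stability denominator:
# (outflow face velocities)/dx + (outflow face velocities)/dy
#   + sum(Dx faces)/dx^2 + sum(Dy faces)/dy^2.
# On uniform fields this reduces to |vx|/dx + |vy|/dy + 2Dx/dx^2 + 2Dy/dy^2.
cfl_denominator <- function(p, grid, face_diffusion = "harmonic") {
  nx <- grid$nx; ny <- grid$ny
  harm <- identical(face_diffusion, "harmonic")
  dmean <- function(a, b) if (harm) ifelse(a + b > 0, 2 * a * b / (a + b), 0) else (a + b) / 2

  # x-direction face arrays, (nx+1) x ny; boundary faces use the cell value
  vxf <- rbind(p$vx[1, , drop = FALSE],
               (p$vx[-nx, , drop = FALSE] + p$vx[-1, , drop = FALSE]) / 2,
               p$vx[nx, , drop = FALSE])
  Dxf <- rbind(p$Dx[1, , drop = FALSE],
               dmean(p$Dx[-nx, , drop = FALSE], p$Dx[-1, , drop = FALSE]),
               p$Dx[nx, , drop = FALSE])
  vyf <- cbind(p$vy[, 1, drop = FALSE],
               (p$vy[, -ny, drop = FALSE] + p$vy[, -1, drop = FALSE]) / 2,
               p$vy[, ny, drop = FALSE])
  Dyf <- cbind(p$Dy[, 1, drop = FALSE],
               dmean(p$Dy[, -ny, drop = FALSE], p$Dy[, -1, drop = FALSE]),
               p$Dy[, ny, drop = FALSE])

  # outflow parts: east/north faces drain the cell when vf > 0, west/south
  # faces when vf < 0; both can drain simultaneously in divergent flow
  vx_cell <- pmax(vxf[-1, , drop = FALSE], 0) +
    pmax(-vxf[-(nx + 1), , drop = FALSE], 0)
  vy_cell <- pmax(vyf[, -1, drop = FALSE], 0) +
    pmax(-vyf[, -(ny + 1), drop = FALSE], 0)
  Dx_cell <- Dxf[-(nx + 1), , drop = FALSE] + Dxf[-1, , drop = FALSE]
  Dy_cell <- Dyf[, -(ny + 1), drop = FALSE] + Dyf[, -1, drop = FALSE]

  vx_cell / grid$dx + vy_cell / grid$dy + Dx_cell / grid$dx^2 + Dy_cell / grid$dy^2
}

#' Largest stable forward-Euler time step
#'
#' Combined advective-diffusive explicit-stability bound
#' `safety * min over cells of psi / (|vx|/dx + |vy|/dy + 2 Dx/dx^2 +
#' 2 Dy/dy^2)`, evaluated with the outflow parts of the face velocities and
#' the face diffusivities the update actually uses (identical to the
#' cell-centred formula on uniform regions; conservative at region
#' interfaces and in locally divergent flow, where both opposite faces can
#' drain a cell). `psi` enters because the update divides the right-hand
#' side by the area-support coefficient.
#'
#' @param p A [build_parameter_fields()] object.
#' @param grid An [fv_grid()].
#' @param safety Fraction of the bound to use, in (0, 1].
#' @param cap Returned value (seconds) when no transport limits the step
#'   (all-zero wind and diffusion); also an upper bound on any returned step.
#' @param face_diffusion `"harmonic"` or `"arithmetic"`.
#' @return Time step in seconds.
#' @examples
#' # a uniform "street" field: 0.3 / (0.025 + 0.075 + 0.00625 + 0.00625) = 2.667 s
#' g <- fv_grid(10, 10, 20, 20)
#' tab <- tibble::tibble(label = "street", psi = 0.3, vx = 0.05, vy = 0.15,
#'                       Dx = 1.25e-2, Dy = 1.25e-2)
#' stable_dt(build_parameter_fields(rasterize_blocks(g), tab), g, safety = 1)
#' @export
stable_dt <- function(p, grid, safety = 0.9, cap = 600,
                      face_diffusion = c("harmonic", "arithmetic")) {
  face_diffusion <- match.arg(face_diffusion)
  if (safety <= 0 || safety > 1) stop("safety must be in (0, 1]", call. = FALSE)
  denom <- cfl_denominator(p, grid, face_diffusion)
  pos <- denom > 0
  if (!any(pos)) return(cap)
  min(cap, safety * min(p$psi[pos] / denom[pos]))
}

#' Simulation state
#'
#' @param M,A Density field matrices for the winged and aquatic phase.
#' @param grid The [fv_grid()] the fields live on.
#' @param t Simulation time in days.
#' @return Object of class `fv_state`.
#' @export
fv_state <- function(M, A, grid, t = 0) {
  check_field(M, grid, "M")
  check_field(A, grid, "A")
  if (min(M) < 0 || min(A) < 0) stop("densities must be non-negative", call. = FALSE)
  structure(list(M = M, A = A, t = t, grid = grid), class = "fv_state")
}

# Low-level multi-step driver around the compiled kernel. biology may carry
# all-zero rates (transport-only twin runs); dt in seconds.
run_kernel <- function(M, A, p, grid, bc, dt, nsteps, t0_s = 0,
                       record_every = 0L, face_diffusion = "harmonic") {
  b <- bc_codes(bc)
  out <- fvm_run_cpp(M, A, p$psi, p$vx, p$vy, p$Dx, p$Dy, p$h1, p$h2,
                     p$gamma, p$r, p$k1, p$k2, p$mu1, p$mu2,
                     grid$dx, grid$dy, b$code, b$value,
                     identical(face_diffusion, "harmonic"),
                     dt, as.integer(nsteps), t0_s, as.integer(record_every))
  if (!out$ok) {
    stop(sprintf(
      "solver aborted at t = %.4f days (step %d): NaN or negative density (min M = %.3e, min A = %.3e); reduce dt",
      (t0_s + out$fail_step * dt) / 86400, out$fail_step, out$min_M, out$min_A),
      call. = FALSE)
  }
  out
}

#' Advance the coupled system by one forward-Euler step
#'
#' Updates `M <- M + (dt / psi) * (flux_divergence(M) + winged_reaction)` and
#' `A <- A + (dt / psi) * aquatic_reaction` (the aquatic phase is static: no
#' transport terms). Day-rate constants are converted to per-second inside
#' the solver; `dt` is in seconds.
#'
#' @param state An [fv_state()].
#' @param p A [build_parameter_fields()] object.
#' @param grid An [fv_grid()].
#' @param bc A [boundary_spec()].
#' @param dt Time step in seconds; must not exceed [stable_dt()].
#' @param face_diffusion `"harmonic"` or `"arithmetic"`.
#' @return List with the advanced `state` and a one-row `report` tibble
#'   (`dt_s`, `max_cfl`, min/max of both fields, `positivity_ok`).
#' @export
fv_step <- function(state, p, grid, bc = boundary_spec(), dt,
                    face_diffusion = c("harmonic", "arithmetic")) {
  face_diffusion <- match.arg(face_diffusion)
  stopifnot(inherits(state, "fv_state"))
  out <- run_kernel(state$M, state$A, p, grid, bc, dt, 1L,
                    t0_s = state$t * 86400, face_diffusion = face_diffusion)
  denom <- cfl_denominator(p, grid, face_diffusion)
  report <- tibble::tibble(
    dt_s = dt,
    max_cfl = max(dt * denom / p$psi),
    min_M = min(out$M), max_M = max(out$M),
    min_A = min(out$A), max_A = max(out$A),
    positivity_ok = out$min_M >= 0 && out$min_A >= 0
  )
  list(state = fv_state(pmax(out$M, 0), pmax(out$A, 0), grid,
                        t = state$t + dt / 86400),
       report = report)
}
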