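# Independent loop-based reference operators and shared fixtures.  These
# deliberately re-derive the discretisation from the flux rules (upwind
# advection, two-point diffusion, Neumann outflow / Dirichlet ghost) without
# touching the package's compiled kernel.

# 1-D flux divergence of G = -v*M_up + D_f * dM/dx on a line of cells.
# bc: length-2 character ("neumann"/"dirichlet") for the low/high end.
oracle_flux_div_1d <- function(M, v, D, dx, bc = c("neumann", "neumann"),
                               bcv = c(0, 0), harmonic = TRUE) {
  n <- length(M)
  dmean <- function(a, b) {
    if (harmonic) if (a + b > 0) 2 * a * b / (a + b) else 0 else (a + b) / 2
  }
  G <- numeric(n + 1)  # faces 0..n
  # low face
  if (bc[1] == "dirichlet") {
    g <- bcv[1]
    Mu <- if (v[1] > 0) g else if (v[1] < 0) M[1] else (g + M[1]) / 2
    G[1] <- -v[1] * Mu + D[1] * (M[1] - g) / dx
  } else {
    G[1] <- if (v[1] < 0) -v[1] * M[1] else 0
  }
  for (f in seq_len(n - 1)) {  # face between cells f and f+1
    vf <- (v[f] + v[f + 1]) / 2
    Mu <- if (vf > 0) M[f] else if (vf < 0) M[f + 1] else (M[f] + M[f + 1]) / 2
    Df <- dmean(D[f], D[f + 1])
    G[f + 1] <- -vf * Mu + Df * (M[f + 1] - M[f]) / dx
  }
  if (bc[2] == "dirichlet") {
    g <- bcv[2]
    Mu <- if (v[n] > 0) M[n] else if (v[n] < 0) g else (M[n] + g) / 2
    G[n + 1] <- -v[n] * Mu + D[n] * (g - M[n]) / dx
  } else {
    G[n + 1] <- if (v[n] > 0) -v[n] * M[n] else 0
  }
  (G[-1] - G[-(n + 1)]) / dx
}

# 2-D ghost-cell reference: pads the field with ghost values implementing the
# boundary conditions, then applies the interior stencil everywhere.
oracle_flux_div_2d <- function(M, vx, vy, Dx, Dy, dx, dy,
                               bc = rep("neumann", 4), bcv = rep(0, 4),
                               harmonic = TRUE) {
  nx <- nrow(M); ny <- ncol(M)
  out <- matrix(0, nx, ny)
  for (j in seq_len(ny)) {
    out[, j] <- out[, j] +
      oracle_flux_div_1d(M[, j], vx[, j], Dx[, j], dx,
                         bc = bc[1:2], bcv = bcv[1:2], harmonic = harmonic)
  }
  for (i in seq_len(nx)) {
    out[i, ] <- out[i, ] +
      oracle_flux_div_1d(M[i, ], vy[i, ], Dy[i, ], dy,
                         bc = bc[3:4], bcv = bcv[3:4], harmonic = harmonic)
  }
  out
}

# Uniform single-region parameter fields on a grid, for solver tests.
uniform_params <- function(grid, psi = 1, vx = 0, vy = 0, Dx = 0, Dy = 0,
                           h1 = 0, h2 = 0, biology = biology_defaults()) {
  structure(
    c(list(psi = const_field(psi, grid), vx = const_field(vx, grid),
           vy = const_field(vy, grid), Dx = const_field(Dx, grid),
           Dy = const_field(Dy, grid), h1 = const_field(h1, grid),
           h2 = const_field(h2, grid), grid = grid),
      unclass(biology)),
    class = "parameter_fields")
}

# Biology with all rates zero: turns the kernel into a pure transport solver.
zero_biology <- function() {
  structure(list(gamma = 0, r = 0, k1 = 1, k2 = 1, mu1 = 0, mu2 = 0),
            class = "biology_params")
}

transport_run <- function(M, p, grid, bc = boundary_spec(), dt, nsteps,
                          record_every = 0L) {
  p[c("gamma", "r", "k1", "k2", "mu1", "mu2")] <- zero_biology()[
    c("gamma", "r", "k1", "k2", "mu1", "mu2")]
  aedesfvm:::run_kernel(M, M, p, grid, bc, dt, nsteps,
                        record_every = record_every)
}

# Closed-form positive equilibrium, independent of the package's root finder.
closed_form_equilibrium <- function(b = biology_defaults()) {
  M <- b$k2 * (b$gamma * b$r - b$mu1 * (b$mu2 + b$gamma)) /
    (b$gamma * b$r * b$k2 / b$k1 + b$mu1 * b$r)
  A <- b$r * M * b$k2 / ((b$mu2 + b$gamma) * b$k2 + b$r * M)
  c(M = M, A = A)
}

# Session-level cache so expensive scenario runs are shared across test files.
.sim_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

run_coarse <- function(preset, dx = 10) {
  cached_run(paste0(preset, "_dx", dx),
             simulate_scenario(scenario_preset(preset, dx = dx)))
}
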