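test_that("upwind face value picks the upstream cell", {
  expect_equal(upwind_face_value(2, 4, 0.1), 2)
  expect_equal(upwind_face_value(2, 4, -0.1), 4)
  expect_equal(upwind_face_value(3, 3, 0.7), 3)
  expect_equal(upwind_face_value(3, 3, 0), 3)
  expect_equal(upwind_face_value(c(1, 2), c(5, 6), c(1, -1)), c(1, 6))
})

test_that("flux divergence vanishes on a uniform field without wind", {
  g <- fv_grid(8, 6, 16, 12)
  p <- uniform_params(g, psi = 0.5, Dx = 0.01, Dy = 0.02)
  expect_equal(flux_divergence(const_field(3, g), p, g, boundary_spec()),
               const_field(0, g))
  expect_error(flux_divergence(matrix(0, 3, 3), p, g), "matrix matching")
})

test_that("flux divergence matches the independent loop oracle elementwise", {
  set.seed(42)
  for (rep in 1:5) {
    g <- fv_grid(12, 9, 24, 27)
    p <- uniform_params(g)
    p$vx <- matrix(runif(g$nx * g$ny, -0.2, 0.2), g$nx)
    p$vy <- matrix(runif(g$nx * g$ny, -0.2, 0.2), g$nx)
    p$Dx <- matrix(runif(g$nx * g$ny, 0, 0.02), g$nx)
    p$Dy <- matrix(runif(g$nx * g$ny, 0, 0.02), g$nx)
    M <- matrix(runif(g$nx * g$ny, 0, 10), g$nx)
    bc <- boundary_spec(right = "dirichlet", top = "dirichlet",
                        values = list(right = 1.5, top = 0))
    got <- flux_divergence(M, p, g, bc)
    want <- oracle_flux_div_2d(M, p$vx, p$vy, p$Dx, p$Dy, g$dx, g$dy,
                               bc = c("neumann", "dirichlet", "neumann", "dirichlet"),
                               bcv = c(0, 1.5, 0, 0))
    expect_equal(got, want, tolerance = 1e-13)
  }
})

test_that("1-D upwind translation matches a brute-force stencil oracle", {
  fx <- make_fixture("1d_advection", n = 64)
  g <- fv_grid(fx$n, 3, fx$L, 3 * fx$dx)  # y-uniform strip = 1-D problem
  p <- uniform_params(g, vx = fx$v, Dx = 0, Dy = 0)
  M <- matrix(fx$M0, g$nx, g$ny)
  got <- flux_divergence(M, p, g, boundary_spec())
  want <- oracle_flux_div_1d(fx$M0, rep(fx$v, fx$n), rep(0, fx$n), fx$dx)
  for (j in 1:3) expect_equal(got[, j], want, tolerance = 1e-14)
})

test_that("pure-diffusion divergence of a delta telescopes to zero total", {
  n <- 5
  g <- fv_grid(n, 2, n, 2)
  p <- uniform_params(g, Dx = 0.01, Dy = 0)
  M <- const_field(0, g); M[3, ] <- 1
  div <- flux_divergence(M, p, g, boundary_spec())
  expect_equal(sum(div), 0, tolerance = 1e-15)
})

test_that("stable_dt reproduces the worked bound, cap and refinement monotonicity", {
  g <- fv_grid(10, 10, 20, 20)  # dx = dy = 2 m
  p <- uniform_params(g, psi = 0.3, vx = 0.05, vy = 0.15,
                      Dx = 1.25e-2, Dy = 1.25e-2)
  expect_equal(stable_dt(p, g, safety = 1), 0.3 / 0.1125, tolerance = 1e-12)
  expect_equal(stable_dt(p, g, safety = 0.5), 0.5 * 0.3 / 0.1125,
               tolerance = 1e-12)
  # no transport: configured cap
  p0 <- uniform_params(g)
  expect_equal(stable_dt(p0, g), 600)
  expect_equal(stable_dt(p0, g, cap = 100), 100)
  # halving dx strictly decreases the bound
  g2 <- fv_grid(20, 20, 20, 20)
  p2 <- uniform_params(g2, psi = 0.3, vx = 0.05, vy = 0.15,
                       Dx = 1.25e-2, Dy = 1.25e-2)
  expect_lt(stable_dt(p2, g2), stable_dt(p, g))
  expect_error(stable_dt(p, g, safety = 1.5), "safety")
})

test_that("extinction and the positive equilibrium are fixed points of the step", {
  g <- fv_grid(8, 8, 40, 40)
  p <- uniform_params(g, psi = 0.3, Dx = 1.25e-2, Dy = 1.25e-2)
  dt <- stable_dt(p, g)

  s0 <- fv_state(const_field(0, g), const_field(0, g), g)
  out0 <- fv_step(s0, p, g, dt = dt)
  expect_equal(out0$state$M, const_field(0, g))
  expect_equal(out0$state$A, const_field(0, g))

  eq <- homogeneous_equilibrium()
  s1 <- fv_state(const_field(eq$M, g), const_field(eq$A, g), g)
  out1 <- fv_step(s1, p, g, dt = dt)
  expect_lt(max(abs(out1$state$M - eq$M)) / eq$M, 1e-8)
  expect_lt(max(abs(out1$state$A - eq$A)) / eq$A, 1e-8)
  expect_lte(out1$report$max_cfl, 1)
  expect_true(out1$report$positivity_ok)
})

test_that("one step changes total support-weighted mass by the reaction term only", {
  g <- fv_grid(9, 9, 18, 18)
  p <- uniform_params(g, psi = 0.4, Dx = 0.01, Dy = 0.01)
  M <- const_field(0, g); M[5, 5] <- 12   # delta spike, v = 0
  A <- const_field(0, g); A[5, 5] <- 30
  s <- fv_state(M, A, g)
  dt <- stable_dt(p, g)
  out <- fv_step(s, p, g, dt = dt)
  tot0 <- total_population(M, p$psi, g)
  tot1 <- total_population(out$state$M, p$psi, g)
  # psi * dM = dt * (flux + R); flux telescopes to zero with v = 0
  reaction <- dt / 86400 * sum(winged_reaction(M, A, c(
    unclass(biology_defaults()), list(h1 = 0)))) * g$dx * g$dy
  expect_equal(tot1 - tot0, reaction, tolerance = 1e-12 * max(1, abs(tot0)))
})

test_that("transport-only runs conserve mass to 1e-10 over 1000 steps", {
  set.seed(7)
  g <- fv_grid(20, 20, 40, 40)
  p <- uniform_params(g)
  p$psi <- matrix(runif(400, 0.3, 1), 20)
  p$Dx <- matrix(runif(400, 0, 0.02), 20)
  p$Dy <- matrix(runif(400, 0, 0.02), 20)
  M <- matrix(runif(400, 0, 100), 20)
  dt <- stable_dt(p, g)
  out <- transport_run(M, p, g, boundary_spec(), dt, 1000, record_every = 1000)
  expect_equal(out$rec_winged[length(out$rec_winged)], out$rec_winged[1],
               tolerance = 1e-10)
  expect_gte(out$min_M, 0)
})

test_that("positivity is preserved under the stability bound across random draws", {
  set.seed(2024)
  for (draw in 1:100) {
    nx <- sample(5:12, 1); ny <- sample(5:12, 1)
    g <- fv_grid(nx, ny, nx * runif(1, 1, 4), ny * runif(1, 1, 4))
    # two-region piecewise-constant coefficients, like the urban rasters
    split <- sample(2:(nx - 1), 1)
    reg <- matrix(1L, nx, ny); reg[seq_len(split), ] <- 2L
    pick <- function(lo, hi) runif(2, lo, hi)[reg]
    p <- uniform_params(g)
    p$psi <- matrix(pick(0.2, 1), nx)
    p$vx <- matrix(pick(-0.3, 0.3), nx)
    p$vy <- matrix(pick(-0.3, 0.3), nx)
    p$Dx <- matrix(pick(0, 0.02), nx)
    p$Dy <- matrix(pick(0, 0.02), nx)
    p$h1 <- matrix(pick(0, 8), nx)
    M <- matrix(runif(nx * ny, 0, 25), nx)
    A <- matrix(runif(nx * ny, 0, 100), nx)
    dt <- stable_dt(p, g)
    out <- aedesfvm:::run_kernel(M, A, p, g, boundary_spec(), dt, 5L)
    expect_gte(out$min_M, -1e-10 * 100)
    expect_gte(out$min_A, -1e-10 * 100)
  }
})

test_that("the 2-D solver on a y-uniform strip equals the scalar 1-D reference", {
  set.seed(11)
  n <- 40
  g <- fv_grid(n, 3, 80, 6)
  p <- uniform_params(g)
  v1 <- runif(n, -0.1, 0.1); D1 <- runif(n, 0, 0.02); psi1 <- runif(n, 0.3, 1)
  p$vx <- matrix(v1, n, 3); p$Dx <- matrix(D1, n, 3)
  p$psi <- matrix(psi1, n, 3)
  M1 <- runif(n, 0, 10)
  M <- matrix(M1, n, 3)
  dt <- stable_dt(p, g)
  out <- transport_run(M, p, g, boundary_spec(), dt, 1L)
  # scalar reference: forward-Euler on the 1-D operator, divided by psi
  ref <- M1 + dt / psi1 * oracle_flux_div_1d(M1, v1, D1, g$dx)
  for (j in 1:3) {
    expect_equal(out$M[, j], ref, tolerance = 1e-13)
  }
})

test_that("upwind advection is first-order accurate on smooth profiles", {
  errs <- c()
  for (n in c(64, 128, 256)) {
    L <- 100; dx <- L / n
    x <- (seq_len(n) - 0.5) * dx
    v <- 0.05
    gauss <- function(x) exp(-(x - 30)^2 / (2 * 6^2))
    g <- fv_grid(n, 3, L, 3 * dx)
    p <- uniform_params(g, vx = v)
    dt <- 0.5 * dx / v                     # fixed Courant number 0.5
    nsteps <- round(20 / v / dt)           # translate by 20 m
    out <- transport_run(matrix(gauss(x), n, 3), p, g, boundary_spec(), dt, nsteps)
    errs <- c(errs, mean(abs(out$M[, 2] - gauss(x - v * nsteps * dt))))
  }
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 0.8 & orders < 1.2))
})

test_that("top-hat advection self-converges at the discontinuous-data rate", {
  # L1 self-convergence for a discontinuity under first-order upwinding is
  # O(sqrt(dx)); assert monotone error decay and an order in [0.3, 1.1].
  sol <- list(); ns <- c(64, 128, 256)
  for (n in ns) {
    fx <- make_fixture("1d_advection", n = n)
    g <- fv_grid(n, 3, fx$L, 3 * fx$dx)
    p <- uniform_params(g, vx = fx$v)
    dt <- 0.5 * fx$dx / fx$v
    nsteps <- round(400 / dt)  # 400 s -> 20 m of translation
    out <- transport_run(matrix(fx$M0, n, 3), p, g, boundary_spec(), dt, nsteps)
    sol[[as.character(n)]] <- list(M = out$M[, 2], t = nsteps * dt,
                                   ref = fx$reference, x = fx$x)
  }
  errs <- vapply(as.character(ns), function(k) {
    s <- sol[[k]]; mean(abs(s$M - s$ref(s$t)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 0.3 & orders < 1.1))
})

test_that("explicit diffusion converges at second order to the heat kernel", {
  errs <- c()
  for (n in c(32, 64, 128)) {
    fx <- make_fixture("1d_diffusion", n = n)
    g <- fv_grid(n, 3, fx$L, 3 * fx$dx)
    p <- uniform_params(g, Dx = fx$D)
    dt <- 0.25 * fx$dx^2 / fx$D
    nsteps <- ceiling(2000 / dt)
    t_end <- nsteps * dt
    out <- transport_run(matrix(fx$M0, n, 3), p, g, boundary_spec(), dt, nsteps)
    errs <- c(errs, mean(abs(out$M[, 2] - fx$reference(t_end))))
  }
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 1.7 & orders < 2.3))
})

test_that("Dirichlet sides honour the prescribed value through a ghost cell", {
  set.seed(3)
  g <- fv_grid(10, 10, 20, 20)
  p <- uniform_params(g, Dx = 0.01, Dy = 0.01, vx = 0.03, vy = -0.02)
  M <- matrix(runif(100, 5, 10), 10)
  bc <- boundary_spec(right = "dirichlet", values = list(right = 0))
  got <- flux_divergence(M, p, g, bc)
  want <- oracle_flux_div_2d(M, p$vx, p$vy, p$Dx, p$Dy, g$dx, g$dy,
                             bc = c("neumann", "dirichlet", "neumann", "neumann"),
                             bcv = rep(0, 4))
  expect_equal(got, want, tolerance = 1e-13)
  # diffusion-only decay towards a zero boundary keeps the boundary-adjacent
  # column below the interior maximum
  p2 <- uniform_params(g, Dx = 0.01, Dy = 0.01)
  out <- transport_run(const_field(8, g), p2, g, bc,
                       dt = stable_dt(p2, g), nsteps = 200L)
  expect_lt(max(out$M[10, ]), max(out$M[2:8, ]))
  expect_true(all(out$M >= 0))
})

test_that("time steps beyond the stability bound abort with a diagnostic", {
  g <- fv_grid(16, 16, 32, 32)
  p <- uniform_params(g, psi = 0.3, vx = 0.1, vy = 0.1, Dx = 0.0125,
                      Dy = 0.0125)
  M <- const_field(0, g); M[8, 8] <- 25
  s <- fv_state(M, M * 4, g)
  dt_bad <- 50 * stable_dt(p, g)
  expect_error({
    st <- s
    for (i in 1:200) st <- fv_step(st, p, g, dt = dt_bad)$state
  }, "aborted")
})
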