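disc_coupled_spec <- function() {
  reaction_spec(D = 1, Ds = 1, g = function(c, cs) c - cs,
                dg_dc = function(c, cs) rep(1, length(c)))
}

test_that("surface predictor is exact for trivial and decay dynamics", {
  th <- 2 * pi * (0:31) / 32
  gam <- cbind(cos(th), sin(th))
  m <- get_disc_mesh(0.2)
  ## stationary curve, Ds = 0, g = h = 0: identity
  ops <- assemble_level(m, reaction_spec(D = 1, Ds = 0))
  set.seed(1)
  Cs <- rnorm(length(m$loops$membrane))
  expect_equal(predict_surface(ops, ops, rep(0, nrow(m$phys)), Cs, 0.01), Cs,
               tolerance = 1e-12)
  ## pure decay h(cs) = -r cs with Ds = 0: explicit treatment gives (1 - r dt) Cs
  r <- 0.3
  opsd <- assemble_level(m, reaction_spec(D = 1, Ds = 0,
                                          h = function(cs) -r * cs))
  expect_equal(predict_surface(opsd, opsd, rep(0, nrow(m$phys)), Cs, 0.01),
               (1 - r * 0.01) * Cs, tolerance = 1e-12)
})

test_that("surface heat equation on the circle decays at the exact rate", {
  ns <- 256
  th <- 2 * pi * (0:(ns - 1)) / ns
  gam <- cbind(cos(th), sin(th))
  s <- assemble_surface(gam, spec = reaction_spec(D = 1, Ds = 1))
  dt <- 1e-3
  cs1 <- as.numeric(Matrix::solve(s$Ms + dt * s$Ks, s$Ms %*% cos(th)))
  ## cos(theta) is the eigenfunction with eigenvalue -1
  expect_lt(max(abs(cs1 - exp(-dt) * cos(th))), 5e-6)
})

test_that("bulk Crank-Nicolson conserves mass exactly for f = g = 0", {
  m <- get_disc_mesh(0.15)
  spec <- reaction_spec(D = 1, Ds = 1)   # no g, no f
  ops <- assemble_level(m, spec)
  set.seed(3)
  C0 <- rnorm(nrow(m$phys))
  Cs0 <- rnorm(length(m$loops$membrane))
  Cs_t <- predict_surface(ops, ops, C0, Cs0, 0.01)
  C1 <- step_bulk_cn(ops, ops, C0, Cs0, Cs_t, 0.01)
  expect_lt(abs(sum(ops$M %*% as.numeric(C1)) - sum(ops$M %*% C0)), 1e-12)
  ## linear problem: Newton converges in one productive iteration
  expect_lte(attr(C1, "newton_iters"), 2L)
})

test_that("bulk + surface ligand-type mass is conserved by the coupled scheme", {
  ## with a pure transfer kernel g (no far field), the bulk loses exactly what
  ## the surface gains, step by step
  m <- get_disc_mesh(0.15)
  spec <- disc_coupled_spec()
  ops <- assemble_level(m, spec)
  loop <- m$loops$membrane
  th <- atan2(m$phys[loop, 2], m$phys[loop, 1])
  C0 <- 2 + m$phys[, 1]
  Cs0 <- 1 + 0.3 * cos(th)
  dt <- 0.01
  total0 <- sum(ops$M %*% C0) + sum(ops$Ms %*% Cs0)
  Cs_t <- predict_surface(ops, ops, C0, Cs0, dt)
  C1 <- as.numeric(step_bulk_cn(ops, ops, C0, Cs0, Cs_t, dt))
  Cs1 <- correct_surface(ops, ops, C0, C1, Cs0, Cs_t, dt)
  total1 <- sum(ops$M %*% C1) + sum(ops$Ms %*% Cs1)
  expect_lt(abs(total1 - total0), 1e-12 * abs(total0))
})

test_that("the corrector restores second-order accuracy (Richardson ratio)", {
  err <- sapply(c(4e-3, 2e-3), function(dt)
    run_disc_problem(h = 0.1, dt = dt, T = 0.2)$err_surf)
  ref <- run_disc_problem(h = 0.1, dt = 1e-4, T = 0.2)$err_surf
  ratio <- (err[1] - ref) / (err[2] - ref)
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 4.8)
})

test_that("the scheme tolerates a time step far above the diffusive scale", {
  r <- run_disc_problem(h = 0.1, dt = 0.1, T = 2)
  expect_true(all(is.finite(r$C)))
  expect_true(all(is.finite(r$Cs)))
  ## solution remains bounded by the initial amplitude
  expect_lt(max(abs(r$C)), 1)
  expect_lt(max(abs(r$Cs)), 1)
})

test_that("advance_one_step leaves a stationary reaction-free state unchanged", {
  m <- get_disc_mesh(0.2)
  st <- list(t = 0, mesh = m,
             curve = curve_state(m$phys[m$loops$membrane, ]),
             C = rep(2, nrow(m$phys)),
             Cs = rep(3, length(m$loops$membrane)))
  model <- list(spec = reaction_spec(D = 1, Ds = 1), normal_velocity = NULL)
  st1 <- advance_one_step(st, model, sim_config(dt = 0.01, n_steps = 1))
  expect_equal(st1$C, st$C, tolerance = 1e-10)
  expect_equal(st1$Cs, st$Cs, tolerance = 1e-10)
  expect_equal(st1$mesh$phys, m$phys)
  expect_equal(st1$t, 0.01)
})

test_that("the generic stepper reproduces the cached disc solver", {
  ex <- disc_exact_solution()
  m <- generate_initial_mesh(domain_spec("disc", h = 0.2, rf = 1))
  th <- atan2(m$phys[m$loops$membrane, 2], m$phys[m$loops$membrane, 1])
  st <- list(t = 0, mesh = m,
             curve = curve_state(m$phys[m$loops$membrane, ]),
             C = ex$c(m$phys[, 1], m$phys[, 2], 0), Cs = ex$cs(th, 0))
  model <- list(spec = disc_coupled_spec(), normal_velocity = NULL)
  cfg <- sim_config(dt = 1e-2, n_steps = 5)
  for (i in 1:5) st <- advance_one_step(st, model, cfg)
  rr <- run_disc_problem(h = 0.2, dt = 1e-2, T = 0.05, mesh = m)
  expect_equal(st$C, rr$C, tolerance = 1e-12)
  expect_equal(st$Cs, rr$Cs, tolerance = 1e-12)
})

test_that("mass is conserved under pure ALE mesh motion", {
  ## f = g = 0, stationary physical boundary, interior nodes redistributed by
  ## the MMPDE: the transported mass 1' M C is invariant even though the mesh
  ## moves (conservative formulation signature)
  m0 <- get_disc_mesh(0.2)
  dt <- 0.05
  m1 <- mmpde_step(m0, monitor = function(x, y, t) 1 + exp(-4 * (x - 0.3)^2),
                   dt = dt, tau = 5e-3)
  expect_gt(max(abs(m1$phys - m0$phys)), 1e-4)   # mesh really moved
  w <- mesh_velocity(m0$phys, m1$phys, dt)
  spec <- reaction_spec(D = 1, Ds = 1)
  ops0 <- assemble_level(m0, spec, w = w)
  ops1 <- assemble_level(m1, spec, w = w)
  C0 <- 1 + m0$phys[, 1]
  Cs0 <- rep(1, length(m0$loops$membrane))
  Cs_t <- predict_surface(ops0, ops1, C0, Cs0, dt)
  C1 <- as.numeric(step_bulk_cn(ops0, ops1, C0, Cs0, Cs_t, dt))
  mass0 <- sum(ops0$M %*% C0)
  mass1 <- sum(ops1$M %*% C1)
  expect_equal(mass1, mass0, tolerance = 1e-10)
})
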