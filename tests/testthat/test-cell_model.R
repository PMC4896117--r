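test_that("membrane reaction terms reduce correctly in degenerate cases", {
  mp <- meinhardt_params()
  th <- 2 * pi * (0:31) / 32
  cu <- curve_state(cbind(0.1 * cos(th), 0.1 * sin(th)))
  ## constant a: nonlocal term equals rb * a so the b equation is rb (a - b)
  r <- meinhardt_rhs(rep(2, 32), rep(0.5, 32), rep(1, 32), rep(0.01, 32), cu, mp)
  expect_equal(r$rb_terms, rep(mp$rb * (2 - 0.5), 32), tolerance = 1e-12)
  ## a = 0 with no basal production: activator term vanishes
  mp0 <- meinhardt_params(ba = 0)
  r0 <- meinhardt_rhs(rep(0, 32), rep(1, 32), rep(1, 32), rep(0.01, 32), cu, mp0)
  expect_equal(r0$ra_terms, rep(0, 32))
  expect_error(meinhardt_rhs(rep(1, 32), rep(0, 32), rep(1, 32),
                             rep(0.01, 32), cu, mp), "singular")
})

test_that("the homogeneous steady state is a root of the kinetics", {
  mp <- meinhardt_params()
  s <- mp$ra * 0.17
  ss <- meinhardt_steady_state(s, mp)
  th <- 2 * pi * (0:31) / 32
  cu <- curve_state(cbind(0.1 * cos(th), 0.1 * sin(th)))
  r <- meinhardt_rhs(rep(ss$a, 32), rep(ss$b, 32), rep(ss$c, 32),
                     rep(s, 32), cu, mp)
  expect_lt(max(abs(c(r$ra_terms, r$rb_terms, r$rc_terms))), 1e-10)
  ## independent fixed-point relations
  expect_equal(ss$b, ss$a)
  expect_equal(ss$c, mp$bc / mp$rc * ss$a)
})

test_that("the steady state is held stationary by the membrane stepper", {
  r <- run_cell_simulation(n_steps = 5, seed = 1, sigma_noise = 0,
                           perturbation = 0, lp = ligand_params(gradient = 0),
                           mot = motility_params(Kprot = 0, lambda = 0))
  ss <- meinhardt_steady_state(2e-2 * mean(r$trajectory$mean_Ro))
  expect_lt(max(abs(r$state$a - ss$a)), 1e-8)
  expect_lt(max(abs(r$state$b - ss$b)), 1e-8)
  expect_lt(max(abs(r$state$c - ss$c)), 1e-8)
})

test_that("receptor binding kinetics match equilibrium and an ODE oracle", {
  lp <- ligand_params()
  ## equilibrium occupancy zeroes the reaction
  l <- 6.2
  ls_eq <- lp$Rtot * l / (l + lp$Kd)
  expect_equal(ligand_surface_reaction(l, ls_eq, lp), 0, tolerance = 1e-9)
  expect_equal(ligand_surface_reaction(l, 0, lp), lp$k1 * lp$Rtot * l)
  ## relaxation toward equilibrium against a brute-force ODE integrator
  skip_if_not_installed("deSolve")
  out <- deSolve::ode(y = c(ls = 0), times = seq(0, 50, 0.5),
                      func = function(t, y, p)
                        list(ligand_surface_reaction(l, y[1], lp)),
                      parms = NULL)
  ## midpoint and endpoint of the relaxation
  expect_equal(unname(out[nrow(out), "ls"]), ls_eq, tolerance = 1e-3)
  rate <- lp$k1 * l + lp$k_minus1
  expect_equal(unname(out[out[, "time"] == 10, "ls"]),
               ls_eq * (1 - exp(-rate * 10)), tolerance = 1e-3)
})

test_that("equilibrium occupancy reproduces the front/back values", {
  field <- function(x) 5.3 + 8.5 * (x + 0.1)
  expect_equal(round(equilibrium_occupancy(field(-0.1), 30), 2), 0.15)
  expect_equal(round(equilibrium_occupancy(field(0.1), 30), 2), 0.19)
  expect_equal(equilibrium_occupancy(30, 30), 0.5)
})

test_that("the boundary velocity law balances protrusion against tension", {
  mot <- motility_params(Kprot = 1e-5)
  ## a = 0: pure tension shrinks a circle of radius R at rate lambda/R
  kap <- rep(1 / 0.1, 16)
  expect_equal(boundary_normal_velocity(rep(0, 16), kap, mot, 2e-6),
               rep(-2e-5, 16))
  ## exact balance
  a <- 2e-6 * kap / 1e-5
  expect_equal(boundary_normal_velocity(a, kap, mot, 2e-6), rep(0, 16))
})

test_that("tension dynamics follow the prescribed ODE", {
  mot <- motility_params(A0 = pi * 0.01)
  ## A = A0, dA/dt = 0: pure decay
  l1 <- tension_step(mot, 1e-6, mot$A0, 0, 0.1)
  expect_equal(l1, 1e-6 * (1 - 0.1 * mot$beta_tension), tolerance = 1e-12)
  ## larger area raises tension relative to pure decay
  l2 <- tension_step(mot, 1e-6, 1.2 * mot$A0, 0, 0.1)
  expect_gt(l2, l1)
  ## Euler trajectory tracks a high-accuracy ODE oracle for frozen inputs
  skip_if_not_installed("deSolve")
  Afro <- 1.1 * mot$A0
  rhs <- function(t, y, p) list(
    mot$lambda0 * y[1] * (Afro - mot$A0) / (mot$A0 * (y[1] + mot$lambda0)) -
      mot$beta_tension * y[1])
  out <- deSolve::ode(y = c(l = 1e-6), times = c(0, 1), func = rhs,
                      parms = NULL, method = "ode45")
  lam <- 1e-6
  for (s in 1:100) lam <- tension_step(mot, lam, Afro, 0, 0.01)
  expect_equal(lam, unname(out[2, "l"]), tolerance = 0.02)
  expect_warning(tension_step(mot, 1e-9, 0.01 * mot$A0, -1, 10), "clamped")
})

test_that("the mean-reverting noise has the right stationary moments", {
  set.seed(42)
  st <- noise_state(theta = 0.1, mu = 0.3)
  ## sigma = 0: deterministic exponential relaxation to mu
  st0 <- noise_state(eta = 1, theta = 0.5, mu = 0.3, sigma = 0)
  for (i in 1:200) st0 <- ou_noise_step(st0, 0.1)
  expect_equal(st0$eta, 0.3 + (1 - 0.3) * (1 - 0.5 * 0.1)^200, tolerance = 1e-9)
  ## stationary mean and variance over a long path
  n <- 1e5
  path <- numeric(n)
  for (i in seq_len(n)) {
    st <- ou_noise_step(st, 0.1)
    path[i] <- st$eta
  }
  keep <- path[1000:n]
  sd_exact <- st$sigma / sqrt(2 * st$theta)
  se <- sd_exact / sqrt(n * 0.1 * 2 * st$theta)   # effective sample size
  expect_lt(abs(mean(keep) - 0.3), 3 * se * 3)
  expect_lt(abs(stats::var(keep) - sd_exact^2) / sd_exact^2, 0.1)
})

test_that("the signal term combines occupancy and noise with a zero floor", {
  expect_equal(signal_term(0.15, 0, ra = 2e-2), 3e-3)
  expect_equal(signal_term(rep(0.2, 5), 0.1), rep(2e-2 * 0.3, 5))
  expect_equal(signal_term(0.2, -0.2), 0)
  expect_equal(signal_term(0.3, -1), 0)
})

test_that("a seeded perturbation grows into a localized activator patch", {
  ## pattern-forming regime: after the initial diffusive smoothing of the
  ## nodal perturbation, the activator maximum grows; fixed-seed regression
  r <- run_cell_simulation(n_steps = 800, seed = 7, perturbation = 0.1,
                           sigma_noise = 0)
  expect_gt(r$trajectory$max_a[800], r$trajectory$max_a[100])
  ## the growing structure is localized, not a uniform shift
  expect_gt((max(r$state$a) - min(r$state$a)) / mean(r$state$a), 0.1)
  expect_equal(r$remesh_count, 0L)
  ## bound receptors stay within [0, Rtot] throughout
  lp <- ligand_params()
  expect_true(all(r$state$ls >= 0 & r$state$ls <= lp$Rtot))
  expect_equal(r$clamp_events, 0L)
})

test_that("identical seeds give identical trajectories", {
  r1 <- run_cell_simulation(n_steps = 10, seed = 5)
  r2 <- run_cell_simulation(n_steps = 10, seed = 5)
  expect_identical(r1$trajectory, r2$trajectory)
  r3 <- run_cell_simulation(n_steps = 10, seed = 6)
  expect_false(identical(r3$trajectory$cx, r1$trajectory$cx))
})

test_that("forced protrusion dilutes the bound complex and retraction enriches it", {
  fp <- run_forced_protrusion(amplitude = 2e-4, n_steps = 20)
  expect_lt(fp$ls_anomaly, 0)
  fr <- run_forced_protrusion(amplitude = -2e-4, n_steps = 20)
  expect_gt(fr$ls_anomaly, 0)
  ## local statement: ls dips below the membrane mean inside the bump
  expect_lt(mean(fp$ls[fp$bump]), mean(fp$ls))
  expect_gt(mean(fr$ls[fr$bump]), mean(fr$ls))
})

test_that("a frozen uniform membrane generates no spurious gradient", {
  r <- run_cell_simulation(n_steps = 20, seed = 1,
                           lp = ligand_params(gradient = 0),
                           sigma_noise = 0, perturbation = 0,
                           mot = motility_params(Kprot = 0, A0 = pi * 0.01,
                                                 lambda = 0))
  expect_lt(diff(range(r$state$l)), 1e-10)
  expect_lt(diff(range(r$state$ls)) / mean(r$state$ls), 1e-10)
})
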