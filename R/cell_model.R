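#' Membrane activator-inhibitor kinetic parameters
#'
#' Nondimensional parameters of the membrane-bound pattern-forming system: a
#' local autocatalytic activator a, a rapidly redistributed global inhibitor b
#' and a slow local inhibitor c. Defaults are the standard values used for the
#' cell migration simulations.
#'
#' @param ra activator decay rate (also scales the signal term).
#' @param ba basal activator production rate.
#' @param sa saturation coefficient of the activator autocatalysis.
#' @param Da activator diffusion coefficient.
#' @param rb production and decay rate of the global inhibitor.
#' @param Db global inhibitor diffusion coefficient.
#' @param bc production rate of the local inhibitor.
#' @param rc decay rate of the local inhibitor.
#' @param Dc local inhibitor diffusion coefficient.
#' @param sc Michaelis-Menten constant of the activator kinetics.
#' @return an object of class `meinhardt_params`.
#' @export
meinhardt_params <- function(ra = 2e-2, ba = 1e-1, sa = 5e-4, Da = 4e-7,
                             rb = 3e-2, Db = 4e-5, bc = 7e-3, rc = 1.3e-2,
                             Dc = 2.8e-6, sc = 2e-1) {
  p <- list(ra = ra, ba = ba, sa = sa, Da = Da, rb = rb, Db = Db,
            bc = bc, rc = rc, Dc = Dc, sc = sc)
  if (any(unlist(p) < 0)) stop("kinetic parameters must be nonnegative")
  structure(p, class = "meinhardt_params")
}

#' Protrusion / cortical tension parameters
#'
#' The membrane moves with normal velocity `V = Kprot a - lambda(t) kappa`:
#' actin-driven protrusion proportional to the activator, opposed by a
#' curvature-proportional cortical tension whose spatially constant factor
#' `lambda(t)` evolves to keep the enclosed area near the prescribed `A0`.
#'
#' @param Kprot protrusive velocity scaling.
#' @param lambda0 tension dynamics constant.
#' @param beta_tension tension decay rate.
#' @param A0 prescribed (initial) cell area.
#' @param lambda initial tension factor; defaults to the value balancing the
#'   homogeneous protrusion pressure on a circle of area `A0`.
#' @return an object of class `motility_params`.
#' @export
motility_params <- function(Kprot = 1e-5, lambda0 = 2e-6, beta_tension = 2e-2,
                            A0 = pi * 0.1^2, lambda = NULL) {
  structure(list(Kprot = Kprot, lambda0 = lambda0,
                 beta_tension = beta_tension, A0 = A0, lambda = lambda),
            class = "motility_params")
}

#' Extracellular ligand and receptor binding parameters
#'
#' The ligand l diffuses in the extracellular region and binds reversibly to
#' membrane receptors, forming a surface-bound complex ls with association
#' rate k1 and disassociation rate k_minus1. The disassociation constant
#' `Kd = k_minus1 / k1 = 30` is taken as authoritative (it reproduces the
#' front/back receptor occupancies 0.19/0.15 under the default linear
#' gradient); pass `k1` explicitly to override. The total receptor
#' concentration is fixed by the total receptor count `2 pi r0 Rtot`.
#'
#' @param D bulk ligand diffusion coefficient.
#' @param Ds_ligand surface diffusion coefficient of the complex.
#' @param k_minus1 disassociation rate.
#' @param Kd disassociation constant; k1 defaults to `k_minus1 / Kd`.
#' @param k1 association rate (overrides `Kd` if given).
#' @param receptors_total total receptor count `2 pi r0 Rtot`.
#' @param r0 initial cell radius.
#' @param rf far-field radius (default `3 r0`).
#' @param l0 ligand level at the initial cell rear reference point.
#' @param gradient linear gradient slope; the initial/far-field ligand field
#'   is `l(x, y) = l0 + gradient * (x + r0)` in the fixed lab frame.
#' @return an object of class `ligand_params` (with derived `Rtot` and the
#'   far-field evaluator `field(points)`).
#' @export
ligand_params <- function(D = 10, Ds_ligand = 1e-6, k_minus1 = 1, Kd = 30,
                          k1 = NULL, receptors_total = 7e4, r0 = 0.1,
                          rf = 3 * r0, l0 = 5.3, gradient = 8.5) {
  if (is.null(k1)) k1 <- k_minus1 / Kd else Kd <- k_minus1 / k1
  Rtot <- receptors_total / (2 * pi * r0)
  field <- function(points) {
    p <- matrix(as.numeric(points), ncol = 2)
    l0 + gradient * (p[, 1] + r0)
  }
  structure(list(D = D, Ds_ligand = Ds_ligand, k1 = k1, k_minus1 = k_minus1,
                 Kd = Kd, Rtot = Rtot, receptors_total = receptors_total,
                 r0 = r0, rf = rf, l0 = l0, gradient = gradient,
                 field = field), class = "ligand_params")
}

#' Mean-reverting (Ornstein-Uhlenbeck) intrinsic noise
#'
#' The intrinsic noise component eta is a mean-reverting diffusion
#' `d eta = theta (mu - eta) dt + sigma dW`, advanced by Euler-Maruyama. The
#' default volatility gives a stationary standard deviation of 0.05.
#'
#' @param eta initial value.
#' @param theta reversion rate.
#' @param mu long-run mean.
#' @param sigma volatility; default `0.05 * sqrt(2 * theta)`.
#' @param n number of independent components (1 = a single spatially uniform
#'   noise; Ns = per-node noise).
#' @return an object of class `noise_state`.
#' @export
noise_state <- function(eta = 0, theta = 0.1, mu = 0, sigma = NULL, n = 1L) {
  if (is.null(sigma)) sigma <- 0.05 * sqrt(2 * theta)
  structure(list(eta = rep_len(eta, n), theta = theta, mu = mu,
                 sigma = sigma, n = n), class = "noise_state")
}

#' Advance the intrinsic noise by one Euler-Maruyama step
#'
#' @param state a [noise_state()].
#' @param dt time step.
#' @return the updated state (draws `state$n` normal variates from the
#'   current RNG stream, so runs are replayable under a fixed seed).
#' @export
ou_noise_step <- function(state, dt) {
  if (dt <= 0) stop("dt must be positive")
  state$eta <- state$eta + state$theta * (state$mu - state$eta) * dt +
    state$sigma * sqrt(dt) * stats::rnorm(state$n)
  state
}

#' Chemotactic signal term
#'
#' `s = ra * (eta + Ro)` node-wise: the activator kinetics are driven
#' multiplicatively by the sum of intrinsic noise and local fractional
#' receptor occupancy. Values driven negative by noise are floored at zero.
#'
#' @param Ro_vec nodal receptor occupancy.
#' @param eta intrinsic noise (scalar or nodal).
#' @param ra activator decay rate.
#' @return nodal signal vector.
#' @export
signal_term <- function(Ro_vec, eta, ra = 2e-2) {
  pmax(0, ra * (eta + Ro_vec))
}

#' Membrane reaction terms of the activator-inhibitor system
#'
#' Nodal reaction rates: activator
#' `s (a^2/b + ba) / ((sc + c)(1 + sa a^2)) - ra a`, global inhibitor
#' `-rb b + rb <a>` with `<a>` the curve-length-weighted mean of a
#' (trapezoidal arc quadrature), and local inhibitor `bc a - rc c`.
#'
#' @param a_vec,b_vec,c_vec nodal membrane fields.
#' @param s_vec nodal signal values.
#' @param curve a `curve_state` supplying the arc weights.
#' @param params a [meinhardt_params()].
#' @return list with `ra_terms`, `rb_terms`, `rc_terms`.
#' @export
meinhardt_rhs <- function(a_vec, b_vec, c_vec, s_vec, curve,
                          params = meinhardt_params()) {
  if (any(b_vec <= 0)) stop("singular kinetics: global inhibitor must stay positive")
  if (any(c_vec + params$sc <= 0)) stop("singular kinetics: sc + c must stay positive")
  len <- segment_lengths(curve$x)
  wts <- (len + len[im1(curve$ns)]) / 2
  abar <- sum(wts * a_vec) / sum(wts)
  list(ra_terms = s_vec * (a_vec^2 / b_vec + params$ba) /
         ((params$sc + c_vec) * (1 + params$sa * a_vec^2)) - params$ra * a_vec,
       rb_terms = -params$rb * b_vec + params$rb * abar,
       rc_terms = params$bc * a_vec - params$rc * c_vec)
}

#' Spatially homogeneous steady state of the membrane kinetics
#'
#' With a constant signal s the homogeneous fixed point satisfies `b = a`,
#' `c = (bc/rc) a` and a scalar balance in a, solved by bracketed
#' root-finding.
#'
#' @param s constant signal value.
#' @param params a [meinhardt_params()].
#' @return list with steady values `a`, `b`, `c`.
#' @export
meinhardt_steady_state <- function(s, params = meinhardt_params()) {
  f <- function(a) s * (a + params$ba) /
    ((params$sc + (params$bc / params$rc) * a) * (1 + params$sa * a^2)) -
    params$ra * a
  upper <- 1
  while (f(upper) > 0 && upper < 1e6) upper <- upper * 2
  a <- stats::uniroot(f, c(0, upper), tol = 1e-14)$root
  list(a = a, b = a, c = (params$bc / params$rc) * a)
}

#' Receptor-ligand surface reaction rate
#'
#' `g(l, ls) = k1 (Rtot - ls) l - k_minus1 ls`, the net binding rate; it is
#' both the source of the surface complex and (with opposite sign in the mass
#' budget) the flux removed from the bulk ligand at the membrane.
#'
#' @param l_on_gamma bulk ligand values at the membrane.
#' @param ls surface complex values.
#' @param params a [ligand_params()].
#' @return nodal reaction rate.
#' @export
ligand_surface_reaction <- function(l_on_gamma, ls, params = ligand_params()) {
  params$k1 * (params$Rtot - ls) * l_on_gamma - params$k_minus1 * ls
}

#' Equilibrium fractional receptor occupancy
#'
#' Setting the binding reaction to zero gives `ls = Rtot l / (l + Kd)`, hence
#' occupancy `Ro = ls / Rtot = l / (l + Kd)`.
#'
#' @param l local ligand concentration.
#' @param Kd disassociation constant.
#' @return occupancy in \[0, 1).
#' @export
equilibrium_occupancy <- function(l, Kd = 30) {
  if (any(l < 0) || Kd <= 0) stop("need l >= 0 and Kd > 0")
  l / (l + Kd)
}

#' Membrane normal velocity of the motile cell
#'
#' `V = Kprot a - lambda kappa` node-wise, with kappa the standard curvature
#' (positive for a convex membrane), so the tension term alone shrinks a
#' convex cell at rate lambda/R.
#'
#' @param a_vec nodal activator values.
#' @param kappa_vec nodal curvature (from [curve_curvature()]).
#' @param params a [motility_params()].
#' @param lambda current tension factor.
#' @return nodal normal velocity (positive = outward).
#' @export
boundary_normal_velocity <- function(a_vec, kappa_vec, params, lambda) {
  params$Kprot * a_vec - lambda * kappa_vec
}

#' Explicit Euler update of the cortical tension factor
#'
#' `d lambda/dt = lambda0 lambda (A - A0 + dA/dt) / (A0 (lambda + lambda0))
#'  - beta lambda`: tension rises when the cell is larger than its prescribed
#' area (or growing) and decays otherwise. A negative update is clamped at
#' zero with a warning.
#'
#' @param params a [motility_params()].
#' @param lambda current tension.
#' @param A current enclosed area.
#' @param dA_dt backward-difference area rate.
#' @param dt time step.
#' @return updated lambda.
#' @export
tension_step <- function(params, lambda, A, dA_dt, dt) {
  dl <- params$lambda0 * lambda * (A - params$A0 + dA_dt) /
    (params$A0 * (lambda + params$lambda0)) - params$beta_tension * lambda
  out <- lambda + dt * dl
  if (out < 0) {
    warning("tension clamped at zero")
    out <- 0
  }
  out
}

## ---- coupled cell simulation engine -----------------------------------------

## Dense periodic P1 mass and unit stiffness on a closed polygon, plus nodal
## normals; dense algebra avoids sparse-construction overhead at membrane size.
surf_dense_ops <- function(x) {
  n <- nrow(x); nxt <- ip1(n); prv <- im1(n)
  len <- sqrt(rowSums((x[nxt, , drop = FALSE] - x)^2))
  Ms <- matrix(0, n, n); Ks <- matrix(0, n, n)
  diag(Ms) <- (len + len[prv]) / 3
  Ms[cbind(seq_len(n), nxt)] <- len / 6
  Ms[cbind(nxt, seq_len(n))] <- len / 6
  diag(Ks) <- 1 / len + 1 / len[prv]
  Ks[cbind(seq_len(n), nxt)] <- -1 / len
  Ks[cbind(nxt, seq_len(n))] <- -1 / len
  dch <- x[nxt, , drop = FALSE] - x[prv, , drop = FALSE]
  tn <- dch / sqrt(rowSums(dch^2))
  list(Ms = Ms, Ks = Ks, len = len, normals = cbind(tn[, 2], -tn[, 1]))
}

## Dense boundary operators for an affine-in-c membrane kernel
## q(x) c + r(x): Q[i,j] = int q phi_i phi_j ds, rv_i = int r phi_i ds
## (2-point Gauss per segment, q and r P1 along the curve).
surf_kernel_ops <- function(x, q, r) {
  n <- nrow(x); nxt <- ip1(n)
  len <- sqrt(rowSums((x[nxt, , drop = FALSE] - x)^2))
  Q <- matrix(0, n, n); rv <- numeric(n)
  i1 <- seq_len(n); i2 <- nxt
  for (gp in gauss2) {
    p1 <- 1 - gp; p2 <- gp; w <- len / 2
    qg <- p1 * q[i1] + p2 * q[i2]
    rg <- p1 * r[i1] + p2 * r[i2]
    Q[cbind(i1, i1)] <- Q[cbind(i1, i1)] + w * qg * p1 * p1
    Q[cbind(i1, i2)] <- Q[cbind(i1, i2)] + w * qg * p1 * p2
    Q[cbind(i2, i1)] <- Q[cbind(i2, i1)] + w * qg * p2 * p1
    Q[cbind(i2, i2)] <- Q[cbind(i2, i2)] + w * qg * p2 * p2
    rv[i1] <- rv[i1] + w * rg * p1
    rv[i2] <- rv[i2] + w * rg * p2
  }
  list(Q = Q, r = rv)
}

## element triplets of the bulk mass and combined stiffness+transport values
bulk_blocks <- function(mesh, w, D) {
  tri <- mesh$tri; pb <- phys_basis(mesh); A <- pb$A
  nel <- nrow(tri)
  ii <- jj <- integer(9 * nel); vM <- vKB <- numeric(9 * nel)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- k * nel + seq_len(nel)
    ii[idx] <- tri[, a]; jj[idx] <- tri[, b]
    vM[idx] <- (A / 12) * (1 + (a == b))
    kb <- D * A * (pb$gx[, a] * pb$gx[, b] + pb$gy[, a] * pb$gy[, b])
    if (!is.null(w)) {
      acc <- 0
      for (cc in 1:3)
        acc <- acc + (w[tri[, cc], 1] * pb$gx[, a] +
                      w[tri[, cc], 2] * pb$gy[, a]) * (A / 12) * (1 + (cc == b))
      kb <- kb - acc   # B = -int (w . grad phi_i) phi_j
    }
    vKB[idx] <- kb
    k <- k + 1L
  }
  list(ii = ii, jj = jj, vM = vM, vKB = vKB)
}

## One predictor / Crank-Nicolson / corrector step of the ligand pair on a
## moving mesh, exploiting that the binding kinetics are affine in l so the
## bulk step is a single sparse solve. Membrane nodes move with the curve
## (u = w there), so the surface advection operator vanishes and the boundary
## matrix A is identically zero.
ligand_ale_step <- function(mesh0, mesh1, loop, w, lp, l, ls, ff_values, dt) {
  n <- nrow(mesh0$phys)
  g0 <- mesh0$phys[loop, , drop = FALSE]
  g1 <- mesh1$phys[loop, , drop = FALSE]
  s0 <- surf_dense_ops(g0)
  s1 <- surf_dense_ops(g1)
  un0 <- rowSums(w[loop, , drop = FALSE] * s0$normals)
  un1 <- rowSums(w[loop, , drop = FALSE] * s1$normals)
  l0g <- l[loop]
  ## predictor: [Ms1 + dt Ds Ks1] ls~ = Ms0 ls0 + dt Ds_vec(l0, ls0)
  k0 <- surf_kernel_ops(g0, lp$k1 * (lp$Rtot - ls), -lp$k_minus1 * ls)
  Ds0 <- as.numeric(k0$Q %*% l0g) + k0$r
  ls_t <- solve(s1$Ms + dt * lp$Ds_ligand * s1$Ks,
                as.numeric(s0$Ms %*% ls) + dt * Ds0)
  ## bulk CN: D kernel q c + r with q = k1(Rtot - ls) - u.n, r = -k_minus1 ls
  kD0 <- surf_kernel_ops(g0, lp$k1 * (lp$Rtot - ls) - un0, -lp$k_minus1 * ls)
  kD1 <- surf_kernel_ops(g1, lp$k1 * (lp$Rtot - ls_t) - un1, -lp$k_minus1 * ls_t)
  b0 <- bulk_blocks(mesh0, w, lp$D)
  b1 <- bulk_blocks(mesh1, w, lp$D)
  rhs <- rowsum_into((b0$vM - (dt / 2) * b0$vKB) * l[b0$jj], b0$ii, n)
  D0 <- as.numeric(kD0$Q %*% l0g) + kD0$r
  rhs[loop] <- rhs[loop] - (dt / 2) * (D0 + kD1$r)
  ff <- mesh1$loops$farfield
  isb <- logical(n); isb[ff] <- TRUE
  keep <- !isb[b1$ii]
  nz <- which(kD1$Q != 0, arr.ind = TRUE)
  L1 <- Matrix::sparseMatrix(
    i = c(b1$ii[keep], loop[nz[, 1]], ff),
    j = c(b1$jj[keep], loop[nz[, 2]], ff),
    x = c(b1$vM[keep] + (dt / 2) * b1$vKB[keep],
          (dt / 2) * kD1$Q[nz], rep(1, length(ff))),
    dims = c(n, n))
  rhs[ff] <- ff_values
  l1 <- as.numeric(Matrix::solve(L1, rhs))
  ## corrector: trapezoidal coupling with new values at (l1, ls~)
  Ds1 <- as.numeric(k0_geom1(g1, lp, ls_t, l1[loop]))
  ls1 <- solve(s1$Ms + (dt / 2) * lp$Ds_ligand * s1$Ks,
               as.numeric((s0$Ms - (dt / 2) * lp$Ds_ligand * s0$Ks) %*% ls) +
                 (dt / 2) * (Ds1 + Ds0))
  list(l = l1, ls = as.numeric(ls1), ls_t = ls_t, surf0 = s0, surf1 = s1)
}

k0_geom1 <- function(g1, lp, ls_t, l1g) {
  k1o <- surf_kernel_ops(g1, lp$k1 * (lp$Rtot - ls_t), -lp$k_minus1 * ls_t)
  as.numeric(k1o$Q %*% l1g) + k1o$r
}

## surface predictor/corrector for one membrane-only species on a moving curve
## (u = w on the membrane, so the advection operator vanishes and dilution
## enters through the moving mass matrix)
surface_species_step <- function(Ms0, Ms1, Ks0_unit, Ks1_unit, Dchi, chi0, R0, dt) {
  K <- Dchi * Ks1_unit
  pred <- as.numeric(solve(Ms1 + dt * K,
                           as.numeric(Ms0 %*% chi0) + dt * as.numeric(Ms0 %*% R0)))
  list(pred = pred,
       correct = function(Rtilde) as.numeric(solve(
         Ms1 + (dt / 2) * K,
         as.numeric((Ms0 - (dt / 2) * Dchi * Ks0_unit) %*% chi0) +
           (dt / 2) * (as.numeric(Ms1 %*% Rtilde) + as.numeric(Ms0 %*% R0)))))
}

#' Run the coupled cell migration simulation
#'
#' Full coupling of the membrane activator-inhibitor system, the
#' protrusion/tension boundary law, the bulk ligand with reversible receptor
#' binding, and intrinsic noise, on the moving annular domain between the cell
#' membrane and a circular far-field boundary held at the initial ligand
#' field. Each step executes the complete moving-mesh algorithm (curve
#' advance, bulk MMPDE, quality-triggered remeshing with the far-field circle
#' re-centred on the cell centroid, ALE predictor/Crank-Nicolson/corrector
#' solves for the ligand pair, and surface predictor/corrector steps for the
#' membrane species).
#'
#' @param n_steps number of time steps.
#' @param dt time step.
#' @param seed RNG seed (controls the initial perturbation and the noise path).
#' @param mp,lp,mot [meinhardt_params()], [ligand_params()],
#'   [motility_params()].
#' @param ns number of membrane nodes.
#' @param sigma_noise OU volatility (`0` disables intrinsic noise);
#'   `NULL` = default of [noise_state()].
#' @param perturbation relative amplitude of the seeded initial activator
#'   perturbation.
#' @param angle_tol remeshing tolerance in degrees.
#' @param tau temporal smoothing parameter of both moving mesh PDEs.
#' @param monitor bulk mesh monitor (default 1: the graded initial mesh is
#'   maintained by the MMPDE with boundary motion only).
#' @param record_profiles cadence (in steps) for storing membrane profiles
#'   (`0` = never).
#' @return list with `trajectory` (`data.frame` per step: t, cx, cy, area,
#'   lambda, eta, mean_Ro, max_a, min_angle, picard, newton), `state` (final
#'   mesh/curve/fields), `profiles`, and `remesh_count`.
#' @export
run_cell_simulation <- function(n_steps, dt = 0.1, seed = 1L,
                                mp = meinhardt_params(),
                                lp = ligand_params(),
                                mot = motility_params(A0 = pi * 0.1^2),
                                ns = 64L, sigma_noise = NULL,
                                perturbation = 0.05, angle_tol = 10,
                                tau = 1e-4, monitor = 1,
                                record_profiles = 0L) {
  set.seed(seed)
  spec <- domain_spec("annulus_cell_in_circle", r0 = lp$r0, rf = lp$rf, ns = ns)
  mesh <- generate_initial_mesh(spec)
  loop <- mesh$loops$membrane
  curve <- curve_state(mesh$phys[loop, , drop = FALSE])
  nsm <- curve$ns
  ## initial fields
  l <- lp$field(mesh$phys)
  Ro0 <- equilibrium_occupancy(l[loop], lp$Kd)
  ss <- meinhardt_steady_state(mp$ra * mean(Ro0), mp)
  a <- ss$a * (1 + perturbation * stats::rnorm(nsm))
  b <- rep(ss$b, nsm)
  cc <- rep(ss$c, nsm)
  ls <- lp$Rtot * Ro0
  noise <- noise_state(sigma = if (is.null(sigma_noise)) NULL else sigma_noise)
  lambda <- if (is.null(mot$lambda)) mot$Kprot * ss$a * lp$r0 else mot$lambda
  A_prev <- polygon_area(curve$x)
  traj <- data.frame(t = dt * seq_len(n_steps), cx = NA_real_, cy = NA_real_,
                     area = NA_real_, lambda = NA_real_, eta = NA_real_,
                     mean_Ro = NA_real_, max_a = NA_real_,
                     min_angle = NA_real_, picard = NA_integer_,
                     newton = NA_integer_)
  profiles <- list()
  remesh_count <- 0L
  clamp_events <- 0L
  t <- 0
  for (stp in seq_len(n_steps)) {
    ## 1. signal from occupancy + intrinsic noise
    noise <- ou_noise_step(noise, dt)
    Ro <- ls / lp$Rtot
    s_vec <- signal_term(Ro, noise$eta, mp$ra)
    ## 2-3. membrane motion: protrusion explicit, tension implicit in curvature
    cpar <- curve_flow_params(alpha = lambda, beta = mot$Kprot * a, tau = tau)
    curve1 <- advance_curve(curve, cpar, dt)
    A_new <- polygon_area(curve1$x)
    ## 4-6. bulk mesh motion with quality-triggered remeshing
    mesh1 <- try(mmpde_step(mesh, list(membrane = curve1$x), monitor, dt,
                            tau = tau, t = t), silent = TRUE)
    if (inherits(mesh1, "try-error") || min_triangle_angle(mesh1) < angle_tol) {
      ctr <- colMeans(curve$x)
      rr <- remesh_recentred(mesh, l, lp, ctr)
      mesh <- rr$mesh
      l <- rr$l
      loop <- mesh$loops$membrane
      remesh_count <- remesh_count + 1L
      mesh1 <- mmpde_step(mesh, list(membrane = curve1$x), monitor, dt,
                          tau = tau, t = t)
      if (min_triangle_angle(mesh1) < angle_tol)
        stop("mesh quality below tolerance after remeshing")
    }
    ## 7-8. ALE velocity and ligand pair (predictor / CN bulk / corrector)
    w <- mesh_velocity(mesh$phys, mesh1$phys, dt)
    ff <- mesh1$loops$farfield
    lig <- ligand_ale_step(mesh, mesh1, loop, w, lp, l, ls,
                           lp$field(mesh1$phys[ff, , drop = FALSE]), dt)
    l1 <- lig$l
    ls1 <- lig$ls
    nwt <- 1L
    if (any(ls1 < 0) || any(ls1 > lp$Rtot)) {
      clamp_events <- clamp_events + 1L
      ls1 <- pmin(lp$Rtot, pmax(0, ls1))
    }
    ## 9. membrane species: predictor / corrector on the moving curve
    rhs0 <- meinhardt_rhs(a, b, cc, s_vec, curve, mp)
    Ms0 <- lig$surf0$Ms; Ms1 <- lig$surf1$Ms
    Ks0u <- lig$surf0$Ks; Ks1u <- lig$surf1$Ks
    sa_ <- surface_species_step(Ms0, Ms1, Ks0u, Ks1u, mp$Da, a, rhs0$ra_terms, dt)
    sb_ <- surface_species_step(Ms0, Ms1, Ks0u, Ks1u, mp$Db, b, rhs0$rb_terms, dt)
    sc_ <- surface_species_step(Ms0, Ms1, Ks0u, Ks1u, mp$Dc, cc, rhs0$rc_terms, dt)
    rhs1 <- meinhardt_rhs(sa_$pred, pmax(sb_$pred, 1e-12), sc_$pred, s_vec,
                          curve1, mp)
    a <- sa_$correct(rhs1$ra_terms)
    b <- pmax(sb_$correct(rhs1$rb_terms), 1e-12)
    cc <- sc_$correct(rhs1$rc_terms)
    ## 10. tension dynamics (explicit Euler, backward-difference area rate)
    lambda <- tension_step(mot, lambda, A_new, (A_new - A_prev) / dt, dt)
    A_prev <- A_new
    ## commit
    mesh <- mesh1
    curve <- curve1
    l <- as.numeric(l1)
    ls <- ls1
    t <- stp * dt
    ctro <- polygon_centroid(curve$x)
    traj$cx[stp] <- ctro[1]; traj$cy[stp] <- ctro[2]
    traj$area[stp] <- A_new; traj$lambda[stp] <- lambda
    traj$eta[stp] <- noise$eta[1]
    traj$mean_Ro[stp] <- mean(ls / lp$Rtot); traj$max_a[stp] <- max(a)
    traj$min_angle[stp] <- min_triangle_angle(mesh)
    traj$picard[stp] <- attr(curve1, "picard_iters")
    traj$newton[stp] <- nwt
    if (record_profiles > 0L && stp %% record_profiles == 0L) {
      len <- segment_lengths(curve$x)
      profiles[[length(profiles) + 1L]] <- data.frame(
        t = t, arc = cumsum(c(0, len[-curve$ns])),
        a = a, b = b, c = cc, ls = ls, Ro = ls / lp$Rtot,
        unbound = (lp$Rtot - ls) / lp$Rtot, l_gamma = l[loop])
    }
  }
  list(trajectory = traj,
       state = list(mesh = mesh, curve = curve, l = l, ls = ls,
                    a = a, b = b, c = cc, lambda = lambda, t = t),
       profiles = profiles, remesh_count = remesh_count,
       clamp_events = clamp_events)
}

## remesh the annulus with the far-field circle re-centred on the cell
## centroid; bulk ligand interpolated, far-field formula filling any region
## uncovered by the old domain
remesh_recentred <- function(mesh, l, lp, centre) {
  spec <- mesh$spec
  mem <- mesh$phys[mesh$loops$membrane, , drop = FALSE]
  ang <- atan2(mem[, 2] - centre[2], mem[, 1] - centre[1])
  outer <- cbind(centre[1] + spec$rf * cos(ang), centre[2] + spec$rf * sin(ang))
  per <- sum(segment_lengths(mem))
  h_min <- if (is.null(spec$h_min)) per / nrow(mem) else spec$h_min
  h_max <- if (is.null(spec$h_max)) 2 * pi * spec$rf / nrow(mem) else spec$h_max
  g <- build_ring_mesh(mem, outer, centre, h_min, h_max)
  newmesh <- new_tri_mesh(g$pts, g$tri, g$loops, spec = spec)
  lnew <- interpolate_to_points(mesh, l, newmesh$phys, snap_tol = 1e-6,
                                fill = lp$field)
  list(mesh = newmesh, l = lnew)
}

#' Polygon centroid
#'
#' Area-weighted centroid of a simple closed polygon.
#'
#' @param x n x 2 vertex matrix.
#' @return length-2 numeric.
#' @export
polygon_centroid <- function(x) {
  n <- nrow(x)
  xn <- x[ip1(n), , drop = FALSE]
  cr <- x[, 1] * xn[, 2] - xn[, 1] * x[, 2]
  A <- sum(cr) / 2
  c(sum((x[, 1] + xn[, 1]) * cr), sum((x[, 2] + xn[, 2]) * cr)) / (6 * A)
}

#' Cell migration in a linear chemoattractant gradient
#'
#' Runs [run_cell_simulation()] with the default linear ligand field
#' `l = 5.3 + 8.5 (x + 0.1)`, under which the initial receptor occupancy is
#' 0.15 at the cell rear and 0.19 at the front; directed migration up the
#' gradient (to the right) emerges from the occupancy-biased activator
#' kinetics.
#'
#' @param n_steps,dt,seed,... passed to [run_cell_simulation()].
#' @return see [run_cell_simulation()].
#' @export
run_linear_gradient <- function(n_steps = 2000, dt = 0.1, seed = 1L, ...) {
  run_cell_simulation(n_steps = n_steps, dt = dt, seed = seed,
                      lp = ligand_params(gradient = 8.5), ...)
}

#' Cell migration in an initially homogeneous ligand field
#'
#' Same machinery with a spatially constant initial and far-field ligand
#' concentration; membrane profiles (occupancy, unbound receptor fraction,
#' ligand at the membrane) are recorded for the self-generated-gradient
#' diagnostics: protruding membrane segments locally dilute the bound
#' complex, retracting segments locally enrich it.
#'
#' @param n_steps,dt,seed number of steps, step size and RNG seed.
#' @param l0 homogeneous ligand level.
#' @param record_profiles profile cadence in steps.
#' @param ... passed to [run_cell_simulation()].
#' @return see [run_cell_simulation()].
#' @export
run_homogeneous_field <- function(n_steps = 2000, dt = 0.1, seed = 1L,
                                  l0 = 5.3, record_profiles = 50L, ...) {
  run_cell_simulation(n_steps = n_steps, dt = dt, seed = seed,
                      lp = ligand_params(gradient = 0, l0 = l0),
                      record_profiles = record_profiles, ...)
}

#' Forced protrusion/retraction oracle for receptor-complex dilution
#'
#' Moves the membrane with a prescribed, activator-independent normal
#' velocity bump `V(theta) = amplitude * exp(-(theta/width)^2)` (outward for
#' positive amplitude, inward for negative) in a homogeneous ligand field and
#' integrates only the ligand/receptor machinery. Under protrusion the local
#' complex concentration is diluted below the membrane mean; under retraction
#' it is enriched.
#'
#' @param amplitude signed normal speed of the bump.
#' @param width angular width of the bump (radians).
#' @param n_steps,dt steps and step size.
#' @param ns membrane nodes.
#' @param lp ligand parameters (homogeneous by default).
#' @return list with `theta`, `ls`, `Ro`, `bump` (logical mask),
#'   `ls_anomaly` = mean(ls in bump) - mean(ls outside).
#' @export
run_forced_protrusion <- function(amplitude = 2e-4, width = 0.5,
                                  n_steps = 20, dt = 0.1, ns = 64L,
                                  lp = ligand_params(gradient = 0)) {
  spec <- domain_spec("annulus_cell_in_circle", r0 = lp$r0, rf = lp$rf, ns = ns)
  mesh <- generate_initial_mesh(spec)
  loop <- mesh$loops$membrane
  curve <- curve_state(mesh$phys[loop, , drop = FALSE])
  l <- lp$field(mesh$phys)
  ls <- lp$Rtot * equilibrium_occupancy(l[loop], lp$Kd)
  t <- 0
  for (stp in seq_len(n_steps)) {
    th <- atan2(curve$x[, 2] - mean(curve$x[, 2]),
                curve$x[, 1] - mean(curve$x[, 1]))
    V <- amplitude * exp(-(th / width)^2)
    cpar <- curve_flow_params(alpha = 0, beta = V, tau = 1e-4, P = 1e-8)
    ## P ~ 0 freezes tangential redistribution so nodes track the bump
    curve1 <- advance_curve(curve, cpar, dt)
    mesh1 <- mmpde_step(mesh, list(membrane = curve1$x), 1, dt, tau = 1e-4)
    w <- mesh_velocity(mesh$phys, mesh1$phys, dt)
    ff <- mesh1$loops$farfield
    lig <- ligand_ale_step(mesh, mesh1, loop, w, lp, l, ls,
                           lp$field(mesh1$phys[ff, , drop = FALSE]), dt)
    l <- lig$l
    ls <- lig$ls
    mesh <- mesh1
    curve <- curve1
    t <- stp * dt
  }
  th <- atan2(curve$x[, 2], curve$x[, 1])
  bump <- abs(th) < width
  list(theta = th, ls = ls, Ro = ls / lp$Rtot, bump = bump,
       ls_anomaly = mean(ls[bump]) - mean(ls[!bump]))
}
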