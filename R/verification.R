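#' Separation constant of the coupled disc model problem
#'
#' The coupled heat equation on the unit disc with surface equation
#' `dcs/dt = Lap_Gamma cs + c - cs` and flux condition `-dc/dr = c - cs`
#' admits the separable solution `c = J1(k r) exp(-k^2 t) cos(theta)`,
#' `cs = A exp(-k^2 t) cos(theta)`; substituting it into the surface equation
#' and the flux condition yields the scalar matching condition
#' `k J1'(k) (2 - k^2) = J1(k) (k^2 - 1)` with `J1'(k) = J0(k) - J1(k)/k`.
#'
#' @param bracket search interval for the smallest positive root.
#' @return the root k (~1.177706027).
#' @export
dispersion_root <- function(bracket = c(0.5, 1.4)) {
  f <- function(k) k * (besselJ(k, 0) - besselJ(k, 1) / k) * (2 - k^2) -
    besselJ(k, 1) * (k^2 - 1)
  if (f(bracket[1]) * f(bracket[2]) > 0)
    stop("no sign change in bracket")
  stats::uniroot(f, bracket, tol = 1e-15)$root
}

#' Exact solution of the disc model problem
#'
#' @return list with the separation constant `k`, the surface amplitude
#'   `amplitude = J1(k)/(2 - k^2)`, and evaluators `c(x, y, t)` (bulk) and
#'   `cs(theta, t)` (surface).
#' @export
disc_exact_solution <- function() {
  k <- dispersion_root()
  amp <- besselJ(k, 1) / (2 - k^2)
  list(k = k, amplitude = amp,
       c = function(x, y, t) {
         r <- sqrt(x^2 + y^2)
         th <- atan2(y, x)
         besselJ(k * r, 1) * exp(-k^2 * t) * cos(th)
       },
       cs = function(theta, t) amp * exp(-k^2 * t) * cos(theta))
}

## reaction specification of the disc model problem: D = Ds = 1, f = 0,
## g(c, cs) = c - cs, h = 0
disc_reaction_spec <- function() {
  reaction_spec(D = 1, Ds = 1,
                g = function(c, cs) c - cs,
                dg_dc = function(c, cs) rep_len(1, length(c)))
}

#' Solve the disc model problem on a stationary mesh
#'
#' Runs the three-step scheme (predictor / Crank-Nicolson / correction) for
#' the coupled disc problem from the exact initial data. The mesh is
#' stationary, so all operators are assembled and factorized once and the
#' per-step work is three triangular solves; the coupling is linear, making
#' the Crank-Nicolson bulk step a single linear solve.
#'
#' @param h target mesh edge length.
#' @param dt time step.
#' @param T final time.
#' @param correction apply the Crank-Nicolson surface correction (`FALSE`
#'   keeps the first-order predictor value, degrading the surface field to
#'   first order in time).
#' @param mesh optional precomputed disc mesh (reused across `dt` values).
#' @return list with `mesh`, final fields `C`, `Cs`, max nodal errors
#'   `err_bulk`, `err_surf` against the exact solution, and `exact`.
#' @export
run_disc_problem <- function(h, dt, T = 1, correction = TRUE, mesh = NULL) {
  ex <- disc_exact_solution()
  spec <- disc_reaction_spec()
  if (is.null(mesh)) mesh <- generate_initial_mesh(domain_spec("disc", h = h, rf = 1))
  loop <- mesh$loops$membrane
  n <- nrow(mesh$phys)
  ns <- length(loop)
  bulk <- assemble_bulk(mesh, w = NULL, spec)
  surf <- assemble_surface(mesh$phys[loop, , drop = FALSE], spec = spec)
  Msu <- surf$Ms   # unit surface mass matrix
  ## linear coupling g = c - cs: D_surf = Ds_surf = Msu (C_gamma - Cs)
  Mg <- lift_surface_matrix(Msu, loop, n)
  lift <- function(v) lift_surface_vector(v, loop, n)
  f_pred <- Matrix::lu(surf$Ms + dt * surf$Ks)
  f_bulk <- Matrix::lu(bulk$M + (dt / 2) * (bulk$K + Mg))
  f_corr <- Matrix::lu(surf$Ms + (dt / 2) * surf$Ks)
  R_bulk <- bulk$M - (dt / 2) * (bulk$K + Mg)
  R_corr <- surf$Ms - (dt / 2) * surf$Ks
  th <- atan2(mesh$phys[loop, 2], mesh$phys[loop, 1])
  C <- ex$c(mesh$phys[, 1], mesh$phys[, 2], 0)
  Cs <- ex$cs(th, 0)
  n_steps <- as.integer(round(T / dt))
  for (s in seq_len(n_steps)) {
    C0_gamma <- C[loop]
    Cs_t <- as.numeric(Matrix::solve(f_pred,
      as.numeric(surf$Ms %*% Cs) + dt * as.numeric(Msu %*% (C0_gamma - Cs))))
    rhs <- as.numeric(R_bulk %*% C) +
      (dt / 2) * (lift(as.numeric(Msu %*% Cs_t)) + lift(as.numeric(Msu %*% Cs)))
    C <- as.numeric(Matrix::solve(f_bulk, rhs))
    Cs <- if (correction) {
      as.numeric(Matrix::solve(f_corr,
        as.numeric(R_corr %*% Cs) +
          (dt / 2) * as.numeric(Msu %*% (C[loop] - Cs_t)) +
          (dt / 2) * as.numeric(Msu %*% (C0_gamma - Cs))))
    } else Cs_t
  }
  tT <- n_steps * dt
  err_bulk <- max(abs(C - ex$c(mesh$phys[, 1], mesh$phys[, 2], tT)))
  err_surf <- max(abs(Cs - ex$cs(th, tT)))
  list(mesh = mesh, C = C, Cs = Cs, t = tT,
       err_bulk = err_bulk, err_surf = err_surf, exact = ex)
}

ls_slope <- function(x, y) {
  stats::coef(stats::lm(log(y) ~ log(x)))[[2]]
}

#' Spatial convergence study for the disc model problem
#'
#' Runs the coupled problem on a sequence of refined isotropic disc meshes
#' from the exact initial data at a fixed small time step, records the maximum
#' nodal error of both fields at the final time, and returns the least-squares
#' slopes of log error versus log h (the observed spatial orders; second-order
#' convergence is the design target of the P1 discretisation).
#'
#' @param h_list decreasing mesh sizes (at least 3).
#' @param dt time step (small enough that temporal error is subdominant).
#' @param T final time.
#' @return list with the error table (`data.frame`) and slopes `order_bulk`,
#'   `order_surf`.
#' @export
run_spatial_convergence <- function(h_list = c(0.2, 0.1, 0.05, 0.025),
                                    dt = 1e-3, T = 1) {
  if (length(h_list) < 3) stop("need at least 3 mesh sizes")
  res <- lapply(h_list, function(h) run_disc_problem(h, dt, T))
  tab <- data.frame(h = h_list,
                    err_bulk = vapply(res, `[[`, 0, "err_bulk"),
                    err_surf = vapply(res, `[[`, 0, "err_surf"),
                    n_nodes = vapply(res, function(r) nrow(r$mesh$phys), 0))
  list(table = tab,
       order_bulk = ls_slope(tab$h, tab$err_bulk),
       order_surf = ls_slope(tab$h, tab$err_surf))
}

#' Temporal convergence study for the disc model problem
#'
#' Runs the coupled problem on one fixed mesh for a sequence of time steps and
#' measures, for each field, the maximum nodal deviation at the final time
#' from a small-time-step reference solution computed on the same mesh (which
#' isolates the temporal discretisation error from the fixed spatial error).
#' Returns least-squares slopes of log error versus log dt. With the surface
#' correction step the scheme is second order in both fields; without it the
#' surface field degrades to first order.
#'
#' @param dt_list decreasing time steps.
#' @param h_fine mesh size of the fixed mesh.
#' @param T final time.
#' @param correction apply the surface correction step.
#' @param dt_ref reference time step (default `min(dt_list)/8`).
#' @return list with the error table and slopes `order_bulk`, `order_surf`.
#' @export
run_temporal_convergence <- function(dt_list = c(8e-3, 4e-3, 2e-3, 1e-3),
                                     h_fine = 0.05, T = 1, correction = TRUE,
                                     dt_ref = NULL) {
  mesh <- generate_initial_mesh(domain_spec("disc", h = h_fine, rf = 1))
  if (is.null(dt_ref)) dt_ref <- min(dt_list) / 8
  ref <- run_disc_problem(h_fine, dt_ref, T, correction = TRUE, mesh = mesh)
  res <- lapply(dt_list, function(dt)
    run_disc_problem(h_fine, dt, T, correction = correction, mesh = mesh))
  eb <- vapply(res, function(r) max(abs(r$C - ref$C)), 0)
  es <- vapply(res, function(r) max(abs(r$Cs - ref$Cs)), 0)
  tab <- data.frame(dt = dt_list, err_bulk = eb, err_surf = es)
  list(table = tab,
       order_bulk = ls_slope(tab$dt, tab$err_bulk),
       order_surf = ls_slope(tab$dt, tab$err_surf))
}

#' Mean-curvature-flow and travelling-wave-monitor demonstration
#'
#' Evolves the ellipse `4x^2 + 16y^2 = 1` inward under mean curvature flow
#' (normal speed alpha times curvature, shrinking) inside a unit circular
#' far-field boundary, while both the boundary and bulk meshes adapt to the
#' travelling-wave monitor [wave_monitor()]. The enclosed polygon area is
#' recorded every step; for mean curvature flow the exact enclosed area
#' satisfies `A(t) = A(0) - 2 pi alpha t`. The arc-length equidistribution
#' residual (monitor = 1) of the boundary mesh is recorded to show the mesh
#' relaxing back to uniform spacing once the wave has passed.
#'
#' @param alpha curvature coefficient (0.75 in the demonstration).
#' @param dt time step.
#' @param T final time.
#' @param ns number of boundary nodes on the ellipse.
#' @param tau temporal smoothing parameter of both moving mesh PDEs.
#' @param angle_tol remeshing tolerance in degrees.
#' @param snapshot_times times at which meshes are stored.
#' @return list with `trace` (`data.frame` of t, area, exact_area,
#'   equid_residual, min_angle), `snapshots` (meshes), and `remesh_count`.
#' @export
run_mcf_wave_demo <- function(alpha = 0.75, dt = 1e-3, T = 0.07, ns = 98,
                              tau = 1e-4, angle_tol = 10,
                              snapshot_times = c(0, 0.02, 0.04, 0.05, 0.055)) {
  ## initial boundary nodes equidistribute the monitor-weighted arc length of
  ## the analytic ellipse, so the tangential MMPDE starts at its steady state
  ## (placing them by arc length alone would trigger one large tangential
  ## slide along the polygon, cutting corners and polluting the area trace)
  inner <- equal_arclength_points(
    function(t) cbind(0.5 * cos(t), 0.25 * sin(t)), ns,
    weight = function(x, y) wave_monitor(x, y, 0))
  spec <- domain_spec("annulus_cell_in_circle", r0 = 0.5, rf = 1,
                      inner_loop = inner)
  mesh <- generate_initial_mesh(spec)
  curve <- curve_state(mesh$phys[mesh$loops$membrane, , drop = FALSE])
  n_steps <- as.integer(round(T / dt))
  trace <- data.frame(t = numeric(n_steps + 1), area = NA_real_,
                      exact_area = NA_real_, equid_residual = NA_real_,
                      min_angle = NA_real_)
  A0 <- polygon_area(curve$x)
  snap <- list()
  remesh_count <- 0L
  record <- function(i, t) {
    trace$t[i] <<- t
    trace$area[i] <<- polygon_area(curve$x)
    trace$exact_area[i] <<- A0 - 2 * pi * alpha * t
    cu <- set_curve_monitor(curve, 1)
    trace$equid_residual[i] <<- equidistribution_residual(cu)
    trace$min_angle[i] <<- min_triangle_angle(mesh)
  }
  record(1L, 0)
  if (any(abs(snapshot_times - 0) < dt / 2)) snap[["t=0"]] <- mesh
  t <- 0
  for (s in seq_len(n_steps)) {
    curve <- set_curve_monitor(curve, function(x, y) wave_monitor(x, y, t))
    params <- curve_flow_params(alpha = alpha, beta = 0, tau = tau)
    curve_new <- advance_curve(curve, params, dt)
    mesh_new <- try(mmpde_step(mesh, list(membrane = curve_new$x),
                               wave_monitor, dt, tau = tau, t = t),
                    silent = TRUE)
    if (inherits(mesh_new, "try-error") ||
        min_triangle_angle(mesh_new) < angle_tol) {
      rr <- remesh(mesh, angle_tol = angle_tol)
      mesh <- rr$mesh
      remesh_count <- remesh_count + 1L
      mesh_new <- mmpde_step(mesh, list(membrane = curve_new$x),
                             wave_monitor, dt, tau = tau, t = t)
    }
    mesh <- mesh_new
    curve <- curve_new
    t <- s * dt
    record(s + 1L, t)
    hit <- which(abs(snapshot_times - t) < dt / 2)
    if (length(hit)) snap[[sprintf("t=%g", snapshot_times[hit[1]])]] <- mesh
  }
  list(trace = trace, snapshots = snap, remesh_count = remesh_count, A0 = A0)
}
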