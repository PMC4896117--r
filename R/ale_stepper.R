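#' Simulation configuration
#'
#' @param dt time step.
#' @param n_steps number of equal time steps (final time = `dt * n_steps`).
#' @param angle_tol remeshing quality tolerance in degrees.
#' @param newton_tol,newton_maxit Newton stopping tolerance (max-norm of the
#'   update) and iteration cap for the Crank-Nicolson bulk step.
#' @param tau temporal smoothing parameter of both moving mesh PDEs.
#' @param seed RNG seed for stochastic model components.
#' @param output_every snapshot cadence in steps (0 = never).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(dt, n_steps, angle_tol = 10, newton_tol = 1e-10,
                       newton_maxit = 20, tau = 1e-4, seed = 1L,
                       output_every = 0L) {
  if (dt <= 0 || n_steps < 1) stop("need dt > 0 and n_steps >= 1")
  if (newton_tol <= 0 || angle_tol <= 0) stop("tolerances must be positive")
  structure(list(dt = dt, n_steps = n_steps, T = dt * n_steps,
                 angle_tol = angle_tol, newton_tol = newton_tol,
                 newton_maxit = newton_maxit, tau = tau, seed = seed,
                 output_every = output_every), class = "sim_config")
}

#' Assemble all operators of one time level
#'
#' Bundles the bulk operators (M, K, B), the surface operators on the
#' membrane loop (Ms, Ks, As, boundary matrix A) and the geometric data
#' needed to evaluate the coupling loads at arbitrary field values.
#'
#' @param mesh a `tri_mesh`.
#' @param spec a [reaction_spec()].
#' @param w N x 2 nodal ALE velocity (`NULL` = stationary).
#' @param u_gamma,w_gamma Ns x 2 material and mesh velocities at the membrane
#'   nodes (`NULL` = zero; membrane nodes move with the curve scheme, so by
#'   default u = w there).
#' @param dirichlet optional list `(nodes, values)` of far-field Dirichlet
#'   data imposed by row replacement in the bulk solves.
#' @return an object of class `ale_operators`.
#' @export
assemble_level <- function(mesh, spec, w = NULL, u_gamma = NULL,
                           w_gamma = NULL, dirichlet = NULL) {
  loop <- mesh$loops$membrane
  gamma <- mesh$phys[loop, , drop = FALSE]
  if (is.null(u_gamma)) u_gamma <- matrix(0, length(loop), 2)
  if (is.null(w_gamma)) w_gamma <- if (is.null(w)) matrix(0, length(loop), 2)
                        else w[loop, , drop = FALSE]
  bulk <- assemble_bulk(mesh, w, spec)
  surf <- assemble_surface(gamma, u_gamma, w_gamma, spec)
  n <- nrow(mesh$phys)
  structure(list(mesh = mesh, spec = spec, loop = loop, gamma = gamma,
                 u_gamma = u_gamma, w_gamma = w_gamma, n = n,
                 M = bulk$M, K = bulk$K, B = bulk$B,
                 Ms = surf$Ms, Ks = surf$Ks, As = surf$As,
                 A = lift_surface_matrix(surf$A, loop, n),
                 dirichlet = dirichlet), class = "ale_operators")
}

## coupling loads at given field values (surface indexing + bulk lift)
level_loads <- function(ops, C, Cs) {
  s <- assemble_surface(ops$gamma, ops$u_gamma, ops$w_gamma, ops$spec,
                        C_gamma = C[ops$loop], Cs = Cs)
  list(D_surf = s$D_vec, Ds_vec = s$Ds_vec, H_vec = s$H_vec,
       D_bulk = lift_surface_vector(s$D_vec, ops$loop, ops$n),
       JD_bulk = lift_surface_matrix(s$JD, ops$loop, ops$n))
}

#' Semi-implicit backward Euler predictor for the surface species
#'
#' Solves `[Ms1 + dt (Ks1 + As1)] Cs~ = Ms0 Cs0 + dt [Ds(C0, Cs0) + H(Cs0)]`:
#' surface diffusion and mesh-movement terms implicit, reaction and coupling
#' terms explicit.
#'
#' @param ops_n,ops_np1 [assemble_level()] bundles at t_n and t_{n+1}.
#' @param C_n,Cs_n fields at t_n.
#' @param dt time step.
#' @return predicted surface vector `Cs~` at t_{n+1}.
#' @export
predict_surface <- function(ops_n, ops_np1, C_n, Cs_n, dt) {
  ld <- level_loads(ops_n, C_n, Cs_n)
  A <- ops_np1$Ms + dt * (ops_np1$Ks + ops_np1$As)
  b <- as.numeric(ops_n$Ms %*% Cs_n) + dt * (ld$Ds_vec + ld$H_vec)
  as.numeric(Matrix::solve(A, b))
}

#' Crank-Nicolson bulk step with Newton iteration
#'
#' Solves the nonlinear Crank-Nicolson system for the bulk field with
#' trapezoidal treatment of the reaction load F and of the membrane coupling
#' D (new coupling evaluated at the predicted surface solution). Newton uses
#' the analytic Jacobian of F and D in C; far-field Dirichlet rows are
#' replaced after assembly. Convergence is declared when the max-norm of the
#' Newton update falls below `newton_tol`.
#'
#' @param ops_n,ops_np1 operator bundles at the two time levels.
#' @param C_n,Cs_n fields at t_n.
#' @param Cs_tilde predicted surface field at t_{n+1}.
#' @param dt time step.
#' @param newton_tol,newton_maxit Newton controls.
#' @return bulk vector at t_{n+1}; attribute `newton_iters` records the count.
#' @export
step_bulk_cn <- function(ops_n, ops_np1, C_n, Cs_n, Cs_tilde, dt,
                         newton_tol = 1e-10, newton_maxit = 20) {
  spec <- ops_np1$spec
  L1 <- ops_np1$M + (dt / 2) * (ops_np1$K + ops_np1$A + ops_np1$B)
  L0 <- ops_n$M - (dt / 2) * (ops_n$K + ops_n$A + ops_n$B)
  ld0 <- level_loads(ops_n, C_n, Cs_n)
  bl0 <- bulk_load(ops_n$mesh, spec, C_n)
  b <- as.numeric(L0 %*% C_n) + (dt / 2) * (bl0$F - ld0$D_bulk)
  dir <- ops_np1$dirichlet
  C <- C_n
  hist <- numeric(0)
  for (it in seq_len(newton_maxit)) {
    ld1 <- level_loads(ops_np1, C, Cs_tilde)
    bl1 <- bulk_load(ops_np1$mesh, spec, C)
    R <- as.numeric(L1 %*% C) - (dt / 2) * (bl1$F - ld1$D_bulk) - b
    J <- L1 - (dt / 2) * (bl1$JF - ld1$JD_bulk)
    if (!is.null(dir)) {
      R[dir$nodes] <- C[dir$nodes] - dir$values
      J[dir$nodes, ] <- 0
      J <- J + Matrix::sparseMatrix(i = dir$nodes, j = dir$nodes,
                                    x = rep(1, length(dir$nodes)),
                                    dims = dim(J))
    }
    dC <- as.numeric(Matrix::solve(J, R))
    C <- C - dC
    hist <- c(hist, max(abs(dC)))
    if (max(abs(dC)) < newton_tol) {
      attr(C, "newton_iters") <- it
      return(C)
    }
  }
  stop(sprintf("Newton did not converge in %d iterations; update history: %s",
               newton_maxit, paste(signif(hist, 3), collapse = " ")))
}

#' Crank-Nicolson correction step for the surface species
#'
#' Linear correction restoring second-order temporal accuracy of the surface
#' field: coupling and surface reaction are treated trapezoidally with the
#' new values evaluated at `(C1, Cs~)`.
#'
#' @param ops_n,ops_np1 operator bundles at the two time levels.
#' @param C_n,C_np1 bulk fields at t_n and t_{n+1}.
#' @param Cs_n surface field at t_n.
#' @param Cs_tilde predicted surface field.
#' @param dt time step.
#' @return corrected surface vector at t_{n+1}.
#' @export
correct_surface <- function(ops_n, ops_np1, C_n, C_np1, Cs_n, Cs_tilde, dt) {
  ld0 <- level_loads(ops_n, C_n, Cs_n)
  ld1 <- level_loads(ops_np1, C_np1, Cs_tilde)
  A <- ops_np1$Ms + (dt / 2) * (ops_np1$Ks + ops_np1$As)
  b <- as.numeric((ops_n$Ms - (dt / 2) * (ops_n$Ks + ops_n$As)) %*% Cs_n) +
    (dt / 2) * (ld1$Ds_vec + ld0$Ds_vec + ld1$H_vec + ld0$H_vec)
  as.numeric(Matrix::solve(A, b))
}

#' Advance the coupled simulation by one full step
#'
#' Executes the complete per-step algorithm: (1a) evaluate the boundary
#' normal-velocity law, (1b) advance the membrane curve, (1c) evaluate the
#' mesh adaptation monitor, (1d) move interior nodes by the bulk MMPDE with
#' the new membrane as Dirichlet data, (1e) test mesh quality and
#' remesh-and-redo once if below tolerance; then (2a) form the discrete ALE
#' velocity and (2b) update the fields with the predictor / Crank-Nicolson /
#' corrector solves.
#'
#' @param state list with `t`, `mesh`, `curve` (`curve_state` mirroring the
#'   membrane loop, or `NULL` for a stationary domain), `C`, `Cs`, and
#'   optionally `remesh_count`.
#' @param model list with components `spec` (a [reaction_spec()]),
#'   `normal_velocity` (`function(state) -> list(alpha, beta)` per membrane
#'   node, or `NULL` for a stationary boundary), `monitor` (bulk monitor
#'   function or constant), `curve_monitor` (function or constant),
#'   `farfield` (`function(points, t) -> values` Dirichlet data on the outer
#'   loop, or `NULL`), and optionally `correction = FALSE` to skip the surface
#'   correction step.
#' @param config a [sim_config()].
#' @return the updated state at `t + dt`.
#' @export
advance_one_step <- function(state, model, config) {
  dt <- config$dt
  mesh0 <- state$mesh
  spec <- model$spec
  moving <- !is.null(model$normal_velocity)
  redo <- 0L
  repeat {
    if (moving) {
      vlaw <- model$normal_velocity(state)
      cm <- if (is.null(model$curve_monitor)) 1 else model$curve_monitor
      curve <- set_curve_monitor(state$curve,
        if (is.function(cm)) function(x, y) cm(x, y, state$t) else cm)
      params <- curve_flow_params(alpha = vlaw$alpha, beta = vlaw$beta,
                                  tau = config$tau)
      curve1 <- advance_curve(curve, params, dt)
      mon <- if (is.null(model$monitor)) 1 else model$monitor
      mesh1 <- mmpde_step(mesh0, list(membrane = curve1$x), mon, dt,
                          tau = config$tau, t = state$t)
      if (min_triangle_angle(mesh1) < config$angle_tol) {
        if (redo >= 1L) stop("mesh quality below tolerance after remeshing")
        redo <- redo + 1L
        rr <- remesh(mesh0, fields = list(C = state$C, Cs = state$Cs),
                     angle_tol = config$angle_tol, fill = model$fill)
        state$mesh <- mesh0 <- rr$mesh
        state$C <- rr$fields$C
        state$curve <- curve_state(mesh0$phys[mesh0$loops$membrane, ,
                                              drop = FALSE],
                                   monitor = state$curve$M)
        state$remesh_count <- (state$remesh_count %||% 0L) + 1L
        next
      }
    } else {
      curve1 <- state$curve
      mesh1 <- mesh0
    }
    break
  }
  w <- mesh_velocity(mesh0$phys, mesh1$phys, dt)
  dir <- NULL
  if (!is.null(model$farfield) && !is.null(mesh1$loops$farfield)) {
    ff <- mesh1$loops$farfield
    dir <- list(nodes = ff,
                values = model$farfield(mesh1$phys[ff, , drop = FALSE],
                                        state$t + dt))
  }
  loop <- mesh1$loops$membrane
  u_g <- w[loop, , drop = FALSE]   # membrane nodes move with the curve scheme
  ops0 <- assemble_level(mesh0, spec, w = w, u_gamma = u_g,
                         w_gamma = w[loop, , drop = FALSE])
  ops1 <- assemble_level(mesh1, spec, w = w, u_gamma = u_g,
                         w_gamma = w[loop, , drop = FALSE], dirichlet = dir)
  Cs_t <- predict_surface(ops0, ops1, state$C, state$Cs, dt)
  C1 <- step_bulk_cn(ops0, ops1, state$C, state$Cs, Cs_t, dt,
                     newton_tol = config$newton_tol,
                     newton_maxit = config$newton_maxit)
  Cs1 <- if (isFALSE(model$correction)) Cs_t else
    correct_surface(ops0, ops1, state$C, as.numeric(C1), state$Cs, Cs_t, dt)
  state$mesh <- mesh1
  state$curve <- curve1
  state$C <- as.numeric(C1)
  state$Cs <- Cs1
  state$t <- state$t + dt
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
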