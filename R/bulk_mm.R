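#' Travelling-wave monitor function
#'
#' `M(x, y, t) = 1 + sech^2((x + t - 0.7)/0.6)`, maximal (value 2) at the
#' centre of a wave travelling from right to left and decaying smoothly to 1
#' far from the front. Used to demonstrate monitor-driven mesh adaptation.
#'
#' @param x,y coordinates (vectorized).
#' @param t time.
#' @return monitor values in (1, 2].
#' @export
wave_monitor <- function(x, y, t = 0) {
  1 + (1 / cosh((x + t - 0.7) / 0.6))^2
}

## per-element derivatives of the P1 map ref -> phys:
## returns x_xi, x_eta, y_xi, y_eta, J for every triangle
ale_map_derivatives <- function(mesh) {
  tri <- mesh$tri
  r <- mesh$ref; p <- mesh$phys
  r21 <- r[tri[, 2], ] - r[tri[, 1], ]; r31 <- r[tri[, 3], ] - r[tri[, 1], ]
  p21 <- p[tri[, 2], ] - p[tri[, 1], ]; p31 <- p[tri[, 3], ] - p[tri[, 1], ]
  detR <- r21[, 1] * r31[, 2] - r31[, 1] * r21[, 2]
  ## F = [p21 p31] %*% inv([r21 r31]) elementwise
  x_xi <- (p21[, 1] * r31[, 2] - p31[, 1] * r21[, 2]) / detR
  x_eta <- (-p21[, 1] * r31[, 1] + p31[, 1] * r21[, 1]) / detR
  y_xi <- (p21[, 2] * r31[, 2] - p31[, 2] * r21[, 2]) / detR
  y_eta <- (-p21[, 2] * r31[, 1] + p31[, 2] * r21[, 1]) / detR
  list(x_xi = x_xi, x_eta = x_eta, y_xi = y_xi, y_eta = y_eta,
       J = x_xi * y_eta - x_eta * y_xi)
}

## area-weighted nodal recovery of the gradient of a nodal field on the
## physical mesh
recover_nodal_gradient <- function(mesh, values) {
  tri <- mesh$tri; p <- mesh$phys
  A <- triangle_areas(mesh, "phys")
  ## P1 basis gradients on physical elements
  b1 <- (p[tri[, 2], 2] - p[tri[, 3], 2]) / (2 * A)
  b2 <- (p[tri[, 3], 2] - p[tri[, 1], 2]) / (2 * A)
  b3 <- (p[tri[, 1], 2] - p[tri[, 2], 2]) / (2 * A)
  c1 <- (p[tri[, 3], 1] - p[tri[, 2], 1]) / (2 * A)
  c2 <- (p[tri[, 1], 1] - p[tri[, 3], 1]) / (2 * A)
  c3 <- (p[tri[, 2], 1] - p[tri[, 1], 1]) / (2 * A)
  gx <- values[tri[, 1]] * b1 + values[tri[, 2]] * b2 + values[tri[, 3]] * b3
  gy <- values[tri[, 1]] * c1 + values[tri[, 2]] * c2 + values[tri[, 3]] * c3
  n <- nrow(p)
  idx <- as.vector(tri)
  wA <- rep(A, 3)
  sumA <- as.vector(rowsum(wA, idx, reorder = TRUE))
  node_gx <- as.vector(rowsum(wA * rep(gx, 3), idx, reorder = TRUE)) / sumA
  node_gy <- as.vector(rowsum(wA * rep(gy, 3), idx, reorder = TRUE)) / sumA
  cbind(node_gx, node_gy)
}

eval_monitor <- function(monitor, x, y, t) {
  if (is.function(monitor)) monitor(x, y, t) else rep_len(monitor, length(x))
}

#' Element coefficients of the Winslow moving mesh PDE
#'
#' Computes, per triangle of the reference mesh, the five coefficients of the
#' interchanged-variable MMPDE together with the Jacobian J of the discrete
#' ALE map: with F the P1 map gradient,
#' `ca = (x_eta^2 + y_eta^2)/(M J^2)`, `cb = -2 (x_xi x_eta + y_xi y_eta)/(M J^2)`,
#' `cc = (x_xi^2 + y_xi^2)/(M J^2)`, and the monitor-gradient terms
#' `cd = (M_xi (x_eta^2+y_eta^2) - M_eta (x_xi x_eta + y_xi y_eta))/(M J)^2`,
#' `ce = (-M_xi (x_xi x_eta + y_xi y_eta) + M_eta (x_xi^2+y_xi^2))/(M J)^2`.
#' The monitor gradient is obtained by chain rule from an area-weighted nodal
#' recovery of the physical gradient of M.
#'
#' @param mesh a `tri_mesh`.
#' @param monitor a function `M(x, y, t) > 0` or a constant.
#' @param t evaluation time.
#' @return list of per-element vectors `ca, cb, cc, cd, ce, J` and nodal
#'   monitor values `M_nodal`.
#' @export
mmpde_coefficients <- function(mesh, monitor, t = 0) {
  dmap <- ale_map_derivatives(mesh)
  if (any(dmap$J <= 0)) stop("tangled mesh: non-positive ALE map Jacobian")
  tri <- mesh$tri
  Mn <- eval_monitor(monitor, mesh$phys[, 1], mesh$phys[, 2], t)
  if (any(Mn <= 0)) stop("monitor must be positive")
  Mel <- (Mn[tri[, 1]] + Mn[tri[, 2]] + Mn[tri[, 3]]) / 3
  g11 <- dmap$x_eta^2 + dmap$y_eta^2
  g12 <- dmap$x_xi * dmap$x_eta + dmap$y_xi * dmap$y_eta
  g22 <- dmap$x_xi^2 + dmap$y_xi^2
  J2 <- dmap$J^2
  if (is.function(monitor)) {
    gr <- recover_nodal_gradient(mesh, Mn)
    Mx <- (gr[tri[, 1], 1] + gr[tri[, 2], 1] + gr[tri[, 3], 1]) / 3
    My <- (gr[tri[, 1], 2] + gr[tri[, 2], 2] + gr[tri[, 3], 2]) / 3
    M_xi <- Mx * dmap$x_xi + My * dmap$y_xi
    M_eta <- Mx * dmap$x_eta + My * dmap$y_eta
  } else {
    M_xi <- M_eta <- numeric(nrow(tri))
  }
  list(ca = g11 / (Mel * J2),
       cb = -2 * g12 / (Mel * J2),
       cc = g22 / (Mel * J2),
       cd = (M_xi * g11 - M_eta * g12) / (Mel * dmap$J)^2,
       ce = (-M_xi * g12 + M_eta * g22) / (Mel * dmap$J)^2,
       J = dmap$J, M_nodal = Mn)
}

## P1 basis gradients and areas on the reference mesh
ref_basis <- function(mesh) {
  tri <- mesh$tri; r <- mesh$ref
  A <- triangle_areas(mesh, "ref")
  list(A = A,
       gx = cbind((r[tri[, 2], 2] - r[tri[, 3], 2]),
                  (r[tri[, 3], 2] - r[tri[, 1], 2]),
                  (r[tri[, 1], 2] - r[tri[, 2], 2])) / (2 * A),
       gy = cbind((r[tri[, 3], 1] - r[tri[, 2], 1]),
                  (r[tri[, 1], 1] - r[tri[, 3], 1]),
                  (r[tri[, 2], 1] - r[tri[, 1], 1])) / (2 * A))
}

#' One backward-Euler step of the bulk moving mesh PDE
#'
#' Updates the interior physical node positions by solving the linear Galerkin
#' system of the Winslow MMPDE with coefficients lagged at the old mesh, the
#' boundary node positions imposed as Dirichlet data, and the balancing
#' function P (default 1/M, giving a spatially uniform mesh relaxation time
#' scale). Raises if the updated mesh has any non-positive element Jacobian.
#'
#' @param mesh a `tri_mesh` at time t_n.
#' @param boundary_positions named list of loop-node coordinate matrices (one
#'   entry per boundary loop, e.g. `membrane`, `farfield`) giving the new
#'   Dirichlet positions; omitted loops keep their current positions.
#' @param monitor monitor function `M(x, y, t)` or constant.
#' @param dt time step.
#' @param tau temporal smoothing parameter.
#' @param P `"1/M"` (default) or a positive constant/nodal vector.
#' @param t evaluation time for the monitor.
#' @return the mesh with updated `phys` coordinates.
#' @export
mmpde_step <- function(mesh, boundary_positions = list(), monitor = 1,
                       dt, tau = 1e-4, P = "1/M", t = 0) {
  if (dt <= 0) stop("dt must be positive")
  co <- mmpde_coefficients(mesh, monitor, t)
  rb <- ref_basis(mesh)
  tri <- mesh$tri
  n <- nrow(mesh$phys); nel <- nrow(tri)
  ## The second-order terms keep the coefficients inside the test-function
  ## derivative, (a vhat)_xi etc.; expanding by the product rule requires the
  ## coefficient gradients, so the element coefficients are first recovered to
  ## nodal P1 fields whose elementwise xi/eta-gradients supply those terms.
  ## Dropping them leaves an operator inconsistent with the non-divergence
  ## form and destabilizes the lagged-coefficient iteration.
  nodal_avg <- function(elv) {
    idx <- as.vector(tri); wA <- rep(rb$A, 3)
    as.vector(rowsum(wA * rep(elv, 3), idx, reorder = TRUE)) /
      as.vector(rowsum(wA, idx, reorder = TRUE))
  }
  an <- nodal_avg(co$ca); bn <- nodal_avg(co$cb); cn <- nodal_avg(co$cc)
  elmean <- function(v) (v[tri[, 1]] + v[tri[, 2]] + v[tri[, 3]]) / 3
  elgrad <- function(v) list(
    xi = v[tri[, 1]] * rb$gx[, 1] + v[tri[, 2]] * rb$gx[, 2] +
      v[tri[, 3]] * rb$gx[, 3],
    eta = v[tri[, 1]] * rb$gy[, 1] + v[tri[, 2]] * rb$gy[, 2] +
      v[tri[, 3]] * rb$gy[, 3])
  abar <- elmean(an); bbar <- elmean(bn); cbar <- elmean(cn)
  da <- elgrad(an); db <- elgrad(bn); dc <- elgrad(cn)
  ## mass weight: tau/(dt*P); P = 1/M makes the kernel tau*M/dt
  invP <- if (identical(P, "1/M")) co$M_nodal else {
    Pv <- rep_len(P, n); if (any(Pv <= 0)) stop("P must be positive"); 1 / Pv
  }
  invPel <- (invP[tri[, 1]] + invP[tri[, 2]] + invP[tri[, 3]]) / 3
  mw <- (tau / dt) * invPel * rb$A / 12
  ii <- jj <- integer(9 * nel); vv <- mv <- numeric(9 * nel)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- k * nel + seq_len(nel)
    ii[idx] <- tri[, a]   # test
    jj[idx] <- tri[, b]   # trial
    vv[idx] <- rb$A * (abar * rb$gx[, b] * rb$gx[, a] +
                       cbar * rb$gy[, b] * rb$gy[, a] +
                       0.5 * bbar * (rb$gx[, b] * rb$gy[, a] +
                                     rb$gy[, b] * rb$gx[, a])) +
      (rb$A / 3) * (da$xi * rb$gx[, b] + dc$eta * rb$gy[, b] +
                    0.5 * (db$eta * rb$gx[, b] + db$xi * rb$gy[, b])) -
      (rb$A / 3) * (co$cd * rb$gx[, b] + co$ce * rb$gy[, b])
    mv[idx] <- mw * (1 + (a == b))
    k <- k + 1L
  }
  ## rhs = (tau/(dt P)) mass * x^n, accumulated without forming the matrix
  rhs <- cbind(rowsum_into(mv * mesh$phys[jj, 1], ii, n),
               rowsum_into(mv * mesh$phys[jj, 2], ii, n))
  ## Dirichlet rows on every boundary loop: filter their triplets and put 1
  ## on the diagonal before construction
  bnodes <- unlist(mesh$loops, use.names = FALSE)
  bpos <- mesh$phys[bnodes, , drop = FALSE]
  off <- 0L
  for (nm in names(mesh$loops)) {
    ln <- length(mesh$loops[[nm]])
    if (!is.null(boundary_positions[[nm]]))
      bpos[off + seq_len(ln), ] <- boundary_positions[[nm]]
    off <- off + ln
  }
  isb <- logical(n); isb[bnodes] <- TRUE
  keep <- !isb[ii]
  A_sys <- Matrix::sparseMatrix(i = c(ii[keep], bnodes), j = c(jj[keep], bnodes),
                                x = c(vv[keep] + mv[keep],
                                      rep(1, length(bnodes))),
                                dims = c(n, n))
  rhs[bnodes, ] <- bpos
  sol <- as.matrix(Matrix::solve(A_sys, rhs))
  out <- mesh
  out$phys <- sol
  if (any(triangle_areas(out, "phys") <= 0))
    stop("tangled mesh after MMPDE step: non-positive element Jacobian")
  out
}
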