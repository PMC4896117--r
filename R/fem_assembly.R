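#' Reaction specification for a coupled bulk-surface species pair
#'
#' Collects the kinetic functions and diffusion coefficients of one bulk
#' species c coupled to one surface species cs: bulk reaction `f(c)`, surface
#' flux/reaction `g(c, cs)` (the rate at which the bulk feeds the surface
#' through the membrane), surface-only reaction `h(cs)`, and the diffusion
#' coefficients `D` (bulk) and `Ds` (surface). Derivatives are needed by the
#' Newton solver of the Crank-Nicolson bulk step.
#'
#' @param D,Ds nonnegative diffusion coefficients.
#' @param f,fprime bulk reaction rate and its derivative in c (`NULL` = zero).
#' @param g,dg_dc surface reaction rate `g(c, cs)` and its partial derivative
#'   in c (`NULL` = zero).
#' @param h surface-only reaction `h(cs)` (`NULL` = zero).
#' @return an object of class `reaction_spec`.
#' @export
reaction_spec <- function(D = 1, Ds = 1, f = NULL, fprime = NULL,
                          g = NULL, dg_dc = NULL, h = NULL) {
  if (D < 0 || Ds < 0) stop("diffusion coefficients must be nonnegative")
  structure(list(D = D, Ds = Ds, f = f, fprime = fprime,
                 g = g, dg_dc = dg_dc, h = h), class = "reaction_spec")
}

#' Discrete ALE mesh velocity
#'
#' Node-wise finite difference `w_i = (x_i^{n+1} - x_i^n)/dt`; the discrete
#' mesh velocity is piecewise constant over the time slab.
#'
#' @param coords_n,coords_np1 N x 2 node coordinate matrices at consecutive
#'   time levels (same connectivity).
#' @param dt time step.
#' @return N x 2 matrix of nodal velocities.
#' @export
mesh_velocity <- function(coords_n, coords_np1, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (!all(dim(coords_n) == dim(coords_np1)))
    stop("mismatched meshes: node counts differ")
  (coords_np1 - coords_n) / dt
}

## P1 basis gradients and areas on the physical mesh
phys_basis <- function(mesh) {
  tri <- mesh$tri; p <- mesh$phys
  A <- triangle_areas(mesh, "phys")
  list(A = A,
       gx = cbind((p[tri[, 2], 2] - p[tri[, 3], 2]),
                  (p[tri[, 3], 2] - p[tri[, 1], 2]),
                  (p[tri[, 1], 2] - p[tri[, 2], 2])) / (2 * A),
       gy = cbind((p[tri[, 3], 1] - p[tri[, 2], 1]),
                  (p[tri[, 1], 1] - p[tri[, 3], 1]),
                  (p[tri[, 2], 1] - p[tri[, 1], 1])) / (2 * A))
}

sp_from_blocks <- function(tri, blocks, n) {
  ## blocks: list over (a,b) in row-major 3x3 order of per-element values
  nel <- nrow(tri)
  ii <- jj <- integer(9 * nel); vv <- numeric(9 * nel)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- k * nel + seq_len(nel)
    ii[idx] <- tri[, a]; jj[idx] <- tri[, b]
    vv[idx] <- blocks[[k + 1L]]
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
}

#' Assemble the bulk P1 operators on the current mesh
#'
#' Exact P1 integration for the mass matrix M and stiffness K (scaled by the
#' bulk diffusion coefficient), and the ALE transport matrix
#' `B[i, j] = -int (w . grad phi_i) phi_j dx` with the mesh velocity
#' interpolated P1.
#'
#' @param mesh a `tri_mesh`.
#' @param w N x 2 nodal ALE velocity (or `NULL` for a stationary mesh).
#' @param spec a [reaction_spec()] (supplies D).
#' @return list with sparse matrices `M`, `K`, `B`.
#' @export
assemble_bulk <- function(mesh, w = NULL, spec = reaction_spec()) {
  tri <- mesh$tri; n <- nrow(mesh$phys); nel <- nrow(tri)
  pb <- phys_basis(mesh)
  A <- pb$A
  mass_blocks <- vector("list", 9)
  stiff_blocks <- vector("list", 9)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    mass_blocks[[k]] <- (A / 12) * (1 + (a == b))
    stiff_blocks[[k]] <- spec$D * A * (pb$gx[, a] * pb$gx[, b] +
                                       pb$gy[, a] * pb$gy[, b])
  }
  M <- sp_from_blocks(tri, mass_blocks, n)
  K <- sp_from_blocks(tri, stiff_blocks, n)
  if (is.null(w)) {
    B <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  } else {
    ## B[i,j] = -int (w . grad phi_i) phi_j; grad phi_i constant per element,
    ## w P1: int w phi_j = sum_k w_k int phi_k phi_j (element mass column)
    wB <- vector("list", 9)
    k <- 0L
    for (a in 1:3) for (b in 1:3) {
      k <- k + 1L
      acc <- 0
      for (cc in 1:3) {
        mab <- (A / 12) * (1 + (cc == b))
        acc <- acc + (w[tri[, cc], 1] * pb$gx[, a] +
                      w[tri[, cc], 2] * pb$gy[, a]) * mab
      }
      wB[[k]] <- -acc
    }
    B <- sp_from_blocks(tri, wB, n)
  }
  list(M = M, K = K, B = B)
}

#' Bulk reaction load vector and its Jacobian
#'
#' `F_i = int f(c_h) phi_i dx` by the 3-point edge-midpoint rule (exact for
#' quadratics), together with the Jacobian `dF/dC` needed by Newton.
#'
#' @param mesh a `tri_mesh`.
#' @param spec a [reaction_spec()].
#' @param C bulk nodal vector.
#' @return list with `F` (vector) and `JF` (sparse matrix).
#' @export
bulk_load <- function(mesh, spec, C) {
  n <- nrow(mesh$phys)
  if (is.null(spec$f))
    return(list(F = numeric(n),
                JF = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                          x = numeric(0), dims = c(n, n))))
  tri <- mesh$tri; A <- triangle_areas(mesh, "phys")
  cv <- cbind(C[tri[, 1]], C[tri[, 2]], C[tri[, 3]])
  ## quadrature points = edge midpoints; basis values there:
  ## point q (opposite vertex q) has phi = 0 at q and 1/2 at the others
  q12 <- (cv[, 1] + cv[, 2]) / 2
  q23 <- (cv[, 2] + cv[, 3]) / 2
  q31 <- (cv[, 3] + cv[, 1]) / 2
  f12 <- spec$f(q12); f23 <- spec$f(q23); f31 <- spec$f(q31)
  Fel <- cbind((f12 + f31) / 2, (f12 + f23) / 2, (f23 + f31) / 2) * (A / 3)
  Fv <- as.vector(rowsum(as.vector(Fel), as.vector(tri), reorder = TRUE))
  Fout <- numeric(n)
  Fout[sort(unique(as.vector(tri)))] <- Fv
  if (is.null(spec$fprime)) stop("fprime required when f is nonlinear")
  fp12 <- spec$fprime(q12); fp23 <- spec$fprime(q23); fp31 <- spec$fprime(q31)
  ## dF_a/dc_b = A/3 * sum_q f'(c_q) phi_a(q) phi_b(q), phi = 1/2 on the two
  ## nodes of each midpoint's edge
  phiq <- list(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5))
  fpq <- list(fp12, fp23, fp31)
  blocks <- vector("list", 9)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    acc <- 0
    for (q in 1:3) acc <- acc + fpq[[q]] * phiq[[q]][a] * phiq[[q]][b]
    blocks[[k]] <- (A / 3) * acc
  }
  JF <- sp_from_blocks(tri, blocks, n)
  list(F = Fout, JF = JF)
}

## 2-point Gauss rule on [0,1]
gauss2 <- c(0.5 - 0.5 / sqrt(3), 0.5 + 0.5 / sqrt(3))

#' Assemble the surface P1 operators on the membrane polygon
#'
#' Periodic one-dimensional P1 operators along the closed membrane polygon:
#' mass `Ms`, Laplace-Beltrami stiffness `Ks` (arc-length derivative, scaled
#' by Ds), the surface advection matrix `As` containing both the
#' tangential-divergence and tangential-advection parts of (u - w), the bulk
#' boundary matrix `A` with kernel (u - w).n, the coupling load vectors
#' `D_vec` (kernel `g - (u.n) c`, entering the bulk system on membrane rows)
#' and `Ds_vec` (kernel `g`, entering the surface system), the surface
#' reaction load `H_vec`, and the Jacobian `JD` of `D_vec` with respect to the
#' membrane values of C. Nonlinear kernels use 2-point Gauss quadrature per
#' segment. The membrane normal n points away from the enclosed region (from
#' the cell into the bulk).
#'
#' @param gamma Ns x 2 membrane node coordinates, counterclockwise.
#' @param u,w Ns x 2 material and mesh velocities at the membrane nodes
#'   (`NULL` = zero).
#' @param spec a [reaction_spec()].
#' @param C_gamma bulk nodal values restricted to the membrane nodes.
#' @param Cs surface nodal vector.
#' @return list with `Ms`, `Ks`, `As`, `A`, `D_vec`, `Ds_vec`, `H_vec`, `JD`,
#'   all in surface (membrane-loop) indexing.
#' @export
assemble_surface <- function(gamma, u = NULL, w = NULL,
                             spec = reaction_spec(),
                             C_gamma = NULL, Cs = NULL) {
  x <- as.matrix(gamma)
  ns <- nrow(x)
  if (ns < 4) stop("open or degenerate membrane loop")
  nxt <- ip1(ns)
  if (is.null(u)) u <- matrix(0, ns, 2)
  if (is.null(w)) w <- matrix(0, ns, 2)
  seg <- x[nxt, , drop = FALSE] - x
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stop("degenerate membrane segment")
  tseg <- seg / len
  ## nodal normals from central-difference tangents (outward for CCW loop)
  dch <- x[nxt, , drop = FALSE] - x[im1(ns), , drop = FALSE]
  tn <- dch / sqrt(rowSums(dch^2))
  nrm <- cbind(tn[, 2], -tn[, 1])
  i1 <- seq_len(ns); i2 <- nxt
  trip <- function(v11, v12, v21, v22)
    Matrix::sparseMatrix(i = c(i1, i1, i2, i2), j = c(i1, i2, i1, i2),
                         x = c(v11, v12, v21, v22), dims = c(ns, ns))
  Ms <- trip(len / 3, len / 6, len / 6, len / 3)
  Ks <- trip(spec$Ds / len, -spec$Ds / len, -spec$Ds / len, spec$Ds / len)
  ## As: v = u - w; divergence part + advection part
  v <- u - w
  va <- rowSums(v[i1, , drop = FALSE] * tseg)
  vb <- rowSums(v[i2, , drop = FALSE] * tseg)
  divv <- (vb - va) / len
  As <- trip(divv * len / 3 - (2 * va + vb) / 6,
             divv * len / 6 + (2 * va + vb) / 6,
             divv * len / 6 - (va + 2 * vb) / 6,
             divv * len / 3 + (va + 2 * vb) / 6)
  ## A: kernel q = (u - w).n, P1 nodal
  qn <- rowSums(v * nrm)
  q1 <- qn[i1]; q2 <- qn[i2]
  Abm <- trip(len / 12 * (3 * q1 + q2), len / 12 * (q1 + q2),
              len / 12 * (q1 + q2), len / 12 * (q1 + 3 * q2))
  ## load vectors by 2-point Gauss per segment
  un <- rowSums(u * nrm)
  gfun <- if (is.null(spec$g)) function(c, cs) 0 * c else spec$g
  hfun <- spec$h
  cg <- if (is.null(C_gamma)) numeric(ns) else C_gamma
  cs_ <- if (is.null(Cs)) numeric(ns) else Cs
  D_vec <- Ds_vec <- H_vec <- numeric(ns)
  JD_i <- JD_j <- integer(0); JD_v <- numeric(0)
  dgc <- spec$dg_dc
  for (gp in gauss2) {
    p1 <- 1 - gp; p2 <- gp
    cq <- p1 * cg[i1] + p2 * cg[i2]
    csq <- p1 * cs_[i1] + p2 * cs_[i2]
    unq <- p1 * un[i1] + p2 * un[i2]
    gq <- gfun(cq, csq)
    wgt <- len / 2
    ## D kernel: g - (u.n) c ; Ds kernel: g
    rD <- gq - unq * cq
    D_vec <- D_vec + addcyc(ns, wgt * rD * p1, wgt * rD * p2)
    Ds_vec <- Ds_vec + addcyc(ns, wgt * gq * p1, wgt * gq * p2)
    if (!is.null(hfun)) {
      hq <- hfun(csq)
      H_vec <- H_vec + addcyc(ns, wgt * hq * p1, wgt * hq * p2)
    }
    ## Jacobian of D in the membrane values of C
    dker <- (if (is.null(dgc)) 0 else dgc(cq, csq)) - unq
    JD_i <- c(JD_i, i1, i1, i2, i2)
    JD_j <- c(JD_j, i1, i2, i1, i2)
    JD_v <- c(JD_v, wgt * dker * p1 * p1, wgt * dker * p1 * p2,
              wgt * dker * p2 * p1, wgt * dker * p2 * p2)
  }
  JD <- Matrix::sparseMatrix(i = JD_i, j = JD_j, x = JD_v, dims = c(ns, ns))
  list(Ms = Ms, Ks = Ks, As = As, A = Abm, D_vec = D_vec, Ds_vec = Ds_vec,
       H_vec = H_vec, JD = JD, lengths = len, normals = nrm)
}

## accumulate segment-wise contributions (value at segment start node i and
## end node i+1) into a periodic nodal vector
addcyc <- function(ns, at_start, at_end) {
  out <- numeric(ns)
  out <- out + at_start
  out[ip1(ns)] <- out[ip1(ns)] + at_end
  out
}

## accumulate v into an n-vector at (possibly repeated) indices idx
rowsum_into <- function(v, idx, n) {
  out <- numeric(n)
  rs <- rowsum(v, idx, reorder = FALSE)
  out[as.integer(rownames(rs))] <- rs
  out
}

## lift surface-indexed operators into bulk indexing on the membrane loop
lift_surface_matrix <- function(S, loop, n) {
  S <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
  Matrix::sparseMatrix(i = loop[S@i + 1L], j = loop[S@j + 1L], x = S@x,
                       dims = c(n, n))
}

lift_surface_vector <- function(v, loop, n) {
  out <- numeric(n)
  out[loop] <- v
  out
}
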