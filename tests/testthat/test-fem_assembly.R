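single_triangle_mesh <- function(p) {
  structure(list(ref = p, phys = p, tri = matrix(1:3, 1),
                 loops = list(membrane = 1:3)), class = "tri_mesh")
}

test_that("mesh velocity is the node-wise finite difference", {
  m <- get_disc_mesh(0.2)
  expect_equal(mesh_velocity(m$phys, m$phys, 0.1),
               matrix(0, nrow(m$phys), 2))
  shifted <- m$phys + matrix(c(0.05, 0), nrow(m$phys), 2, byrow = TRUE)
  w <- mesh_velocity(m$phys, shifted, 0.1)
  expect_equal(w[, 1], rep(0.5, nrow(m$phys)))
  expect_equal(w[, 2], rep(0, nrow(m$phys)))
  ## small rotation: speed = eps * |x| / dt + O(eps^2)
  eps <- 1e-4
  R <- rbind(c(cos(eps), -sin(eps)), c(sin(eps), cos(eps)))
  w2 <- mesh_velocity(m$phys, m$phys %*% t(R), 1)
  expect_equal(sqrt(rowSums(w2^2)), eps * sqrt(rowSums(m$phys^2)),
               tolerance = 1e-4)
  expect_error(mesh_velocity(m$phys, m$phys[-1, ], 0.1), "mismatched")
})

test_that("element mass matrix matches the exact P1 formula", {
  p <- rbind(c(0, 0), c(2, 0), c(0, 3))
  A <- 3
  m <- single_triangle_mesh(p)
  ops <- assemble_bulk(m, NULL, reaction_spec(D = 1))
  expect_equal(as.matrix(ops$M),
               (A / 12) * matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("stiffness annihilates constants and B vanishes for zero velocity", {
  m <- get_disc_mesh(0.1)
  ops <- assemble_bulk(m, NULL, reaction_spec(D = 2))
  one <- rep(1, nrow(m$phys))
  expect_lt(max(abs(ops$K %*% one)), 1e-12)
  expect_equal(Matrix::nnzero(ops$B), 0)
  ## 1' M 1 = total area exactly
  expect_equal(sum(ops$M %*% one), sum(triangle_areas(m)), tolerance = 1e-12)
  ## transport matrix has zero column sums (mass-neutral)
  set.seed(4)
  w <- matrix(rnorm(2 * nrow(m$phys)), ncol = 2)
  opsw <- assemble_bulk(m, w, reaction_spec(D = 1))
  expect_lt(max(abs(Matrix::colSums(opsw$B))), 1e-12)
})

test_that("surface operators match 1D P1 formulas on a uniform polygon", {
  th <- 2 * pi * (0:31) / 32
  gam <- cbind(cos(th), sin(th))
  ell <- sqrt(sum((gam[2, ] - gam[1, ])^2))
  s <- assemble_surface(gam, spec = reaction_spec(D = 1, Ds = 3))
  Ms <- as.matrix(s$Ms)
  expect_equal(Ms[1, 1], 2 * ell / 3, tolerance = 1e-12)
  expect_equal(Ms[1, 2], ell / 6, tolerance = 1e-12)
  ones <- rep(1, 32)
  ## partition of unity: total length
  expect_equal(sum(Ms), 32 * ell, tolerance = 1e-12)
  expect_lt(max(abs(s$Ks %*% ones)), 1e-12)
  ## Ks scales with Ds
  s1 <- assemble_surface(gam, spec = reaction_spec(D = 1, Ds = 1))
  expect_equal(as.matrix(s$Ks), 3 * as.matrix(s1$Ks), tolerance = 1e-12)
})

test_that("advection operators vanish when u equals w", {
  th <- 2 * pi * (0:31) / 32
  gam <- cbind(cos(th), sin(th))
  v <- cbind(sin(3 * th), cos(th))
  s <- assemble_surface(gam, u = v, w = v, spec = reaction_spec())
  expect_equal(Matrix::nnzero(s$As), 0)
  expect_equal(Matrix::nnzero(s$A), 0)
})

test_that("assemblies are linear in the velocity argument", {
  th <- 2 * pi * (0:31) / 32
  gam <- cbind(cos(th), sin(th))
  set.seed(9)
  u <- cbind(rnorm(32), rnorm(32))
  s1 <- assemble_surface(gam, u = u, spec = reaction_spec())
  s2 <- assemble_surface(gam, u = 2 * u, spec = reaction_spec())
  expect_equal(as.matrix(s2$As), 2 * as.matrix(s1$As), tolerance = 1e-12)
  expect_equal(as.matrix(s2$A), 2 * as.matrix(s1$A), tolerance = 1e-12)
})

test_that("discrete Reynolds identity holds on a randomly moved mesh", {
  m0 <- get_disc_mesh(0.2)
  set.seed(21)
  n <- nrow(m0$phys)
  interior <- setdiff(seq_len(n), m0$loops$membrane)
  dt <- 1e-3
  disp <- matrix(0, n, 2)
  disp[interior, ] <- 0.02 * matrix(rnorm(2 * length(interior)), ncol = 2)
  m1 <- m0
  m1$phys <- m0$phys + disp * dt
  w <- mesh_velocity(m0$phys, m1$phys, dt)
  v <- 1 + m0$phys[, 1] + m0$phys[, 2]^2
  M0 <- assemble_bulk(m0, NULL, reaction_spec())$M
  M1 <- assemble_bulk(m1, NULL, reaction_spec())$M
  lhs <- (sum(M1 %*% v) - sum(M0 %*% v)) / dt
  ## int v div(w) on the midpoint mesh, with elementwise-constant div(w)
  mm <- m0
  mm$phys <- (m0$phys + m1$phys) / 2
  pb <- alefem:::phys_basis(mm)
  tri <- mm$tri
  divw <- rowSums(sapply(1:3, function(k)
    w[tri[, k], 1] * pb$gx[, k] + w[tri[, k], 2] * pb$gy[, k]))
  vbar <- (v[tri[, 1]] + v[tri[, 2]] + v[tri[, 3]]) / 3
  rhs <- sum(pb$A * divw * vbar)
  expect_equal(lhs, rhs, tolerance = 1e-3)
})

test_that("coupling loads integrate the printed kernels", {
  th <- 2 * pi * (0:63) / 64
  gam <- cbind(cos(th), sin(th))
  spec <- reaction_spec(D = 1, Ds = 1, g = function(c, cs) c - cs,
                        dg_dc = function(c, cs) rep(1, length(c)))
  Cg <- 2 + cos(th)
  Cs <- 1 + 0 * th
  s <- assemble_surface(gam, spec = spec, C_gamma = Cg, Cs = Cs)
  ## int (c - cs) phi_i summed over i = int (c - cs) ds = 2 pi mean (here
  ## integral of 1 + cos(theta) over the polygon)
  perim <- sum(s$lengths)
  expect_equal(sum(s$D_vec), perim * 1, tolerance = 1e-3)
  expect_equal(s$D_vec, s$Ds_vec)  # u = 0 so the kernels coincide
  ## h load: h(cs) = -2 cs with cs = 1 integrates to -2 * perimeter
  spec2 <- reaction_spec(h = function(cs) -2 * cs)
  s2 <- assemble_surface(gam, spec = spec2, C_gamma = Cg, Cs = Cs)
  expect_equal(sum(s2$H_vec), -2 * perim, tolerance = 1e-12)
})
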