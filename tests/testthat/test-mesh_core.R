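test_that("generated meshes conform to analytic boundaries and are well shaped", {
  m <- get_disc_mesh(0.1)
  bn <- m$loops$membrane
  expect_lt(max(abs(sqrt(rowSums(m$phys[bn, ]^2)) - 1)), 1e-10)
  expect_lt(abs(sum(triangle_areas(m)) - pi) / pi, 0.005)
  expect_true(all(triangle_areas(m) > 0))
  expect_gte(min_triangle_angle(m), 20)

  a <- generate_initial_mesh(domain_spec("annulus_cell_in_circle",
                                         r0 = 0.1, rf = 0.3, h = 0.01))
  expect_gte(min_triangle_angle(a), 20)
  expect_lt(max(abs(sqrt(rowSums(a$phys[a$loops$membrane, ]^2)) - 0.1)), 1e-10)
  expect_lt(max(abs(sqrt(rowSums(a$phys[a$loops$farfield, ]^2)) - 0.3)), 1e-10)
  ## membrane CCW (positive enclosed area), farfield CCW
  expect_gt(polygon_area(a$phys[a$loops$membrane, ]), 0)
  expect_gt(polygon_area(a$phys[a$loops$farfield, ]), 0)

  e <- generate_initial_mesh(domain_spec("annulus_ellipse_in_circle",
                                         ns = 98, rf = 1))
  onell <- 4 * e$phys[e$loops$membrane, 1]^2 + 16 * e$phys[e$loops$membrane, 2]^2
  expect_lt(max(abs(onell - 1)), 1e-10)

  expect_error(domain_spec("annulus_cell_in_circle", r0 = 0.3, rf = 0.1),
               "invalid domain")
})

test_that("minimum triangle angle matches a law-of-cosines oracle", {
  one_tri <- function(p) {
    structure(list(ref = p, phys = p, tri = matrix(1:3, 1),
                   loops = list(membrane = 1:3)), class = "tri_mesh")
  }
  eq <- one_tri(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  expect_equal(min_triangle_angle(eq), 60, tolerance = 1e-12)
  iso <- one_tri(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(min_triangle_angle(iso), 45, tolerance = 1e-12)
  ## sliver: independent oracle via side lengths and acos
  p <- rbind(c(0, 0), c(1, 0), c(2, 1e-6))
  sl <- function(u, v) sqrt(sum((u - v)^2))
  ab <- sl(p[1, ], p[2, ]); bc <- sl(p[2, ], p[3, ]); ca <- sl(p[3, ], p[1, ])
  oracle <- min(acos((ab^2 + ca^2 - bc^2) / (2 * ab * ca)),
                acos((ab^2 + bc^2 - ca^2) / (2 * ab * bc)),
                acos((bc^2 + ca^2 - ab^2) / (2 * bc * ca))) * 180 / pi
  expect_equal(min_triangle_angle(one_tri(p)), oracle, tolerance = 1e-10)
  expect_lt(oracle, 5e-5)
})

test_that("polygon_area is the shoelace formula with orientation sign", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  th <- 2 * pi * (0:999) / 1000
  expect_equal(polygon_area(cbind(cos(th), sin(th))), 500 * sin(2 * pi / 1000),
               tolerance = 1e-12)
  ## reversal property
  expect_equal(polygon_area(sq[4:1, ]), -polygon_area(sq))
})

test_that("barycentric interpolation reproduces linears and is a projection", {
  m <- get_disc_mesh(0.1)
  f <- 2 * m$phys[, 1] + 3 * m$phys[, 2] - 1
  set.seed(11)
  q <- cbind(runif(100, -0.6, 0.6), runif(100, -0.6, 0.6))
  expect_lt(max(abs(interpolate_to_points(m, f, q) -
                    (2 * q[, 1] + 3 * q[, 2] - 1))), 1e-12)
  ## node queries return nodal values exactly
  expect_equal(interpolate_to_points(m, f, m$phys), f)
  ## outside point errors, naming the point
  expect_error(interpolate_to_points(m, f, cbind(2, 2)), "2.*outside mesh")
})

test_that("interpolation error for a quadratic scales as h^2", {
  set.seed(7)
  q <- cbind(runif(300, -0.5, 0.5), runif(300, -0.5, 0.5))
  err <- sapply(c(0.1, 0.05), function(h) {
    m <- generate_initial_mesh(domain_spec("disc", h = h, rf = 1))
    f <- m$phys[, 1]^2
    max(abs(interpolate_to_points(m, f, q) - q[, 1]^2))
  })
  ## calibrate C on the coarse mesh, check the bound on the fine one
  C <- err[1] / 0.1^2
  expect_lt(err[2], 1.5 * C * 0.05^2)
})

test_that("remeshing preserves the boundary and transfers fields conservatively", {
  spec <- domain_spec("annulus_cell_in_circle", r0 = 0.1, rf = 0.3, ns = 32)
  m <- generate_initial_mesh(spec)
  C <- 1 + m$phys[, 1]
  Cs <- rep(2, 32)
  rr <- remesh(m, fields = list(C = C, Cs = Cs))
  ## membrane polygon held fixed node-for-node
  expect_equal(rr$mesh$phys[rr$mesh$loops$membrane, ],
               m$phys[m$loops$membrane, ])
  expect_equal(rr$fields$Cs, Cs)
  ## linear bulk field transfers exactly; lumped mass within O(h^2)
  expect_lt(max(abs(rr$fields$C - (1 + rr$mesh$phys[, 1]))), 1e-10)
  expect_gte(min_triangle_angle(rr$mesh), 10)
  ## constant field preserved exactly
  r2 <- remesh(m, fields = list(C = rep(3, nrow(m$phys))))
  expect_equal(r2$fields$C, rep(3, nrow(r2$mesh$phys)), tolerance = 1e-12)
})

test_that("bulk mass is preserved through remeshing to interpolation accuracy", {
  spec <- domain_spec("annulus_cell_in_circle", r0 = 0.1, rf = 0.3, ns = 48)
  m <- generate_initial_mesh(spec)
  C <- sin(10 * m$phys[, 1]) + m$phys[, 2]^2
  lumped_mass <- function(mesh, C) {
    A <- triangle_areas(mesh)
    sum((C[mesh$tri[, 1]] + C[mesh$tri[, 2]] + C[mesh$tri[, 3]]) / 3 * A)
  }
  rr <- remesh(m, fields = list(C = C))
  h2 <- (0.02)^2
  expect_lt(abs(lumped_mass(rr$mesh, rr$fields$C) - lumped_mass(m, C)), 5 * h2)
})

test_that("VTK output round-trips points, cells, loops and fields", {
  m <- get_disc_mesh(0.2)
  f <- tempfile(fileext = ".vtk")
  write_vtk(m, f, point_data = list(u = m$phys[, 1] + 2))
  v <- read_vtk(f)
  expect_equal(v$points, unname(m$phys), tolerance = 1e-12)
  expect_equal(nrow(v$triangles), nrow(m$tri))
  expect_equal(sort(v$loops[[1]]), sort(m$loops$membrane))
  expect_equal(v$point_data$u, m$phys[, 1] + 2, tolerance = 1e-12)
  unlink(f)
})
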