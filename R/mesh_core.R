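#' Domain specification for mesh generation
#'
#' Describes one of the supported two-dimensional computational domains: a
#' disc, the annular region between an ellipse and a circular far-field
#' boundary, or the annular region between an arbitrary star-shaped closed
#' polygon (a cell membrane) and a circular far-field boundary.
#'
#' @param kind one of `"disc"`, `"annulus_ellipse_in_circle"`,
#'   `"annulus_cell_in_circle"`.
#' @param h target edge length of the mesh.
#' @param r0 inner radius (cell radius) for `"annulus_cell_in_circle"`, or the
#'   disc radius for `"disc"`.
#' @param rf far-field (outer) radius for annular domains.
#' @param centre centre of the domain, length-2 numeric.
#' @param ellipse_axes semi-axes `c(a, b)` of the inner ellipse for
#'   `"annulus_ellipse_in_circle"` (the ellipse `x^2/a^2 + y^2/b^2 = 1`).
#' @param ns number of boundary nodes on the inner loop; defaults to the
#'   number implied by `h`.
#' @param h_min,h_max radially graded layer thickness near the inner boundary
#'   and the far field; defaults grade from the inner node spacing to the
#'   outer node spacing, realizing boundary-adapted isotropic refinement
#'   towards the membrane.
#' @param inner_loop optional explicit inner boundary polygon (Ns x 2 matrix,
#'   counterclockwise) for `"annulus_cell_in_circle"`; defaults to a circle of
#'   radius `r0`.
#' @return an object of class `domain_spec`.
#' @export
domain_spec <- function(kind = c("disc", "annulus_ellipse_in_circle",
                                 "annulus_cell_in_circle"),
                        h = 0.1, r0 = 0.1, rf = NULL, centre = c(0, 0),
                        ellipse_axes = c(0.5, 0.25), ns = NULL,
                        h_min = NULL, h_max = NULL, inner_loop = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(h) || h <= 0) stop("h must be positive")
  if (kind == "disc") {
    if (is.null(rf)) rf <- if (!is.null(r0) && r0 > 0.1) r0 else 1
  } else if (kind == "annulus_cell_in_circle") {
    if (is.null(rf)) rf <- 3 * r0
    if (rf <= r0 || r0 <= 0) stop("invalid domain: need rf > r0 > 0")
  } else {
    if (is.null(rf)) rf <- 1
    if (any(ellipse_axes <= 0) || rf <= max(ellipse_axes))
      stop("invalid domain: ellipse must lie strictly inside the far-field circle")
  }
  structure(list(kind = kind, h = h, r0 = r0, rf = rf, centre = centre,
                 ellipse_axes = ellipse_axes, ns = ns,
                 h_min = h_min, h_max = h_max, inner_loop = inner_loop),
            class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  cat("<domain_spec>", x$kind, " h =", x$h, "\n")
  invisible(x)
}

new_tri_mesh <- function(phys, tri, loops, spec = NULL, ref = phys) {
  m <- structure(list(ref = ref, phys = phys, tri = tri, loops = loops,
                      spec = spec), class = "tri_mesh")
  validate_tri_mesh(m)
  m
}

validate_tri_mesh <- function(mesh) {
  if (any(triangle_areas(mesh, "phys") <= 0))
    stop("tangled mesh: non-positive triangle area in physical coordinates")
  if (any(triangle_areas(mesh, "ref") <= 0))
    stop("tangled mesh: non-positive triangle area in reference coordinates")
  invisible(mesh)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("<tri_mesh> ", nrow(x$phys), " nodes, ", nrow(x$tri), " triangles, ",
      length(x$loops), " boundary loop(s) [",
      paste(names(x$loops), vapply(x$loops, length, 1L), collapse = ", "),
      "]\n", sep = "")
  cat("  min angle:", format(min_triangle_angle(x), digits = 4), "deg\n")
  invisible(x)
}

#' Signed triangle areas of a mesh
#'
#' @param mesh a `tri_mesh`.
#' @param which `"phys"` (default) or `"ref"` coordinates.
#' @return numeric vector of signed areas (positive for the stored
#'   counterclockwise orientation).
#' @export
triangle_areas <- function(mesh, which = c("phys", "ref")) {
  which <- match.arg(which)
  p <- mesh[[which]]
  t1 <- mesh$tri[, 1]; t2 <- mesh$tri[, 2]; t3 <- mesh$tri[, 3]
  0.5 * ((p[t2, 1] - p[t1, 1]) * (p[t3, 2] - p[t1, 2]) -
         (p[t3, 1] - p[t1, 1]) * (p[t2, 2] - p[t1, 2]))
}

#' Minimum interior angle over all triangles
#'
#' Used as the mesh quality measure that triggers remeshing: a value below the
#' quality tolerance signals that the moving mesh is close to tangling.
#'
#' @param mesh a `tri_mesh`.
#' @return minimum interior angle in degrees, in (0, 60]; a degenerate
#'   (zero-area) triangle yields 0.
#' @export
min_triangle_angle <- function(mesh) {
  p <- mesh$phys
  if (nrow(mesh$tri) == 0L) stop("empty mesh")
  e1 <- p[mesh$tri[, 3], , drop = FALSE] - p[mesh$tri[, 2], , drop = FALSE]
  e2 <- p[mesh$tri[, 1], , drop = FALSE] - p[mesh$tri[, 3], , drop = FALSE]
  e3 <- p[mesh$tri[, 2], , drop = FALSE] - p[mesh$tri[, 1], , drop = FALSE]
  a2 <- rowSums(e1^2); b2 <- rowSums(e2^2); c2 <- rowSums(e3^2)
  a <- sqrt(a2); b <- sqrt(b2); c <- sqrt(c2)
  if (any(a == 0 | b == 0 | c == 0)) return(0)
  clamp1 <- function(x) pmin(1, pmax(-1, x))
  A1 <- acos(clamp1((b2 + c2 - a2) / (2 * b * c)))
  A2 <- acos(clamp1((a2 + c2 - b2) / (2 * a * c)))
  A3 <- acos(clamp1((a2 + b2 - c2) / (2 * a * b)))
  ang <- min(A1, A2, A3) * 180 / pi
  if (!is.finite(ang)) 0 else ang
}

#' Signed area of a closed polygon (shoelace formula)
#'
#' @param loop_coords n x 2 matrix of ordered vertices (closing edge implied).
#' @return signed area; positive for counterclockwise orientation.
#' @export
polygon_area <- function(loop_coords) {
  p <- as.matrix(loop_coords)
  if (nrow(p) < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

## ---- structured boundary-conforming mesh generation -------------------------

## Triangulate the band between two concentric closed node rings given by
## angular position; rings may have different node counts (zipper by angle).
## Returns triangles with counterclockwise orientation (inner ring CCW inside
## outer ring CCW).
zipper_band <- function(idx_in, ang_in, idx_out, ang_out) {
  mA <- length(idx_in); mB <- length(idx_out)
  if (mA == 1L) {
    j <- seq_len(mB)
    return(cbind(rep(idx_in, mB), idx_out[j], idx_out[c(seq_len(mB)[-1], 1L)]))
  }
  ## rotate outer ring so its first node sits just after the inner first node
  rot <- which.min((ang_out - ang_in[1]) %% (2 * pi))
  ordB <- c(rot:mB, if (rot > 1) 1:(rot - 1))
  idxB <- idx_out[ordB]
  angB <- ang_out[ordB]
  angB <- ang_in[1] + (angB - ang_in[1]) %% (2 * pi)
  angA <- ang_in[1] + (ang_in - ang_in[1]) %% (2 * pi)
  angA <- c(angA, angA[1] + 2 * pi)
  angB <- c(angB, angB[1] + 2 * pi)
  tris <- matrix(0L, mA + mB, 3)
  t <- 0L; u <- 0L; k <- 0L
  Anode <- function(t) idx_in[(t %% mA) + 1L]
  Bnode <- function(u) idxB[(u %% mB) + 1L]
  while (t < mA || u < mB) {
    k <- k + 1L
    adv_b <- (t == mA) || (u < mB && angB[u + 2L] <= angA[t + 2L])
    if (adv_b) {
      tris[k, ] <- c(Anode(t), Bnode(u), Bnode(u + 1L))
      u <- u + 1L
    } else {
      tris[k, ] <- c(Anode(t), Bnode(u), Anode(t + 1L))
      t <- t + 1L
    }
  }
  tris[seq_len(k), , drop = FALSE]
}

## Polar "spiderweb" disc mesh: ring j has 6j nodes at radius j*R/n.
disc_mesh <- function(R, h, centre = c(0, 0)) {
  n <- max(2L, as.integer(round(R / h)))
  pts <- matrix(centre, 1, 2)
  ring_idx <- list(1L)
  ring_ang <- list(0)
  for (j in seq_len(n)) {
    m <- 6L * j
    th <- 2 * pi * (seq_len(m) - 1L) / m + (j %% 2L) * pi / m
    r <- R * j / n
    new <- cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
    idx <- nrow(pts) + seq_len(m)
    pts <- rbind(pts, new)
    ring_idx[[j + 1L]] <- idx
    ring_ang[[j + 1L]] <- th
  }
  tri <- do.call(rbind, lapply(seq_len(n), function(j)
    zipper_band(ring_idx[[j]], ring_ang[[j]], ring_idx[[j + 1L]], ring_ang[[j + 1L]])))
  loops <- list(membrane = ring_idx[[n + 1L]])
  list(pts = pts, tri = tri, loops = loops)
}

## Equidistributed radial ring fractions in [0,1] for a linearly graded layer
## thickness h(d) = h_min + (h_max - h_min) d over a band of width L.
ring_fractions <- function(L, h_min, h_max) {
  dd <- seq(0, 1, length.out = 513)
  hh <- h_min + (h_max - h_min) * dd
  cum <- c(0, cumsum((L / hh[-1] + L / hh[-length(hh)]) / 2 * diff(dd)))
  n <- max(2L, as.integer(ceiling(cum[length(cum)])))
  stats::approx(cum, dd, xout = seq(0, cum[length(cum)], length.out = n + 1))$y
}

## Transfinite ring mesh between an inner closed polygon and an outer ring of
## the same node count, matched by angle about `centre`. Inner loop nodes come
## first (indices 1..Ns), outer loop nodes last.
build_ring_mesh <- function(inner, outer, centre, h_min, h_max) {
  ns <- nrow(inner)
  stopifnot(nrow(outer) == ns)
  L <- mean(sqrt(rowSums((outer - inner)^2)))
  s <- ring_fractions(L, h_min, h_max)
  nr <- length(s) - 1L
  ang <- atan2(inner[, 2] - centre[2], inner[, 1] - centre[1])
  pts <- inner
  ring_idx <- list(seq_len(ns))
  for (k in seq_len(nr)) {
    ring <- inner + s[k + 1L] * (outer - inner)
    idx <- nrow(pts) + seq_len(ns)
    pts <- rbind(pts, ring)
    ring_idx[[k + 1L]] <- idx
  }
  tri <- do.call(rbind, lapply(seq_len(nr), function(k)
    zipper_band(ring_idx[[k]], ang, ring_idx[[k + 1L]], ang)))
  loops <- list(membrane = ring_idx[[1L]], farfield = ring_idx[[nr + 1L]])
  list(pts = pts, tri = tri, loops = loops)
}

## Sample a closed analytic curve at ns points equidistributing the
## weight-function-weighted arc length (weight = 1 gives equal arc length).
## f(t) for t in [0, 2*pi) must trace the curve counterclockwise.
equal_arclength_points <- function(f, ns, n_dense = 4096, weight = NULL) {
  t <- seq(0, 2 * pi, length.out = n_dense + 1)
  p <- f(t)
  seg <- sqrt(rowSums(diff(p)^2))
  if (!is.null(weight)) {
    wmid <- weight((p[-1, 1] + p[-nrow(p), 1]) / 2,
                   (p[-1, 2] + p[-nrow(p), 2]) / 2)
    seg <- seg * wmid
  }
  cum <- c(0, cumsum(seg))
  tot <- cum[length(cum)]
  ti <- stats::approx(cum, t, xout = tot * (seq_len(ns) - 1L) / ns)$y
  f(ti)
}

#' Generate the initial mesh for a domain
#'
#' Builds a boundary-conforming triangulation whose boundary nodes lie on the
#' analytic boundary curves to round-off accuracy. Discs are meshed with a
#' polar layout; annular domains with transfinite rings between the inner loop
#' and the far-field circle, with layer thickness graded from `h_min` at the
#' inner boundary to `h_max` at the far field (boundary-adapted isotropic
#' refinement towards the membrane). Reference coordinates are initialized
#' equal to the physical coordinates, so the computational domain is the
#' initial physical domain.
#'
#' @param spec a [domain_spec()].
#' @return a `tri_mesh` with positively oriented triangles and
#'   counterclockwise boundary loops (`membrane`, and `farfield` for annuli).
#' @export
generate_initial_mesh <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"))
  ctr <- spec$centre
  if (spec$kind == "disc") {
    g <- disc_mesh(spec$rf, spec$h, ctr)
  } else if (spec$kind == "annulus_ellipse_in_circle") {
    a <- spec$ellipse_axes[1]; b <- spec$ellipse_axes[2]
    per <- sum(sqrt(rowSums(diff(cbind(
      ctr[1] + a * cos(seq(0, 2 * pi, length.out = 2049)),
      ctr[2] + b * sin(seq(0, 2 * pi, length.out = 2049))))^2)))
    ns <- if (is.null(spec$ns)) max(8L, as.integer(round(per / spec$h))) else spec$ns
    inner <- equal_arclength_points(function(t)
      cbind(ctr[1] + a * cos(t), ctr[2] + b * sin(t)), ns)
    ang <- atan2(inner[, 2] - ctr[2], inner[, 1] - ctr[1])
    outer <- cbind(ctr[1] + spec$rf * cos(ang), ctr[2] + spec$rf * sin(ang))
    h_min <- if (is.null(spec$h_min)) per / ns else spec$h_min
    h_max <- if (is.null(spec$h_max)) 2 * pi * spec$rf / ns else spec$h_max
    g <- build_ring_mesh(inner, outer, ctr, h_min, h_max)
  } else { # annulus_cell_in_circle
    if (spec$rf <= spec$r0) stop("invalid domain: need rf > r0")
    if (is.null(spec$inner_loop)) {
      ns <- if (is.null(spec$ns)) max(8L, as.integer(round(2 * pi * spec$r0 / spec$h))) else spec$ns
      th <- 2 * pi * (seq_len(ns) - 1L) / ns
      inner <- cbind(ctr[1] + spec$r0 * cos(th), ctr[2] + spec$r0 * sin(th))
    } else {
      inner <- as.matrix(spec$inner_loop)
      ns <- nrow(inner)
      if (polygon_area(inner) < 0) stop("inner loop must be counterclockwise")
    }
    ang <- atan2(inner[, 2] - ctr[2], inner[, 1] - ctr[1])
    outer <- cbind(ctr[1] + spec$rf * cos(ang), ctr[2] + spec$rf * sin(ang))
    per <- sum(sqrt(rowSums((inner[c(2:ns, 1), ] - inner)^2)))
    h_min <- if (is.null(spec$h_min)) per / ns else spec$h_min
    h_max <- if (is.null(spec$h_max)) 2 * pi * spec$rf / ns else spec$h_max
    g <- build_ring_mesh(inner, outer, ctr, h_min, h_max)
  }
  if (nrow(g$pts) < 8L || any(vapply(g$loops, length, 1L) < 8L))
    stop("h too large: boundary polygons need at least 8 nodes")
  new_tri_mesh(g$pts, g$tri, g$loops, spec = spec)
}

## ---- point location and interpolation ---------------------------------------

## Locate query points in the physical mesh; returns triangle index and
## barycentric coordinates. Uses a uniform background grid over triangle
## bounding boxes for candidate lookup.
locate_points <- function(mesh, points, snap_tol = 1e-6) {
  p <- mesh$phys; tri <- mesh$tri
  pts <- matrix(as.numeric(points), ncol = 2)
  nq <- nrow(pts); nt <- nrow(tri)
  x1 <- p[tri[, 1], 1]; y1 <- p[tri[, 1], 2]
  x2 <- p[tri[, 2], 1]; y2 <- p[tri[, 2], 2]
  x3 <- p[tri[, 3], 1]; y3 <- p[tri[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  bxmin <- pmin(x1, x2, x3); bxmax <- pmax(x1, x2, x3)
  bymin <- pmin(y1, y2, y3); bymax <- pmax(y1, y2, y3)
  cell <- max(bxmax - bxmin, bymax - bymin) * 1.01
  gx0 <- min(bxmin); gy0 <- min(bymin)
  ngx <- max(1L, as.integer(ceiling((max(bxmax) - gx0) / cell)))
  ngy <- max(1L, as.integer(ceiling((max(bymax) - gy0) / cell)))
  cix <- function(x) pmin(ngx - 1L, pmax(0L, as.integer(floor((x - gx0) / cell))))
  ciy <- function(y) pmin(ngy - 1L, pmax(0L, as.integer(floor((y - gy0) / cell))))
  ## each triangle registered in every grid cell its bbox touches
  ix0 <- cix(bxmin); ix1 <- cix(bxmax); iy0 <- ciy(bymin); iy1 <- ciy(bymax)
  reps <- (ix1 - ix0 + 1L) * (iy1 - iy0 + 1L)
  tid <- rep.int(seq_len(nt), reps)
  cells <- integer(sum(reps)); k <- 0L
  for (t in seq_len(nt)) {
    for (ix in ix0[t]:ix1[t]) for (iy in iy0[t]:iy1[t]) {
      k <- k + 1L; cells[k] <- ix + ngx * iy
    }
  }
  buckets <- split(tid, cells)
  tri_of <- integer(nq); bary <- matrix(NA_real_, nq, 3)
  qcell <- cix(pts[, 1]) + ngx * ciy(pts[, 2])
  for (i in seq_len(nq)) {
    cand <- buckets[[as.character(qcell[i])]]
    if (is.null(cand)) cand <- seq_len(nt)  # fall back to full scan
    dx <- pts[i, 1] - x1[cand]; dy <- pts[i, 2] - y1[cand]
    l2 <- ((y3[cand] - y1[cand]) * dx - (x3[cand] - x1[cand]) * dy) / det[cand]
    l3 <- (-(y2[cand] - y1[cand]) * dx + (x2[cand] - x1[cand]) * dy) / det[cand]
    l1 <- 1 - l2 - l3
    score <- pmin(l1, l2, l3)
    j <- which.max(score)
    if (score[j] < -snap_tol) {
      ## retry against all triangles before failing (bbox grid can miss
      ## boundary-snapped points)
      dx <- pts[i, 1] - x1; dy <- pts[i, 2] - y1
      l2a <- ((y3 - y1) * dx - (x3 - x1) * dy) / det
      l3a <- (-(y2 - y1) * dx + (x2 - x1) * dy) / det
      l1a <- 1 - l2a - l3a
      sa <- pmin(l1a, l2a, l3a)
      j2 <- which.max(sa)
      if (sa[j2] < -snap_tol) {
        tri_of[i] <- NA_integer_
        next
      }
      tri_of[i] <- j2
      lam <- pmax(0, c(l1a[j2], l2a[j2], l3a[j2]))
    } else {
      tri_of[i] <- cand[j]
      lam <- pmax(0, c(l1[j], l2[j], l3[j]))
    }
    bary[i, ] <- lam / sum(lam)
  }
  list(triangle = tri_of, bary = bary)
}

#' Interpolate a nodal field to arbitrary points
#'
#' Piecewise-linear (barycentric) interpolation of a P1 nodal field on the
#' physical mesh; exact for fields that are linear in x. Points outside the
#' mesh beyond the snap tolerance raise an error naming the first offending
#' point, unless a `fill` function is supplied to evaluate them.
#'
#' @param mesh a `tri_mesh`.
#' @param nodal_field numeric vector of length `nrow(mesh$phys)`.
#' @param query_points m x 2 matrix of evaluation points.
#' @param snap_tol barycentric tolerance for accepting points marginally
#'   outside an element (boundary round-off).
#' @param fill optional function `f(points)` used for points that cannot be
#'   located (e.g. a far-field formula when the domain has moved).
#' @return numeric vector of interpolated values.
#' @export
interpolate_to_points <- function(mesh, nodal_field, query_points,
                                  snap_tol = 1e-6, fill = NULL) {
  pts <- matrix(as.numeric(query_points), ncol = 2)
  loc <- locate_points(mesh, pts, snap_tol)
  out <- numeric(nrow(pts))
  miss <- is.na(loc$triangle)
  if (any(miss)) {
    if (is.null(fill)) {
      i <- which(miss)[1]
      stop(sprintf("point location failed at (%.8g, %.8g): outside mesh",
                   pts[i, 1], pts[i, 2]))
    }
    out[miss] <- fill(pts[miss, , drop = FALSE])
  }
  ok <- which(!miss)
  if (length(ok)) {
    tr <- mesh$tri[loc$triangle[ok], , drop = FALSE]
    out[ok] <- loc$bary[ok, 1] * nodal_field[tr[, 1]] +
      loc$bary[ok, 2] * nodal_field[tr[, 2]] +
      loc$bary[ok, 3] * nodal_field[tr[, 3]]
  }
  out
}

#' Regenerate the mesh keeping the current boundary polygons fixed
#'
#' Called when the minimum triangle angle falls below the quality tolerance.
#' A new mesh is generated with the current membrane polygon (and, for annular
#' domains, the current far-field circle) held fixed; the bulk field is
#' transferred by piecewise-linear interpolation and surface fields carry over
#' node-for-node since membrane nodes are preserved. The new mesh becomes its
#' own reference (computational) mesh.
#'
#' @param mesh a `tri_mesh` carrying its `domain_spec`.
#' @param fields optional list with elements `C` (bulk nodal vector) and `Cs`
#'   (surface vector or list of vectors on the membrane loop).
#' @param angle_tol quality tolerance in degrees (recorded, not enforced here).
#' @param fill optional fill function passed to [interpolate_to_points()].
#' @return list with elements `mesh` and `fields`.
#' @export
remesh <- function(mesh, fields = NULL, angle_tol = 10, fill = NULL) {
  spec <- mesh$spec
  if (is.null(spec)) stop("remesh failure: mesh carries no domain_spec")
  mem <- mesh$phys[mesh$loops$membrane, , drop = FALSE]
  if (spec$kind == "disc") {
    newmesh <- generate_initial_mesh(spec)
  } else {
    out <- mesh$phys[mesh$loops$farfield, , drop = FALSE]
    ctr <- colMeans(out)
    per <- sum(sqrt(rowSums((mem[c(2:nrow(mem), 1), ] - mem)^2)))
    h_min <- if (is.null(spec$h_min)) per / nrow(mem) else spec$h_min
    h_max <- if (is.null(spec$h_max)) 2 * pi * spec$rf / nrow(mem) else spec$h_max
    ang <- atan2(mem[, 2] - ctr[2], mem[, 1] - ctr[1])
    outer <- cbind(ctr[1] + spec$rf * cos(ang), ctr[2] + spec$rf * sin(ang))
    g <- build_ring_mesh(mem, outer, ctr, h_min, h_max)
    newmesh <- new_tri_mesh(g$pts, g$tri, g$loops, spec = spec)
  }
  newfields <- fields
  if (!is.null(fields$C)) {
    newfields$C <- interpolate_to_points(mesh, fields$C, newmesh$phys,
                                         snap_tol = 1e-6, fill = fill)
  }
  ## membrane nodes are held fixed node-for-node, so surface fields carry over
  list(mesh = newmesh, fields = newfields)
}

## ---- VTK legacy output -------------------------------------------------------

#' Write a mesh and nodal fields as a legacy ASCII VTK file
#'
#' Triangles are written as VTK cells of type 5 and boundary loops as line
#' cells (type 3) tagged by a `loop_id` cell-data array, so membranes render
#' as polylines alongside the bulk mesh.
#'
#' @param mesh a `tri_mesh`.
#' @param file output path.
#' @param point_data named list of nodal numeric vectors.
#' @export
write_vtk <- function(mesh, file, point_data = list()) {
  p <- mesh$phys; np <- nrow(p)
  tri <- mesh$tri - 1L
  segs <- do.call(rbind, lapply(mesh$loops, function(lp)
    cbind(lp, c(lp[-1], lp[1])) - 1L))
  loop_id <- rep(seq_along(mesh$loops), vapply(mesh$loops, length, 1L))
  ncell <- nrow(tri) + nrow(segs)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "alefem mesh snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", np)), con)
  utils::write.table(cbind(p, 0), con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", ncell, 4 * nrow(tri) + 3 * nrow(segs)), con)
  utils::write.table(cbind(3L, tri), con, row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(2L, segs), con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ncell), con)
  writeLines(as.character(c(rep(5L, nrow(tri)), rep(3L, nrow(segs)))), con)
  writeLines(sprintf("CELL_DATA %d", ncell), con)
  writeLines(c("SCALARS loop_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(c(rep(0L, nrow(tri)), loop_id)), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", np), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 17), con)
    }
  }
  invisible(file)
}

#' Read a legacy ASCII VTK file written by [write_vtk()]
#'
#' @param file path to a `.vtk` file.
#' @return list with `points`, `triangles`, `loops` (as index vectors) and
#'   `point_data`.
#' @export
read_vtk <- function(file) {
  lines <- readLines(file)
  ip <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- matrix(scan(text = lines[(ip + 1):(ip + np)], quiet = TRUE),
                np, 3, byrow = TRUE)[, 1:2, drop = FALSE]
  ic <- grep("^CELLS", lines)[1]
  ncell <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  rows <- strsplit(trimws(lines[(ic + 1):(ic + ncell)]), "\\s+")
  tris <- do.call(rbind, lapply(rows[vapply(rows, function(r) r[1] == "3", TRUE)],
                                function(r) as.integer(r[2:4]) + 1L))
  segs <- do.call(rbind, lapply(rows[vapply(rows, function(r) r[1] == "2", TRUE)],
                                function(r) as.integer(r[2:3]) + 1L))
  pd <- list()
  ipd <- grep("^POINT_DATA", lines)
  if (length(ipd)) {
    isc <- grep("^SCALARS", lines)
    isc <- isc[isc > ipd[1]]
    for (i in isc) {
      nm <- strsplit(lines[i], "\\s+")[[1]][2]
      pd[[nm]] <- scan(text = lines[(i + 2):(i + 1 + np)], quiet = TRUE)
    }
  }
  loops <- NULL
  if (!is.null(segs)) {
    ## reconstruct ordered loops from segment chains
    nxt <- integer(np); nxt[segs[, 1]] <- segs[, 2]
    used <- rep(FALSE, np)
    loops <- list()
    for (s in segs[, 1]) {
      if (used[s]) next
      lp <- s; used[s] <- TRUE; cur <- nxt[s]
      while (cur != s && cur != 0L) { lp <- c(lp, cur); used[cur] <- TRUE; cur <- nxt[cur] }
      loops[[length(loops) + 1L]] <- lp
    }
  }
  list(points = pts, triangles = tris, loops = loops, point_data = pd)
}
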