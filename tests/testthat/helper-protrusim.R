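# shared fixtures and a cache for expensive trajectory runs (computed once
# per test session, reused across test files)

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, config = NULL) {
  key <- if (is.null(config)) name else paste0(name, "#custom")
  if (is.null(.run_cache[[key]])) {
    cfg <- if (is.null(config)) scenario_config(name) else config
    assign(key, run_growth(cfg), envir = .run_cache)
  }
  .run_cache[[key]]
}

# disk of radius R centered at (R, 0), plus its quadrature mesh
disk_fixture <- function(R = 1, h = 0.05) {
  curve <- elliptical_cluster(2 * R, 2 * R, h)
  list(curve = curve, mesh = interior_mesh(curve, h), R = R, center = c(R, 0))
}

# closed curve from a polar function r(theta) about the origin
polar_curve <- function(rfun, n = 256, h = 0.05) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- rfun(th)
  boundary_curve(r * cos(th), r * sin(th), h)
}

# maximum distance from each point of curve a to the point set of curve b
point_set_distance <- function(a, b) {
  pa <- cbind(a$x, a$y); pb <- cbind(b$x, b$y)
  max(vapply(seq_len(nrow(pa)), function(i)
    sqrt(min((pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2)), 0))
}

# maximum distance from the points of curve a to the closed polyline of b
# (a one-sided Hausdorff distance to the polygon, not just its vertices)
curve_to_polyline_distance <- function(a, b) {
  pa <- cbind(a$x, a$y)
  pb <- cbind(b$x, b$y)
  n <- nrow(pb)
  b2 <- pb[c(2:n, 1), , drop = FALSE]
  ex <- b2[, 1] - pb[, 1]; ey <- b2[, 2] - pb[, 2]
  el2 <- pmax(ex^2 + ey^2, 1e-300)
  max(vapply(seq_len(nrow(pa)), function(i) {
    tt <- pmin(pmax(((pa[i, 1] - pb[, 1]) * ex + (pa[i, 2] - pb[, 2]) * ey) / el2, 0), 1)
    sqrt(min((pb[, 1] + tt * ex - pa[i, 1])^2 + (pb[, 2] + tt * ey - pa[i, 2])^2))
  }, 0))
}

# closed polygon through the given corner points with edges subdivided at ~h
poly_path <- function(x, y, h) {
  n <- length(x)
  xs <- ys <- numeric(0)
  for (i in 1:n) {
    j <- if (i == n) 1 else i + 1
    len <- sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
    m <- max(1, ceiling(len / h))
    tt <- seq(0, 1, length.out = m + 1)[-(m + 1)]
    xs <- c(xs, x[i] + tt * (x[j] - x[i]))
    ys <- c(ys, y[i] + tt * (y[j] - y[i]))
  }
  boundary_curve(xs, ys, h, validate = FALSE)
}

# deviation of a curve from mirror symmetry about y = 0: for every point,
# distance to the nearest point of the reflected set
symmetry_error <- function(curve) {
  refl <- curve
  refl$y <- -refl$y
  point_set_distance(curve, refl)
}

# independent pixel flood fill of a thresholded node field, rasterized at
# resolution `px` (used as the oracle for mesh-based component counting)
raster_components <- function(curve, mesh, member, px) {
  p <- cbind(curve$x, curve$y)
  xs <- seq(min(p[, 1]) - px, max(p[, 1]) + px, by = px)
  ys <- seq(min(p[, 2]) - px, max(p[, 2]) + px, by = px)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  inside <- protrusim:::cpp_point_in_poly(pts, p[, 1], p[, 2])
  on <- matrix(FALSE, length(xs), length(ys))
  idx <- which(inside)
  for (k in idx) {
    i <- ((k - 1) %% length(xs)) + 1
    j <- ((k - 1) %/% length(xs)) + 1
    d2 <- (mesh$nodes[, 1] - xs[i])^2 + (mesh$nodes[, 2] - ys[j])^2
    nn <- which.min(d2)
    if (d2[nn] < (2 * mesh$h_mesh)^2 && member[nn]) on[i, j] <- TRUE
  }
  lab <- matrix(0L, nrow(on), ncol(on))
  comp <- 0L
  for (s in which(on)) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (lab[v] != 0L || !on[v]) next
      lab[v] <- comp
      i <- ((v - 1) %% nrow(on)) + 1; j <- ((v - 1) %/% nrow(on)) + 1
      nb <- c(if (i > 1) v - 1, if (i < nrow(on)) v + 1,
              if (j > 1) v - nrow(on), if (j < ncol(on)) v + nrow(on))
      queue <- c(queue, nb[lab[nb] == 0L & on[nb]])
    }
  }
  comp
}
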