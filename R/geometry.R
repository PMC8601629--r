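#' Closed boundary curve of a cell cluster
#'
#' Construct a `boundary_curve`: a closed, simple, counterclockwise polygon of
#' marker points tracking the cluster outline. Coordinates are in rescaled
#' length units (lengths divided by the decay length `sqrt(D/gamma)` of the
#' reference chemical), the unit system used throughout the package.
#'
#' @param x,y numeric vectors of vertex coordinates (the closing edge from the
#'   last to the first vertex is implicit; do not repeat the first point).
#' @param h target marker spacing used when the curve is resampled.
#' @param validate check closedness, simplicity and orientation.
#' @return An object of class `boundary_curve`: a list with elements `x`, `y`,
#'   `h`.
#' @seealso [parabolic_cluster()], [elliptical_cluster()],
#'   [resample_boundary()], [apply_cut()]
#' @export
boundary_curve <- function(x, y, h = 0.05, validate = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 3, h > 0)
  if (validate) {
    if (!cpp_poly_simple(as.numeric(x), as.numeric(y)))
      stop("boundary curve is self-intersecting")
    a <- shoelace_area(x, y)
    if (a <= 0)
      stop("boundary curve must be counterclockwise (signed area > 0), got area ",
           signif(a, 6))
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), h = h),
            class = "boundary_curve")
}

# vertex matrix (n x 2) of a curve or anything coercible
bc_pts <- function(curve) {
  if (inherits(curve, "boundary_curve")) cbind(curve$x, curve$y)
  else if (is.matrix(curve)) curve
  else stop("expected a boundary_curve or an n x 2 matrix")
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  0.5 * sum(x * y[j] - x[j] * y)
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf("<boundary_curve> %d points, area %.4f, perimeter %.4f, h = %g\n",
              length(x$x), polygon_area(x), arc_lengths(x)$total, x$h))
  invisible(x)
}

#' @export
plot.boundary_curve <- function(x, ..., add = FALSE, asp = 1) {
  if (!add) plot(c(x$x, x$x[1]), c(x$y, x$y[1]), type = "l", asp = asp,
                 xlab = "x", ylab = "y", ...)
  else lines(c(x$x, x$x[1]), c(x$y, x$y[1]), ...)
  invisible(x)
}

# cumulative and total arc length of the closed polygon
arc_lengths <- function(curve) {
  p <- bc_pts(curve)
  n <- nrow(p)
  seg <- sqrt(rowSums((p[c(2:n, 1), , drop = FALSE] - p)^2))
  list(seg = seg, cum = c(0, cumsum(seg))[1:n], total = sum(seg))
}

#' Initial parabolic cell cluster
#'
#' Builds the standard initial condition: a rightward-pointing parabolic
#' cluster of length `x0` and maximal width `y0`, bounding the region
#' `0 <= x <= x0`, `|y| <= (y0/2) * sqrt((x0 - x)/x0)`. The tip (apex) is at
#' `(x0, 0)` and the flat vertical back end at `x = 0`. The curve is symmetric
#' about `y = 0` and oriented counterclockwise, starting at the tip.
#'
#' @param x0 cluster length (rescaled units), > 0.
#' @param y0 cluster width at the back end, > 0.
#' @param h target marker spacing.
#' @return A [boundary_curve()]. Its area converges to `(2/3) * x0 * y0` as
#'   `h -> 0`.
#' @examples
#' cl <- parabolic_cluster(1.5, 1)
#' polygon_area(cl)   # ~ 1.0
#' @export
parabolic_cluster <- function(x0, y0, h = 0.05) {
  if (x0 <= 0 || y0 <= 0 || h <= 0)
    stop("x0, y0 and h must all be positive")
  # parameterize branches by y (the tangent is vertical at the tip)
  m <- max(40, ceiling(4 * (x0 + y0) / h))
  yy <- seq(0, y0 / 2, length.out = m)
  xx <- x0 * (1 - (2 * yy / y0)^2)
  up <- cbind(xx, yy)                        # tip -> back-top
  nb <- max(2, ceiling(4 * y0 / h))
  back <- cbind(0, seq(y0 / 2, -y0 / 2, length.out = nb + 2)[-1]) # down back
  lo <- cbind(rev(xx), -rev(yy))[-1, , drop = FALSE]              # back-bottom -> tip
  lo <- lo[-nrow(lo), , drop = FALSE]
  p <- rbind(up, back, lo)
  resample_boundary(boundary_curve(p[, 1], p[, 2], h, validate = FALSE), h)
}

#' Initial elliptical cell cluster
#'
#' Ellipse with semi-axes `x0/2` and `y0/2`, centered at `(x0/2, 0)` so that
#' the tip sits at `(x0, 0)`, matching the parabolic-cluster convention.
#'
#' @inheritParams parabolic_cluster
#' @return A [boundary_curve()] of area converging to `pi * x0 * y0 / 4`.
#' @export
elliptical_cluster <- function(x0, y0, h = 0.05) {
  if (x0 <= 0 || y0 <= 0 || h <= 0)
    stop("x0, y0 and h must all be positive")
  a <- x0 / 2; b <- y0 / 2
  m <- max(64, ceiling(8 * pi * max(a, b) / h))
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  resample_boundary(
    boundary_curve(x0 / 2 + a * cos(th), b * sin(th), h, validate = FALSE), h)
}

#' Signed polygon area (shoelace formula)
#'
#' Positive for counterclockwise orientation (the package convention);
#' a negative value signals a reversed (clockwise) curve.
#'
#' @param curve a [boundary_curve()] or an n x 2 coordinate matrix.
#' @return signed area in rescaled area units.
#' @export
polygon_area <- function(curve) {
  p <- bc_pts(curve)
  shoelace_area(p[, 1], p[, 2])
}

#' Outward unit normals along a boundary curve
#'
#' One unit vector per marker point, pointing away from the cluster interior,
#' computed from the central-difference tangent (adjacent-segment average).
#'
#' @param curve a [boundary_curve()].
#' @return n x 2 matrix of unit normals.
#' @export
outward_normals <- function(curve) {
  p <- bc_pts(curve)
  n <- nrow(p)
  seg <- sqrt(rowSums((p[c(2:n, 1), , drop = FALSE] - p)^2))
  if (any(seg < 1e-12)) stop("degenerate (repeated) boundary points")
  tp <- p[c(2:n, 1), , drop = FALSE] - p[c(n, 1:(n - 1)), , drop = FALSE]
  len <- sqrt(rowSums(tp^2))
  tp <- tp / len
  cbind(tp[, 2], -tp[, 1])   # CCW curve: outward normal = tangent rotated -90deg
}

# signed curvature at each marker (three-point circumcircle); positive where
# the CCW curve bends like a convex arc
boundary_curvature <- function(curve) {
  p <- bc_pts(curve)
  n <- nrow(p)
  pm <- p[c(n, 1:(n - 1)), , drop = FALSE]
  pp <- p[c(2:n, 1), , drop = FALSE]
  a <- p - pm; b <- pp - p; cc <- pp - pm
  cr <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  den <- sqrt(rowSums(a^2) * rowSums(b^2) * rowSums(cc^2))
  k <- 2 * cr / pmax(den, 1e-300)
  k[den < 1e-30] <- 0
  k
}

#' Resample a boundary curve at uniform arc-length spacing
#'
#' Redistributes the marker points at (approximately) equal arc length `h`
#' along a periodic cubic spline through the current points. The first point
#' is kept anchored, which preserves the symmetry of axis-symmetric curves.
#' Total arc length and shape are preserved to within the spline tolerance.
#'
#' @param curve a [boundary_curve()].
#' @param h target spacing (defaults to the curve's stored `h`).
#' @return A resampled [boundary_curve()].
#' @export
resample_boundary <- function(curve, h = NULL) {
  if (is.null(h)) h <- curve$h
  p <- bc_pts(curve)
  n <- nrow(p)
  al <- arc_lengths(curve)
  if (h >= al$total / 4)
    stop("spacing h is too large for this curve (fewer than 4 points would remain)")
  tt <- c(al$cum, al$total)
  xs <- c(p[, 1], p[1, 1]); ys <- c(p[, 2], p[1, 2])
  m <- max(256, 8L * n)
  td <- seq(0, al$total, length.out = m + 1)
  dx <- stats::spline(tt, xs, method = "periodic", xout = td)$y
  dy <- stats::spline(tt, ys, method = "periodic", xout = td)$y
  # arc-length reparameterization on the dense sampling
  dseg <- sqrt(diff(dx)^2 + diff(dy)^2)
  dcum <- c(0, cumsum(dseg))
  L <- dcum[m + 1]
  nn <- max(8, round(L / h))
  s <- seq(0, L, length.out = nn + 1)[1:nn]
  nx <- stats::approx(dcum, dx, xout = s)$y
  ny <- stats::approx(dcum, dy, xout = s)$y
  boundary_curve(nx, ny, h, validate = FALSE)
}

#' Cut a cluster and keep the bulk side (regeneration experiments)
#'
#' Removes the tip side of the cluster along a cut locus and closes the kept
#' region along the cut: either a straight vertical segment at `x = xc`
#' (leaving a flat end with two sharp corners) or the forward arc of an
#' ellipse (leaving a smooth convex cap bulging toward the removed tip).
#'
#' @param curve a [boundary_curve()].
#' @param cut a list: `list(type = "straight", x = xc)` or
#'   `list(type = "elliptical", center = c(xc, yc), semi_axes = c(a, b))`.
#'   For the elliptical cut the locus is the arc `x >= xc` of the ellipse.
#' @param h resampling spacing for the result (defaults to the curve's `h`).
#' @return A [boundary_curve()] for the retained (bulk-side) region.
#' @export
apply_cut <- function(curve, cut, h = NULL) {
  if (is.null(h)) h <- curve$h
  p <- bc_pts(curve)
  n <- nrow(p)
  type <- match.arg(cut$type, c("straight", "elliptical"))
  hits <- list()   # each: list(edge, t, pt)
  if (type == "straight") {
    xc <- cut$x
    for (i in 1:n) {
      j <- if (i == n) 1L else i + 1L
      x1 <- p[i, 1]; x2 <- p[j, 1]
      # half-open rule so a vertex exactly on the cut line is counted once
      if ((x1 <= xc && x2 > xc) || (x2 <= xc && x1 > xc)) {
        t <- (xc - x1) / (x2 - x1)
        hits[[length(hits) + 1]] <-
          list(edge = i, t = t, pt = c(xc, p[i, 2] + t * (p[j, 2] - p[i, 2])))
      }
    }
  } else {
    ctr <- cut$center; ax <- cut$semi_axes
    stopifnot(length(ctr) == 2, length(ax) == 2, all(ax > 0))
    for (i in 1:n) {
      j <- if (i == n) 1L else i + 1L
      # segment p_i + t d, intersected with ((x-xc)/a)^2 + ((y-yc)/b)^2 = 1
      px <- (p[i, 1] - ctr[1]) / ax[1]; py <- (p[i, 2] - ctr[2]) / ax[2]
      dx <- (p[j, 1] - p[i, 1]) / ax[1]; dy <- (p[j, 2] - p[i, 2]) / ax[2]
      A <- dx^2 + dy^2; B <- 2 * (px * dx + py * dy); C <- px^2 + py^2 - 1
      disc <- B^2 - 4 * A * C
      if (disc <= 0 || A == 0) next
      for (t in sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))) {
        if (t < 0 || t >= 1) next
        pt <- p[i, ] + t * (p[j, ] - p[i, ])
        if (pt[1] >= ctr[1])               # forward arc only
          hits[[length(hits) + 1]] <- list(edge = i, t = t, pt = pt)
      }
    }
  }
  if (length(hits) == 0) stop("cut does not intersect the cluster")
  if (length(hits) != 2)
    stop("cut intersects the boundary in ", length(hits),
         " points (expected 2); it would produce multiple components")
  # order the two hits along the polygon
  key <- vapply(hits, function(hh) hh$edge + hh$t, 0)
  hits <- hits[order(key)]
  h1 <- hits[[1]]; h2 <- hits[[2]]
  idx_between <- if (h1$edge + 1 <= h2$edge) seq(h1$edge + 1, h2$edge) else integer()
  idx_outside <- setdiff(1:n, idx_between)
  # the chain containing the max-x vertex is on the tip side and is removed
  tipv <- which.max(p[, 1])
  if (tipv %in% idx_between) {
    chain <- p[idx_outside[order((idx_outside - h2$edge - 1) %% n)], , drop = FALSE]
    ends <- list(from = h2$pt, to = h1$pt)
  } else {
    chain <- p[idx_between, , drop = FALSE]
    ends <- list(from = h1$pt, to = h2$pt)
  }
  kept <- rbind(ends$from, chain, ends$to)
  # close along the cut locus from ends$to back to ends$from, sampled at ~h
  # so the spline resampler sees an evenly parameterized polygon
  if (type == "straight") {
    seg <- ends$from - ends$to
    ns <- max(2, ceiling(sqrt(sum(seg^2)) / h))
    tt <- seq(0, 1, length.out = ns + 1)[-c(1, ns + 1)]
    kept <- rbind(kept, cbind(ends$to[1] + tt * seg[1], ends$to[2] + tt * seg[2]))
  }
  if (type == "elliptical") {
    ctr <- cut$center; ax <- cut$semi_axes
    th_a <- atan2((ends$to[2] - ctr[2]) / ax[2], (ends$to[1] - ctr[1]) / ax[1])
    th_b <- atan2((ends$from[2] - ctr[2]) / ax[2], (ends$from[1] - ctr[1]) / ax[1])
    # go through theta = 0 (the forward apex of the cap)
    if (th_a < th_b) th_b <- th_b - 2 * pi
    th <- seq(th_a, th_b, length.out = max(8, ceiling(abs(th_a - th_b) * max(ax) / h)))
    arc <- cbind(ctr[1] + ax[1] * cos(th), ctr[2] + ax[2] * sin(th))
    if (max(arc[, 1]) < ctr[1] + 0.99 * ax[1]) {  # wrong way round: flip
      if (th_b < th_a) th_b <- th_b + 2 * pi
      th <- seq(th_a, th_b, length.out = length(th))
      arc <- cbind(ctr[1] + ax[1] * cos(th), ctr[2] + ax[2] * sin(th))
    }
    kept <- rbind(kept, arc[-c(1, nrow(arc)), , drop = FALSE])
  }
  if (shoelace_area(kept[, 1], kept[, 2]) < 0) kept <- kept[nrow(kept):1, ]
  # drop near-duplicate consecutive points before resampling
  dup <- c(FALSE, sqrt(diff(kept[, 1])^2 + diff(kept[, 2])^2) < 1e-10)
  kept <- kept[!dup, , drop = FALSE]
  resample_boundary(boundary_curve(kept[, 1], kept[, 2], h, validate = FALSE), h)
}
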