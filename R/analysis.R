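# area centroid of the polygon (not the vertex mean)
polygon_centroid <- function(curve) {
  p <- bc_pts(curve)
  n <- nrow(p)
  j <- c(2:n, 1)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

# topographic prominence of each strict local maximum of a cyclic signal
cyclic_peak_prominence <- function(r) {
  n <- length(r)
  left <- c(n, 1:(n - 1)); right <- c(2:n, 1)
  peaks <- which(r > r[left] & r > r[right])
  if (!length(peaks)) return(data.frame(index = integer(), prominence = numeric()))
  prom <- vapply(peaks, function(pk) {
    saddle <- function(step) {
      i <- pk; lo <- Inf
      for (it in 1:n) {
        i <- if (step > 0) right[i] else left[i]
        if (r[i] > r[pk]) return(lo)
        lo <- min(lo, r[i])
        if (i == pk) return(lo)       # wrapped: this is the global maximum
      }
      lo
    }
    r[pk] - max(saddle(1), saddle(-1))
  }, 0)
  data.frame(index = peaks, prominence = prom)
}

#' Count protrusions of a cluster boundary
#'
#' Operationalizes the visual protrusion count: the radial distance from the
#' cluster (area) centroid to each boundary marker is treated as a cyclic
#' signal, and protrusions are its local maxima with topographic prominence
#' above a threshold. A circle has a constant signal and zero protrusions;
#' small boundary ripples are filtered out by the prominence threshold.
#'
#' @param curve a [boundary_curve()].
#' @param prominence minimum topographic prominence (rescaled length) for a
#'   maximum to count as a protrusion tip. The simulation default is half
#'   the initial cluster width.
#' @param xmin only count tips with `x >= xmin`. Runs with the front-half
#'   growth mask use `xmin = x0/2`: the static back end of the cluster keeps
#'   its corners, which are geometric features of the non-growing region,
#'   not protrusions.
#' @return list with `count`, and `tips`: a data frame with one row per
#'   protrusion (marker `index`, tip coordinates `x`, `y`, centroid distance
#'   `height`, `prominence`, axis direction `ax`, `ay` from centroid to tip,
#'   and `length` = height minus the deeper adjacent saddle).
#' @export
count_protrusions <- function(curve, prominence = 0.5, xmin = -Inf) {
  stopifnot(prominence > 0)
  p <- bc_pts(curve)
  if (nrow(p) < 8) stop("degenerate curve")
  ctr <- polygon_centroid(curve)
  r <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
  pk <- cyclic_peak_prominence(r)
  pk <- pk[pk$prominence > prominence & p[pk$index, 1] >= xmin, , drop = FALSE]
  tips <- data.frame(index = pk$index,
                     x = p[pk$index, 1], y = p[pk$index, 2],
                     height = r[pk$index], prominence = pk$prominence)
  if (nrow(tips)) {
    ax <- cbind(tips$x - ctr[1], tips$y - ctr[2]) / tips$height
    tips$ax <- ax[, 1]; tips$ay <- ax[, 2]
    tips$length <- tips$prominence
  } else {
    tips$ax <- tips$ay <- tips$length <- numeric(0)
  }
  list(count = nrow(tips), tips = tips, centroid = ctr)
}

#' Width profile of a protrusion
#'
#' Measures the cluster cross-section perpendicular to a protrusion axis at
#' given distances behind the tip. At each station the cutting line is
#' intersected with the boundary and the width is the extent of the
#' cross-section interval containing the axis point (other protrusions
#' crossed by the same line are ignored).
#'
#' @param curve a [boundary_curve()].
#' @param tip length-2 tip point (on or near the boundary).
#' @param axis length-2 direction of the protrusion (base to tip); defaults
#'   to the direction from the cluster centroid to `tip`.
#' @param stations distances behind the tip at which to measure.
#' @return data frame with `station` and `width` (NA where the station
#'   leaves the cluster).
#' @export
width_profile <- function(curve, tip, axis = NULL,
                          stations = seq(0.1, 0.5, by = 0.1)) {
  p <- bc_pts(curve)
  if (is.null(axis)) axis <- tip - polygon_centroid(curve)
  nr <- sqrt(sum(axis^2))
  if (nr < 1e-12) stop("axis direction is degenerate")
  axis <- axis / nr
  m <- c(-axis[2], axis[1])
  w <- vapply(stations, function(s) {
    q <- tip - s * axis
    a <- (p[, 1] - q[1]) * axis[1] + (p[, 2] - q[2]) * axis[2]
    b <- (p[, 1] - q[1]) * m[1] + (p[, 2] - q[2]) * m[2]
    n <- length(a)
    j <- c(2:n, 1)
    aj <- a[j]
    cross <- which((a <= 0 & aj > 0) | (aj <= 0 & a > 0))
    if (length(cross) < 2) return(NA_real_)
    u <- sort(b[cross] + (b[j][cross] - b[cross]) * (-a[cross]) / (a[j][cross] - a[cross]))
    if (length(u) %% 2 == 1) return(NA_real_)
    lo <- u[seq(1, length(u), by = 2)]; hi <- u[seq(2, length(u), by = 2)]
    k <- which(lo <= 0 & hi >= 0)
    if (!length(k)) return(NA_real_)
    hi[k[1]] - lo[k[1]]
  }, 0)
  data.frame(station = stations, width = w)
}

#' Classify the final morphology of a growth trajectory
#'
#' Decision rule: `multi` if the final protrusion count is at least 2;
#' otherwise `cone` if the tip width shrinks over the last half of the run
#' and the growth zone has (nearly) vanished; otherwise `rod` if the late
#' tip width is stable (coefficient of variation < 10%); otherwise `round`.
#'
#' @param trajectory a `growth_trajectory` from [run_growth()].
#' @return one of `"multi"`, `"cone"`, `"rod"`, `"round"`.
#' @export
classify_shape <- function(trajectory) {
  m <- trajectory$metrics
  if (nrow(m) < 3) stop("trajectory too short to classify (need >= 3 records)")
  final <- m[nrow(m), ]
  if (final$protrusions >= 2) return("multi")
  late <- m[m$t >= max(m$t) / 2, ]
  w <- late$tip_width[!is.na(late$tip_width)]
  h2 <- trajectory$config$h_mesh^2
  if (length(w) >= 3) {
    shrinking <- mean(diff(w) <= 0) >= 0.8 && w[length(w)] < 0.9 * w[1]
    if (shrinking && final$a_gz < 4 * h2) return("cone")
    if (stats::sd(w) / mean(w) < 0.10 && final$protrusions >= 1) return("rod")
  }
  "round"
}

#' Growth-zone statistics
#'
#' Thresholds the per-node growth field at 1/2 (the midpoint of the
#' near-step Hill output, so the result is insensitive to the exact value)
#' and reports the growth-zone area, its number of connected components
#' (grid 4-adjacency of the mesh) and its area centroid.
#'
#' @param mesh an [interior_mesh()].
#' @param g per-node growth rates.
#' @return list with `area`, `components`, `centroid` (NA when empty) and
#'   the per-node component `labels` (0 outside the zone).
#' @export
growth_zone_stats <- function(mesh, g) {
  stopifnot(length(g) == nrow(mesh$nodes))
  member <- g > 0.5
  lab <- mesh_components(mesh, member)
  area <- sum(mesh$weights[member])
  ctr <- if (any(member))
    colSums(mesh$nodes[member, , drop = FALSE] * mesh$weights[member]) / area
  else c(NA_real_, NA_real_)
  list(area = area, components = max(lab, 0L), centroid = ctr, labels = lab)
}
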