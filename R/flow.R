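#' Boundary normal velocity of the growing cluster
#'
#' Solves the incompressible-growth flow problem: the cluster is a Darcy
#' fluid with velocity `u = -grad(P)` and `div(u) = g`, so the pressure
#' satisfies `laplacian(P) = -g` in the cluster with `P = 0` on the boundary;
#' the boundary advances with the outward normal speed `u_n = -dP/dn`.
#'
#' The solve uses a boundary-integral method. The particular solution is the
#' Newtonian potential of the growth field over the mesh nodes,
#' `P_p(x) = -sum_j w_j g_j log|x - x_j| / (2*pi)`, and a single-layer
#' harmonic correction enforces `P = 0` on the boundary: its density solves
#' Symm's first-kind equation `S[sigma] = -P_p`, collocated at the boundary
#' markers (midpoint panels, analytic self-integral of the log kernel). By
#' Green's second identity this representation vanishes identically outside
#' the cluster, so the layer density is itself the boundary flux:
#' `u_n = sigma`, and its total is fixed by the divergence theorem,
#' `contour-integral sigma ds = integral g dA`. That total is imposed as an
#' augmentation row (with a free additive constant), which keeps the
#' first-kind system solvable even when the contour's logarithmic capacity
#' equals 1 (e.g. a unit disk) and makes the discrete mass balance exact by
#' construction.
#'
#' Growth-only dynamics give `u_n >= 0` up to solver noise.
#'
#' @param curve a [boundary_curve()].
#' @param mesh an [interior_mesh()] of the same cluster.
#' @param g per-node growth rates in `[0, 1]`.
#' @return numeric vector of outward normal speeds, one per boundary marker
#'   (units: rescaled length per unit of the maximal growth rate).
#' @export
solve_boundary_velocity <- function(curve, mesh, g) {
  stopifnot(inherits(mesh, "interior_mesh"))
  if (length(g) != nrow(mesh$nodes))
    stop("g must have one value per mesh node")
  p <- bc_pts(curve)
  n <- nrow(p)
  strength <- mesh$weights * g
  if (sum(strength) < 1e-300) return(rep(0, n))
  al <- arc_lengths(curve)
  seg <- al$seg
  L <- (seg + seg[c(n, 1:(n - 1))]) / 2        # panel length at each marker

  dx <- outer(p[, 1], p[, 1], "-")
  dy <- outer(p[, 2], p[, 2], "-")
  d2 <- dx^2 + dy^2
  diag(d2) <- 1
  A <- (0.25 * log(d2) / pi) * rep(L, each = n)  # log(d)/(2pi) * L_j
  # near-diagonal panels: exact integral of the log kernel over the actual
  # polygon panel of marker j (the two half-chords meeting at p_j); the
  # midpoint rule is the accuracy bottleneck there
  mid_prev <- (p + p[c(n, 1:(n - 1)), , drop = FALSE]) / 2
  mid_next <- (p + p[c(2:n, 1), , drop = FALSE]) / 2
  seg_log_int <- function(x, a, b) {
    # integral of log|x - y| over the segment a -> b, rows vectorized
    d <- b - a
    len <- sqrt(rowSums(d^2))
    t1 <- d / len
    rel <- x - a
    ap <- rowSums(rel * t1)
    b2 <- pmax(rowSums(rel^2) - ap^2, 0)
    bb <- sqrt(b2)
    Fi <- function(s) {
      u <- s - ap
      v <- 0.5 * u * log(pmax(u * u + b2, 1e-300)) - u
      v + ifelse(bb > 1e-14, bb * atan(u / bb), 0)
    }
    Fi(len) - Fi(0)
  }
  for (o in -3:3) {
    j <- ((seq_len(n) - 1 + o) %% n) + 1
    A[cbind(seq_len(n), j)] <-
      (seg_log_int(p, mid_prev[j, , drop = FALSE], p[j, , drop = FALSE]) +
       seg_log_int(p, p[j, , drop = FALSE], mid_next[j, , drop = FALSE])) / (2 * pi)
  }
  rhs <- cpp_log_sum(p, mesh$nodes, strength)    # = -P_p on the boundary
  M <- rbind(cbind(A, 1), c(L, 0))
  sol <- solve(M, c(rhs, sum(strength)))
  u <- sol[1:n]
  # first-kind systems amplify grid-scale quadrature noise in the rhs into a
  # high-frequency ripple of the density; one pass of a (1/4, 1/2, 1/4)
  # filter removes it (bias O(h^2 u'')), renormalized to keep the flux total
  # (the discrete divergence theorem) exact
  u <- 0.25 * u[c(n, 1:(n - 1))] + 0.5 * u + 0.25 * u[c(2:n, 1)]
  tot <- sum(u * L)
  if (abs(tot) > 1e-300) u <- u * (sum(strength) / tot)
  u
}

#' Outward velocity vectors along the boundary
#'
#' Scales the outward unit normals by the normal speeds, giving the advection
#' (or arrow-plot) vectors of the boundary markers.
#'
#' @param curve a [boundary_curve()].
#' @param u_n per-marker normal speeds, as from [solve_boundary_velocity()].
#' @return n x 2 matrix of velocity vectors.
#' @export
velocity_arrows <- function(curve, u_n) {
  p <- bc_pts(curve)
  if (length(u_n) != nrow(p))
    stop("u_n must have one value per boundary point")
  outward_normals(curve) * u_n
}
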