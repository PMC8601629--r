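#' Free-space Green's function of the steady reaction-diffusion operator
#'
#' The 2D free-space Green's function of `(laplacian - gamma_r)`:
#' `G(r) = K0(sqrt(gamma_r) * r) / (2*pi)`, with `K0` the modified Bessel
#' function of the second kind. It decays exponentially (the far-field
#' condition that concentrations vanish away from the cluster) and carries
#' total mass `integral G(r) 2 pi r dr = 1/gamma_r`. Singular
#' (logarithmically) at `r = 0`; the quadrature handles the self term
#' analytically, see [solve_concentration()].
#'
#' @param r distance(s), >= 0 (rescaled length units).
#' @param gamma_r rescaled degradation ratio, > 0.
#' @return kernel value(s); `Inf` at `r = 0`.
#' @export
greens_kernel <- function(r, gamma_r = 1) {
  if (any(r < 0)) stop("negative distance")
  stopifnot(gamma_r > 0)
  out <- rep(Inf, length(r))
  pos <- r > 0
  out[pos] <- besselK(sqrt(gamma_r) * r[pos], 0) / (2 * pi)
  out
}

#' Steady-state concentration field of one chemical
#'
#' Solves `laplacian(c) + mu(x) - gamma_r * c = 0` on the unbounded plane
#' with the source `mu` supported on the cluster interior and `c -> 0` at
#' infinity, by Green's-function quadrature over the interior mesh:
#' `c(x) = sum_j w_j mu_j G(|x - x_j|)`. The singular self term is replaced
#' by the analytic mean of the kernel over a disk of the element's area
#' (`integral_disk G dA = (1 - k R K1(k R)) / gamma_r`, `k = sqrt(gamma_r)`,
#' `R = sqrt(w_j / pi)`), which preserves the convergence order of the
#' midpoint rule.
#'
#' @param mesh an [interior_mesh()].
#' @param source per-node secretion rates `mu`, >= 0.
#' @param gamma_r rescaled degradation ratio.
#' @param points optional m x 2 matrix of evaluation points; by default the
#'   field is evaluated at the mesh nodes (with the self-term correction).
#' @return per-point concentrations (all >= 0).
#' @export
solve_concentration <- function(mesh, source, gamma_r = 1, points = NULL) {
  stopifnot(inherits(mesh, "interior_mesh"), gamma_r > 0)
  if (length(source) != nrow(mesh$nodes))
    stop("source must have one value per mesh node")
  if (any(source < 0)) stop("negative source")
  k <- sqrt(gamma_r)
  strength <- mesh$weights * source
  if (is.null(points)) {
    cc <- cpp_k0_sum(mesh$nodes, mesh$nodes, strength, k)
    R <- sqrt(mesh$weights / pi)
    cc + source * (1 - k * R * besselK(k * R, 1)) / gamma_r
  } else {
    cpp_k0_sum(bc_pts(points), mesh$nodes, strength, k)
  }
}

# gradient magnitude of a node field via grid-neighbor differences
node_grad_mag <- function(mesh, c) {
  ng <- mesh$node_grid
  h <- mesh$h_mesh
  n <- nrow(mesh$ij)
  gx <- gy <- numeric(n)
  for (k in seq_len(n)) {
    i <- mesh$ij[k, 1]; j <- mesh$ij[k, 2]
    xr <- if (i < mesh$nx) ng[i + 1, j] else NA
    xl <- if (i > 1) ng[i - 1, j] else NA
    gx[k] <- if (!is.na(xr) && !is.na(xl)) (c[xr] - c[xl]) / (2 * h)
             else if (!is.na(xr)) (c[xr] - c[k]) / h
             else if (!is.na(xl)) (c[k] - c[xl]) / h else 0
    yu <- if (j < mesh$ny) ng[i, j + 1] else NA
    yd <- if (j > 1) ng[i, j - 1] else NA
    gy[k] <- if (!is.na(yu) && !is.na(yd)) (c[yu] - c[yd]) / (2 * h)
             else if (!is.na(yu)) (c[yu] - c[k]) / h
             else if (!is.na(yd)) (c[k] - c[yd]) / h else 0
  }
  sqrt(gx^2 + gy^2)
}

# sub-cell fraction of each node's cell where the field is below (lower =
# TRUE) or above the threshold K, assuming a locally linear field: a linear
# ramp of width |grad c| * h around the threshold crossing. Far from the
# interface this reduces to the 0/1 indicator; at the interface it removes
# the O(h) staircase bias of node-wise thresholding.
interface_fraction <- function(mesh, c, K, lower = TRUE) {
  gm <- node_grad_mag(mesh, c)
  f <- pmin(1, pmax(0, 0.5 + (K - c) / pmax(gm * mesh$h_mesh, 1e-12)))
  if (lower) f else 1 - f
}

# threshold gates for secretion links of one chemical, anti-aliased at the
# sub-cell level in the near-step regime (|n| >= 50), plain Hill otherwise
secretion_gates <- function(ch, values, mesh) {
  gate <- rep(1, nrow(values))
  for (sl in ch$secretion_links) {
    creg <- values[, sl$regulator]
    gate <- gate * if (abs(sl$n) >= 50)
      interface_fraction(mesh, creg, sl$Ks, lower = sl$n < 0)
    else hill(creg, sl$Ks, sl$n)
  }
  gate
}

#' Solve all concentration fields of a circuit
#'
#' Chemicals are solved in topological order of the secretion-dependency
#' graph: each chemical's per-node source is its [secretion_rate()] evaluated
#' on the already-computed fields, then its field is obtained with
#' [solve_concentration()]. For the two-chemical schemes this reduces to:
#' solve `c_X` with constant source; set the `Y` source node-wise from `c_X`;
#' solve `c_Y` with its degradation ratio.
#'
#' Secretion sources are evaluated with sub-cell resolution of the
#' threshold (near-step Hill) gates: each node's cell is weighted by the
#' estimated fraction of the cell on the secreting side of the interface
#' (a linear reconstruction from grid-neighbor gradients). This removes the
#' O(h) staircase bias of node-wise thresholding, which matters in the
#' threshold-marginal regimes where growth-zone morphology is decided.
#'
#' @param circuit a [circuit()].
#' @param mesh an [interior_mesh()].
#' @param source_mask optional per-node factors in `[0, 1]` applied to the
#'   sources of *regulated* chemicals (those with secretion links);
#'   constitutively secreted chemicals are never masked. Simulations with
#'   the front-half growth mask pass it here too: the static back end keeps
#'   its baseline (constitutive) secretion but does not switch on regulated
#'   programs, so downstream signals are produced only in the active front
#'   region — in particular this suppresses the spurious secretion slivers
#'   at the sharp back corners of the idealized initial cluster, where the
#'   upstream concentration dips below threshold for purely geometric
#'   reasons.
#' @return object of class `concentration_fields`: list with `values` and
#'   `sources` (node x chemical matrices), `mesh` and `circuit`. Use
#'   [eval_fields()] to evaluate at arbitrary points.
#' @export
solve_circuit_fields <- function(circuit, mesh, source_mask = NULL) {
  nm <- names(circuit$chemicals)
  m <- nrow(mesh$nodes)
  values <- sources <- matrix(0, m, length(nm), dimnames = list(NULL, nm))
  for (name in circuit$topo_order) {
    ch <- circuit$chemicals[[name]]
    mu <- rep(ch$mu0, m)
    if (!is.null(ch$secretion_max))
      mu <- mu * pmax(1 + ch$secretion_max$b * values[, ch$secretion_max$regulator], 0)
    mu <- mu * secretion_gates(ch, values, mesh)
    if (!is.null(source_mask) && length(ch$secretion_links) > 0)
      mu <- mu * source_mask
    sources[, name] <- mu
    values[, name] <- solve_concentration(mesh, mu, ch$gamma_r)
  }
  structure(list(values = values, sources = sources, mesh = mesh,
                 circuit = circuit),
            class = "concentration_fields")
}

# growth field over mesh nodes with the same sub-cell anti-aliasing as the
# secretion gates; reduces to growth_rate() at nodes away from interfaces
growth_field <- function(circuit, fields, mesh) {
  g <- rep(1, nrow(mesh$nodes))
  for (gl in circuit$growth_links) {
    red <- rep(0, nrow(mesh$nodes))
    for (mm in gl$modifiers) red <- red + mm$a * fields$values[, mm$chemical]
    Keff <- gl$Kg * pmax(1 - red, 0)
    creg <- fields$values[, gl$regulator]
    g <- g * if (abs(gl$n) >= 50)
      interface_fraction(mesh, creg - Keff, 0, lower = gl$n < 0)
    else hill(creg, Keff, gl$n)
  }
  g
}

#' Evaluate circuit fields at arbitrary points
#'
#' Uses the same kernel sums as [solve_circuit_fields()] with the stored
#' per-node source strengths (no re-solve), e.g. to read concentrations on
#' the cluster boundary.
#'
#' @param fields a `concentration_fields` object.
#' @param points m x 2 matrix (or [boundary_curve()]).
#' @return m x chemical matrix of concentrations.
#' @export
eval_fields <- function(fields, points) {
  p <- bc_pts(points)
  nm <- colnames(fields$values)
  out <- matrix(0, nrow(p), length(nm), dimnames = list(NULL, nm))
  for (name in nm)
    out[, name] <- solve_concentration(fields$mesh, fields$sources[, name],
                                       fields$circuit$chemicals[[name]]$gamma_r,
                                       points = p)
  out
}

#' Export concentration fields as CSV
#'
#' One row per mesh node: coordinates `x`, `y`, the quadrature weight, and
#' one column per chemical with the node concentration.
#'
#' @param fields a `concentration_fields` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fields_csv <- function(fields, path) {
  df <- data.frame(x = fields$mesh$nodes[, 1], y = fields$mesh$nodes[, 2],
                   weight = fields$mesh$weights)
  for (nm in colnames(fields$values)) df[[nm]] <- fields$values[, nm]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.concentration_fields <- function(x, ...) {
  rng <- apply(x$values, 2, range)
  cat(sprintf("<concentration_fields> %d nodes, %d chemical(s)\n",
              nrow(x$values), ncol(x$values)))
  for (nm in colnames(x$values))
    cat(sprintf("  %s: range [%.4g, %.4g]\n", nm, rng[1, nm], rng[2, nm]))
  invisible(x)
}
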