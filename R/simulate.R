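#' Simulation configuration
#'
#' Assembles and validates the full configuration of a growth run: the
#' regulatory scheme and its parameters, the initial cluster, discretization
#' controls and stop conditions. All defaults are resolved here, so the
#' returned object is a complete provenance record of the run.
#'
#' @param scheme name of a regulatory scheme, see [named_scheme()].
#' @param params named list of scheme parameters.
#' @param shape initial cluster: `"parabolic"`, `"elliptical"`, or
#'   `"custom"` (then supply `custom_points`, an n x 2 CCW matrix).
#' @param x0,y0 initial cluster length and width (rescaled units).
#' @param h boundary marker spacing; the boundary is resampled to `h` every
#'   step.
#' @param h_mesh interior quadrature cell size.
#' @param alpha CFL factor in `(0, 1]`: `dt = alpha * h / max(u_n)`.
#' @param t_max total rescaled simulation time (units of the inverse maximal
#'   growth rate).
#' @param mask growth mask: `"front_half"` zeroes growth behind the fixed
#'   lab-frame plane `x = x0/2` (growth is studied at the cluster front);
#'   `"none"` applies no mask.
#' @param snapshot_every store a boundary snapshot every this many steps
#'   (the initial and final boundaries are always stored).
#' @param stop_gz_vanish stop when the growth-zone area drops below
#'   `h_mesh^2` (an autonomously terminating protrusion).
#' @param stop_stable_protrusions stop once the protrusion count has been
#'   constant for the trailing `stable_frac` fraction of elapsed time (and
#'   `t >= min_stop_time`).
#' @param stable_frac,min_stop_time stability-stop controls.
#' @param prominence protrusion-detection prominence threshold; default half
#'   the initial width `y0/2`.
#' @param width_station distance behind the leading tip at which the tip
#'   width metric is measured.
#' @param cut optional cut specification for regeneration runs, applied to
#'   the precursor's final boundary: `list(type = "straight", at =
#'   "mid_protrusion")` (or `at = <x>`), or `list(type = "elliptical", at =,
#'   semi_axes = c(a, b))`.
#' @param precursor optional `sim_config` run first to produce the cluster
#'   that is then cut and regrown.
#' @param custom_points initial boundary for `shape = "custom"`.
#' @param name optional scenario label.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(scheme = "none", params = list(),
                       shape = c("parabolic", "elliptical", "custom"),
                       x0 = 1.5, y0 = 1, h = 0.05, h_mesh = 0.05,
                       alpha = 0.3, t_max = 10,
                       mask = c("front_half", "none"),
                       snapshot_every = 10,
                       stop_gz_vanish = FALSE,
                       stop_stable_protrusions = FALSE,
                       stable_frac = 0.2, min_stop_time = 3,
                       prominence = y0 / 2, width_station = 0.25,
                       cut = NULL, precursor = NULL, custom_points = NULL,
                       name = NULL) {
  shape <- match.arg(shape)
  mask <- match.arg(mask)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (t_max <= 0) stop("t_max must be positive")
  if (h <= 0 || h_mesh <= 0) stop("h and h_mesh must be positive")
  if (x0 <= 0 || y0 <= 0) stop("x0 and y0 must be positive")
  if (shape == "custom" && is.null(custom_points) && is.null(precursor))
    stop("shape = 'custom' requires custom_points")
  if (!is.null(cut) && is.null(precursor))
    stop("a cut requires a precursor run")
  circ <- do.call(named_scheme, c(list(name = scheme), params))
  structure(list(scheme = scheme, params = params, shape = shape,
                 x0 = x0, y0 = y0, h = h, h_mesh = h_mesh, alpha = alpha,
                 t_max = t_max, mask = mask, snapshot_every = snapshot_every,
                 stop_gz_vanish = stop_gz_vanish,
                 stop_stable_protrusions = stop_stable_protrusions,
                 stable_frac = stable_frac, min_stop_time = min_stop_time,
                 prominence = prominence, width_station = width_station,
                 cut = cut, precursor = precursor,
                 custom_points = custom_points, name = name,
                 circuit = circ),
            class = "sim_config")
}

#' Growth mask over mesh nodes
#'
#' The protrusion studies only follow growth at the cluster front:
#' `"front_half"` zeroes the growth rate at nodes behind the fixed lab-frame
#' plane through the initial cluster midpoint (`x < x0/2`), for all times.
#' `"none"` leaves the growth field untouched.
#'
#' @param mesh an [interior_mesh()].
#' @param config a [sim_config()] (uses its `mask` mode and `x0`).
#' @return per-node factors in `{0, 1}`.
#' @export
growth_mask <- function(mesh, config) {
  if (config$mask == "none") rep(1, nrow(mesh$nodes))
  else as.numeric(mesh$nodes[, 1] >= config$x0 / 2)
}

# build the initial boundary of a run (precursor + cut handled in run_growth)
initial_curve <- function(config) {
  switch(config$shape,
    parabolic = parabolic_cluster(config$x0, config$y0, config$h),
    elliptical = elliptical_cluster(config$x0, config$y0, config$h),
    custom = resample_boundary(
      boundary_curve(config$custom_points[, 1], config$custom_points[, 2],
                     config$h), config$h))
}

# resolve a cut specification against the curve it is applied to
resolve_cut <- function(cut, curve, x0) {
  at <- cut$at
  xc <- if (identical(at, "mid_protrusion")) (x0 + max(curve$x)) / 2
        else as.numeric(at)
  if (cut$type == "straight") list(type = "straight", x = xc)
  else list(type = "elliptical", center = c(xc, 0),
            semi_axes = if (!is.null(cut$semi_axes)) cut$semi_axes else c(0.3, 0.6))
}

# evaluate the quasi-static problem on the current boundary: mesh, fields,
# growth field, normal velocity, and all per-step metrics
eval_state <- function(curve, config) {
  mesh <- interior_mesh(curve, config$h_mesh)
  circ <- config$circuit
  q <- length(circ$chemicals)
  if (q > 0) {
    fields <- solve_circuit_fields(circ, mesh,
                                   source_mask = if (config$mask == "front_half")
                                     growth_mask(mesh, config))
    g_raw <- growth_field(circ, fields, mesh)
  } else {
    fields <- NULL
    g_raw <- rep(1, nrow(mesh$nodes))
  }
  g <- g_raw * growth_mask(mesh, config)
  gz <- growth_zone_stats(mesh, g)
  u_n <- solve_boundary_velocity(curve, mesh, g)
  p <- bc_pts(curve)

  cx_min <- a_y <- NA_real_
  if (q > 0) {
    bvals <- eval_fields(fields, p)
    ref <- if ("X" %in% colnames(bvals)) "X" else colnames(bvals)[1]
    front <- p[, 1] >= config$x0 / 2
    if (any(front)) cx_min <- min(bvals[front, ref])
    # secretion-region area of the first secretion-regulated chemical,
    # restricted to the growing (front) region: the static back corners also
    # dip below the secretion threshold but play no role in protrusion growth
    reg <- Filter(function(ch) length(ch$secretion_links) > 0, circ$chemicals)
    if (length(reg)) {
      ch <- reg[[1]]
      gate <- rep(1, nrow(mesh$nodes))
      for (sl in ch$secretion_links)
        gate <- gate * hill(fields$values[, sl$regulator], sl$Ks, sl$n)
      a_y <- sum(mesh$weights[gate > 0.5 & growth_mask(mesh, config) > 0])
    }
  }
  pr <- count_protrusions(curve, config$prominence,
                          xmin = if (config$mask == "front_half")
                            config$x0 / 2 else -Inf)
  tipi <- which.max(p[, 1])
  tip <- p[tipi, ]
  wp <- width_profile(curve, tip, stations = config$width_station)
  list(mesh = mesh, fields = fields, g = g, u_n = u_n, max_un = max(u_n),
       metrics = list(area = polygon_area(curve),
                      perimeter = arc_lengths(curve)$total,
                      a_gz = gz$area,
                      gz_components = gz$components, cx_min = cx_min,
                      a_y = a_y, protrusions = pr$count,
                      tip_x = tip[1], tip_width = wp$width[1],
                      int_g = sum(mesh$weights * g), max_un = max(u_n),
                      min_un = min(u_n)))
}

# advect boundary markers by u_n * n * dt with self-intersection rejection
advect_boundary <- function(curve, u_n, dt) {
  p <- bc_pts(curve)
  nrm <- outward_normals(curve)
  for (try in 1:10) {
    np <- p + dt * u_n * nrm
    if (cpp_poly_simple(np[, 1], np[, 2]))
      return(list(curve = boundary_curve(np[, 1], np[, 2], curve$h,
                                         validate = FALSE),
                  dt = dt))
    dt <- dt / 2
  }
  stop("boundary self-intersects even after 10 step halvings")
}

#' Advance the simulation by one time step
#'
#' One cycle of the quasi-static loop: re-mesh the interior, solve the
#' steady-state concentration fields, evaluate the masked growth field,
#' solve the boundary velocity, advect the markers with an adaptive CFL time
#' step (`dt = alpha * h / max(u_n)`, halved on self-intersection), and
#' resample the boundary. Fields are fully re-solved every step: the model
#' assumes chemical kinetics much faster than growth.
#'
#' @param state list with `curve` (a [boundary_curve()]) and time `t`.
#' @param config a [sim_config()].
#' @return list with the advanced `curve`, `t`, the step size `dt`, the
#'   pre-step evaluation `eval` (metrics, growth field, velocity), and
#'   `balance_err`: the relative mismatch between the polygon-area increase
#'   and `dt * integral(g) dA` (divergence-theorem check).
#' @export
sim_step <- function(state, config) {
  ev <- eval_state(state$curve, config)
  if (ev$max_un < 1e-9)
    return(list(curve = state$curve, t = state$t, dt = 0, eval = ev,
                balance_err = NA_real_, static = TRUE))
  # CFL step, additionally capped so the second-order (curvature) term of
  # the swept area, ~ kappa * u^2 * dt / 2 per unit flux, stays ~1% of the
  # area increment (keeps the per-step mass balance tight at sharp tips)
  ku <- max(pmax(boundary_curvature(state$curve), 0) * pmax(ev$u_n, 0))
  dt <- min(config$alpha * state$curve$h / ev$max_un, 0.5,
            if (ku > 1e-12) 0.025 / ku else Inf)
  adv <- advect_boundary(state$curve, ev$u_n, dt)
  new_curve <- resample_boundary(adv$curve, config$h)
  # divergence-theorem check of the advection itself (the subsequent
  # resampling redistributes markers along the curve and is checked
  # separately by its own shape-preservation tolerance)
  dA <- polygon_area(adv$curve) - ev$metrics$area
  growth <- adv$dt * ev$metrics$int_g
  list(curve = new_curve, t = state$t + adv$dt, dt = adv$dt, eval = ev,
       balance_err = abs(dA - growth) / max(abs(dA), 1e-300), static = FALSE)
}

#' Run a growth simulation
#'
#' Iterates [sim_step()] from the configured initial cluster (or from a cut
#' precursor cluster for regeneration runs) until a stop condition is met:
#' the time horizon `t_max`, a vanished growth zone, a stable protrusion
#' count, or a static boundary (no growing cells). The dynamics are fully
#' deterministic: identical configurations produce identical trajectories.
#'
#' @param config a [sim_config()] (or a scenario name, see
#'   [scenario_config()]).
#' @param quiet suppress per-step progress messages.
#' @return object of class `growth_trajectory`: list with `config`, a
#'   per-step `metrics` data frame (time, step size, cluster area,
#'   growth-zone area and component count, minimum front-boundary inhibitor
#'   concentration `cx_min`, secretion-region area `a_y`, protrusion count,
#'   tip position and width, max normal speed, mass-balance error),
#'   `snapshots` (list of `list(step, t, curve)`), the `final_curve`, the
#'   stop `status`, and for regeneration runs the `precursor` trajectory.
#' @export
run_growth <- function(config, quiet = TRUE) {
  if (is.character(config)) config <- scenario_config(config)
  stopifnot(inherits(config, "sim_config"))
  pre_traj <- NULL
  if (!is.null(config$precursor)) {
    pre_traj <- run_growth(config$precursor, quiet = quiet)
    cut <- resolve_cut(config$cut, pre_traj$final_curve, config$precursor$x0)
    curve <- apply_cut(pre_traj$final_curve, cut, config$h)
  } else {
    curve <- initial_curve(config)
  }
  t <- 0; step <- 0L
  rows <- list(); snaps <- list()
  status <- "max_steps"
  max_steps <- 20000L
  take_snap <- function(curve, step, t)
    list(step = step, t = t, curve = curve)
  repeat {
    st <- sim_step(list(curve = curve, t = t), config)
    rows[[step + 1L]] <- c(list(step = step, t = t, dt = st$dt,
                                balance_err = st$balance_err),
                           st$eval$metrics)
    if (step %% config$snapshot_every == 0L)
      snaps[[length(snaps) + 1L]] <- take_snap(curve, step, t)
    if (!quiet)
      message(sprintf(
        "step %4d t=%.3f dt=%.4f A=%.4f A_gz=%.4f comp=%d prot=%d u=%.4f bal=%.2g",
        step, t, st$dt, st$eval$metrics$area, st$eval$metrics$a_gz,
        st$eval$metrics$gz_components, st$eval$metrics$protrusions,
        st$eval$max_un, st$balance_err))
    if (st$static) { status <- "static"; break }
    if (config$stop_gz_vanish && st$eval$metrics$a_gz < config$h_mesh^2) {
      status <- "gz_vanished"; break
    }
    if (config$stop_stable_protrusions && t >= config$min_stop_time) {
      counts <- vapply(rows, function(r) r$protrusions, 0)
      times <- vapply(rows, function(r) r$t, 0)
      win <- times >= t * (1 - config$stable_frac)
      if (sum(win) >= 3 && counts[length(counts)] >= 1 &&
          length(unique(counts[win])) == 1L) {
        status <- "protrusions_stable"; break
      }
    }
    if (t + st$dt >= config$t_max - 1e-12) {
      # finish exactly at the horizon with a truncated step
      if (t < config$t_max - 1e-9) {
        dt_rem <- config$t_max - t
        adv <- advect_boundary(curve, st$eval$u_n, dt_rem)
        dA <- polygon_area(adv$curve) - st$eval$metrics$area
        rows[[step + 1L]]$dt <- adv$dt
        rows[[step + 1L]]$balance_err <-
          abs(dA - adv$dt * st$eval$metrics$int_g) / max(abs(dA), 1e-300)
        curve <- resample_boundary(adv$curve, config$h)
        t <- config$t_max; step <- step + 1L
      }
      status <- "t_max"; break
    }
    curve <- st$curve; t <- st$t; step <- step + 1L
    if (step >= max_steps) break
  }
  # the t_max path advances the boundary one last time after the final
  # recorded row; evaluate and record the terminal state
  if (t > rows[[length(rows)]]$t + 1e-15) {
    ev <- eval_state(curve, config)
    rows[[length(rows) + 1L]] <- c(list(step = step, t = t, dt = NA_real_,
                                        balance_err = NA_real_), ev$metrics)
  }
  snaps[[length(snaps) + 1L]] <- take_snap(curve, step, t)
  metrics <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  structure(list(config = config, metrics = metrics, snapshots = snaps,
                 final_curve = curve, status = status, precursor = pre_traj),
            class = "growth_trajectory")
}

#' @export
print.growth_trajectory <- function(x, ...) {
  m <- x$metrics
  f <- m[nrow(m), ]
  cat(sprintf(
    "<growth_trajectory> %s: %d steps, t = %.3f (%s)\n",
    if (!is.null(x$config$name)) x$config$name else x$config$scheme,
    f$step, f$t, x$status))
  cat(sprintf("  area %.4f -> %.4f | growth zone %.4f | protrusions %d\n",
              m$area[1], f$area, f$a_gz, f$protrusions))
  invisible(x)
}

#' @export
summary.growth_trajectory <- function(object, ...) {
  m <- object$metrics
  out <- list(scheme = object$config$scheme, status = object$status,
              steps = nrow(m) - 1, t_final = m$t[nrow(m)],
              area_final = m$area[nrow(m)], a_gz_final = m$a_gz[nrow(m)],
              protrusions_final = m$protrusions[nrow(m)],
              shape_class = tryCatch(classify_shape(object),
                                     error = function(e) NA_character_),
              max_balance_err = suppressWarnings(max(m$balance_err, na.rm = TRUE)))
  class(out) <- "summary.growth_trajectory"
  out
}

#' @export
print.summary.growth_trajectory <- function(x, ...) {
  cat(sprintf("Growth run [%s], stopped: %s after %d steps (t = %.3f)\n",
              x$scheme, x$status, x$steps, x$t_final))
  cat(sprintf("  final area %.4f, growth zone %.4f, %d protrusion(s), class: %s\n",
              x$area_final, x$a_gz_final, x$protrusions_final, x$shape_class))
  cat(sprintf("  worst step mass-balance error %.3g\n", x$max_balance_err))
  invisible(x)
}

#' Plot boundary snapshots of a trajectory
#'
#' Overlays the stored boundary snapshots (early to late) with a color ramp.
#'
#' @param x a `growth_trajectory`.
#' @param ... passed to the base plot of the first snapshot.
#' @export
plot.growth_trajectory <- function(x, ...) {
  cols <- grDevices::hcl.colors(length(x$snapshots), "viridis")
  xs <- range(unlist(lapply(x$snapshots, function(s) s$curve$x)))
  ys <- range(unlist(lapply(x$snapshots, function(s) s$curve$y)))
  plot(NA, xlim = xs, ylim = ys, asp = 1, xlab = "x", ylab = "y", ...)
  for (i in seq_along(x$snapshots))
    plot(x$snapshots[[i]]$curve, add = TRUE, col = cols[i])
  invisible(x)
}
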