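# serializable representation of a sim_config (drops the derived circuit)
config_to_list <- function(config) {
  keep <- setdiff(names(config), "circuit")
  out <- lapply(keep, function(k) {
    v <- config[[k]]
    if (k == "precursor" && !is.null(v)) config_to_list(v)
    else if (k == "custom_points" && !is.null(v))
      list(x = as.numeric(v[, 1]), y = as.numeric(v[, 2]))
    else v
  })
  names(out) <- keep
  out[!vapply(out, is.null, TRUE)]
}

config_from_list <- function(lst, where = "config") {
  known <- c("scheme", "params", "shape", "x0", "y0", "h", "h_mesh", "alpha",
             "t_max", "mask", "snapshot_every", "stop_gz_vanish",
             "stop_stable_protrusions", "stable_frac", "min_stop_time",
             "prominence", "width_station", "cut", "precursor",
             "custom_points", "name")
  extra <- setdiff(names(lst), known)
  if (length(extra))
    stop("unknown configuration field(s) at ", where, ": ",
         paste0(where, "$", extra, collapse = ", "))
  if (!is.null(lst$precursor)) {
    lst$precursor <- if (is.character(lst$precursor))
      scenario_config(lst$precursor)
    else config_from_list(lst$precursor, paste0(where, "$precursor"))
  }
  if (!is.null(lst$custom_points))
    lst$custom_points <- cbind(as.numeric(lst$custom_points$x),
                               as.numeric(lst$custom_points$y))
  if (!is.null(lst$cut) && !is.null(lst$cut$semi_axes))
    lst$cut$semi_axes <- as.numeric(lst$cut$semi_axes)
  if (!is.null(lst$params)) lst$params <- lapply(lst$params, as.numeric)
  do.call(sim_config, lst)
}

#' Load a simulation configuration from a YAML file
#'
#' Reads a plain-text configuration (fields as in [sim_config()]), validates
#' it, and resolves all defaults. Unknown fields, unknown schemes and
#' invalid parameter values raise errors naming the offending field.
#'
#' @param path YAML file.
#' @return a validated [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  config_from_list(yaml::read_yaml(path))
}

#' Named scenario registry
#'
#' `list_scenarios()` lists the shipped scenario names; `scenario_config()`
#' returns the fully resolved configuration of one. The registry covers the
#' canonical study conditions of the model: uniform growth (circularizing
#' clusters), single-inhibitor rods at several secretion rates, the
#' two-inhibitor growth-zone morphologies and the three-protrusion run,
#' threshold-regulator cones across secretion-max regulation strengths, the
#' growth-activator variant, a small elliptical cluster, and the two
#' regeneration (cut) experiments.
#'
#' @param name scenario name, one of `list_scenarios()`.
#' @return `scenario_config()`: a [sim_config()]; `list_scenarios()`: a
#'   character vector.
#' @export
scenario_config <- function(name) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; see list_scenarios()")
  reg[[name]]()
}

#' @rdname scenario_config
#' @export
list_scenarios <- function() names(scenario_registry())

scenario_registry <- function() {
  two_inh <- function(muY0, Ks, t_max, stable = FALSE, nm) {
    sim_config("two_inhibitors",
               params = list(mu_X = 8, mu_Y0 = muY0, Ks = Ks, gamma_r = 1),
               shape = "parabolic", x0 = 1.5, y0 = 1, t_max = t_max,
               stop_stable_protrusions = stable, min_stop_time = 6,
               name = nm)
  }
  cone <- function(b, muY, nm) {
    sim_config("threshold_regulator",
               params = list(mu_X = 8, mu_Y0 = muY, Ks = 0.9,
                             gamma_r = 0.2, b = b),
               shape = "parabolic", x0 = 1.5, y0 = 1, t_max = 40,
               stop_gz_vanish = TRUE, name = nm)
  }
  rod <- function(muX, t_max, nm)
    sim_config("single_inhibitor", params = list(mu_X = muX),
               shape = "parabolic", x0 = 1.5, y0 = 1, t_max = t_max,
               name = nm)
  s7 <- function(type, semi_axes = NULL, nm)
    sim_config("single_inhibitor", params = list(mu_X = 8),
               shape = "custom", x0 = 1.5, y0 = 1, t_max = 14,
               precursor = rod(8, 14, "s7_precursor"),
               cut = c(list(type = type, at = "mid_protrusion"),
                       if (!is.null(semi_axes)) list(semi_axes = semi_axes)),
               name = nm)
  list(
    fig2_parabola = function()
      sim_config("none", shape = "parabolic", x0 = 1.5, y0 = 1,
                 mask = "none", t_max = 1.5, snapshot_every = 5,
                 name = "fig2_parabola"),
    fig2_ellipse = function()
      sim_config("none", shape = "elliptical", x0 = 1.6, y0 = 0.4,
                 mask = "none", t_max = 1.5, snapshot_every = 5,
                 name = "fig2_ellipse"),
    fig3_muX6 = function() rod(6, 24, "fig3_muX6"),
    fig3_muX8 = function() rod(8, 24, "fig3_muX8"),
    fig3_muX10 = function() rod(10, 24, "fig3_muX10"),
    fig4_Ks0.9_muY150 = function() two_inh(150, 0.9, 10, FALSE, "fig4_Ks0.9_muY150"),
    fig4_Ks0.9_muY200 = function() two_inh(200, 0.9, 10, FALSE, "fig4_Ks0.9_muY200"),
    fig4_Ks1.0_muY56 = function() two_inh(56, 1.0, 10, FALSE, "fig4_Ks1.0_muY56"),
    fig4_Ks1.0_muY60 = function() two_inh(60, 1.0, 10, FALSE, "fig4_Ks1.0_muY60"),
    fig4_Ks1.0_muY65 = function() {
      cfg <- two_inh(65, 1.0, 50, TRUE, "fig4_Ks1.0_muY65")
      cfg$min_stop_time <- 30   # the count settles after the middle stalls
      cfg
    },
    fig4_Ks1.2_muY20 = function() two_inh(20, 1.2, 10, FALSE, "fig4_Ks1.2_muY20"),
    fig4_Ks1.2_muY22 = function() two_inh(22, 1.2, 10, FALSE, "fig4_Ks1.2_muY22"),
    fig5_b0 = function() cone(0, 15, "fig5_b0"),
    "fig5_b-0.5" = function() cone(-0.5, 26.5, "fig5_b-0.5"),
    "fig5_b-0.8" = function() cone(-0.8, 48, "fig5_b-0.8"),
    s2_activator = function()
      sim_config("activator_s2",
                 params = list(mu_X0 = 48, mu_Y = 7 / 1.2, gamma_r = 0.5),
                 shape = "parabolic", x0 = 1.5, y0 = 1, t_max = 8,
                 name = "s2_activator"),
    s3_small_ellipse = function()
      sim_config("single_inhibitor", params = list(mu_X = 7),
                 shape = "elliptical", x0 = 1.6, y0 = 0.4, t_max = 8,
                 name = "s3_small_ellipse"),
    s7_straight_cut = function() s7("straight", NULL, "s7_straight_cut"),
    # cap semi-axes chosen so the cap's apex curvature matches the natural
    # rod-tip curvature (the mechanism behind single-protrusion regeneration)
    s7_elliptical_cut = function() s7("elliptical", c(0.3, 0.35), "s7_elliptical_cut"))
}

fmt_num <- function(x) sprintf("%.17g", x)

write_num_csv <- function(df, path) {
  out <- df
  for (k in names(out)) if (is.numeric(out[[k]])) out[[k]] <- fmt_num(out[[k]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write / read a trajectory archive
#'
#' Serializes a trajectory to a directory of plain-text files: the fully
#' resolved configuration (`config.yaml`), the per-step metrics
#' (`metrics.csv`), one boundary snapshot per file (`boundary_XXXX.csv` with
#' columns step, time, point_index, x, y), a `trajectory.json` with run
#' metadata and GeoJSON-style polygon records, and a `manifest.json` with
#' md5 checksums. Numbers are written with 17 significant digits so the
#' round trip is bit-exact; `read_trajectory()` verifies the checksums and
#' rebuilds the trajectory.
#'
#' @param trajectory a `growth_trajectory`.
#' @param dir target directory (created if needed).
#' @return `write_trajectory()`: `dir`, invisibly. `read_trajectory()`: the
#'   rebuilt `growth_trajectory` (metrics and boundary coordinates identical
#'   to the written ones).
#' @export
write_trajectory <- function(trajectory, dir) {
  stopifnot(inherits(trajectory, "growth_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config_to_list(trajectory$config),
                   file.path(dir, "config.yaml"))
  write_num_csv(trajectory$metrics, file.path(dir, "metrics.csv"))
  files <- c("config.yaml", "metrics.csv")
  for (i in seq_along(trajectory$snapshots)) {
    s <- trajectory$snapshots[[i]]
    f <- sprintf("boundary_%04d.csv", i)
    write_num_csv(data.frame(step = s$step, time = s$t,
                             point_index = seq_along(s$curve$x),
                             x = s$curve$x, y = s$curve$y),
                  file.path(dir, f))
    files <- c(files, f)
  }
  meta <- list(
    package = "protrusim",
    status = trajectory$status,
    n_snapshots = length(trajectory$snapshots),
    snapshots = lapply(trajectory$snapshots, function(s)
      list(step = s$step, time = s$t,
           polygon = list(type = "Polygon",
                          coordinates = list(cbind(c(s$curve$x, s$curve$x[1]),
                                                   c(s$curve$y, s$curve$y[1])))))))
  jsonlite::write_json(meta, file.path(dir, "trajectory.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "trajectory.json")
  md5 <- as.list(tools::md5sum(file.path(dir, files)))
  names(md5) <- files
  jsonlite::write_json(md5, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("not a trajectory directory (no manifest): ", dir)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  for (f in names(man)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("trajectory archive incomplete: missing ", f)
    if (unname(tools::md5sum(p)) != man[[f]])
      stop("trajectory archive corrupt: checksum mismatch for ", f)
  }
  config <- config_from_list(yaml::read_yaml(file.path(dir, "config.yaml")))
  metrics <- utils::read.csv(file.path(dir, "metrics.csv"))
  bfiles <- sort(grep("^boundary_", names(man), value = TRUE))
  snaps <- lapply(bfiles, function(f) {
    b <- utils::read.csv(file.path(dir, f))
    list(step = b$step[1], t = b$time[1],
         curve = boundary_curve(b$x, b$y, config$h, validate = FALSE))
  })
  structure(list(config = config, metrics = metrics, snapshots = snaps,
                 final_curve = snaps[[length(snaps)]]$curve,
                 status = jsonlite::read_json(
                   file.path(dir, "trajectory.json"))$status,
                 precursor = NULL),
            class = "growth_trajectory")
}
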