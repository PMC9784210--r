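# Result writers (VTK / CSV / JSON), YAML scenario configs with schema
# validation, run logging, and the functions behind the command-line front
# end.

#' Write a mesh (with optional fields) as a legacy ASCII VTK file
#'
#' Unstructured grid of triangles; point coordinates in metres. Region tags
#' are stored as integer cell data `region_id`; the tag order is recorded in
#' the VTK title line so [read_vtk_mesh()] can restore them.
#'
#' @param mesh a `pef_mesh`.
#' @param path output file.
#' @param point_data named list of nodal vectors (e.g. `phi`, `T`).
#' @param cell_data named list of per-element vectors (e.g. `E_mag`,
#'   `sigma`).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  regions <- sort(unique(mesh$region))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w("pefsim mesh; regions=", paste(regions, collapse = ","))
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  w("POINTS ", n, " double")
  writeLines(sprintf("%.12g %.12g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  w("CELLS ", m, " ", 4 * m)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  w("CELL_TYPES ", m)
  writeLines(rep("5", m), con)
  w("CELL_DATA ", m)
  w("SCALARS region_id int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(match(mesh$region, regions) - 1L), con)
  for (nm in names(cell_data)) {
    w("SCALARS ", nm, " double 1")
    w("LOOKUP_TABLE default")
    writeLines(sprintf("%.12g", rep_len(cell_data[[nm]], m)), con)
  }
  if (length(point_data)) {
    w("POINT_DATA ", n)
    for (nm in names(point_data)) {
      w("SCALARS ", nm, " double 1")
      w("LOOKUP_TABLE default")
      writeLines(sprintf("%.12g", rep_len(point_data[[nm]], n)), con)
    }
  }
  invisible(path)
}

#' Read a mesh written by [write_vtk()]
#'
#' Restores nodes, triangles and region tags (edge tags and geometry
#' metadata are not serialised; re-mesh from the config when those are
#' needed).
#'
#' @param path a VTK file produced by [write_vtk()].
#' @return a `pef_mesh` (without `edges`/`geom`).
#' @export
read_vtk_mesh <- function(path) {
  ln <- readLines(path)
  title <- ln[2]
  regions <- strsplit(sub(".*regions=", "", title), ",")[[1]]
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[ip], " +")[[1]][2])
  pts <- do.call(rbind, lapply(strsplit(ln[ip + seq_len(n)], " +"), as.numeric))
  ic <- grep("^CELLS", ln)[1]
  m <- as.integer(strsplit(ln[ic], " +")[[1]][2])
  cl <- do.call(rbind, lapply(strsplit(ln[ic + seq_len(m)], " +"), as.integer))
  stopifnot(all(cl[, 1] == 3L))
  ir <- grep("^SCALARS region_id", ln)[1]
  rid <- as.integer(ln[ir + 1 + seq_len(m)])
  mesh <- structure(list(nodes = pts[, 1:2, drop = FALSE],
                         tri = cl[, 2:4, drop = FALSE] + 1L,
                         region = regions[rid + 1L],
                         edges = data.frame(n1 = integer(0), n2 = integer(0),
                                            tag = character(0)),
                         geom = NULL), class = "pef_mesh")
  mesh$areas <- abs(signed_area(mesh$nodes, mesh$tri))
  mesh
}

# ---- scenario configs ------------------------------------------------------

geometry_fields <- function() names(formals(geometry_config))
protocol_fields <- c("pulses", "amplitude_V", "width_us", "interval_us",
                     "latency_ms")

#' Serialise a scenario to a YAML config
#'
#' The config carries a `schema` version, the full geometry and protocol
#' blocks, and provenance notes for the convective film coefficients (the
#' blood-flow assumptions they were derived from, recorded as metadata, not
#' re-computed).
#'
#' @param sc a [scenario()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(sc, path) {
  p <- sc$protocol
  obj <- list(
    schema = 1L,
    label = sc$label,
    geometry = unclass(sc$geometry),
    protocol = list(pulses = p$n_pulses, amplitude_V = p$amplitude,
                    width_us = p$pulse_width, interval_us = p$interval,
                    latency_ms = p$latency_window),
    lumen_robin = sc$lumen_robin,
    saline_flowing = sc$saline_flowing,
    provenance = list(
      air_convection = "h = 20 W/m2K, T = 21 C (ambient air)",
      endocardial_convection = "h = 1417 W/m2K, T = 37 C (chamber blood, 24.4 cm/s)",
      lumen_convection = "h = 63.19 W/m2K, T = 37 C (lumen blood, 0.5 m/s)",
      blood_viscosity_kg_per_ms = 2.1e-3))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read and validate a scenario config
#'
#' Unknown keys anywhere in the file are rejected before any computation.
#'
#' @param path a YAML file written by [write_scenario_config()] (or by
#'   hand to the same schema).
#' @return a [scenario()].
#' @export
read_scenario_config <- function(path) {
  obj <- yaml::read_yaml(path)
  top_known <- c("schema", "label", "geometry", "protocol", "lumen_robin",
                 "saline_flowing", "provenance")
  bad <- setdiff(names(obj), top_known)
  if (length(bad)) stop("config: unknown top-level keys: ",
                        paste(bad, collapse = ", "))
  if (is.null(obj$schema) || obj$schema != 1L)
    stop("config: missing or unsupported schema version")
  bad <- setdiff(names(obj$geometry), geometry_fields())
  if (length(bad)) stop("config: unknown geometry keys: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(names(obj$protocol), protocol_fields)
  if (length(bad)) stop("config: unknown protocol keys: ",
                        paste(bad, collapse = ", "))
  geo <- do.call(geometry_config, obj$geometry)
  pr <- obj$protocol %||% list()
  proto <- pulse_train(n_pulses = pr$pulses %||% 10,
                       amplitude = pr$amplitude_V %||% 1000,
                       pulse_width = pr$width_us %||% 100,
                       interval = pr$interval_us %||% 100,
                       latency_window = pr$latency_ms %||% 10)
  scenario(geo, proto, label = obj$label %||% "scenario",
           lumen_robin = obj$lumen_robin %||% TRUE,
           saline_flowing = obj$saline_flowing %||% TRUE)
}

# ---- result writers --------------------------------------------------------

#' Write the T_max trace of a result as CSV
#'
#' Columns: `t_s`, `Tmax_C`, `x_mm`, `y_mm` (location of the maximum).
#'
#' @param res a [run_scenario()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(res, path) {
  utils::write.csv(res$trace, path, row.names = FALSE)
  invisible(path)
}

#' Write the metrics summary of a result as JSON
#'
#' @param res a [run_scenario()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(res, path) {
  s <- as.list(metrics_summary(res))
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run a scenario and write its results directory
#'
#' Produces VTK snapshots of the end-of-train field and temperature, the
#' T_max CSV trace, a JSON metrics summary, the scenario config and a run
#' log with the nonlinear-solver convergence history.
#'
#' @param sc a [scenario()].
#' @param out_dir output directory (created; one subdirectory per scenario
#'   label).
#' @param profile a [solver_profile()].
#' @param verbose print progress lines.
#' @return the result object, invisibly.
#' @export
cli_run <- function(sc, out_dir, profile = solver_profile(),
                    verbose = TRUE) {
  dir <- file.path(out_dir, sc$label)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(dir, "run.log")
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  logline("start scenario ", sc$label)
  res <- run_scenario(sc, profile)
  for (cv in res$convergence)
    logline(sprintf("field solve t=%.6fs (%s): %d iterations, residual %.2e",
                    cv$t_s, cv$reason, cv$iterations, cv$residual))
  Tn <- res$T_end_train
  write_vtk(res$mesh, file.path(dir, "end_of_train.vtk"),
            point_data = list(phi = res$field$phi, T = Tn),
            cell_data = list(E_mag = res$field$E_mag,
                             sigma = res$field$sigma_elem))
  write_trace_csv(res, file.path(dir, "tmax_trace.csv"))
  write_metrics_json(res, file.path(dir, "metrics.json"))
  write_scenario_config(res$scenario, file.path(dir, "scenario.yaml"))
  logline(sprintf("done: Tmax=%.2fC width=%.2fmm", res$metrics$probe$T_max_global,
                  res$metrics$zone$width_mm))
  invisible(res)
}

#' Tabulate completed runs under a results directory
#'
#' One row per scenario subdirectory containing a `metrics.json`; incomplete
#' runs (missing metrics) are listed with `complete = FALSE`.
#'
#' @param results_dir directory previously populated by [cli_run()].
#' @return data.frame of metrics with `complete` flag.
#' @export
cli_report <- function(results_dir) {
  subs <- list.dirs(results_dir, recursive = FALSE)
  if (length(subs) == 0) stop("no runs found under ", results_dir)
  rows <- lapply(subs, function(d) {
    f <- file.path(d, "metrics.json")
    if (!file.exists(f))
      return(data.frame(scenario = basename(d), complete = FALSE))
    m <- jsonlite::read_json(f, simplifyVector = TRUE)
    m <- lapply(m, function(v) if (is.null(v)) NA else v)
    cbind(as.data.frame(m, stringsAsFactors = FALSE), complete = TRUE)
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(c("scenario", "width_mm", "depth_mm", "confined_to_fat",
                      "lumen_mean_Vcm", "lumen_center_Vcm", "front_T",
                      "rear_T", "Tmax", "t_peak_s", "latency_flag",
                      "complete"), names(r))
    for (f in miss) r[[f]] <- NA
    r[c("scenario", "width_mm", "depth_mm", "confined_to_fat",
        "lumen_mean_Vcm", "lumen_center_Vcm", "front_T", "rear_T", "Tmax",
        "t_peak_s", "latency_flag", "complete")]
  }))
  rownames(out) <- NULL
  out
}
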