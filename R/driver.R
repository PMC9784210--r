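# Coupled electro-thermal orchestration over the pulse-train timeline.
#
# Coupling policy: the nonlinear field is re-solved at every pulse onset and
# again whenever the temperature anywhere in the thermal domain has drifted
# more than `dT_resolve` (default 0.5 C) since the last field solve — the
# only feedback from the thermal problem into the electrical one is the
# +2 %/degC conductivity factor. Off segments advance heat only.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define a simulation scenario
#'
#' @param geometry a [geometry_config()].
#' @param protocol a [pulse_train()].
#' @param label scenario label (used in reports and output files).
#' @param lumen_robin apply the lumen film condition with a stent present
#'   (see [thermal_domain()]).
#' @param saline_flowing treat the irrigated saline film as flowing fluid,
#'   excluded from the solid thermal solve (see [thermal_domain()]).
#' @param materials optional material table override.
#' @param sigmoid optional [sigmoid_model()] override.
#' @param output_times_s optional times (s) at which temperature snapshots
#'   are kept.
#' @return object of class `pef_scenario`.
#' @export
scenario <- function(geometry = geometry_config(), protocol = pulse_train(),
                     label = "scenario", lumen_robin = TRUE,
                     saline_flowing = TRUE, materials = NULL, sigmoid = NULL,
                     output_times_s = numeric(0)) {
  end_s <- (train_end_us(protocol) + protocol$latency_window * 1000) * 1e-6
  if (length(output_times_s) && any(output_times_s < 0 | output_times_s > end_s + 1e-12))
    stop("output_times_s must lie within [0, end of latency window]")
  structure(list(geometry = geometry, protocol = protocol, label = label,
                 lumen_robin = isTRUE(lumen_robin),
                 saline_flowing = isTRUE(saline_flowing),
                 materials = materials,
                 sigmoid = sigmoid, output_times_s = output_times_s),
            class = "pef_scenario")
}

#' Solver profile: mesh sizing, time steps, tolerances
#'
#' `dt_on_us = NULL` picks the default policy: 10 us steps for inter-pulse
#' intervals of 50 us or more, 2 us steps for shorter intervals; the latency
#' window uses geometrically growing steps capped at `dt_latency_max_us`.
#'
#' @param profile mesh sizing profile ("standard" or "coarse").
#' @param refine global mesh refinement factor.
#' @param dt_on_us time step during pulse/interval segments, us (NULL =
#'   policy above).
#' @param dt_latency_max_us cap on latency-window steps, us.
#' @param dT_resolve field re-solve trigger, degrees C of drift.
#' @param picard_tol sigma-change tolerance of the nonlinear field solve.
#' @param ... sizing overrides passed to [mesh_sizing()].
#' @return object of class `pef_profile`.
#' @export
solver_profile <- function(profile = "standard", refine = 1, dt_on_us = NULL,
                           dt_latency_max_us = 500, dT_resolve = 0.5,
                           picard_tol = 1e-3, ...) {
  structure(list(sizing = mesh_sizing(profile, refine = refine, ...),
                 dt_on_us = dt_on_us,
                 dt_latency_max_us = dt_latency_max_us,
                 dT_resolve = dT_resolve, picard_tol = picard_tol),
            class = "pef_profile")
}

#' Run one coupled electro-thermal scenario
#'
#' Meshes the geometry, then walks the pulse-train timeline: on-segments use
#' the self-consistent field (re-solved per the coupling policy) and its
#' Joule source, off-segments and the latency window advance heat only.
#' Collects the end-of-train field and temperature, the T_max trace, lesion
#' and probe metrics and the solver convergence log.
#'
#' @param sc a [scenario()].
#' @param profile a [solver_profile()].
#' @return object of class `pef_result`.
#' @export
run_scenario <- function(sc, profile = solver_profile()) {
  stopifnot(inherits(sc, "pef_scenario"))
  train <- sc$protocol
  geom <- build_geometry(sc$geometry)
  mesh <- generate_mesh(geom, profile$sizing)
  table <- sc$materials %||% material_table()
  model <- sc$sigmoid %||% sigmoid_model()
  dom <- thermal_domain(mesh, sc$lumen_robin, sc$saline_flowing %||% TRUE)
  n <- nrow(mesh$nodes)
  amp <- train$amplitude

  dt_on <- (profile$dt_on_us %||% (if (train$interval < 50) 2 else 10)) * 1e-6
  sys_cache <- new.env(hash = TRUE)
  get_sys <- function(dt) {
    key <- sprintf("%.9e", dt)
    s <- get0(key, envir = sys_cache)
    if (is.null(s)) {
      s <- thermal_system(mesh, dom, table, dt)
      assign(key, s, envir = sys_cache)
    }
    s
  }

  T_now <- rep(37, n)
  T_at_solve <- T_now
  elec_cache <- new.env(parent = emptyenv())
  field <- NULL
  Q <- rep(0, nrow(mesh$tri))
  conv_log <- list()
  resolve_field <- function(t_s, why) {
    if (amp <= 0) {
      gf0 <- rep(0, nrow(mesh$tri))
      field <<- structure(list(phi = rep(0, n), Ex = gf0, Ey = gf0,
                               E_mag = gf0,
                               sigma_elem = sigma_from_state(
                                 mesh, table, model, gf0,
                                 rep(37, nrow(mesh$tri))),
                               iterations = 0L, residual = 0,
                               history = numeric(0)), class = "pef_field")
    } else {
      field <<- solve_selfconsistent(mesh, table, model, T_now, amp,
                                     tol = profile$picard_tol,
                                     E_init = field$E_mag,
                                     cache = elec_cache)
    }
    Q <<- joule_source(field$sigma_elem, field$E_mag)
    T_at_solve <<- T_now
    conv_log[[length(conv_log) + 1]] <<-
      list(t_s = t_s, reason = why, iterations = field$iterations,
           residual = field$residual)
  }

  segs <- segments(train)
  t_now <- 0
  tr_t <- 0; tr_T <- 37
  i0 <- dom$nodes[1]
  tr_x <- mesh$nodes[i0, 1] * 1e3; tr_y <- mesh$nodes[i0, 2] * 1e3
  record <- function(t_s) {
    Tm <- T_now[dom$nodes]
    k <- which.max(Tm)
    tr_t <<- c(tr_t, t_s); tr_T <<- c(tr_T, Tm[k])
    tr_x <<- c(tr_x, mesh$nodes[dom$nodes[k], 1] * 1e3)
    tr_y <<- c(tr_y, mesh$nodes[dom$nodes[k], 2] * 1e3)
  }
  snapshots <- list()
  want <- sort(sc$output_times_s)
  maybe_snapshot <- function(t_s) {
    while (length(want) && t_s >= want[1] - 1e-12) {
      snapshots[[length(snapshots) + 1]] <<- list(t_s = t_s, T_nodal = T_now)
      want <<- want[-1]
    }
  }

  T_end_train <- NULL; field_end <- NULL
  t_end_train_s <- train_end_us(train) * 1e-6

  for (si in seq_len(nrow(segs))) {
    seg <- segs[si, ]
    seg_len <- (seg$t_end_us - seg$t_start_us) * 1e-6
    if (seg$kind == "latency") {
      dts <- numeric(0); acc <- 0; d <- dt_on
      while (acc < seg_len - 1e-15) {
        d <- min(d * 1.6, profile$dt_latency_max_us * 1e-6, seg_len - acc)
        dts <- c(dts, d); acc <- acc + d
      }
    } else {
      nst <- max(1L, as.integer(round(seg_len / dt_on)))
      dts <- rep(seg_len / nst, nst)
    }
    if (seg$on) resolve_field(t_now, sprintf("pulse onset #%d", (si + 1) %/% 2))
    for (k in seq_along(dts)) {
      d <- dts[k]
      sys <- get_sys(d)
      src <- if (seg$on) Q else 0
      T_now <- advance_state(sys, T_now, src)
      t_now <- t_now + d
      record(t_now)
      maybe_snapshot(t_now)
      # refresh the Joule source mid-pulse once the temperature has drifted
      if (seg$on && k < length(dts) &&
          max(abs(T_now[dom$nodes] - T_at_solve[dom$nodes])) > profile$dT_resolve)
        resolve_field(t_now, "dT trigger")
    }
    if (seg$on && abs(seg$t_end_us - train_end_us(train)) < 1e-9) {
      T_end_train <- T_now
      field_end <- field
    }
  }
  if (is.null(field_end)) { field_end <- field; T_end_train <- T_now }

  res <- structure(list(
    label = sc$label, scenario = sc, profile = profile, mesh = mesh,
    field = field_end, T_end_train = T_end_train, T_final = T_now,
    trace = data.frame(t_s = tr_t, Tmax_C = tr_T, x_mm = tr_x, y_mm = tr_y),
    t_end_train_s = t_end_train_s, thermal_nodes = dom$nodes,
    robin = dom$robin, snapshots = snapshots,
    convergence = conv_log), class = "pef_result")

  zone <- pef_zone_metrics(mesh, field_end$E_mag)
  lum <- if (!is.null(mesh$geom$artery)) lumen_stats(mesh, field_end) else NULL
  res$metrics <- list(zone = zone, lumen = lum, probe = hotspot_report(res))
  res
}

#' Flat summary of a result's outcome metrics
#'
#' @param res a [run_scenario()] result.
#' @return one-row data.frame: scenario, PEF-zone width/depth (mm),
#'   confinement flag, lumen mean/centre field (V/cm), hot-spot and global
#'   maximum temperatures (C), peak time (s), latency flag.
#' @export
metrics_summary <- function(res) {
  z <- res$metrics$zone; l <- res$metrics$lumen; p <- res$metrics$probe
  data.frame(scenario = res$label,
             width_mm = z$width_mm, depth_mm = z$depth_mm,
             confined_to_fat = z$confined_to_fat,
             lumen_mean_Vcm = if (is.null(l)) NA_real_ else l$mean_Vcm,
             lumen_center_Vcm = if (is.null(l)) NA_real_ else l$center_Vcm,
             front_T = p$front_hotspot_T, rear_T = p$rear_hotspot_T,
             Tmax = p$T_max_global, t_peak_s = p$t_peak,
             latency_flag = p$latency_flag,
             stringsAsFactors = FALSE)
}

#' Re-run one geometry under several inter-pulse intervals
#'
#' Identical geometry and mesh policy per run; reports end-of-train global
#' maximum temperature per interval and the spread across intervals.
#'
#' @param sc a [scenario()]; its protocol supplies everything but the
#'   interval.
#' @param intervals_us inter-pulse intervals to compare, us.
#' @param profile a [solver_profile()].
#' @return data.frame with `interval_us`, `Tmax_C`, `dTmax_C` (difference to
#'   the first row).
#' @export
compare_protocols <- function(sc, intervals_us, profile = solver_profile()) {
  stopifnot(length(intervals_us) >= 1)
  rows <- lapply(intervals_us, function(iv) {
    p <- sc$protocol
    sc2 <- scenario(sc$geometry,
                    pulse_train(p$n_pulses, p$amplitude, p$pulse_width, iv,
                                p$latency_window),
                    label = paste0(sc$label, "_i", iv),
                    lumen_robin = sc$lumen_robin,
                    saline_flowing = sc$saline_flowing,
                    materials = sc$materials, sigmoid = sc$sigmoid)
    r <- run_scenario(sc2, profile)
    data.frame(interval_us = iv, Tmax_C = r$metrics$probe$T_max_global)
  })
  out <- do.call(rbind, rows)
  out$dTmax_C <- out$Tmax_C - out$Tmax_C[1]
  out
}
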