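# Outcome measures: nodal field recovery, marching-triangles isolines, the
# 1000 V/cm PEF-zone and its dimensions, artery-lumen field statistics and
# hot-spot temperature reporting.

#' Area-weighted nodal recovery of a per-element field
#'
#' Each node receives the area-weighted average of the values on its adjacent
#' elements (optionally restricted to an element subset).
#'
#' @param mesh a `pef_mesh`.
#' @param value_elem per-element values.
#' @param elements optional element subset to average over.
#' @return nodal vector (NA at nodes touched by no selected element).
#' @export
nodal_field <- function(mesh, value_elem, elements = seq_len(nrow(mesh$tri))) {
  n <- nrow(mesh$nodes)
  tr <- mesh$tri[elements, , drop = FALSE]
  A <- mesh$areas[elements]
  v <- rep_len(value_elem, nrow(mesh$tri))[elements]
  num <- den <- numeric(n)
  for (a in 1:3) {
    num <- num + tabulate_add(tr[, a], A * v, n)
    den <- den + tabulate_add(tr[, a], A, n)
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Extract isolines of a nodal field (marching triangles)
#'
#' Linear interpolation along element edges; crossing segments are chained
#' into polylines (closed where the contour closes, open where it meets the
#' subset boundary). Ordering is deterministic.
#'
#' @param mesh a `pef_mesh`.
#' @param f_nodal nodal scalar field.
#' @param threshold contour level (> 0 for field magnitudes).
#' @param elements optional element subset to contour within.
#' @return list of polyline matrices (columns x, y in mm); empty list if the
#'   field never crosses the threshold.
#' @export
extract_isolines <- function(mesh, f_nodal, threshold,
                             elements = seq_len(nrow(mesh$tri))) {
  tr <- mesh$tri[elements, , drop = FALSE]
  f <- f_nodal
  g <- cbind(f[tr[, 1]], f[tr[, 2]], f[tr[, 3]]) - threshold
  segs <- list()
  edge_pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  cross <- (g[, 1] > 0) + (g[, 2] > 0) + (g[, 3] > 0)
  active <- which(cross %in% c(1, 2) &
                  apply(is.finite(g), 1, all))
  for (e in active) {
    pts <- NULL
    for (ep in edge_pairs) {
      ga <- g[e, ep[1]]; gb <- g[e, ep[2]]
      if ((ga > 0) != (gb > 0)) {
        t <- ga / (ga - gb)
        pa <- mesh$nodes[tr[e, ep[1]], ]; pb <- mesh$nodes[tr[e, ep[2]], ]
        pts <- rbind(pts, pa + t * (pb - pa))
      }
    }
    if (!is.null(pts) && nrow(pts) == 2)
      segs[[length(segs) + 1]] <- pts
  }
  if (length(segs) == 0) return(list())
  chain_segments(segs)
}

# chain loose segments into polylines by matching endpoints (rounded keys)
chain_segments <- function(segs) {
  key <- function(p) paste(round(p[1] * 1e9), round(p[2] * 1e9))
  ends <- lapply(segs, function(s) c(key(s[1, ]), key(s[2, ])))
  adj <- new.env(hash = TRUE)
  push <- function(k, v) assign(k, c(get0(k, envir = adj, ifnotfound = integer(0)), v), envir = adj)
  for (i in seq_along(segs)) { push(ends[[i]][1], i); push(ends[[i]][2], i) }
  used <- logical(length(segs))
  out <- list()
  # start from open endpoints first (degree-1 keys), then any remaining loop
  deg1 <- names(which(vapply(ls(adj), function(k) length(get(k, envir = adj)), 1L) == 1))
  starts <- c(sort(deg1), rep(NA, length(segs)))
  for (st in starts) {
    i0 <- if (is.na(st)) {
      w <- which(!used); if (length(w) == 0) break; w[1]
    } else {
      cand <- get(st, envir = adj)
      cand <- cand[!used[cand]]
      if (length(cand) == 0) next
      cand[1]
    }
    # walk
    used[i0] <- TRUE
    poly <- segs[[i0]]
    repeat {
      k <- key(poly[nrow(poly), ])
      nxt <- get0(k, envir = adj, ifnotfound = integer(0))
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      j <- nxt[1]
      used[j] <- TRUE
      s <- segs[[j]]
      if (key(s[1, ]) == k) poly <- rbind(poly, s[2, ])
      else poly <- rbind(poly, s[1, ])
    }
    # try to extend backwards too
    repeat {
      k <- key(poly[1, ])
      nxt <- get0(k, envir = adj, ifnotfound = integer(0))
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      j <- nxt[1]
      used[j] <- TRUE
      s <- segs[[j]]
      if (key(s[1, ]) == k) poly <- rbind(s[2, ], poly)
      else poly <- rbind(s[1, ], poly)
    }
    colnames(poly) <- c("x", "y")
    out[[length(out) + 1]] <- poly * 1e3      # report mm
    if (all(used)) break
  }
  out
}

#' PEF-zone metrics from the end-of-train field
#'
#' The PEF-zone is the tissue region (fat + myocardium; the saline film and
#' device are excluded) where |E| exceeds the irreversible-electroporation
#' threshold, by convention 1000 V/cm. Width is the maximum horizontal extent
#' of the super-threshold tissue, depth the maximum vertical extent below the
#' fat surface; sub-element accuracy comes from the isoline crossing points.
#'
#' @param mesh a `pef_mesh` with study geometry attached.
#' @param E_mag_elem per-element field magnitude, V/m.
#' @param threshold_Vcm threshold in V/cm (default 1000).
#' @param tissue region tags counted as tissue.
#' @return list of class `pef_zone_metrics`: `threshold_Vcm`, `width_mm`,
#'   `depth_mm`, `confined_to_fat`, `polylines`.
#' @export
pef_zone_metrics <- function(mesh, E_mag_elem, threshold_Vcm = 1000,
                             tissue = c("fat", "myocardium")) {
  thr <- threshold_Vcm * 100                  # V/m
  # nodal recovery is done per material so the sharp conductivity jump at
  # the fat/myocardium interface is not smeared into a spurious crossing
  polylines <- list()
  xs <- ys <- numeric(0)
  for (reg in intersect(tissue, unique(mesh$region))) {
    el <- which(mesh$region == reg)
    En <- nodal_field(mesh, E_mag_elem, el)
    polylines <- c(polylines, extract_isolines(mesh, En, thr, el))
    nds <- unique(as.vector(mesh$tri[el, , drop = FALSE]))
    sup_nodes <- nds[!is.na(En[nds]) & En[nds] >= thr]
    xs <- c(xs, mesh$nodes[sup_nodes, 1] * 1e3)
    ys <- c(ys, mesh$nodes[sup_nodes, 2] * 1e3)
  }
  for (p in polylines) { xs <- c(xs, p[, "x"]); ys <- c(ys, p[, "y"]) }
  fatF <- if (!is.null(mesh$geom)) mesh$geom$config$fat_thickness else Inf
  if (length(xs) == 0) {
    out <- list(threshold_Vcm = threshold_Vcm, width_mm = 0, depth_mm = 0,
                confined_to_fat = TRUE, polylines = polylines)
  } else {
    depth <- max(c(0, ys))
    out <- list(threshold_Vcm = threshold_Vcm,
                width_mm = max(xs) - min(xs),
                depth_mm = depth,
                confined_to_fat = depth <= fatF + 1e-6,
                polylines = polylines)
  }
  class(out) <- "pef_zone_metrics"
  out
}

#' Electric field statistics inside the artery lumen
#'
#' Area-weighted mean and centre-point |E| over the lumen, reported in V/cm.
#'
#' @param mesh a `pef_mesh` with an artery.
#' @param solution a `pef_field`.
#' @return list with `mean_Vcm`, `center_Vcm`, `area_mm2`.
#' @export
lumen_stats <- function(mesh, solution) {
  if (is.null(mesh$geom$artery)) stop("scenario has no artery")
  el <- which(mesh$region == "artery_lumen")
  A <- mesh$areas[el]
  meanE <- sum(solution$E_mag[el] * A) / sum(A)
  ctr <- c(mesh$geom$artery$cx, mesh$geom$artery$cy) * 1e-3
  hit <- containing_triangles(mesh, ctr)
  hit <- hit[mesh$region[hit] == "artery_lumen"]
  ctrE <- if (length(hit)) solution$E_mag[min(hit)] else NA_real_
  list(mean_Vcm = meanE / 100, center_Vcm = ctrE / 100,
       area_mm2 = sum(A) * 1e6)
}

#' Hot-spot and latency report for a simulation result
#'
#' Front hot spot: maximum end-of-train temperature in the vertical band of
#' artery-diameter width between the electrode face (fat surface) and the
#' artery top. Rear hot spot: same band between the artery bottom and the
#' myocardium surface. `t_peak` is the earliest time at which the global
#' maximum temperature is reached; `latency_flag` is TRUE when that peak sits
#' at (or before) the end of the last pulse.
#'
#' @param result a [run_scenario()] result.
#' @return list of class `pef_probe_report`.
#' @export
hotspot_report <- function(result) {
  mesh <- result$mesh
  Tn <- result$T_end_train
  act <- result$thermal_nodes
  xy <- mesh$nodes * 1e3
  front_T <- rear_T <- NA_real_
  ar <- mesh$geom$artery
  if (!is.null(ar)) {
    band <- abs(xy[, 1] - ar$cx) <= ar$r_out
    front <- act[band[act] & xy[act, 2] >= 0 & xy[act, 2] <= ar$cy - ar$r_out + 1e-9]
    rear <- act[band[act] & xy[act, 2] >= ar$cy + ar$r_out - 1e-9 &
                  xy[act, 2] <= mesh$geom$config$fat_thickness + 1e-9]
    if (length(front)) front_T <- max(Tn[front])
    if (length(rear)) rear_T <- max(Tn[rear])
  }
  tr <- result$trace
  Tmax <- max(tr$Tmax_C)
  ipk <- which(tr$Tmax_C >= Tmax - 1e-9)[1]   # 1 nK slack: earliest tie wins
  dt1 <- if (nrow(tr) > 1) max(diff(tr$t_s)[1], 0) else 0
  structure(list(front_hotspot_T = front_T, rear_hotspot_T = rear_T,
                 T_max_global = Tmax, t_peak = tr$t_s[ipk],
                 latency_flag = tr$t_s[ipk] <= result$t_end_train_s + dt1 + 1e-12),
            class = "pef_probe_report")
}
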