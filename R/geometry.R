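# Parametric 2D cross-section geometry: ablation device embedded in a saline
# film over fat / myocardium / blood layers, with an optional coronary artery
# (and stent annulus) buried in the fat below the device centre.
#
# Coordinates: origin on the fat surface under the device centre, y positive
# DOWNWARD into the tissue. Geometry is specified in mm; mesh node
# coordinates are emitted in metres.

#' Geometry configuration
#'
#' All lengths in mm except `stent_wall` (micrometres). The device footprint
#' is `device_diameter` wide; the metal electrode is an `electrode_length`
#' strip with a central `hole_width` saline-filled irrigation gap (i.e. two
#' metal segments), `electrode_height` tall, sitting on the fat surface inside
#' the saline film; the rest of the footprint is catheter polymer. The artery
#' is a disc of `artery_diameter` centred horizontally under the device, its
#' top `electrode_artery_gap` below the fat surface; the stent is a concentric
#' annulus of `stent_wall` thickness whose outer circle is the artery circle.
#'
#' @param domain_width,domain_height outer domain size, mm.
#' @param saline_thickness saline film thickness, mm.
#' @param fat_thickness epicardial fat layer thickness, mm (not printed in the
#'   source study; 5.0 mm accommodates the 1 mm gap plus the 2.3 mm artery
#'   with margin and is exposed here for sensitivity work).
#' @param myocardium_thickness myocardium layer thickness, mm.
#' @param device_diameter ablation device footprint, mm.
#' @param electrode_length total metal electrode length, mm.
#' @param electrode_height electrode cross-section height inside the saline
#'   film, mm.
#' @param hole_width central irrigation hole width, mm.
#' @param artery_present logical.
#' @param artery_diameter coronary artery diameter, mm.
#' @param stent_present logical (requires `artery_present`).
#' @param stent_wall stent wall thickness, micrometres.
#' @param electrode_artery_gap distance from fat surface to artery top, mm
#'   (0.25 or 1.0 in the study).
#' @return an object of class `pef_geometry_config`.
#' @export
geometry_config <- function(domain_width = 80, domain_height = 40,
                            saline_thickness = 0.5, fat_thickness = 5.0,
                            myocardium_thickness = 2.7,
                            device_diameter = 3.98, electrode_length = 2.56,
                            electrode_height = 0.2, hole_width = 0.76,
                            artery_present = FALSE, artery_diameter = 2.3,
                            stent_present = FALSE, stent_wall = 100,
                            electrode_artery_gap = 1.0) {
  cfg <- list(domain_width = domain_width, domain_height = domain_height,
              saline_thickness = saline_thickness, fat_thickness = fat_thickness,
              myocardium_thickness = myocardium_thickness,
              device_diameter = device_diameter,
              electrode_length = electrode_length,
              electrode_height = electrode_height, hole_width = hole_width,
              artery_present = isTRUE(artery_present),
              artery_diameter = artery_diameter,
              stent_present = isTRUE(stent_present), stent_wall = stent_wall,
              electrode_artery_gap = electrode_artery_gap)
  validate_geometry_config(cfg)
  structure(cfg, class = "pef_geometry_config")
}

validate_geometry_config <- function(cfg) {
  lens <- c("domain_width", "domain_height", "saline_thickness",
            "fat_thickness", "myocardium_thickness", "device_diameter",
            "electrode_length", "electrode_height", "hole_width",
            "artery_diameter", "stent_wall", "electrode_artery_gap")
  for (f in lens)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("geometry config: '", f, "' must be a single positive number")
  if (cfg$electrode_length <= cfg$hole_width)
    stop("geometry config: electrode_length must exceed hole_width")
  if (cfg$electrode_length >= cfg$device_diameter)
    stop("geometry config: electrode_length must fit inside device_diameter")
  if (cfg$electrode_height >= cfg$saline_thickness)
    stop("geometry config: electrode must be embedded in the saline film ",
         "(electrode_height < saline_thickness)")
  if (cfg$stent_present && !cfg$artery_present)
    stop("geometry config: stent_present requires artery_present")
  if (cfg$artery_present) {
    if (cfg$electrode_artery_gap + cfg$artery_diameter >= cfg$fat_thickness)
      stop("geometry config: artery does not fit in the fat layer ",
           "(electrode_artery_gap + artery_diameter must be < fat_thickness; ",
           cfg$electrode_artery_gap + cfg$artery_diameter, " vs ",
           cfg$fat_thickness, " mm)")
    if (cfg$stent_present && cfg$stent_wall / 1000 >= cfg$artery_diameter / 2)
      stop("geometry config: stent wall thicker than the artery radius")
    if (cfg$artery_diameter >= cfg$domain_width / 4)
      stop("geometry config: artery too large for the domain")
  }
  si <- cfg$saline_thickness + cfg$fat_thickness + cfg$myocardium_thickness
  if (si >= cfg$domain_height)
    stop("geometry config: layers exceed domain_height")
  invisible(cfg)
}

#' Build the region description of the cross-section
#'
#' Decomposes the rectangular domain into axis-aligned region rectangles
#' (saline film, device, tissue layers, blood chamber) plus the analytic
#' artery/stent circles. Every region is also exposed as a closed planar
#' polygon via [geometry_outlines()]; exact areas come from
#' [geometry_areas()].
#'
#' @param config a [geometry_config()].
#' @return an object of class `pef_geometry` with elements `rects`
#'   (data.frame: region, x0, x1, y0, y1 in mm), `artery` (NULL or list with
#'   centre, outer/inner radii, stent flag) and `config`.
#' @export
build_geometry <- function(config) {
  cfg <- validate_geometry_config(config)
  W <- cfg$domain_width; H <- cfg$domain_height
  sal <- cfg$saline_thickness; F <- cfg$fat_thickness
  myo <- cfg$myocardium_thickness
  eh <- cfg$electrode_height
  xw <- W / 2
  dev <- cfg$device_diameter / 2           # device footprint half width
  el  <- cfg$electrode_length / 2          # electrode half length
  hw  <- cfg$hole_width / 2                # irrigation hole half width
  ybot <- H - sal                           # domain bottom (y down)

  r <- function(region, x0, x1, y0, y1)
    data.frame(region = region, x0 = x0, x1 = x1, y0 = y0, y1 = y1,
               stringsAsFactors = FALSE)
  rects <- rbind(
    # saline film: the full layer minus the catheter cap and the metal; the
    # electrode is fully embedded in saline, so the irrigation hole and the
    # band beside the metal segments are saline too
    r("saline", -xw, -dev, -sal, 0),
    r("saline",  dev,  xw, -sal, 0),
    r("saline", -hw,  hw, -eh, 0),
    r("saline", -dev, -el, -eh, 0),
    r("saline",  el,  dev, -eh, 0),
    # catheter polymer cap above the electrode band
    r("catheter_body", -dev, dev, -sal, -eh),
    # electrode metal: two segments flanking the irrigation hole
    r("electrode_metal", -el, -hw, -eh, 0),
    r("electrode_metal",  hw,  el, -eh, 0),
    # tissue layers
    r("fat", -xw, xw, 0, F),
    r("myocardium", -xw, xw, F, F + myo),
    r("blood_chamber", -xw, xw, F + myo, ybot)
  )

  artery <- NULL
  if (cfg$artery_present) {
    r_out <- cfg$artery_diameter / 2
    r_in <- if (cfg$stent_present) r_out - cfg$stent_wall / 1000 else NA_real_
    artery <- list(cx = 0, cy = cfg$electrode_artery_gap + r_out,
                   r_out = r_out, r_in = r_in, stent = cfg$stent_present)
  }
  structure(list(rects = rects, artery = artery, config = cfg),
            class = "pef_geometry")
}

#' Exact region areas of a geometry, mm^2
#'
#' Rectangle areas with the artery disc subtracted from the fat layer;
#' lumen/stent areas are the analytic disc/annulus areas.
#'
#' @param geom a [build_geometry()] result.
#' @return named numeric vector of areas (mm^2).
#' @export
geometry_areas <- function(geom) {
  a <- with(geom$rects, tapply((x1 - x0) * (y1 - y0), region, sum))
  out <- as.numeric(a); names(out) <- names(a)
  if (!is.null(geom$artery)) {
    ar <- geom$artery
    disc <- pi * ar$r_out^2
    out["fat"] <- out["fat"] - disc
    if (ar$stent) {
      out["stent"] <- pi * (ar$r_out^2 - ar$r_in^2)
      out["artery_lumen"] <- pi * ar$r_in^2
    } else {
      out["artery_lumen"] <- disc
    }
  }
  out
}

#' Closed outline polygons of every region
#'
#' Rectangles become 4-point closed loops; circles are discretised with
#' `n_circle` points. Intended for plotting and geometric checks, not for
#' meshing (the mesher works from the analytic description).
#'
#' @param geom a [build_geometry()] result.
#' @param n_circle number of points on each circle.
#' @return named list of closed polygon matrices (columns x, y in mm); region
#'   names may repeat for multi-rectangle regions.
#' @export
geometry_outlines <- function(geom, n_circle = 128) {
  out <- list()
  for (i in seq_len(nrow(geom$rects))) {
    rr <- geom$rects[i, ]
    p <- cbind(x = c(rr$x0, rr$x1, rr$x1, rr$x0, rr$x0),
               y = c(rr$y0, rr$y0, rr$y1, rr$y1, rr$y0))
    out[[length(out) + 1L]] <- p
    names(out)[length(out)] <- rr$region
  }
  if (!is.null(geom$artery)) {
    ar <- geom$artery
    th <- seq(0, 2 * pi, length.out = n_circle + 1)
    circ <- function(r) cbind(x = ar$cx + r * cos(th), y = ar$cy + r * sin(th))
    out[[length(out) + 1L]] <- circ(ar$r_out)
    names(out)[length(out)] <- if (ar$stent) "stent" else "artery_lumen"
    if (ar$stent) {
      out[[length(out) + 1L]] <- circ(ar$r_in)
      names(out)[length(out)] <- "artery_lumen"
    }
  }
  out
}
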