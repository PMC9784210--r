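# Deterministic block-structured triangular mesher.
#
# The rectangular domain is meshed as a graded tensor-product grid whose
# division lines are forced through every material interface (layer
# boundaries, device outline). The artery is handled by carving a square
# block out of the grid and filling it with a mapped O-grid: a transition
# band from the square down to the artery circle, optional stent annulus
# rings, concentric lumen rings and a centre fan. All nodes on shared block
# boundaries are created once, so the mesh is conforming by construction and
# fully deterministic (no randomised point placement).

#' Mesh sizing profile
#'
#' Target element sizes in mm. `h_edge` applies at the electrode metal edges
#' and around the artery/stent wall, `h_fine` over the device footprint,
#' `h_fat`/`h_myo` in the bulk tissue layers, `h_coarse` at the domain
#' border; sizes grow away from features with gradient `slope`. `refine`
#' divides every target size (refine = 2 halves all element sizes).
#'
#' @param profile "standard" (production resolution) or "coarse" (fast
#'   profile for iterative work and continuous testing).
#' @param refine global refinement factor (> 0).
#' @param ... named overrides of individual sizing fields.
#' @return an object of class `pef_sizing`.
#' @export
mesh_sizing <- function(profile = c("standard", "coarse"), refine = 1, ...) {
  profile <- match.arg(profile)
  s <- if (profile == "standard") {
    list(h_edge = 0.05, h_fine = 0.10, h_fat = 0.14, h_myo = 0.35,
         h_coarse = 2.5, slope = 0.3, n_band = 3, n_stent = 2)
  } else {
    list(h_edge = 0.12, h_fine = 0.22, h_fat = 0.30, h_myo = 0.7,
         h_coarse = 5, slope = 0.5, n_band = 2, n_stent = 2)
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(s)) stop("unknown sizing field: ", nm)
    s[[nm]] <- dots[[nm]]
  }
  stopifnot(refine > 0)
  for (f in c("h_edge", "h_fine", "h_fat", "h_myo", "h_coarse"))
    s[[f]] <- s[[f]] / refine
  s$profile <- profile
  s$refine <- refine
  structure(s, class = "pef_sizing")
}

# 1D graded division of [x0, x1] following a local size field hfun(x).
# Steps are laid greedily from both ends (always advancing the finer end) and
# the closing gap is absorbed as a single step, so mandatory breakpoints are
# hit exactly and step sizes stay within roughly [0.6 h, 1.6 h].
grade_interval <- function(x0, x1, hfun) {
  L <- x1 - x0
  stopifnot(L > 0)
  fa <- numeric(0); fb <- numeric(0)
  pa <- x0; pb <- x1
  repeat {
    ha <- hfun(pa); hb <- hfun(pb)
    gap <- pb - pa
    if (gap < 1.6 * min(ha, hb)) break
    if (ha <= hb) { fa <- c(fa, ha); pa <- pa + ha }
    else { fb <- c(fb, hb); pb <- pb - hb }
  }
  steps <- c(fa, pb - pa, rev(fb))
  out <- x0 + cumsum(steps)
  out[length(out)] <- x1
  c(x0, out)
}

build_axis_divisions <- function(breaks, hfun) {
  breaks <- sort(unique(round(breaks, 9)))
  out <- breaks[1]
  for (i in seq_len(length(breaks) - 1)) {
    seg <- grade_interval(breaks[i], breaks[i + 1], hfun)
    out <- c(out, seg[-1])
  }
  unique(out)
}

dist_to_interval <- function(x, lo, hi) pmax(0, pmax(lo - x, x - hi))
dist_to_points <- function(x, pts) {
  apply(abs(outer(x, pts, "-")), 1, min)
}

# Pick the O-grid square half-side: nominally r + gap/2, kept inside the fat
# layer and nudged/snapped away from grid breakpoints so no sliver columns
# appear.
resolve_square_half <- function(a_nom, lo, hi, xb, yb, cy, tol = 0.08) {
  clash <- function(a) {
    d <- abs(c(xb - a, xb + a, yb - (cy - a), yb - (cy + a)))
    d <- d[d > 1e-9]            # exact coincidences are merged, not clashes
    if (length(d) == 0) Inf else min(d)
  }
  cand <- c(a_nom,
            abs(xb), abs(yb - cy),                 # snap to an existing break
            a_nom + seq(-0.3, 0.3, by = 0.05))
  cand <- cand[cand > lo & cand <= hi]
  for (a in cand) if (clash(a) >= tol) return(a)
  a_nom
}

split_quads <- function(nodes, q, prefer13 = NULL) {
  # q: k x 4 matrix of node ids in cyclic order; split along the shorter
  # diagonal. Near-ties (rectangles) take `prefer13` so a mirror-symmetric
  # quad layout yields a mirror-symmetric triangulation.
  d13 <- rowSums((nodes[q[, 1], , drop = FALSE] - nodes[q[, 3], , drop = FALSE])^2)
  d24 <- rowSums((nodes[q[, 2], , drop = FALSE] - nodes[q[, 4], , drop = FALSE])^2)
  tie <- abs(d13 - d24) <= 1e-9 * (d13 + d24)
  use13 <- d13 < d24
  if (is.null(prefer13)) prefer13 <- TRUE
  use13[tie] <- rep_len(prefer13, nrow(q))[tie]
  tri <- rbind(
    cbind(q[use13, 1], q[use13, 2], q[use13, 3]),
    cbind(q[use13, 1], q[use13, 3], q[use13, 4]),
    cbind(q[!use13, 1], q[!use13, 2], q[!use13, 4]),
    cbind(q[!use13, 2], q[!use13, 3], q[!use13, 4])
  )
  list(tri = tri, use13 = use13)
}

# region vector matching split_quads()'s rbind layout
split_regions <- function(reg, use13) {
  c(reg[use13], reg[use13], reg[!use13], reg[!use13])
}

signed_area <- function(nodes, tri) {
  p1 <- nodes[tri[, 1], , drop = FALSE]
  p2 <- nodes[tri[, 2], , drop = FALSE]
  p3 <- nodes[tri[, 3], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

# Assemble a pef_mesh from node coordinates (mm), triangles and per-triangle
# regions; tags exterior edges with `exterior_tagger(xm, ym)` and interface
# edges between named region pairs.
finish_mesh <- function(nodes_mm, tri, region, geom = NULL,
                        exterior_tagger = NULL) {
  # drop unreferenced nodes (grid points swallowed by the O-grid square)
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(nodes_mm)); remap[used] <- seq_along(used)
  nodes_mm <- nodes_mm[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3)

  sa <- signed_area(nodes_mm, tri)
  if (any(abs(sa) < 1e-12))
    stop("degenerate triangle produced at (",
         paste(round(colMeans(nodes_mm[tri[which.min(abs(sa)), ], ]), 4),
               collapse = ", "), ") mm")
  flip <- sa < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]

  # edge table: exterior edges (one triangle) and region interfaces
  e_all <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e_reg <- rep(region, 3)
  key <- paste(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  first <- !duplicated(key)
  cnt <- table(key)[key[first]]
  e1 <- e_all[first, , drop = FALSE]
  r1 <- e_reg[first]
  r2 <- rep(NA_character_, sum(first))
  dup_idx <- which(duplicated(key))
  m2 <- match(key[dup_idx], key[first])
  r2[m2] <- e_reg[dup_idx]

  tag <- rep(NA_character_, nrow(e1))
  ext <- as.integer(cnt) == 1L
  if (!is.null(exterior_tagger) && any(ext)) {
    mx <- 0.5 * (nodes_mm[e1[ext, 1], 1] + nodes_mm[e1[ext, 2], 1])
    my <- 0.5 * (nodes_mm[e1[ext, 1], 2] + nodes_mm[e1[ext, 2], 2])
    tag[ext] <- exterior_tagger(mx, my)
  }
  iface <- function(a, b)
    !ext & ((r1 == a & r2 == b) | (r1 == b & r2 == a))
  tag[iface("electrode_metal", "saline")] <- "electrode_surface"
  tag[iface("electrode_metal", "catheter_body")] <- "electrode_surface"
  tag[iface("electrode_metal", "fat")] <- "electrode_surface"
  tag[iface("fat", "stent")] <- "artery_wall"
  tag[iface("fat", "artery_lumen")] <- "artery_wall"
  tag[iface("stent", "artery_lumen")] <- "stent_inner_wall"
  tag[iface("myocardium", "blood_chamber")] <- "endocardial_wall"
  keep <- !is.na(tag)
  edges <- data.frame(n1 = e1[keep, 1], n2 = e1[keep, 2], tag = tag[keep],
                      stringsAsFactors = FALSE)

  m <- structure(list(nodes = nodes_mm * 1e-3,   # metres
                      tri = tri, region = region, edges = edges,
                      geom = geom, cache = new.env(parent = emptyenv())),
                 class = "pef_mesh")
  m$areas <- abs(signed_area(m$nodes, m$tri))    # m^2
  m
}

#' Generate the study mesh for a geometry
#'
#' Builds the graded conforming triangulation described above. The stent
#' annulus is always resolved by at least `n_stent` (>= 2) element layers
#' across its wall; electrode edges and the artery wall carry the finest
#' sizing.
#'
#' @param geom a [build_geometry()] result.
#' @param sizing a [mesh_sizing()] profile.
#' @return an object of class `pef_mesh`: `nodes` (metres), `tri` (node index
#'   triples, counter-clockwise), `region` (tag per triangle), `edges`
#'   (tagged boundary/interface edges), `areas` (m^2 per triangle), `geom`.
#' @export
generate_mesh <- function(geom, sizing = mesh_sizing()) {
  stopifnot(inherits(geom, "pef_geometry"))
  cfg <- geom$config
  W <- cfg$domain_width; H <- cfg$domain_height
  sal <- cfg$saline_thickness; F <- cfg$fat_thickness
  myo <- cfg$myocardium_thickness; eh <- cfg$electrode_height
  xw <- W / 2; ybot <- H - sal
  dev <- cfg$device_diameter / 2
  el <- cfg$electrode_length / 2
  hw <- cfg$hole_width / 2
  ar <- geom$artery
  s <- sizing

  xb <- c(-xw, -dev, -el, -hw, hw, el, dev, xw)
  yb <- c(-sal, -eh, 0, F, F + myo, ybot)

  a_half <- NULL
  if (!is.null(ar)) {
    g <- cfg$electrode_artery_gap
    a_nom <- ar$r_out + 0.5 * min(g, F - g - 2 * ar$r_out)
    a_half <- resolve_square_half(a_nom, lo = ar$r_out + 0.3 * s$h_edge,
                                  hi = min(ar$cy, F - ar$cy) - 1e-6,
                                  xb = xb, yb = yb, cy = ar$cy,
                                  tol = 1.2 * s$h_edge)
    xb <- c(xb, -a_half, a_half)
    yb <- c(yb, ar$cy - a_half, ar$cy + a_half)
  }

  h_x <- function(x) {
    h <- pmin(s$h_edge + s$slope * dist_to_points(x, c(-el, -hw, hw, el)),
              s$h_fine + s$slope * dist_to_interval(x, -dev, dev))
    if (!is.null(ar))
      h <- pmin(h, s$h_edge + s$slope * dist_to_interval(x, -a_half, a_half))
    pmin(h, s$h_coarse)
  }
  h_y <- function(y) {
    h <- pmin(s$h_edge + s$slope * dist_to_interval(y, -eh, 0),
              s$h_fat + s$slope * dist_to_interval(y, -sal, F),
              s$h_myo + s$slope * dist_to_interval(y, F, F + myo))
    if (!is.null(ar))
      h <- pmin(h, s$h_edge + s$slope *
                     dist_to_interval(y, ar$cy - a_half, ar$cy + a_half))
    pmin(h, s$h_coarse)
  }

  xdiv <- build_axis_divisions(xb, h_x)
  ydiv <- build_axis_divisions(yb, h_y)
  nx <- length(xdiv); ny <- length(ydiv)

  # tensor grid nodes, id = (j - 1) * nx + i
  nodes <- cbind(rep(xdiv, ny), rep(ydiv, each = nx))
  gid <- function(i, j) (j - 1L) * nx + i

  ii <- rep(seq_len(nx - 1), ny - 1)
  jj <- rep(seq_len(ny - 1), each = nx - 1)
  xc <- 0.5 * (xdiv[ii] + xdiv[ii + 1])
  yc <- 0.5 * (ydiv[jj] + ydiv[jj + 1])

  keep <- rep(TRUE, length(ii))
  if (!is.null(ar))
    keep <- !(xc > -a_half & xc < a_half &
              yc > ar$cy - a_half & yc < ar$cy + a_half)

  # classify cells by centre against the region rectangles
  cell_region <- rep(NA_character_, length(ii))
  for (k in seq_len(nrow(geom$rects))) {
    rr <- geom$rects[k, ]
    inr <- xc >= rr$x0 & xc <= rr$x1 & yc >= rr$y0 & yc <= rr$y1 &
      is.na(cell_region)
    cell_region[inr] <- rr$region
  }
  if (any(is.na(cell_region[keep])))
    stop("internal: unclassified grid cell")

  q <- cbind(gid(ii, jj), gid(ii + 1L, jj), gid(ii + 1L, jj + 1L),
             gid(ii, jj + 1L))[keep, , drop = FALSE]
  qreg <- cell_region[keep]
  sq <- split_quads(nodes, q, prefer13 = xc[keep] >= 0)
  tri <- sq$tri
  region <- split_regions(qreg, sq$use13)

  if (!is.null(ar)) {
    og <- build_ogrid(nodes, xdiv, ydiv, nx, ar, a_half, s)
    nodes <- og$nodes
    tri <- rbind(tri, og$tri)
    region <- c(region, og$region)
  }

  exterior_tagger <- function(mx, my) {
    tol <- 1e-6
    out <- rep(NA_character_, length(mx))
    out[abs(my - (-sal)) < tol] <- "air_top"
    out[abs(my - ybot) < tol] <- "dispersive_pad"
    out[abs(abs(mx) - xw) < tol] <- "lateral"
    out
  }
  finish_mesh(nodes, tri, region, geom = geom,
              exterior_tagger = exterior_tagger)
}

# O-grid filling of the artery square: transition band (fat), optional stent
# annulus, lumen rings + centre fan. Returns extended node table plus the new
# triangles/regions.
build_ogrid <- function(nodes, xdiv, ydiv, nx, ar, a_half, s) {
  cx <- ar$cx; cy <- ar$cy
  xs <- xdiv[xdiv >= cx - a_half - 1e-9 & xdiv <= cx + a_half + 1e-9]
  ys <- ydiv[ydiv >= cy - a_half - 1e-9 & ydiv <= cy + a_half + 1e-9]
  gidx <- function(x, y) {
    i <- match(round(x, 9), round(xdiv, 9))
    j <- match(round(y, 9), round(ydiv, 9))
    (j - 1L) * nx + i
  }
  per <- rbind(
    cbind(xs, cy - a_half), cbind(xs, cy + a_half),
    cbind(cx - a_half, ys), cbind(cx + a_half, ys))
  per <- per[!duplicated(round(per, 9)), , drop = FALSE]
  ang <- atan2(per[, 2] - cy, per[, 1] - cx)
  ord <- order(ang)
  per <- per[ord, , drop = FALSE]
  theta <- ang[ord]
  N <- nrow(per)
  per_id <- gidx(per[, 1], per[, 2])

  new_nodes <- list()
  n0 <- nrow(nodes)
  add_ring <- function(pts) {
    ids <- n0 + length(unlist(new_nodes)) / 2 + seq_len(nrow(pts))
    new_nodes[[length(new_nodes) + 1L]] <<- pts
    as.integer(ids)
  }
  ring_at <- function(r) cbind(cx + r * cos(theta), cy + r * sin(theta))

  tri <- list(); region <- list()
  emit <- function(ring_in, ring_out, reg) {
    jn <- c(seq_len(N)[-1], 1L)
    q <- cbind(ring_in, ring_in[jn], ring_out[jn], ring_out)
    all_nodes <- rbind(nodes, do.call(rbind, new_nodes))
    xmid <- (all_nodes[q[, 1], 1] + all_nodes[q[, 3], 1]) / 2
    t2 <- split_quads(all_nodes, q, prefer13 = xmid >= cx)$tri
    tri[[length(tri) + 1L]] <<- t2
    region[[length(region) + 1L]] <<- rep(reg, nrow(t2))
  }

  circle_ids <- add_ring(ring_at(ar$r_out))
  # transition band: circle -> square, linear blend, n_band layers
  prev <- circle_ids
  circ <- ring_at(ar$r_out)
  for (l in seq_len(s$n_band)) {
    if (l == s$n_band) ids <- per_id
    else ids <- add_ring(circ + (l / s$n_band) * (per - circ))
    emit(prev, ids, "fat")
    prev <- ids
  }

  inner_start <- ar$r_out
  lum_outer_ids <- circle_ids
  if (ar$stent) {
    radii <- seq(ar$r_out, ar$r_in, length.out = max(2, s$n_stent) + 1)[-1]
    prev <- circle_ids
    for (r in radii) {
      ids <- add_ring(ring_at(r))
      emit(ids, prev, "stent")
      prev <- ids
    }
    inner_start <- ar$r_in
    lum_outer_ids <- prev
  }

  chord <- 2 * pi * inner_start / N
  nr <- max(2L, as.integer(round(inner_start / chord)))
  prev <- lum_outer_ids
  for (k in seq_len(nr - 1)) {
    r <- inner_start * (nr - k) / nr
    ids <- add_ring(ring_at(r))
    emit(ids, prev, "artery_lumen")
    prev <- ids
  }
  centre <- add_ring(cbind(cx, cy))
  jn <- c(seq_len(N)[-1], 1L)
  fan <- cbind(rep(centre, N), prev, prev[jn])
  tri[[length(tri) + 1L]] <- fan
  region[[length(region) + 1L]] <- rep("artery_lumen", N)

  list(nodes = rbind(nodes, do.call(rbind, new_nodes)),
       tri = do.call(rbind, tri), region = unlist(region))
}

#' Per-region mesh areas, mm^2
#'
#' @param mesh a `pef_mesh`.
#' @return named numeric vector of summed triangle areas per region tag.
#' @export
region_areas <- function(mesh) {
  a <- tapply(mesh$areas, mesh$region, sum) * 1e6
  out <- as.numeric(a); names(out) <- names(a)
  out
}

#' Total length of a tagged edge chain, mm
#'
#' @param mesh a `pef_mesh`.
#' @param tag edge tag (e.g. "artery_wall", "dispersive_pad").
#' @return length in mm.
#' @export
boundary_length <- function(mesh, tag) {
  e <- mesh$edges[mesh$edges$tag == tag, , drop = FALSE]
  if (nrow(e) == 0) return(0)
  d <- mesh$nodes[e$n1, , drop = FALSE] - mesh$nodes[e$n2, , drop = FALSE]
  sum(sqrt(rowSums(d^2))) * 1e3
}

# barycentric containment test; returns indices of triangles containing p_m
containing_triangles <- function(mesh, p_m, tol = 1e-10) {
  nd <- mesh$nodes; tr <- mesh$tri
  bx <- cbind(nd[tr[, 1], 1], nd[tr[, 2], 1], nd[tr[, 3], 1])
  by <- cbind(nd[tr[, 1], 2], nd[tr[, 2], 2], nd[tr[, 3], 2])
  cand <- which(p_m[1] >= apply(bx, 1, min) - tol &
                p_m[1] <= apply(bx, 1, max) + tol &
                p_m[2] >= apply(by, 1, min) - tol &
                p_m[2] <= apply(by, 1, max) + tol)
  if (length(cand) == 0) return(integer(0))
  inside <- logical(length(cand))
  for (k in seq_along(cand)) {
    t <- tr[cand[k], ]
    v0 <- nd[t[2], ] - nd[t[1], ]; v1 <- nd[t[3], ] - nd[t[1], ]
    v2 <- p_m - nd[t[1], ]
    den <- v0[1] * v1[2] - v1[1] * v0[2]
    u <- (v2[1] * v1[2] - v1[1] * v2[2]) / den
    v <- (v0[1] * v2[2] - v2[1] * v0[2]) / den
    eps <- tol / max(abs(den), 1e-300)
    inside[k] <- u >= -1e-9 && v >= -1e-9 && u + v <= 1 + 1e-9
  }
  cand[inside]
}

#' Region tag at a point
#'
#' Finds the triangle containing the point; points on a shared edge take the
#' lowest containing triangle index (deterministic tie-break).
#'
#' @param mesh a `pef_mesh`.
#' @param point numeric length-2, coordinates in mm (same frame as the
#'   geometry: origin at the fat surface under the device centre, y down).
#' @return region tag (character).
#' @export
locate_region <- function(mesh, point) {
  hit <- containing_triangles(mesh, as.numeric(point) * 1e-3)
  if (length(hit) == 0)
    stop("point (", point[1], ", ", point[2], ") mm is outside the domain")
  mesh$region[min(hit)]
}

#' Structured rectangle mesh (benchmark fixtures)
#'
#' Tensor-product triangulation of `[x0, x1] x [y0, y1]` (mm). Regions are
#' assigned per cell by `region_fun(xc, yc)` (defaults to a single region).
#' Exterior edges are tagged `electrode_surface` (top, y = y0),
#' `dispersive_pad` (bottom, y = y1) and `lateral` (sides), matching the
#' solver's Dirichlet conventions so closed-form strip/slab problems can be
#' driven exactly like the study geometry.
#'
#' @param x0,x1,y0,y1 rectangle extents, mm (y down).
#' @param nx,ny cell counts.
#' @param region_fun vectorised classifier `f(xc, yc) -> tag`, or a single
#'   tag string.
#' @return a `pef_mesh`.
#' @export
structured_rect_mesh <- function(x0, x1, y0, y1, nx, ny, region_fun = "fat") {
  xdiv <- seq(x0, x1, length.out = nx + 1)
  ydiv <- seq(y0, y1, length.out = ny + 1)
  nxd <- length(xdiv)
  nodes <- cbind(rep(xdiv, length(ydiv)), rep(ydiv, each = nxd))
  ii <- rep(seq_len(nx), ny); jj <- rep(seq_len(ny), each = nx)
  gid <- function(i, j) (j - 1L) * nxd + i
  q <- cbind(gid(ii, jj), gid(ii + 1L, jj), gid(ii + 1L, jj + 1L),
             gid(ii, jj + 1L))
  xc <- 0.5 * (xdiv[ii] + xdiv[ii + 1]); yc <- 0.5 * (ydiv[jj] + ydiv[jj + 1])
  reg <- if (is.function(region_fun)) region_fun(xc, yc)
         else rep(region_fun, length(xc))
  sq <- split_quads(nodes, q, prefer13 = xc >= (x0 + x1) / 2)
  tri <- sq$tri
  region <- split_regions(reg, sq$use13)
  tagger <- function(mx, my) {
    out <- rep(NA_character_, length(mx))
    out[abs(my - y0) < 1e-9] <- "electrode_surface"
    out[abs(my - y1) < 1e-9] <- "dispersive_pad"
    out[abs(mx - x0) < 1e-9 | abs(mx - x1) < 1e-9] <- "lateral"
    out
  }
  finish_mesh(nodes, tri, region, exterior_tagger = tagger)
}

#' Disc mesh with an embedded annulus (shielding fixture)
#'
#' Concentric-ring triangulation of a disc of radius `R` (mm) with region
#' tags `core` (r < r1), `shell` (r1..r2) and `outside` (r2..R); the outer
#' circle's exterior edges are tagged `outer`. Used for the analytic
#' annular-shield benchmark.
#'
#' @param R,r1,r2 radii in mm (0 < r1 < r2 < R).
#' @param N angular divisions.
#' @return a `pef_mesh`.
#' @export
disc_annulus_mesh <- function(R = 10, r1 = 2, r2 = 2.4, N = 96) {
  stopifnot(0 < r1, r1 < r2, r2 < R)
  theta <- seq(0, 2 * pi, length.out = N + 1)[-(N + 1)]
  hfun_out <- function(r) pmax(0.3 * (r2 - r1), pmin(2 * pi * pmax(r, r2) / N, (R - r2) / 2))
  hfun_in <- function(r) pmax(0.3 * (r2 - r1), pmin(2 * pi * pmax(r, 0.2 * r1) / N, r1 / 2))
  radii_out <- rev(build_axis_divisions(c(r2, R), hfun_out))   # R .. r2
  radii_shell <- seq(r2, r1, length.out = 3)
  inner <- build_axis_divisions(c(0.35 * r1, r1), hfun_in)     # fan core below
  radii_in <- rev(inner)
  radii <- c(radii_out, radii_shell[-1], radii_in[-1])
  reg_of <- function(r_mid) if (r_mid > r2) "outside" else if (r_mid > r1) "shell" else "core"

  rings <- lapply(radii, function(r) cbind(r * cos(theta), r * sin(theta)))
  nodes <- do.call(rbind, rings)
  nodes <- rbind(nodes, c(0, 0))
  centre <- nrow(nodes)
  ids <- function(k) (k - 1L) * N + seq_len(N)
  jn <- c(seq_len(N)[-1], 1L)
  tri <- list(); region <- list()
  for (k in seq_len(length(radii) - 1)) {
    o <- ids(k); i <- ids(k + 1)
    q <- cbind(i, i[jn], o[jn], o)
    t2 <- split_quads(nodes, q, prefer13 = nodes[q[, 1], 1] >= 0)$tri
    tri[[k]] <- t2
    region[[k]] <- rep(reg_of(0.5 * (radii[k] + radii[k + 1])), nrow(t2))
  }
  i <- ids(length(radii))
  tri[[length(tri) + 1]] <- cbind(rep(centre, N), i, i[jn])
  region[[length(region) + 1]] <- rep("core", N)
  tagger <- function(mx, my) rep("outer", length(mx))
  finish_mesh(nodes, do.call(rbind, tri), unlist(region),
              exterior_tagger = tagger)
}
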