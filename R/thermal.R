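# Transient bioheat solve: rho c dT/dt = div(k grad T) + Q on the thermal
# subdomain (blood pools replaced by convective Robin walls), backward Euler
# in time. Perfusion and metabolic source terms are zero in this model.

#' Joule heat source
#'
#' Q = sigma |E|^2, W/m^3 per element. Zero wherever the field is zero (off
#' segments of the pulse train).
#'
#' @param sigma_elem per-element conductivity, S/m.
#' @param E_mag_elem per-element field magnitude, V/m.
#' @return volumetric power density per element, W/m^3.
#' @export
joule_source <- function(sigma_elem, E_mag_elem) sigma_elem * E_mag_elem^2

#' Robin (convective film) condition
#'
#' @param tag edge tag the condition applies to.
#' @param h film coefficient, W/(m^2 K) (>= 0).
#' @param T_inf far-field temperature, degrees C.
#' @return list of class `pef_robin`.
#' @export
robin_condition <- function(tag, h, T_inf) {
  stopifnot(h >= 0)
  structure(list(tag = tag, h = h, T_inf = T_inf), class = "pef_robin")
}

#' Thermal subdomain and its convective walls for a scenario
#'
#' The blood chamber and (when blood is taken as flowing) the artery lumen
#' are removed from the thermal solve and replaced by Robin conditions on
#' their walls: 1417 W/(m^2 K) at 37 C on the endocardial wall, 63.19
#' W/(m^2 K) at 37 C on the artery wall (no stent) or the stent inner wall
#' (stent present), and 20 W/(m^2 K) at 21 C against air on the top surface.
#'
#' The saline film is irrigation fluid: it is continuously infused through
#' the device hole and flows over the epicardium, so by default it is treated
#' as moving fluid and likewise excluded from the solid heat-conduction solve
#' (its interfaces are natural, i.e. adiabatic); `saline_flowing = FALSE`
#' keeps it in the solve as a static Joule-heated layer instead.
#'
#' @param mesh a `pef_mesh` built from the study geometry.
#' @param lumen_robin logical: apply the lumen film condition when the stent
#'   is present (blood flowing through the stented artery); if `FALSE` the
#'   lumen wall is insulated instead (lumen stays excluded either way).
#' @param saline_flowing logical: exclude the irrigated saline film from the
#'   thermal solve (default) or treat it as a static heated layer.
#' @return list with `elements` (indices into mesh triangles), `nodes`
#'   (participating node indices) and `robin` (list of [robin_condition()]).
#' @export
thermal_domain <- function(mesh, lumen_robin = TRUE, saline_flowing = TRUE) {
  excluded <- c("blood_chamber", "artery_lumen")
  if (saline_flowing) excluded <- c(excluded, "saline")
  elements <- which(!(mesh$region %in% excluded))
  nodes <- sort(unique(as.vector(mesh$tri[elements, ])))
  robin <- list(robin_condition("air_top", 20, 21),
                robin_condition("endocardial_wall", 1417, 37))
  has_artery <- !is.null(mesh$geom) && !is.null(mesh$geom$artery)
  if (has_artery) {
    if (mesh$geom$artery$stent) {
      if (lumen_robin)
        robin <- c(robin, list(robin_condition("stent_inner_wall", 63.19, 37)))
    } else {
      robin <- c(robin, list(robin_condition("artery_wall", 63.19, 37)))
    }
  }
  list(elements = elements, nodes = nodes, robin = robin)
}

# P1 mass matrix with density rho_elem (rho*c for the heat equation),
# restricted to the given elements, in global numbering. Lumped (row-sum)
# mass by default: together with backward Euler it preserves the discrete
# maximum principle on this mesh, so the temperature maximum cannot drift
# upward after the source switches off.
assemble_mass <- function(mesh, rho_elem, elements = seq_len(nrow(mesh$tri)),
                          lumped = TRUE) {
  g <- elem_geometry(mesh)
  A <- abs(g$A[elements])
  tr <- mesh$tri[elements, , drop = FALSE]
  rho <- rep_len(rho_elem, nrow(mesh$tri))[elements]
  n <- nrow(mesh$nodes)
  if (lumped) {
    d <- numeric(n)
    for (a in 1:3) d <- d + tabulate_add(tr[, a], rho * A / 3, n)
    return(Matrix::Diagonal(n, d))
  }
  w <- rho * A / 12
  ii <- jj <- xx <- vector("list", 9)
  k <- 1
  for (a in 1:3) for (b in 1:3) {
    ii[[k]] <- tr[, a]; jj[[k]] <- tr[, b]
    xx[[k]] <- w * ifelse(a == b, 2, 1)
    k <- k + 1
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(n, 2))
}

# stiffness restricted to an element subset (global numbering)
assemble_stiffness_sub <- function(mesh, coef_elem, elements) {
  g <- elem_geometry(mesh)
  tr <- mesh$tri[elements, , drop = FALSE]
  coef <- rep_len(coef_elem, nrow(mesh$tri))[elements]
  w <- coef / (4 * g$A[elements])
  ii <- jj <- xx <- vector("list", 9)
  k <- 1
  for (a in 1:3) for (b in 1:3) {
    ii[[k]] <- tr[, a]; jj[[k]] <- tr[, b]
    xx[[k]] <- w * (g$b[elements, a] * g$b[elements, b] +
                    g$c[elements, a] * g$c[elements, b])
    k <- k + 1
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(mesh$nodes), 2))
}

# Robin boundary matrix and constant load: h * integral(T) over tagged
# edges. Only edges with both end nodes inside the active thermal domain
# participate: an edge straddling an excluded region (e.g. the air-top edge
# of the flowing saline film next to the catheter cap) would otherwise leave
# an unbalanced one-node contribution behind after restriction.
robin_terms <- function(mesh, robin, nodes_in = NULL) {
  n <- nrow(mesh$nodes)
  R <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, n))
  f <- numeric(n)
  for (rc in robin) {
    e <- mesh$edges[mesh$edges$tag == rc$tag, , drop = FALSE]
    if (!is.null(nodes_in))
      e <- e[e$n1 %in% nodes_in & e$n2 %in% nodes_in, , drop = FALSE]
    if (nrow(e) == 0 || rc$h == 0) next
    d <- mesh$nodes[e$n1, , drop = FALSE] - mesh$nodes[e$n2, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    ii <- c(e$n1, e$n2, e$n1, e$n2)
    jj <- c(e$n1, e$n2, e$n2, e$n1)
    xx <- c(rc$h * len / 3, rc$h * len / 3, rc$h * len / 6, rc$h * len / 6)
    R <- R + Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
    f[e$n1] <- f[e$n1] + rc$h * rc$T_inf * len / 2
    f[e$n2] <- f[e$n2] + rc$h * rc$T_inf * len / 2
  }
  list(R = R, f = f)
}

#' Build a reusable implicit thermal stepper
#'
#' Assembles mass (rho c), conduction (k) and Robin terms on the thermal
#' subdomain and factorises the backward-Euler system matrix
#' `M/dt + K + R` once, so each step is a pair of triangular solves. The
#' system is unconditionally stable for any dt.
#'
#' @param mesh a `pef_mesh`.
#' @param domain a [thermal_domain()] result.
#' @param table material table.
#' @param dt time step, s (> 0).
#' @return object of class `pef_thermal_system`.
#' @export
thermal_system <- function(mesh, domain, table = material_table(), dt) {
  stopifnot(dt > 0)
  m <- nrow(mesh$tri)
  k_e <- rhoc_e <- numeric(m)
  for (tag in unique(mesh$region)) {
    pr <- material_for(tag, table)
    k_e[mesh$region == tag] <- pr$k
    rhoc_e[mesh$region == tag] <- pr$rho * pr$c
  }
  M <- assemble_mass(mesh, rhoc_e, domain$elements)
  K <- assemble_stiffness_sub(mesh, k_e, domain$elements)
  rt <- robin_terms(mesh, domain$robin, nodes_in = domain$nodes)
  act <- domain$nodes
  A <- (M / dt + K + rt$R)[act, act]
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  structure(list(mesh = mesh, domain = domain, dt = dt,
                 M = M[act, act], fac = fac, f_robin = rt$f[act],
                 act = act), class = "pef_thermal_system")
}

# element -> nodal load vector for a per-element volumetric source
source_load <- function(mesh, Q_elem, elements, n) {
  A <- abs(elem_geometry(mesh)$A[elements])
  tr <- mesh$tri[elements, , drop = FALSE]
  Q <- rep_len(Q_elem, nrow(mesh$tri))[elements]
  w <- Q * A / 3
  f <- numeric(n)
  for (a in 1:3) f <- f + tabulate_add(tr[, a], w, n)
  f
}

tabulate_add <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Advance the thermal state by one implicit step
#'
#' @param sys a [thermal_system()].
#' @param T_nodal full-length nodal temperature vector, degrees C (values on
#'   excluded nodes are carried through unchanged).
#' @param Q_elem per-element Joule source, W/m^3 (zero during off segments).
#' @return updated nodal temperature vector.
#' @export
advance_state <- function(sys, T_nodal, Q_elem = 0) {
  mesh <- sys$mesh
  act <- sys$act
  fQ <- source_load(mesh, Q_elem, sys$domain$elements, nrow(mesh$nodes))[act]
  rhs <- sys$M %*% T_nodal[act] / sys$dt + fQ + sys$f_robin
  Tn <- T_nodal
  Tn[act] <- as.numeric(Matrix::solve(sys$fac, rhs, system = "A"))
  Tn
}

#' One-off implicit bioheat step (assembles and factorises on the fly)
#'
#' Convenience wrapper over [thermal_system()] + [advance_state()] for single
#' steps and benchmark problems; the coupling driver uses the cached system.
#'
#' @inheritParams thermal_system
#' @param T_nodal nodal temperatures, degrees C.
#' @param Q_elem per-element source, W/m^3.
#' @export
advance <- function(mesh, domain, T_nodal, dt, Q_elem = 0,
                    table = material_table()) {
  advance_state(thermal_system(mesh, domain, table, dt), T_nodal, Q_elem)
}
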