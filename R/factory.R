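# Study matrix and analytic benchmark fixtures. Everything here is generated
# in code; no external inputs.

#' The full study matrix
#'
#' Five geometric configurations — no artery; artery without stent at 1 mm
#' and 0.25 mm electrode gaps; artery with stent at both gaps — each run
#' under the 100 us and 10 us inter-pulse-interval protocols: 10 scenarios.
#'
#' @param gaps_mm electrode-artery gaps, mm.
#' @param intervals_us inter-pulse intervals, us.
#' @return list of class `pef_study_matrix` containing [scenario()] objects
#'   with unique labels.
#' @export
study_scenarios <- function(gaps_mm = c(1.0, 0.25), intervals_us = c(100, 10)) {
  out <- list()
  for (iv in intervals_us) {
    proto <- pulse_train(interval = iv)
    out[[length(out) + 1]] <- scenario(geometry_config(), proto,
                                       label = sprintf("no_artery_%gus", iv))
    for (g in gaps_mm) {
      out[[length(out) + 1]] <- scenario(
        geometry_config(artery_present = TRUE, electrode_artery_gap = g),
        proto, label = sprintf("artery_%gmm_%gus", g, iv))
      out[[length(out) + 1]] <- scenario(
        geometry_config(artery_present = TRUE, stent_present = TRUE,
                        electrode_artery_gap = g),
        proto, label = sprintf("stent_%gmm_%gus", g, iv))
    }
  }
  names(out) <- vapply(out, function(s) s$label, "")
  if (anyDuplicated(names(out))) stop("internal: duplicate scenario labels")
  structure(out, class = c("pef_study_matrix", "list"))
}

#' Analytic shielding factor of a conducting annulus in a disc domain
#'
#' Closed-form series solution for a disc of radius `R_mm` (conductivity
#' `sig_m`) containing a concentric shell `r1..r2` of conductivity `sig_s`,
#' with the potential of a uniform field (phi = -E0 x) imposed on the outer
#' circle. Each region carries phi = (A r + B/r) cos(theta); matching
#' potential and normal current at the two interfaces gives a 5x5 linear
#' system whose core coefficient is the (uniform) interior field. Returns
#' |E_core| / E0.
#'
#' @param sig_m medium (and core) conductivity, S/m.
#' @param sig_s shell conductivity, S/m.
#' @param r1,r2,R_mm radii, mm.
#' @return dimensionless interior/applied field ratio.
#' @export
annulus_shield_ratio <- function(sig_m, sig_s, r1, r2, R_mm) {
  # The ratio is scale invariant, so radii are used in mm as given.
  # Unknowns: A1, A2, B2, A3, B3 (phi_i = (A_i r + B_i / r) cos theta); E0 = 1.
  R <- R_mm
  M <- rbind(
    c(r1, -r1, -1 / r1, 0, 0),                        # phi continuous at r1
    c(sig_m, -sig_s, sig_s / r1^2, 0, 0),             # J_r continuous at r1
    c(0, r2, 1 / r2, -r2, -1 / r2),                   # phi continuous at r2
    c(0, sig_s, -sig_s / r2^2, -sig_m, sig_m / r2^2), # J_r continuous at r2
    c(0, 0, 0, R, 1 / R))                             # phi = -E0 R at R
  rhs <- c(0, 0, 0, 0, -R)
  sc <- apply(abs(M), 1, max)                         # row equilibration
  sol <- solve(M / sc, rhs / sc)
  abs(sol[1])
}

#' Analytic benchmark fixtures
#'
#' Small problems with closed-form references, used as solver oracles:
#' \describe{
#'   \item{strip}{homogeneous 10 mm strip, 1000 V across: phi linear,
#'     |E| = 1000 V/cm, current sigma V/L per unit width.}
#'   \item{two_layer}{equal-thickness slabs (sigma 1 and 0.1 S/m) in series:
#'     interface potential V sigma_a/(sigma_a + sigma_b), fields inversely
#'     proportional to sigma.}
#'   \item{shield}{disc with a conducting annulus (contrast 1e8) in an
#'     imposed uniform field; reference ratio from
#'     [annulus_shield_ratio()].}
#'   \item{heated_block}{insulated block under uniform volumetric power:
#'     dT = Q t / (rho c), spatially uniform.}
#' }
#' The strip and slab use exact structured meshes (the piecewise-linear
#' solution is reproduced to machine precision there); the disc uses the
#' ring mesh of [disc_annulus_mesh()].
#'
#' @return named list of fixtures; each has `name`, `mesh`, `params` and
#'   `reference` values.
#' @export
toy_fixtures <- function() {
  V <- 1000; L <- 10 # mm
  strip_mesh <- structured_rect_mesh(0, 10, 0, L, nx = 6, ny = 12, "fat")
  strip <- list(
    name = "strip", mesh = strip_mesh,
    params = list(V = V, L_mm = L, width_mm = 10, sigma = 1),
    reference = list(E_mag = V / (L * 1e-3),             # 1e5 V/m = 1000 V/cm
                     current_per_width = 1 * V / (L * 1e-3) * 10e-3,
                     phi_at = function(y_mm) V * (1 - y_mm / L)))

  sa <- 1; sb <- 0.1
  two_mesh <- structured_rect_mesh(0, 10, 0, L, nx = 6, ny = 16,
                                   function(xc, yc) ifelse(yc < L / 2,
                                                           "layer_a", "layer_b"))
  phi_int <- V * sa / (sa + sb)
  two_layer <- list(
    name = "two_layer", mesh = two_mesh,
    params = list(V = V, L_mm = L, sigma_a = sa, sigma_b = sb),
    reference = list(phi_interface = phi_int,
                     E_a = (V - phi_int) / (L / 2 * 1e-3),
                     E_b = phi_int / (L / 2 * 1e-3)))

  shield <- list(
    name = "shield", mesh = disc_annulus_mesh(R = 10, r1 = 2, r2 = 2.4, N = 96),
    params = list(sig_m = 1, sig_s = 1e8, r1 = 2, r2 = 2.4, R = 10, E0 = 1e4),
    reference = list(ratio = annulus_shield_ratio(1, 1e8, 2, 2.4, 10)))

  fat <- material_for("fat")
  Qv <- 4.38e8; t_s <- 1e-3
  heated_block <- list(
    name = "heated_block",
    mesh = structured_rect_mesh(0, 4, 0, 4, nx = 6, ny = 6, "fat"),
    params = list(Q = Qv, t_s = t_s, rho = fat$rho, c = fat$c),
    reference = list(dT = Qv * t_s / (fat$rho * fat$c)))

  list(strip = strip, two_layer = two_layer, shield = shield,
       heated_block = heated_block)
}
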