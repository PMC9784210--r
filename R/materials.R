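# Material property set and the field/temperature dependent conductivity law.

#' Material properties of one model region
#'
#' Electrical and thermal constants for one region of the model. `sigma0` and
#' `sigma1` are the pre- and post-electroporation electrical conductivities
#' (low/high frequency limits); for materials without cell membranes (metals,
#' polymer, saline) `sigma1 == sigma0` and the electroporation sigmoid is
#' disabled. `temp_coeff` is the per-degree multiplier applied as
#' `temp_coeff^(T - 37)` (1.02 for the aqueous/biological media, 1 otherwise).
#'
#' @param sigma0 electrical conductivity before electroporation, S/m.
#' @param sigma1 electrical conductivity after electroporation, S/m.
#' @param k thermal conductivity, W/(m K).
#' @param rho density, kg/m^3.
#' @param c specific heat, J/(kg K).
#' @param temp_coeff temperature multiplier base per degree Celsius.
#' @param electroporation_dependent logical; apply the field sigmoid?
#' @return an object of class `pef_material`.
#' @export
material_properties <- function(sigma0, sigma1 = sigma0, k, rho, c,
                                temp_coeff = 1, electroporation_dependent = FALSE) {
  stopifnot(sigma0 > 0, sigma1 > 0, k > 0, rho > 0, c > 0, temp_coeff > 0)
  if (electroporation_dependent && sigma1 < sigma0)
    stop("sigma1 must be >= sigma0 for electroporation-dependent materials")
  structure(list(sigma0 = sigma0, sigma1 = sigma1, k = k, rho = rho, c = c,
                 temp_coeff = temp_coeff,
                 electroporation_dependent = electroporation_dependent),
            class = "pef_material")
}

#' Sigmoid electroporation conductivity model
#'
#' Parameters of the sigmoid transition of electrical conductivity with field
#' magnitude: sigma(E) = sigma0 + (sigma1 - sigma0) / (1 + prefactor *
#' exp(-(|E| - E_center)/E_scale)). The default centre (58 kV/m = 580 V/cm)
#' and scale (3 kV/m) place the transition around the electroporation
#' threshold of cardiac tissue.
#'
#' @param E_center field magnitude at the sigmoid centre, V/m.
#' @param E_scale sigmoid width, V/m.
#' @param prefactor dimensionless factor multiplying the exponential.
#' @param T_ref reference temperature for the thermal factor, degrees C.
#' @return an object of class `pef_sigmoid`.
#' @export
sigmoid_model <- function(E_center = 58000, E_scale = 3000, prefactor = 10,
                          T_ref = 37) {
  stopifnot(E_scale > 0, prefactor > 0)
  structure(list(E_center = E_center, E_scale = E_scale,
                 prefactor = prefactor, T_ref = T_ref),
            class = "pef_sigmoid")
}

#' Effective electrical conductivity at a given field and temperature
#'
#' Evaluates sigma(E, T) = [sigma0 + (sigma1 - sigma0) / (1 + 10 *
#' exp(-(|E| - 58000)/3000))] * temp_coeff^(T - 37). The sigmoid term is
#' applied only for electroporation-dependent materials; otherwise the base is
#' `sigma0`. Vectorised over `E_mag` and `T`.
#'
#' @param props a [material_properties()] object.
#' @param model a [sigmoid_model()] object.
#' @param E_mag electric field magnitude, V/m (>= 0).
#' @param T_C temperature, degrees Celsius.
#' @return conductivity in S/m, same length as `E_mag`/`T_C` recycled.
#' @export
effective_conductivity <- function(props, model = sigmoid_model(), E_mag, T_C = 37) {
  if (any(E_mag < 0)) stop("E_mag must be non-negative")
  n <- max(length(E_mag), length(T_C))
  E_mag <- rep_len(E_mag, n)
  T_C <- rep_len(T_C, n)
  base <- if (props$electroporation_dependent) {
    # clamp the exponent: exp() overflows for very low fields otherwise
    z <- pmin((model$E_center - E_mag) / model$E_scale, 700)
    props$sigma0 + (props$sigma1 - props$sigma0) / (1 + model$prefactor * exp(z))
  } else {
    props$sigma0
  }
  base * props$temp_coeff^(T_C - model$T_ref)
}

#' Default material table
#'
#' Returns the full property set of the model regions: Pt-Ir electrode,
#' polyurethane catheter body, stainless-steel stent, isotonic saline,
#' epicardial fat, myocardium and blood. Fat, myocardium and blood carry the
#' electroporation sigmoid; saline, fat, myocardium and blood carry the
#' +2 %/degC temperature coefficient. The polyurethane thermal conductivity
#' is 0.023 W/(m K).
#'
#' @return named list of [material_properties()] keyed by region tag:
#'   `electrode_metal`, `catheter_body`, `stent`, `saline`, `fat`,
#'   `myocardium`, `blood_chamber`, `artery_lumen` (same blood properties as
#'   the chamber).
#' @export
material_table <- function() {
  blood <- material_properties(0.7, 0.748, k = 0.52, rho = 1050, c = 3617,
                               temp_coeff = 1.02, electroporation_dependent = TRUE)
  list(
    electrode_metal = material_properties(4.6e6, k = 71, rho = 21500, c = 132),
    catheter_body   = material_properties(1e-5, k = 0.023, rho = 1440, c = 1050),
    stent           = material_properties(7.4e6, k = 15, rho = 8000, c = 480),
    saline          = material_properties(1.392, k = 0.628, rho = 980, c = 4184,
                                          temp_coeff = 1.02),
    fat             = material_properties(0.0377, 0.0438, k = 0.21, rho = 911,
                                          c = 2348, temp_coeff = 1.02,
                                          electroporation_dependent = TRUE),
    myocardium      = material_properties(0.0537, 0.281, k = 0.56, rho = 1081,
                                          c = 3686, temp_coeff = 1.02,
                                          electroporation_dependent = TRUE),
    blood_chamber   = blood,
    artery_lumen    = blood
  )
}

#' Look up material properties for a region tag
#'
#' @param tag region tag (see [material_table()]).
#' @param table material table; defaults to [material_table()].
#' @return a [material_properties()] object.
#' @export
material_for <- function(tag, table = material_table()) {
  if (!tag %in% names(table)) stop("unknown region tag: ", tag)
  table[[tag]]
}
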