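# Transport parameter sets, boundary model and unit constants.

# 1 mm Hg in Pa; used to convert pressure drops to SI inside the flow solver
MMHG_PA <- 133.322

#' Radius-dependent inlet boundary model
#'
#' Inlet pO2 assigned to vessels entering the simulated domain:
#' `min(p0 + slope * radius, pmax)`. Larger vessels enter with higher pO2 up
#' to a cap.
#'
#' @param p0 Minimum inlet boundary pO2, mm Hg.
#' @param slope Rate of change of boundary pO2 with vessel radius, mm Hg/um.
#' @param pmax Maximum inlet boundary pO2, mm Hg.
#' @return An object of class `boundary_model`.
#' @export
boundary_model <- function(p0 = 50, slope = 1, pmax = 100) {
  stopifnot(p0 > 0, p0 <= pmax, slope >= 0)
  structure(list(p0 = p0, slope = slope, pmax = pmax),
            class = "boundary_model")
}

#' @export
print.boundary_model <- function(x, ...) {
  cat(sprintf("<boundary_model> pO2 = min(%.3g + %.3g r, %.3g) mm Hg\n",
              x$p0, x$slope, x$pmax))
  invisible(x)
}

#' Inlet pO2 at the domain boundary
#'
#' Evaluates the radius-dependent linear boundary model
#' `min(p0 + slope * radius, pmax)`.
#'
#' @param radius Vessel radius, um (> 0). Vectorised.
#' @param bc A [boundary_model()].
#' @return Inlet pO2, mm Hg.
#' @export
boundary_inlet_po2 <- function(radius, bc = boundary_model()) {
  stopifnot(all(radius > 0))
  pmin(bc$p0 + bc$slope * radius, bc$pmax)
}

#' Species-specific tissue and transport parameters
#'
#' Physical constants of the oxygen transport model for a mouse or human
#' host. Diffusivities are stated in cm^2/s as usual in the physiology
#' literature and converted to um^2/s internally; solubilities in uM/mm Hg;
#' maximum Michaelis-Menten consumption rates in uM/s and Michaelis constants
#' in mm Hg. Mouse host tissue consumes O2 roughly three times faster than
#' human host tissue; tumor parameters are shared.
#'
#' @param species `"mouse"` or `"human"`.
#' @param sherwood Wall Sherwood number: a single number (default 3.66, the
#'   classical constant-wall-condition value) or a function
#'   `f(radius, hct, c_hboc)` returning one (see [fit_sherwood()]).
#' @param segment_step Axial integration step along vessel segments, um.
#' @param outer_tol Outer-loop convergence tolerance on the tissue field,
#'   mm Hg.
#' @param max_outer_iter Maximum outer coupling iterations.
#' @param relaxation Under-relaxation factor for the tissue field update,
#'   in (0, 1].
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(species = c("mouse", "human"),
                             sherwood = 3.66,
                             segment_step = 10,
                             outer_tol = 0.01,
                             max_outer_iter = 200,
                             relaxation = 0.5) {
  species <- match.arg(species)
  stopifnot(segment_step > 0, outer_tol > 0, max_outer_iter >= 1,
            relaxation > 0, relaxation <= 1)
  structure(list(
    species       = species,
    alpha_plasma  = 1.71,                 # uM / mm Hg
    alpha_tissue  = 1.54,                 # uM / mm Hg
    d_plasma      = 1.85e-5 * 1e8,        # cm^2/s -> um^2/s
    d_tissue      = 6.30e-6 * 1e8,        # cm^2/s -> um^2/s
    v_m_host      = if (species == "mouse") 45 else 15,  # uM/s
    v_m_tumor     = 80,                   # uM/s
    k_m_host      = 5,                    # mm Hg
    k_m_tumor     = 2,                    # mm Hg
    sherwood      = sherwood,
    segment_step  = segment_step,
    outer_tol     = outer_tol,
    max_outer_iter = max_outer_iter,
    relaxation    = relaxation
  ), class = "transport_params")
}

#' Host blood composition for a species
#'
#' Baseline (unsupplemented) blood: HCT 0.45, no HBOC, species RBC carrier,
#' plasma viscosity 1.26 cP.
#'
#' @param species `"mouse"` or `"human"`.
#' @return A [blood_composition()].
#' @export
host_blood <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  blood_composition(
    hct = 0.45,
    rbc_carrier = carrier_preset(if (species == "mouse") "mouse_rbc" else "human_rbc")
  )
}

sherwood_value <- function(params, radius, hct = 0, c_hboc = 0) {
  sh <- params$sherwood
  if (is.function(sh)) sh(radius, hct, c_hboc) else sh
}
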