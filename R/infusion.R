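# Infusion scenarios: top-load and exchange dosing of T-State / R-State
# polymerized hemoglobin or a non-O2-carrying control, with hemodilution,
# viscosity and shear-sensitivity changes, and the extraction-conserving
# recalibration of the inlet boundary model.

#' Infusion scenario presets
#'
#' The seven simulated treatment conditions: an unsupplemented baseline,
#' top-load (HCT 0.45 -> 0.41) and exchange (HCT 0.45 -> 0.35) infusion of a
#' non-O2-carrying control, 35:1 T-State PolyhHb (P50 34 mm Hg, n = 1) and
#' 30:1 R-State PolyhHb (P50 1.3 mm Hg, n = 1). Each scenario carries its
#' plasma viscosity, HBOC dose (mg/mL), and the shear-stimulus attenuation
#' `k_s` that emulates NO scavenging by cell-free hemoglobin.
#'
#' @return A tibble with one row per scenario: `name`, `dose`, `material`,
#'   `hct`, `plasma_viscosity` (cP), `c_hboc_mass` (mg/mL), `hboc_p50`
#'   (mm Hg), `hboc_n`, `k_s`.
#' @export
infusion_scenarios <- function() {
  tibble::tribble(
    ~name,                ~dose,      ~material,  ~hct, ~plasma_viscosity,
    ~c_hboc_mass, ~hboc_p50, ~hboc_n, ~k_s,
    "baseline",           "none",     "none",     0.45, 1.26, 0,  NA,  NA, 1.00,
    "topload_control",    "topload",  "control",  0.41, 1.26, 0,  NA,  NA, 1.00,
    "topload_t_state",    "topload",  "t_state",  0.41, 1.35, 8,  34,  1,  0.96,
    "topload_r_state",    "topload",  "r_state",  0.41, 1.32, 8,  1.3, 1,  0.95,
    "exchange_control",   "exchange", "control",  0.35, 1.26, 0,  NA,  NA, 1.00,
    "exchange_t_state",   "exchange", "t_state",  0.35, 1.51, 14, 34,  1,  0.95,
    "exchange_r_state",   "exchange", "r_state",  0.35, 1.47, 14, 1.3, 1,  0.90
  )
}

scenario_row <- function(name) {
  tab <- infusion_scenarios()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1) {
    stop("unknown infusion scenario '", name, "'; see infusion_scenarios()",
         call. = FALSE)
  }
  row
}

#' Apply an infusion scenario to a baseline blood composition
#'
#' Returns the post-infusion [blood_composition()]: the scenario's
#' hematocrit and plasma viscosity, and (for PolyhHb scenarios) an HBOC
#' carrier with the scenario's P50 and cooperativity at the heme molarity
#' converted from the mass dose. The baseline scenario returns the input
#' unchanged.
#'
#' @param baseline The unsupplemented [blood_composition()] (HCT 0.45, no
#'   HBOC).
#' @param scenario Scenario name (see [infusion_scenarios()]) or a one-row
#'   scenario tibble.
#' @return A [blood_composition()].
#' @export
apply_scenario <- function(baseline, scenario) {
  row <- if (is.character(scenario)) scenario_row(scenario) else scenario
  if (row$name == "baseline") return(baseline)
  hboc <- NULL
  c_hboc <- 0
  if (row$c_hboc_mass > 0) {
    hboc <- oxygen_carrier(paste0("polyhhb_", row$material),
                           p50 = row$hboc_p50, n_hill = row$hboc_n)
    c_hboc <- hboc_heme_concentration(row$c_hboc_mass)
  }
  blood_composition(
    hct = row$hct,
    rbc_carrier = baseline$rbc_carrier,
    hboc_carrier = hboc,
    c_hboc = c_hboc,
    c_hb_rbc = baseline$c_hb_rbc,
    alpha_plasma = baseline$alpha_plasma,
    plasma_viscosity = row$plasma_viscosity)
}

#' Upstream oxygen extraction implied by the boundary model
#'
#' O2 extracted from blood between the lungs and a vessel of radius `r`
#' entering the simulated domain: the blood O2 content at the maximum
#' boundary pO2 minus the content at the radius-dependent inlet pO2.
#' Zero for radii large enough that the boundary model caps at its maximum.
#'
#' @param radius Vessel radius, um. Vectorised.
#' @param bc A [boundary_model()].
#' @param comp A [blood_composition()].
#' @return Extraction, uM.
#' @export
upstream_extraction <- function(radius, bc, comp) {
  stopifnot(all(radius > 0))
  blood_o2_content(bc$pmax, comp) -
    blood_o2_content(boundary_inlet_po2(radius, bc), comp)
}

#' Recalibrate the boundary model after an infusion
#'
#' Post-infusion blood carries less O2 per volume (hemodilution) but may
#' carry some in the HBOC; holding the upstream tissue's O2 extraction fixed
#' therefore changes the pO2 at which blood arrives. For each sampled radius
#' this solves `OE_baseline(r) = OE_enhanced(pO2, r)` for the arriving pO2
#' (bisection on the strictly increasing content function, tolerance 1e-6
#' mm Hg), then refits the linear boundary model (p0, slope) to the solved
#' pO2-vs-radius points by least squares. The cap `pmax` is held at the
#' baseline value.
#'
#' @param baseline_comp,new_comp Pre- and post-infusion
#'   [blood_composition()]s.
#' @param baseline_bc The baseline [boundary_model()].
#' @param radii_sample Radii (um) spanning the uncapped range of the boundary
#'   model; default 25 radii uniform on \[1, 49\] um (strictly below the
#'   baseline 50 um cap radius).
#' @return A list: `bc` (the refitted [boundary_model()]), `points` (tibble
#'   `radius`, `po2_required`), `max_conservation_error` (relative, before
#'   the linear fit).
#' @export
recalibrate_boundary <- function(baseline_comp, new_comp, baseline_bc,
                                 radii_sample = seq(1, 49, length.out = 25)) {
  stopifnot(all(radii_sample > 0))
  oe_base <- upstream_extraction(radii_sample, baseline_bc, baseline_comp)
  c_max_new <- blood_o2_content(baseline_bc$pmax, new_comp)
  po2_req <- vapply(seq_along(radii_sample), function(i) {
    target <- c_max_new - oe_base[i]      # required content at arrival
    if (target < 0) {
      stop(sprintf(
        "extraction infeasible at radius %.1f um: post-infusion blood cannot supply the baseline upstream extraction",
        radii_sample[i]), call. = FALSE)
    }
    lo <- 0; hi <- baseline_bc$pmax
    while (hi - lo > 1e-6) {
      mid <- (hi + lo) / 2
      if (blood_o2_content(mid, new_comp) < target) lo <- mid else hi <- mid
    }
    (hi + lo) / 2
  }, numeric(1))
  # conservation check prior to the linear fit
  oe_new <- c_max_new - blood_o2_content(po2_req, new_comp)
  err <- max(abs(oe_new - oe_base) / pmax(abs(oe_base), 1e-12))
  fit <- stats::lm(po2_req ~ radii_sample)
  bc <- boundary_model(p0 = unname(stats::coef(fit)[1]),
                       slope = max(0, unname(stats::coef(fit)[2])),
                       pmax = baseline_bc$pmax)
  list(bc = bc,
       points = tibble::tibble(radius = radii_sample, po2_required = po2_req),
       max_conservation_error = err)
}
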