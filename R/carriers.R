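# Oxygen equilibrium curves (Hill model) and whole-blood oxygen content for
# plasma, RBC hemoglobin and plasma-phase HBOC species.
#
# Unit conventions, package-wide:
#   pressure mm Hg, length um, concentration uM (1 uM = 1e-3 mol/m^3),
#   volumetric flow um^3/s, viscosity cP, diffusivity um^2/s.

#' Define an oxygen-binding species
#'
#' An oxygen carrier is a species whose fractional saturation follows the Hill
#' model \eqn{Y = pO_2^n / (pO_2^n + P_{50}^n)}. Both RBC hemoglobin and
#' cell-free polymerized hemoglobin (HBOC) are represented this way; saturation
#' is assumed to be at equilibrium with the local dissolved oxygen (no binding
#' kinetics are stored).
#'
#' @param name Label for the carrier.
#' @param p50 Partial pressure of O2 at half saturation (mm Hg), > 0.
#' @param n_hill Hill cooperativity coefficient (dimensionless), > 0.
#' @param basis Concentration basis; only "heme" is supported (all
#'   concentrations in the package are per heme group).
#'
#' @return An object of class `oxygen_carrier`.
#' @examples
#' mouse <- oxygen_carrier("mouse_rbc", p50 = 42.1, n_hill = 2.2)
#' hill_saturation(42.1, mouse) # 0.5 by construction
#' @export
oxygen_carrier <- function(name, p50, n_hill, basis = "heme") {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(p50) || length(p50) != 1 || p50 <= 0) {
    stop("`p50` must be a single positive pressure (mm Hg)", call. = FALSE)
  }
  if (!is.numeric(n_hill) || length(n_hill) != 1 || n_hill <= 0) {
    stop("`n_hill` must be a single positive number", call. = FALSE)
  }
  basis <- match.arg(basis, "heme")
  structure(
    list(name = name, p50 = as.numeric(p50), n_hill = as.numeric(n_hill),
         basis = basis),
    class = "oxygen_carrier"
  )
}

#' @export
print.oxygen_carrier <- function(x, ...) {
  cat(sprintf("<oxygen_carrier> %s: P50 = %g mm Hg, n = %g (per-%s basis)\n",
              x$name, x$p50, x$n_hill, x$basis))
  invisible(x)
}

#' Shipped carrier presets
#'
#' Named carriers used throughout the simulations: murine and human RBC
#' hemoglobin, 35:1 T-State polymerized human Hb (low affinity, P50 34 mm Hg,
#' n = 1) and 30:1 R-State polymerized human Hb (high affinity, P50 1.3 mm Hg,
#' n = 1).
#'
#' @param name One of `"mouse_rbc"`, `"human_rbc"`, `"t_state_35"`,
#'   `"r_state_30"`.
#' @return An [oxygen_carrier()].
#' @export
carrier_preset <- function(name = c("mouse_rbc", "human_rbc", "t_state_35",
                                    "r_state_30")) {
  name <- match.arg(name)
  switch(name,
    mouse_rbc  = oxygen_carrier("mouse_rbc",  p50 = 42.1, n_hill = 2.2),
    human_rbc  = oxygen_carrier("human_rbc",  p50 = 29.3, n_hill = 2.9),
    t_state_35 = oxygen_carrier("t_state_35", p50 = 34.0, n_hill = 1.0),
    r_state_30 = oxygen_carrier("r_state_30", p50 = 1.3,  n_hill = 1.0)
  )
}

check_po2 <- function(pO2) {
  if (any(!is.finite(pO2)) || any(pO2 < 0)) {
    stop("pO2 must be finite and >= 0 mm Hg", call. = FALSE)
  }
  invisible(pO2)
}

#' Hill saturation
#'
#' Fractional saturation \eqn{Y(pO_2) = pO_2^n / (pO_2^n + P_{50}^n)} of a
#' carrier at a given oxygen partial pressure. Vectorised over `pO2`.
#'
#' @param pO2 Oxygen partial pressure, mm Hg (>= 0).
#' @param carrier An [oxygen_carrier()].
#' @return Saturation in \[0, 1\].
#' @export
hill_saturation <- function(pO2, carrier) {
  check_po2(pO2)
  pn <- pO2^carrier$n_hill
  pn / (pn + carrier$p50^carrier$n_hill)
}

#' Slope of the Hill saturation curve
#'
#' Analytic derivative \eqn{dY/dpO_2} of [hill_saturation()], used in the
#' oxygen capacitance of blood (the denominator of the axial pO2 ODE).
#' Strictly positive for `pO2 > 0`; at `pO2 = 0` the limit is 0 for n > 1,
#' `1/P50` for n = 1, and +Inf for n < 1 (returned as such).
#'
#' @inheritParams hill_saturation
#' @return Derivative in 1/mm Hg.
#' @export
hill_slope <- function(pO2, carrier) {
  check_po2(pO2)
  n <- carrier$n_hill
  p50n <- carrier$p50^n
  pn <- pO2^n
  out <- n * p50n * pO2^(n - 1) / (pn + p50n)^2
  # limits at exactly zero
  zero <- pO2 == 0
  if (any(zero)) {
    out[zero] <- if (n > 1) 0 else if (n == 1) 1 / carrier$p50 else Inf
  }
  out
}

#' Heme molarity of an HBOC mass concentration
#'
#' Converts an HBOC dose stated as mg tetramer per mL of blood to heme
#' molarity, using a tetramer molar mass of 64,500 g/mol and 4 hemes per
#' tetramer (both configurable).
#'
#' @param mg_per_ml HBOC mass concentration, mg/mL.
#' @param tetramer_mw Tetramer molar mass, g/mol.
#' @param hemes_per_tetramer Heme groups per tetramer.
#' @return Heme concentration in uM.
#' @export
hboc_heme_concentration <- function(mg_per_ml, tetramer_mw = 64500,
                                    hemes_per_tetramer = 4) {
  stopifnot(mg_per_ml >= 0)
  # mg/mL = g/L; g/L / (g/mol) = mol/L; * 1e6 = uM
  mg_per_ml / tetramer_mw * hemes_per_tetramer * 1e6
}

#' Blood composition
#'
#' The oxygen-carrying make-up of blood: hematocrit, heme concentration of
#' hemoglobin inside RBCs, plasma-phase HBOC heme concentration, plasma O2
#' solubility and plasma viscosity, plus the Hill carriers for the RBC and
#' HBOC species.
#'
#' The default RBC heme concentration of 21,100 uM (21.1 mol heme/m^3) follows
#' from a mean corpuscular hemoglobin concentration of 0.34 g/mL and a
#' tetramer molar mass of 64,450 g/mol with 4 hemes per tetramer.
#'
#' @param hct Hematocrit as a volume fraction in \[0, 1).
#' @param rbc_carrier [oxygen_carrier()] for hemoglobin in RBCs.
#' @param hboc_carrier [oxygen_carrier()] for the plasma-phase HBOC, or `NULL`
#'   when no HBOC is present.
#' @param c_hboc HBOC heme concentration in whole blood, uM. Must be 0 when
#'   `hboc_carrier` is `NULL`.
#' @param c_hb_rbc Heme concentration of Hb inside RBCs, uM.
#' @param alpha_plasma Plasma O2 solubility, uM/mm Hg.
#' @param plasma_viscosity Plasma viscosity, cP.
#' @return An object of class `blood_composition`.
#' @export
blood_composition <- function(hct = 0.45,
                              rbc_carrier = carrier_preset("mouse_rbc"),
                              hboc_carrier = NULL,
                              c_hboc = 0,
                              c_hb_rbc = 21100,
                              alpha_plasma = 1.71,
                              plasma_viscosity = 1.26) {
  if (hct < 0 || hct >= 1) stop("`hct` must lie in [0, 1)", call. = FALSE)
  stopifnot(c_hboc >= 0, c_hb_rbc >= 0, alpha_plasma > 0, plasma_viscosity > 0)
  if (is.null(hboc_carrier) && c_hboc != 0) {
    stop("`c_hboc` must be 0 when no HBOC carrier is present", call. = FALSE)
  }
  if (!is.null(hboc_carrier)) stopifnot(inherits(hboc_carrier, "oxygen_carrier"))
  stopifnot(inherits(rbc_carrier, "oxygen_carrier"))
  structure(
    list(hct = hct, rbc_carrier = rbc_carrier, hboc_carrier = hboc_carrier,
         c_hboc = c_hboc, c_hb_rbc = c_hb_rbc, alpha_plasma = alpha_plasma,
         plasma_viscosity = plasma_viscosity),
    class = "blood_composition"
  )
}

#' @export
print.blood_composition <- function(x, ...) {
  cat(sprintf(
    "<blood_composition> HCT %.2f, RBC %s, HBOC %s (%.1f uM heme), plasma %.2f cP\n",
    x$hct, x$rbc_carrier$name,
    if (is.null(x$hboc_carrier)) "none" else x$hboc_carrier$name,
    x$c_hboc, x$plasma_viscosity))
  invisible(x)
}

#' Total blood oxygen content
#'
#' Whole-blood O2 content as the sum of dissolved plasma O2, O2 bound to Hb in
#' RBCs, and O2 bound to the plasma-phase HBOC:
#' \deqn{C_{O_2}(p) = \alpha_{pls} p + HCT \cdot C_{Hb,RBC} Y_{Hb}(p)
#'   + C_{HBOC} Y_{HBOC}(p).}
#'
#' @param pO2 Oxygen partial pressure, mm Hg. Vectorised.
#' @param comp A [blood_composition()].
#' @return O2 content in uM.
#' @export
blood_o2_content <- function(pO2, comp) {
  check_po2(pO2)
  out <- comp$alpha_plasma * pO2 +
    comp$hct * comp$c_hb_rbc * hill_saturation(pO2, comp$rbc_carrier)
  if (!is.null(comp$hboc_carrier) && comp$c_hboc > 0) {
    out <- out + comp$c_hboc * hill_saturation(pO2, comp$hboc_carrier)
  }
  out
}

#' Oxygen capacitance of blood
#'
#' Derivative of [blood_o2_content()] with respect to pO2 (the effective
#' oxygen-carrying capacitance): \eqn{\alpha_{pls} + HCT\,C_{Hb,RBC}\,dY_{Hb}/dp
#' + C_{HBOC}\,dY_{HBOC}/dp}. Always at least `alpha_plasma`.
#'
#' @inheritParams blood_o2_content
#' @return Capacitance in uM/mm Hg.
#' @export
o2_capacitance <- function(pO2, comp) {
  check_po2(pO2)
  out <- comp$alpha_plasma +
    comp$hct * comp$c_hb_rbc * hill_slope(pO2, comp$rbc_carrier)
  if (!is.null(comp$hboc_carrier) && comp$c_hboc > 0) {
    out <- out + comp$c_hboc * hill_slope(pO2, comp$hboc_carrier)
  }
  out
}

#' Per-heme oxygen delivery deficit of one carrier relative to another
#'
#' How much less O2 (percent) carrier `carrier_a` releases than `carrier_b`
#' per heme over a fixed arteriolar pO2 window:
#' \eqn{100 (1 - \Delta Y_a / \Delta Y_b)} with
#' \eqn{\Delta Y = Y(p_{hi}) - Y(p_{lo})}. The default window \[50, 100\] mm Hg
#' spans the radius-dependent inlet boundary model (its minimum and capped
#' maximum inlet pO2), i.e. upstream arteries and arterioles.
#'
#' @param carrier_a,carrier_b [oxygen_carrier()] objects; the deficit of `a`
#'   is measured relative to `b`.
#' @param p_hi,p_lo Window limits, mm Hg, `p_hi > p_lo >= 0`.
#' @return Percent deficit (positive when `a` delivers less than `b`).
#' @export
per_heme_delivery_deficit <- function(carrier_a, carrier_b,
                                      p_hi = 100, p_lo = 50) {
  stopifnot(p_lo >= 0, p_hi > p_lo)
  dy_a <- hill_saturation(p_hi, carrier_a) - hill_saturation(p_lo, carrier_a)
  dy_b <- hill_saturation(p_hi, carrier_b) - hill_saturation(p_lo, carrier_b)
  if (dy_b == 0) {
    stop("reference carrier releases no O2 over this window; deficit undefined",
         call. = FALSE)
  }
  100 * (1 - dy_a / dy_b)
}

#' Oxygen equilibrium curves as a tidy table
#'
#' Evaluates saturation (and, optionally, the per-pressure offloading slope)
#' for a set of carriers on a pO2 grid, in long format ready for ggplot2.
#'
#' @param carriers A named list of [oxygen_carrier()] objects.
#' @param pO2 Vector of pO2 values (mm Hg).
#' @return A tibble with columns `carrier`, `po2`, `saturation`, `slope`.
#' @export
oec_table <- function(carriers = list(mouse_rbc = carrier_preset("mouse_rbc"),
                                      human_rbc = carrier_preset("human_rbc"),
                                      t_state_35 = carrier_preset("t_state_35"),
                                      r_state_30 = carrier_preset("r_state_30")),
                      pO2 = seq(0, 100, by = 0.5)) {
  purrr::imap_dfr(carriers, function(ca, nm) {
    tibble::tibble(carrier = nm, po2 = pO2,
                   saturation = hill_saturation(pO2, ca),
                   slope = hill_slope(pO2, ca))
  })
}

#' Plot oxygen equilibrium curves
#'
#' @inheritParams oec_table
#' @param what `"saturation"` for the OEC or `"slope"` for the offloading
#'   slope dY/dpO2.
#' @return A ggplot object.
#' @export
plot_oec <- function(carriers = NULL, pO2 = seq(0, 100, by = 0.5),
                     what = c("saturation", "slope")) {
  what <- match.arg(what)
  tab <- if (is.null(carriers)) oec_table(pO2 = pO2) else oec_table(carriers, pO2)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$po2, y = .data[[what]],
                                    colour = .data$carrier)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pO2 (mm Hg)",
                  y = if (what == "saturation") "saturation Y" else "dY/dpO2 (1/mm Hg)") +
    ggplot2::theme_minimal()
}
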