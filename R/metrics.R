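# Clinically analogous bulk summaries of a converged simulation: stereological
# vascular metrics (MVD, RBV, RBF), tissue Hb/HBOC concentrations and
# saturations, the oxygen extraction fraction decomposition, MRO2 and hypoxic
# fractions.

#' Region mask on the tissue grid
#'
#' `"whole"` selects all voxels; `"tumor"` the tumor mass (viable shell plus
#' necrotic core); `"host"` normal tissue; `"boundary"` the viable tumor rim
#' (tumor phase present, necrotic phase absent).
#'
#' @param grid A [tissue_grid()].
#' @param region One of `"whole"`, `"tumor"`, `"host"`, `"boundary"`.
#' @return Logical array over voxels.
#' @export
region_mask <- function(grid, region = c("whole", "tumor", "host",
                                         "boundary")) {
  region <- match.arg(region)
  switch(region,
    whole = array(TRUE, grid$shape),
    tumor = (grid$phi_tumor + grid$phi_necrotic) > 0,
    host = grid$phi_normal > 0 & (grid$phi_tumor + grid$phi_necrotic) == 0,
    boundary = grid$phi_tumor > 0 & grid$phi_necrotic == 0)
}

# nearest-voxel membership of points in a mask
points_in_mask <- function(points, grid, mask) {
  h <- grid$spacing
  sh <- grid$shape
  ijk <- pmin(pmax(floor(sweep(points, 2, grid$origin) / h), 0),
              rep(1, nrow(points)) %o% (sh - 1))
  idx <- as.integer(ijk[, 1] + sh[1] * (ijk[, 2] + sh[2] * ijk[, 3])) + 1L
  mask[idx]
}

#' Bulk vascular and oxygenation metrics over a region
#'
#' Iterates through the vessels clipped to a tissue region and accumulates
#' stereological and oxygenation summaries: microvascular density (length
#' per volume), regional blood volume fraction, regional blood flow (blood
#' inflow crossing into the region per tissue mass at density 1 g/mL),
#' tissue Hb and oxyHb concentrations (heme in RBCs referred to tissue
#' volume), HBOC analogues, their saturations, and mean blood/tissue pO2.
#' Segment-region intersection uses fine sample points along each segment
#' (clipped length weighting).
#'
#' @param network A [vascular_network()].
#' @param flow A [solve_flow()] result.
#' @param oxygen An [solve_coupled()] result (or `NULL` for purely
#'   architectural metrics; saturations then come back `NA`).
#' @param grid A [tissue_grid()].
#' @param region Region name (see [region_mask()]).
#' @param step Sampling step along segments, um.
#' @return One-row tibble of class `bulk_metrics`.
#' @export
vascular_bulk_metrics <- function(network, flow, oxygen, grid,
                                  region = "whole", step = 10) {
  mask <- region_mask(grid, region)
  v_region <- sum(mask) * grid$spacing^3
  if (v_region == 0) stop("empty region '", region, "'", call. = FALSE)
  seg <- network$segments
  pts <- segment_sample_points(network, step)
  inm <- points_in_mask(cbind(pts$x, pts$y, pts$z), grid, mask)
  w <- pts$w_len[inm]
  sidx <- pts$seg_row[inm]

  sflow <- flow$segments[match(seg$id, flow$segments$id), ]
  mean_po2_seg <- if (!is.null(oxygen)) {
    ox <- oxygen$segments[match(seg$id, oxygen$segments$id), ]
    ox$mean_po2
  } else rep(NA_real_, nrow(seg))
  comp <- if (!is.null(oxygen)) oxygen$comp else NULL

  len <- sum(w)
  rbv_num <- sum(pi * seg$radius[sidx]^2 * w)
  chb_num <- sum(pi * seg$radius[sidx]^2 * w * sflow$hct[sidx])
  chboc_num <- sum(pi * seg$radius[sidx]^2 * w * sflow$c_hboc[sidx])
  c_hb_rbc <- if (!is.null(comp)) comp$c_hb_rbc else 21100
  y_hb <- y_hboc <- rep(NA_real_, nrow(seg))
  if (!is.null(oxygen)) {
    y_hb <- hill_saturation(pmax(mean_po2_seg, 0), oxygen$comp$rbc_carrier)
    y_hboc <- if (!is.null(oxygen$comp$hboc_carrier)) {
      hill_saturation(pmax(mean_po2_seg, 0), oxygen$comp$hboc_carrier)
    } else rep(0, nrow(seg))
  }
  coxyhb_num <- sum(pi * seg$radius[sidx]^2 * w * sflow$hct[sidx] *
                      y_hb[sidx])
  coxyhboc_num <- sum(pi * seg$radius[sidx]^2 * w * sflow$c_hboc[sidx] *
                        y_hboc[sidx])

  # inflow crossing into the region: oriented segments whose upstream sample
  # is outside and downstream inside (roots feeding the region count via
  # their first in-region segment)
  ori <- orient_segments(network, flow)
  nod <- network$nodes
  pos_from <- cbind(nod$x[ori$from], nod$y[ori$from], nod$z[ori$from])
  pos_to <- cbind(nod$x[ori$to], nod$y[ori$to], nod$z[ori$to])
  from_in <- points_in_mask(pos_from, grid, mask)
  to_in <- points_in_mask(pos_to, grid, mask)
  inflow <- sum(ori$q[!from_in & to_in])
  if (region == "whole") {
    root_out <- nod$kind != "interior"
    inflow <- sum(ori$q[root_out[ori$from]])
  }

  c_hb_tis <- chb_num * c_hb_rbc / v_region
  c_oxyhb_tis <- coxyhb_num * c_hb_rbc / v_region
  c_hboc_tis <- chboc_num / v_region
  c_oxyhboc_tis <- coxyhboc_num / v_region
  blood_po2 <- if (len > 0 && !is.null(oxygen)) {
    sum(w * mean_po2_seg[sidx]) / len
  } else NA_real_

  tibble::tibble(
    region = region,
    mvd = len / v_region * 1e6,                      # mm / mm^3
    rbv = rbv_num / v_region,                        # volume fraction
    rbf = 60 * inflow / v_region,                    # mL / (g min), rho = 1
    c_hb_tis = c_hb_tis,                             # uM heme
    c_oxyhb_tis = c_oxyhb_tis,
    s_hb_tis = if (c_hb_tis > 0) c_oxyhb_tis / c_hb_tis else NA_real_,
    c_hboc_tis = c_hboc_tis,
    c_oxyhboc_tis = c_oxyhboc_tis,
    s_hboc_tis = if (c_hboc_tis > 0) c_oxyhboc_tis / c_hboc_tis else NA_real_,
    mean_blood_po2 = blood_po2,
    mean_tissue_po2 = if (!is.null(oxygen)) mean(oxygen$grid$po2[mask])
                      else mean(grid$po2[mask]))
}

#' Oxygen extraction fraction decomposition
#'
#' Species-resolved molar O2 flows at the domain inlets (arterial roots,
#' flow inward) and outlets (venous roots): dissolved plasma O2
#' (`Q * alpha * pO2`), RBC-bound (`Q * HCT * C_Hb,RBC * Y_Hb`), HBOC-bound
#' (`Q * C_HBOC * Y_HBOC`). Each OEF is `(J_in - J_out) / J_in` for its
#' species; the total OEF combines all species flows, so the decomposition
#' identity `OEF_total * J_in_total = sum_s OEF_s * J_in_s` holds to rounding.
#'
#' @param network A [vascular_network()].
#' @param flow A [solve_flow()] result.
#' @param oxygen A [solve_coupled()] result.
#' @param comp A [blood_composition()] (defaults to the one in `oxygen`).
#' @return One-row tibble: `oef_total`, `oef_plas`, `oef_hb`, `oef_hboc`
#'   (NA where a species has no inflow), plus the species `j_in_*` /
#'   `j_out_*` molar flows (uM um^3/s).
#' @export
oef_breakdown <- function(network, flow, oxygen, comp = oxygen$comp) {
  nod <- network$nodes
  seg <- network$segments
  ori <- orient_segments(network, flow)
  is_root <- nod$kind != "interior"
  ox <- oxygen$segments[match(seg$id, oxygen$segments$id), ]
  sflow <- flow$segments[match(seg$id, flow$segments$id), ]

  inlet <- is_root[ori$from] & ori$q > 0
  outlet <- is_root[ori$to] & ori$q > 0

  species_flow <- function(sel, po2) {
    q <- ori$q[sel]
    h <- sflow$hct[sel]
    cb <- sflow$c_hboc[sel]
    y_hb <- hill_saturation(pmax(po2, 0), comp$rbc_carrier)
    y_hboc <- if (!is.null(comp$hboc_carrier)) {
      hill_saturation(pmax(po2, 0), comp$hboc_carrier)
    } else rep(0, length(po2))
    c(pls = sum(q * comp$alpha_plasma * po2),
      hb = sum(q * h * comp$c_hb_rbc * y_hb),
      hboc = sum(q * cb * y_hboc))
  }
  j_in <- species_flow(inlet, ox$inlet_po2[inlet])
  j_out <- species_flow(outlet, ox$outlet_po2[outlet])
  oef <- function(jin, jout) if (jin > 0) (jin - jout) / jin else NA_real_
  tibble::tibble(
    oef_total = oef(sum(j_in), sum(j_out)),
    oef_plas = oef(j_in[["pls"]], j_out[["pls"]]),
    oef_hb = oef(j_in[["hb"]], j_out[["hb"]]),
    oef_hboc = oef(j_in[["hboc"]], j_out[["hboc"]]),
    j_in_pls = j_in[["pls"]], j_in_hb = j_in[["hb"]],
    j_in_hboc = j_in[["hboc"]],
    j_out_pls = j_out[["pls"]], j_out_hb = j_out[["hb"]],
    j_out_hboc = j_out[["hboc"]])
}

#' Metabolic rate of oxygen consumption
#'
#' Volume average of the Michaelis-Menten uptake over a region:
#' \eqn{MRO_2 = |\Omega|^{-1} \sum_v V_M P_v/(K_M + P_v) \cdot \Delta V}.
#' Bounded above by the regional maximum `v_m`.
#'
#' @param grid A [tissue_grid()] with a solved `po2` field (or pass
#'   `tissue_po2`).
#' @param region Region name (see [region_mask()]).
#' @param tissue_po2 Optional pO2 array overriding `grid$po2`.
#' @return MRO2 in uM/s.
#' @export
mro2 <- function(grid, region = "whole", tissue_po2 = NULL) {
  mask <- region_mask(grid, region)
  p <- if (is.null(tissue_po2)) grid$po2 else tissue_po2
  p <- pmax(p, 0)
  rate <- grid$v_m * p / (grid$k_m + p)
  mean(rate[mask])
}

#' Hypoxic volume fractions
#'
#' Fraction of non-necrotic tissue (normal plus viable tumor; necrotic
#' voxels are excluded from both numerator and denominator since dead tissue
#' mounts no hypoxic response) below a pO2 threshold, and the same fraction
#' restricted to the tumor/host boundary region (tumor phase present,
#' necrotic phase absent).
#'
#' @param grid A [tissue_grid()] with solved `po2` (or pass `tissue_po2`).
#' @param threshold Hypoxia threshold, mm Hg (default 5).
#' @param tissue_po2 Optional pO2 array overriding `grid$po2`.
#' @return Tibble with `total_fraction` and `boundary_fraction`.
#' @export
hypoxic_fractions <- function(grid, threshold = 5, tissue_po2 = NULL) {
  p <- if (is.null(tissue_po2)) grid$po2 else tissue_po2
  non_necrotic <- grid$phi_necrotic == 0 &
    (grid$phi_normal + grid$phi_tumor) > 0
  boundary <- region_mask(grid, "boundary")
  frac <- function(mask) {
    if (!any(mask)) return(NA_real_)
    sum(p[mask] < threshold) / sum(mask)
  }
  tibble::tibble(total_fraction = frac(non_necrotic),
                 boundary_fraction = frac(boundary))
}

#' Percent change versus a baseline
#'
#' \eqn{\Delta\% = 100 (V - V_{BL}) / V_{BL}}.
#'
#' @param value Observed value(s).
#' @param baseline Baseline value(s); zero gives `NA` with a warning.
#' @return Percent change.
#' @export
percent_change <- function(value, baseline) {
  out <- 100 * (value - baseline) / baseline
  if (any(baseline == 0)) {
    warning("percent change undefined for zero baseline; returning NA",
            call. = FALSE)
    out[baseline == 0] <- NA_real_
  }
  out
}
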