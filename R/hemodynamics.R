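# Steady Poiseuille flow on the vascular graph, hematocrit / HBOC
# partitioning at bifurcations, and a simplified shear-driven structural
# adaptation whose stimulus can be attenuated (k_s < 1) to emulate NO
# scavenging by cell-free hemoglobin.

#' Effective in-vivo blood viscosity
#'
#' Empirical diameter- and hematocrit-dependent relative apparent viscosity of
#' blood flowing in narrow tubes in vivo (the Fahraeus-Lindqvist effect with
#' the endothelial surface layer), multiplied by the plasma viscosity. At
#' `hct = 0` the relative viscosity is 1, so the result is the plasma
#' viscosity itself.
#'
#' @param radius Vessel radius, um. Vectorised.
#' @param hct Hematocrit fraction. Vectorised.
#' @param plasma_viscosity Plasma viscosity, cP.
#' @param model `"invivo"` for the empirical law, `"plasma"` for plain plasma
#'   viscosity (useful for analytic checks).
#' @return Effective viscosity, cP.
#' @export
effective_viscosity <- function(radius, hct, plasma_viscosity = 1.26,
                                model = c("invivo", "plasma")) {
  model <- match.arg(model)
  stopifnot(all(radius > 0), all(hct >= 0), all(hct < 1))
  if (model == "plasma") {
    return(rep_len(plasma_viscosity, max(length(radius), length(hct))))
  }
  effective_viscosity_invivo(radius, hct, plasma_viscosity)
}

# Empirical diameter- and hematocrit-dependent relative apparent viscosity
# (Fahraeus-Lindqvist): a 0.45-hematocrit reference curve in tube diameter,
# rescaled to the actual hematocrit through the shape exponent C. Goes to 1
# exactly as hct -> 0 and increases monotonically with hct.
effective_viscosity_invivo <- function(radius, hct, plasma_viscosity = 1.26) {
  d <- 2 * radius
  eta45 <- 6 * exp(-0.085 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  cc <- (0.8 + exp(-0.075 * d)) * (-1 + 1 / (1 + 1e-11 * d^12)) +
    1 / (1 + 1e-11 * d^12)
  rel <- 1 + (eta45 - 1) * ((1 - hct)^cc - 1) / ((1 - 0.45)^cc - 1)
  pmax(rel, 1) * plasma_viscosity
}

#' Adaptation parameters
#'
#' Controls for the shear-driven radius adaptation rule
#' `r <- r * (1 + step * (k_s * S_H - S_ref))` with
#' `S_H = log10(tau + 0.103)` (wall shear stress `tau` in dyn/cm^2) and
#' `S_ref = log10(tau_ref + 0.103)`. `k_s = 1` is the native shear
#' sensitivity; values below 1 (0.96, 0.95, 0.90 across the infusion
#' scenarios) weaken the dilatory shear stimulus and drive vasoconstriction.
#'
#' @param k_s Shear-stimulus multiplier in (0, 1].
#' @param n_iter Maximum adaptation iterations.
#' @param step Relative radius step per iteration.
#' @param radius_bounds Allowed radius range, um.
#' @param tau_ref Reference wall shear stress, dyn/cm^2.
#' @return An object of class `adaptation_params`.
#' @export
adaptation_params <- function(k_s = 1, n_iter = 60, step = 0.02,
                              radius_bounds = c(2, 40), tau_ref = 10) {
  stopifnot(k_s > 0, k_s <= 1, n_iter >= 1, step >= 0,
            length(radius_bounds) == 2, radius_bounds[1] > 0,
            radius_bounds[2] > radius_bounds[1], tau_ref > 0)
  structure(list(k_s = k_s, n_iter = n_iter, step = step,
                 radius_bounds = radius_bounds, tau_ref = tau_ref),
            class = "adaptation_params")
}

#' Default root pressures
#'
#' Arterial roots at 60 mm Hg and venous roots at 15 mm Hg (configurable;
#' physiologic arteriolar/venular values).
#'
#' @param arterial,venous Pressures, mm Hg.
#' @return Named numeric vector.
#' @export
root_pressures <- function(arterial = 60, venous = 15) {
  c(arterial = arterial, venous = venous)
}

#' Solve steady Poiseuille flow on a network
#'
#' Node pressures solve the sparse linear conductance system with segment
#' conductance \eqn{g = \pi r^4 / (8 \mu l)} (viscosity from
#' [effective_viscosity()]); flows follow from pressure differences. Because
#' the effective viscosity depends on the hematocrit distribution, the solve
#' alternates pressure solves with hematocrit/HBOC partitioning
#' ([partition_hematocrit_and_hboc()]) until the segment hematocrits settle.
#'
#' @param network A [vascular_network()].
#' @param comp A [blood_composition()] (inlet hematocrit, HBOC level, plasma
#'   viscosity).
#' @param pressures Named vector from [root_pressures()].
#' @param viscosity_model `"invivo"` or `"plasma"`.
#' @param hct_model `"pries"` (empirical phase separation at diverging
#'   bifurcations) or `"proportional"` (flow-proportional split).
#' @param n_hct_iter Maximum viscosity/hematocrit fixed-point iterations.
#' @param root_conductance Optional hydraulic conductance (um^3/(s mm Hg))
#'   of a feed resistance placed between each boundary root and its fixed
#'   pressure, representing the truncated upstream/downstream vasculature
#'   outside the desk-scale domain. The stated value refers to baseline
#'   blood (HCT 0.45, plasma 1.26 cP); since the feed vessels carry the same
#'   blood as the network, the effective conductance is rescaled by the
#'   ratio of baseline to current blood viscosity at the feed diameter
#'   (`feed_radius`), so hemodilution speeds up the supply as it does in
#'   vivo. `NULL` (default) pins root pressures directly (Dirichlet).
#' @param feed_radius Representative radius of the upstream feed vessels,
#'   um (used only with `root_conductance`).
#' @return An object of class `flow_solution`: tibbles `segments` (`id`,
#'   `flow` signed a->b in um^3/s, `hct`, `c_hboc` uM, `viscosity` cP,
#'   `shear` dyn/cm^2) and `nodes` (`id`, `pressure` mm Hg).
#' @export
solve_flow <- function(network, comp = host_blood("mouse"),
                       pressures = root_pressures(),
                       viscosity_model = c("invivo", "plasma"),
                       hct_model = c("pries", "proportional"),
                       n_hct_iter = 12, root_conductance = NULL,
                       feed_radius = 50) {
  viscosity_model <- match.arg(viscosity_model)
  hct_model <- match.arg(hct_model)
  if (!is.null(root_conductance)) {
    # the feed stands for the autoregulated upstream circulation: its
    # conductance tracks the rheological effect of hemodilution (hematocrit
    # at the feed diameter) while modest infusate plasma-viscosity changes
    # are taken as buffered by upstream tone (vasoactivity of cell-free Hb
    # is modeled separately through k_s)
    mu_ref <- effective_viscosity_invivo(feed_radius, 0.45, 1.26)
    mu_feed <- effective_viscosity_invivo(feed_radius, comp$hct, 1.26)
    root_conductance <- root_conductance * mu_ref / mu_feed
  }
  nod <- network$nodes
  seg <- network$segments
  n <- nrow(nod)
  if (!any(nod$kind == "arterial_root") || !any(nod$kind == "venous_root")) {
    stop("network needs at least one arterial and one venous root", call. = FALSE)
  }
  ia <- match(seg$a, nod$id); ib <- match(seg$b, nod$id)
  comp_id <- components_of(ia, ib, n)
  rooted <- unique(comp_id[nod$kind != "interior"])
  if (!all(comp_id %in% rooted)) {
    bad <- which(!(comp_id %in% rooted))
    stop("disconnected component without boundary root (nodes ",
         paste(utils::head(nod$id[bad], 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "", ")", call. = FALSE)
  }
  fixed <- nod$kind != "interior"
  p_fixed <- ifelse(nod$kind == "arterial_root", pressures[["arterial"]],
                    pressures[["venous"]])

  hct <- rep(comp$hct, nrow(seg))
  c_hboc <- rep(comp$c_hboc, nrow(seg))
  p <- numeric(n)
  flow <- numeric(nrow(seg))
  for (it in seq_len(max(1L, n_hct_iter))) {
    mu <- if (viscosity_model == "invivo") {
      effective_viscosity_invivo(seg$radius, pmin(hct, 0.95),
                                 comp$plasma_viscosity)
    } else rep(comp$plasma_viscosity, nrow(seg))
    # conductance in um^3 / (s mm Hg): mu cP -> Pa s via 1e-3
    g <- pi * seg$radius^4 * MMHG_PA / (8 * mu * 1e-3 * seg$length)
    p <- solve_node_pressures(ia, ib, g, fixed, p_fixed, n, root_conductance)
    flow_new <- g * (p[ia] - p[ib])
    done_flow <- max(abs(flow_new - flow)) <=
      1e-10 * max(abs(flow_new), 1e-300)
    flow <- flow_new
    part <- partition_hematocrit_and_hboc_impl(
      seg, ia, ib, p, flow, comp$hct, comp$c_hboc,
      nod$kind, model = hct_model)
    done_hct <- max(abs(part$hct - hct)) < 1e-8
    hct <- part$hct
    c_hboc <- part$c_hboc
    if ((done_flow && done_hct) ||
        (viscosity_model == "plasma" && it >= 2)) break
  }
  mu <- if (viscosity_model == "invivo") {
    effective_viscosity_invivo(seg$radius, pmin(hct, 0.95),
                               comp$plasma_viscosity)
  } else rep(comp$plasma_viscosity, nrow(seg))
  # wall shear stress tau = 4 mu Q / (pi r^3); Pa -> dyn/cm^2 is x10
  shear <- 10 * abs(4 * (mu * 1e-3) * flow / (pi * seg$radius^3))
  structure(list(
    segments = tibble::tibble(id = seg$id, flow = flow, hct = hct,
                              c_hboc = c_hboc, viscosity = mu, shear = shear),
    nodes = tibble::tibble(id = nod$id, pressure = p),
    pressures = pressures, hct_model = hct_model,
    viscosity_model = viscosity_model),
    class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %d segments, %d nodes\n",
              nrow(x$segments), nrow(x$nodes)))
  cat(sprintf("  |Q| median %.3g um^3/s, HCT range [%.3f, %.3f]\n",
              stats::median(abs(x$segments$flow)),
              min(x$segments$hct), max(x$segments$hct)))
  invisible(x)
}

solve_node_pressures <- function(ia, ib, g, fixed, p_fixed, n,
                                 root_conductance = NULL) {
  if (!is.null(root_conductance)) {
    # roots become free nodes tied to their pressure through a feed
    # conductance: adds g_r to the diagonal and g_r * p_root to the rhs
    diag_extra <- numeric(n)
    b_extra <- numeric(n)
    diag_extra[fixed] <- root_conductance
    b_extra[fixed] <- root_conductance * p_fixed[fixed]
    A <- Matrix::sparseMatrix(
      i = c(ia, ib, ia, ib, seq_len(n)),
      j = c(ib, ia, ia, ib, seq_len(n)),
      x = c(-g, -g, g, g, diag_extra), dims = c(n, n))
    return(as.numeric(Matrix::solve(A, b_extra)))
  }
  free <- which(!fixed)
  idx_free <- integer(n); idx_free[free] <- seq_along(free)
  # Laplacian rows for free nodes
  rows <- c(idx_free[ia], idx_free[ib])
  cols_node <- c(ib, ia)
  gg <- c(g, g)
  on_free_row <- rows > 0
  rows <- rows[on_free_row]; cols_node <- cols_node[on_free_row]
  gg <- gg[on_free_row]
  b <- numeric(length(free))
  to_fixed <- fixed[cols_node]
  if (any(to_fixed)) {
    bb <- rowsum(gg[to_fixed] * p_fixed[cols_node[to_fixed]],
                 rows[to_fixed])
    b[as.integer(rownames(bb))] <- bb[, 1]
  }
  tri_i <- c(rows[!to_fixed], rows)
  tri_j <- c(idx_free[cols_node[!to_fixed]], rows)
  tri_x <- c(-gg[!to_fixed], gg)
  A <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x,
                            dims = c(length(free), length(free)))
  p <- numeric(n)
  p[fixed] <- p_fixed[fixed]
  if (length(free)) {
    sol <- tryCatch(Matrix::solve(A, b),
                    error = function(e) stop(
                      "singular flow system (isolated subnetwork?): ",
                      conditionMessage(e), call. = FALSE))
    p[free] <- as.numeric(sol)
  }
  p
}

#' Partition hematocrit and HBOC over an oriented flow field
#'
#' Propagates RBC flux (`Q * HCT`) and HBOC flux (`Q * C_HBOC`) from the
#' arterial roots through the network in descending-pressure order, conserving
#' both at every node. At diverging bifurcations the RBC flux splits by the
#' empirical phase-separation law (`model = "pries"`; plasma skimming) or in
#' proportion to blood flow (`model = "proportional"`); the HBOC, being
#' plasma-borne, always splits in proportion to plasma flow.
#'
#' @param network A [vascular_network()].
#' @param flow A [solve_flow()] result (its pressures/flows are used).
#' @param inlet_hct Hematocrit entering at arterial roots.
#' @param inlet_c_hboc HBOC heme concentration entering at arterial roots, uM.
#' @param model `"pries"` or `"proportional"`.
#' @return The `flow_solution` with updated `hct` and `c_hboc` columns.
#' @export
partition_hematocrit_and_hboc <- function(network, flow, inlet_hct,
                                          inlet_c_hboc = 0,
                                          model = c("pries", "proportional")) {
  model <- match.arg(model)
  nod <- network$nodes
  seg <- network$segments
  ia <- match(seg$a, nod$id); ib <- match(seg$b, nod$id)
  p <- flow$nodes$pressure[match(nod$id, flow$nodes$id)]
  part <- partition_hematocrit_and_hboc_impl(
    seg, ia, ib, p, flow$segments$flow, inlet_hct, inlet_c_hboc, nod$kind,
    model)
  flow$segments$hct <- part$hct
  flow$segments$c_hboc <- part$c_hboc
  flow
}

partition_hematocrit_and_hboc_impl <- function(seg, ia, ib, p, flow,
                                               inlet_hct, inlet_c_hboc,
                                               node_kind, model) {
  ns <- nrow(seg)
  n <- length(p)
  # orient: "from" node is the higher-pressure endpoint; ties by node index
  from <- ifelse(flow >= 0, ia, ib)
  to <- ifelse(flow >= 0, ib, ia)
  q <- abs(flow)
  hct <- rep(inlet_hct, ns)
  c_hboc <- rep(inlet_c_hboc, ns)
  ord_nodes <- order(-p, seq_len(n))
  out_of <- split(seq_len(ns), factor(from, levels = seq_len(n)))
  in_of <- split(seq_len(ns), factor(to, levels = seq_len(n)))
  for (u in ord_nodes) {
    outs <- out_of[[u]]
    outs <- outs[q[outs] > 0]
    if (!length(outs)) next
    ins <- in_of[[u]]
    ins <- ins[q[ins] > 0]
    if (node_kind[u] == "arterial_root" && !length(ins)) {
      rbc_in <- sum(q[outs]) * inlet_hct
      hboc_in <- sum(q[outs]) * inlet_c_hboc
      d_feed <- 2 * max(seg$radius[outs])
    } else if (!length(ins)) {
      # interior source of flow should not occur; carry inlet values
      rbc_in <- sum(q[outs]) * inlet_hct
      hboc_in <- sum(q[outs]) * inlet_c_hboc
      d_feed <- 2 * max(seg$radius[outs])
    } else {
      rbc_in <- sum(q[ins] * hct[ins])
      hboc_in <- sum(q[ins] * c_hboc[ins])
      d_feed <- 2 * seg$radius[ins[which.max(q[ins])]]
    }
    q_tot <- sum(q[outs])
    h_feed <- min(rbc_in / q_tot, 0.95)
    if (length(outs) == 2 && model == "pries" && h_feed > 0) {
      fqb1 <- q[outs[1]] / q_tot
      fqe1 <- pries_rbc_fraction(fqb1, d_feed,
                                 2 * seg$radius[outs[1]],
                                 2 * seg$radius[outs[2]], h_feed)
      rbc_s <- rbc_in * c(fqe1, 1 - fqe1)
    } else {
      rbc_s <- rbc_in * q[outs] / q_tot
    }
    # cap branch hematocrit at 0.95, handing excess RBC flux to the others
    for (rep_i in 1:3) {
      h_s <- rbc_s / q[outs]
      over <- h_s > 0.95
      if (!any(over) || all(over)) break
      excess <- sum(rbc_s[over] - 0.95 * q[outs][over])
      rbc_s[over] <- 0.95 * q[outs][over]
      rbc_s[!over] <- rbc_s[!over] +
        excess * q[outs][!over] / sum(q[outs][!over])
    }
    hct[outs] <- pmin(rbc_s / q[outs], 0.95)
    plasma_s <- q[outs] * (1 - hct[outs])
    tot_plasma <- sum(plasma_s)
    hboc_s <- if (tot_plasma > 0) hboc_in * plasma_s / tot_plasma
              else hboc_in * q[outs] / q_tot
    c_hboc[outs] <- hboc_s / q[outs]
  }
  list(hct = hct, c_hboc = c_hboc)
}

# Empirical phase-separation (plasma skimming) law at a diverging
# bifurcation: fraction of RBC flux entering daughter 1 as a function of its
# fractional blood flow, feed diameter/hematocrit and daughter diameters.
pries_rbc_fraction <- function(fqb1, d_feed, d1, d2, h_feed) {
  x0 <- min(0.964 * (1 - h_feed) / d_feed, 0.49)
  if (fqb1 <= x0) return(0)
  if (fqb1 >= 1 - x0) return(1)
  a <- -13.29 * ((d1^2 - d2^2) / (d1^2 + d2^2)) * (1 - h_feed) / d_feed
  b <- 1 + 6.98 * (1 - h_feed) / d_feed
  xi <- (fqb1 - x0) / (1 - 2 * x0)
  logit <- a + b * log(xi / (1 - xi))
  1 / (1 + exp(-logit))
}

#' Shear-driven radius adaptation
#'
#' Iterates `r <- r * (1 + step * (k_s * S_H - S_ref))` with
#' `S_H = log10(tau + 0.103)` on the wall shear stress `tau` (dyn/cm^2),
#' re-solving flow each iteration, until the largest relative radius change
#' falls below `1e-4` or `n_iter` is reached. Radii are clamped to
#' `radius_bounds`. With `step = 0` the network is returned unchanged; at a
#' converged state re-running the adaptation leaves radii (essentially)
#' untouched. Reduced `k_s` demands a higher shear stress at equilibrium and
#' therefore narrower vessels.
#'
#' @param network A [vascular_network()].
#' @param flow Initial [solve_flow()] result (used for the first stimulus).
#' @param params An [adaptation_params()].
#' @param comp A [blood_composition()] used for the internal flow re-solves.
#' @param pressures Root pressures for the re-solves.
#' @param root_conductance Passed through to [solve_flow()].
#' @return The adapted [vascular_network()] with attributes
#'   `adapt_iterations` and `adapt_converged`.
#' @export
adapt_radii <- function(network, flow, params = adaptation_params(),
                        comp = host_blood("mouse"),
                        pressures = root_pressures(),
                        root_conductance = NULL) {
  if (params$step == 0) {
    attr(network, "adapt_iterations") <- 0L
    attr(network, "adapt_converged") <- TRUE
    return(network)
  }
  s_ref <- log10(params$tau_ref + 0.103)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(params$n_iter)) {
    tau <- flow$segments$shear
    stim <- params$k_s * log10(tau + 0.103) - s_ref
    r_new <- network$segments$radius * (1 + params$step * stim)
    r_new <- pmin(pmax(r_new, params$radius_bounds[1]),
                  params$radius_bounds[2])
    rel <- max(abs(r_new - network$segments$radius) /
                 network$segments$radius)
    network$segments$radius <- r_new
    flow <- solve_flow(network, comp, pressures,
                       viscosity_model = flow$viscosity_model,
                       hct_model = flow$hct_model,
                       root_conductance = root_conductance)
    if (rel < 1e-4) { converged <- TRUE; break }
  }
  if (!converged && params$n_iter >= 30) {
    # small n_iter budgets are deliberate partial remodeling; only a long
    # run that still fails to settle deserves a warning
    warning("radius adaptation did not converge in ", params$n_iter,
            " iterations; returning last state", call. = FALSE)
  }
  attr(network, "adapt_iterations") <- it
  attr(network, "adapt_converged") <- converged
  network
}
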