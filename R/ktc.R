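# Krogh tissue cylinder with an HBOC-laden lumen: an axisymmetric
# convection-diffusion solve used to extract an effective wall Sherwood
# number and calibrate the network solver's lumped wall flux.

#' Krogh cylinder configuration
#'
#' A single vessel of radius `vessel_radius` carrying blood with composition
#' `comp` at volumetric flow `flow`, surrounded by a concentric tissue
#' annulus out to `tissue_radius` consuming oxygen at Michaelis-Menten rate
#' (`v_m`, `k_m`).
#'
#' @param vessel_radius,tissue_radius Radii, um (`tissue_radius` >
#'   `vessel_radius`).
#' @param comp A [blood_composition()].
#' @param v_m Maximum consumption, uM/s.
#' @param k_m Michaelis constant, mm Hg.
#' @param inlet_po2 Inlet pO2, mm Hg.
#' @param flow Volumetric flow, um^3/s.
#' @param length Cylinder length, um.
#' @param n_radial Radial cells in the tissue annulus (>= 8; the lumen uses
#'   half as many, at least 8).
#' @param n_axial Axial marching steps (>= 8).
#' @param params A [transport_params()] (diffusivities, solubilities).
#' @return An object of class `ktc_config`.
#' @export
ktc_config <- function(vessel_radius = 5, tissue_radius = 40,
                       comp = host_blood("mouse"), v_m = 45, k_m = 5,
                       inlet_po2 = 60, flow = 1e5, length = 400,
                       n_radial = 24, n_axial = 40,
                       params = transport_params("mouse")) {
  stopifnot(tissue_radius > vessel_radius, n_radial >= 8, n_axial >= 8,
            vessel_radius > 0, flow > 0, inlet_po2 >= 0, v_m >= 0, k_m > 0)
  structure(list(vessel_radius = vessel_radius, tissue_radius = tissue_radius,
                 comp = comp, v_m = v_m, k_m = k_m, inlet_po2 = inlet_po2,
                 flow = flow, length = length, n_radial = n_radial,
                 n_axial = n_axial, params = params),
            class = "ktc_config")
}

#' Solve the Krogh tissue cylinder
#'
#' Steady axisymmetric solve: Poiseuille (parabolic) axial convection of
#' whole-blood O2 content in the lumen, radial diffusion throughout, and a
#' Michaelis-Menten sink in the tissue annulus, with flux continuity at the
#' vessel wall and a no-flux outer boundary. The solution marches in z
#' (axial diffusion neglected, the standard parabolic approximation), solving
#' a linearised radial system at each station.
#'
#' With `wall_bc = "dirichlet"` the tissue annulus is replaced by a fixed
#' wall pO2 (the classical constant-wall-condition configuration used to
#' check the Sherwood extraction against its textbook limit).
#'
#' @param config A [ktc_config()].
#' @param wall_bc `"tissue"` (annulus, default) or `"dirichlet"`.
#' @param wall_po2 Fixed wall pO2 for `wall_bc = "dirichlet"`.
#' @return An object of class `ktc_solution`: `axial` tibble (z, mixed lumen
#'   pO2, wall pO2, wall flux uM um/s, local Sherwood), `radial` tibble
#'   (radius, pO2 at the outlet station), `outlet_po2`, `sherwood`
#'   (flow-developed effective value), `config`.
#' @export
solve_ktc <- function(config, wall_bc = c("tissue", "dirichlet"),
                      wall_po2 = NULL) {
  wall_bc <- match.arg(wall_bc)
  cf <- config
  pm <- cf$params
  rv <- cf$vessel_radius
  rt <- cf$tissue_radius
  n_lum <- max(8L, as.integer(round(cf$n_radial / 2)))
  n_tis <- if (wall_bc == "tissue") as.integer(cf$n_radial) else 0L
  dl <- rv / n_lum
  dt <- if (n_tis > 0) (rt - rv) / n_tis else NA_real_
  r_lum <- (seq_len(n_lum) - 0.5) * dl
  r_tis <- if (n_tis > 0) rv + (seq_len(n_tis) - 0.5) * dt else numeric(0)
  r_all <- c(r_lum, r_tis)
  n_all <- n_lum + n_tis
  dpap <- pm$d_plasma * pm$alpha_plasma
  dtat <- pm$d_tissue * pm$alpha_tissue
  ubar <- cf$flow / (pi * rv^2)
  u <- 2 * ubar * (1 - (r_lum / rv)^2)          # parabolic profile
  u <- pmax(u, 1e-12 * ubar)
  cell_area <- c(2 * pi * r_lum * dl, if (n_tis) 2 * pi * r_tis * dt)

  # radial conductances between adjacent nodes (per unit z)
  cond <- numeric(n_all - 1)
  for (i in seq_len(n_all - 1)) {
    r_face <- if (i < n_lum) i * dl else if (i == n_lum && n_tis > 0) rv
      else rv + (i - n_lum) * dt
    if (i < n_lum) {
      cond[i] <- 2 * pi * r_face * dpap / dl
    } else if (i == n_lum && n_tis > 0) {
      cond[i] <- 2 * pi * r_face / (dl / (2 * dpap) + dt / (2 * dtat))
    } else {
      cond[i] <- 2 * pi * r_face * dtat / dt
    }
  }
  # wall conductance for the dirichlet case (half lumen cell to the wall)
  cond_wall <- 2 * pi * rv * dpap / (dl / 2)

  dz <- cf$length / cf$n_axial
  p <- rep(cf$inlet_po2, n_all)
  if (n_tis > 0) p[(n_lum + 1):n_all] <- cf$inlet_po2 * 0.5
  vm_vec <- c(rep(0, n_lum), rep(cf$v_m, n_tis))
  km_vec <- c(rep(1, n_lum), rep(cf$k_m, n_tis))

  # initial tissue equilibration at the inlet station: a near-zero axial step
  # pins the lumen at the inlet state while the annulus relaxes to it
  p <- ktc_station_solve(p, p, dz * 1e-9, u, cf, cond, cond_wall, cell_area,
                         vm_vec, km_vec, n_lum, n_tis, wall_bc, wall_po2,
                         advect = TRUE)

  z <- (seq_len(cf$n_axial)) * dz
  mix <- wallp <- flux <- shloc <- numeric(cf$n_axial)
  for (k in seq_len(cf$n_axial)) {
    p <- ktc_station_solve(p, p, dz, u, cf, cond, cond_wall, cell_area,
                           vm_vec, km_vec, n_lum, n_tis, wall_bc, wall_po2,
                           advect = TRUE)
    wgt <- u * r_lum
    kap <- o2_capacitance(pmax(p[seq_len(n_lum)], 0), cf$comp)
    mix[k] <- sum(wgt * kap * p[seq_len(n_lum)]) / sum(wgt * kap)
    if (wall_bc == "tissue") {
      rl <- dl / (2 * dpap); rtt <- dt / (2 * dtat)
      pw <- (p[n_lum] / rl + p[n_lum + 1] / rtt) / (1 / rl + 1 / rtt)
      jw <- cond[n_lum] * (p[n_lum] - p[n_lum + 1]) / (2 * pi * rv)
    } else {
      pw <- wall_po2
      jw <- cond_wall * (p[n_lum] - wall_po2) / (2 * pi * rv)
    }
    wallp[k] <- pw
    flux[k] <- jw
    dr <- mix[k] - pw
    # invert the lumped wall-flux law j = Sh * D_p * alpha_p * dP / (2 r)
    shloc[k] <- if (abs(dr) > 1e-12) jw * 2 * rv / (dpap * dr) else NA_real_
  }
  # developed effective Sh: once the lumen equilibrates with the wall the
  # flux/driving-force ratio degenerates to 0/0, so use the downstream half
  # of the stations that still carry a resolvable driving force
  fin <- which(is.finite(shloc))
  sh_dev <- if (length(fin)) {
    stats::median(shloc[fin[fin >= fin[ceiling(length(fin) / 2)]]])
  } else NA_real_
  structure(list(
    axial = tibble::tibble(z = z, lumen_po2 = mix, wall_po2 = wallp,
                           wall_flux = flux, sherwood_local = shloc),
    radial = tibble::tibble(radius = r_all, po2 = p),
    outlet_po2 = mix[cf$n_axial], sherwood = sh_dev, config = cf),
    class = "ktc_solution")
}

# One axial station: implicit radial diffusion + MM sink, advective storage
# term for lumen cells; Newton iteration on the nonlinearities.
ktc_station_solve <- function(p_old, p_init, dz, u, cf, cond, cond_wall,
                              cell_area, vm_vec, km_vec, n_lum, n_tis,
                              wall_bc, wall_po2, advect = TRUE) {
  n_all <- n_lum + n_tis
  p <- p_init
  for (newton in 1:30) {
    kap <- numeric(n_all)
    kap[seq_len(n_lum)] <- o2_capacitance(pmax(p[seq_len(n_lum)], 0), cf$comp)
    adv <- if (advect && dz > 0) c(u, rep(0, n_tis)) * kap *
      cell_area / dz else rep(0, n_all)
    pk <- pmax(p, 0)
    mm <- vm_vec * pk / (km_vec + pk) * cell_area
    dmm <- vm_vec * km_vec / (km_vec + pk)^2 * cell_area
    # tridiagonal system with the MM sink linearised about pk:
    # (adv + dmm + diffusion) p_new = adv p_old + dmm pk - mm(pk)
    lower <- -cond
    upper <- -cond
    diagv <- adv + dmm + c(cond, 0) + c(0, cond)
    rhs <- adv * p_old + dmm * pk - mm
    if (wall_bc == "dirichlet") {
      diagv[n_lum] <- diagv[n_lum] + cond_wall
      rhs[n_lum] <- rhs[n_lum] + cond_wall * wall_po2
    }
    sol <- thomas_solve(lower, diagv, upper, rhs)
    delta <- max(abs(sol - p))
    p <- sol
    if (delta < 1e-10 * max(1, max(abs(p)))) break
  }
  p
}

thomas_solve <- function(lower, diagv, upper, rhs) {
  n <- length(diagv)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diagv[1]
  dp[1] <- rhs[1] / diagv[1]
  for (i in 2:n) {
    m <- diagv[i] - lower[i - 1] * cp[i - 1]
    cp[i] <- if (i < n) upper[i] / m else 0
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Closed-form Krogh annulus profile (zeroth-order consumption)
#'
#' Steady radial pO2 profile around a vessel for constant (zeroth-order)
#' consumption `v_m` in an annulus from the vessel wall `r_v` to a no-flux
#' outer radius `r_t`:
#' \deqn{P(r) = P_w + \frac{V_M}{\alpha_t D_t}\left[\frac{r^2 - r_v^2}{4}
#'   - \frac{r_t^2}{2}\ln\frac{r}{r_v}\right].}
#'
#' @param r Radii at which to evaluate, um.
#' @param r_v Vessel radius, um.
#' @param r_t Outer (no-flux) radius, um.
#' @param p_wall Wall pO2, mm Hg.
#' @param v_m Consumption, uM/s.
#' @param params A [transport_params()].
#' @return pO2 at `r`, mm Hg (may go negative if the annulus is too wide:
#'   the anoxic-corner regime of the closed form).
#' @export
krogh_annulus_po2 <- function(r, r_v, r_t, p_wall, v_m,
                              params = transport_params("mouse")) {
  aD <- params$alpha_tissue * params$d_tissue
  p_wall + v_m / aD * ((r^2 - r_v^2) / 4 - r_t^2 / 2 * log(r / r_v))
}

#' Fit a Sherwood-number correlation from a KTC parameter sweep
#'
#' Least-squares regression of the effective Sherwood number extracted from
#' Krogh-cylinder solves against configurable predictors (default: inverse
#' vessel radius, hematocrit, HBOC concentration). Predictors that do not
#' vary across the sweep are dropped automatically, so a sweep of identical
#' points reduces to an intercept-only fit.
#'
#' @param sweep Tibble with columns `radius` (um), `hct`, `c_hboc` (uM) and
#'   `sherwood` (effective Sh from [solve_ktc()]), one row per sweep point
#'   (>= 1; >= 10 spanning radius and composition for a meaningful fit).
#' @return An object of class `sherwood_fit`: `coefficients`, `r_squared`,
#'   `fn(radius, hct, c_hboc)` usable as `transport_params(sherwood = fn)`.
#' @export
fit_sherwood <- function(sweep) {
  sweep <- tibble::as_tibble(sweep)
  stopifnot(all(c("radius", "hct", "c_hboc", "sherwood") %in% names(sweep)))
  if (any(!is.finite(sweep$sherwood))) {
    stop("sweep contains non-finite Sherwood values", call. = FALSE)
  }
  df <- tibble::tibble(sh = sweep$sherwood, inv_r = 1 / sweep$radius,
                       hct = sweep$hct, c_hboc = sweep$c_hboc)
  preds <- c("inv_r", "hct", "c_hboc")
  keep <- preds[vapply(preds, function(v) stats::sd(df[[v]]) > 1e-12,
                       logical(1))]
  fml <- if (length(keep)) {
    stats::as.formula(paste("sh ~", paste(keep, collapse = " + ")))
  } else sh ~ 1
  fit <- stats::lm(fml, data = df)
  if (length(keep) && any(is.na(stats::coef(fit)))) {
    stop("rank-deficient Sherwood design: sweep does not span its predictors",
         call. = FALSE)
  }
  co <- stats::coef(fit)
  full <- c(`(Intercept)` = 0, inv_r = 0, hct = 0, c_hboc = 0)
  full[names(co)] <- co
  r2 <- if (length(keep)) {
    suppressWarnings(summary(fit)$r.squared)   # exact fits are fine here
  } else 1
  fn <- function(radius, hct = 0, c_hboc = 0) {
    pmax(0.5, full[["(Intercept)"]] + full[["inv_r"]] / radius +
           full[["hct"]] * hct + full[["c_hboc"]] * c_hboc)
  }
  structure(list(coefficients = full, r_squared = r2, fn = fn,
                 n_points = nrow(df)),
            class = "sherwood_fit")
}

#' @export
print.sherwood_fit <- function(x, ...) {
  cat("<sherwood_fit> Sh =", signif(x$coefficients[1], 4))
  if (x$coefficients[2] != 0) cat(" +", signif(x$coefficients[2], 4), "/ r")
  if (x$coefficients[3] != 0) cat(" +", signif(x$coefficients[3], 4), "* HCT")
  if (x$coefficients[4] != 0) cat(" +", signif(x$coefficients[4], 4), "* C_HBOC")
  cat(sprintf("  (R^2 = %.4f, n = %d)\n", x$r_squared, x$n_points))
  invisible(x)
}

#' Run a KTC sweep and collect effective Sherwood numbers
#'
#' @param configs List of [ktc_config()] objects.
#' @return Tibble with `radius`, `hct`, `c_hboc`, `outlet_po2`, `sherwood`.
#' @export
ktc_sweep <- function(configs) {
  purrr::map_dfr(configs, function(cf) {
    sol <- solve_ktc(cf)
    tibble::tibble(radius = cf$vessel_radius, hct = cf$comp$hct,
                   c_hboc = cf$comp$c_hboc, outlet_po2 = sol$outlet_po2,
                   sherwood = sol$sherwood)
  })
}
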