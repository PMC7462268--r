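# Boundary model, transvascular flux, segment ODE, node mixing, tissue
# solver and the coupled solve.

params_m <- transport_params("mouse")

test_that("radius-dependent boundary inlet pO2", {
  bc <- boundary_model(50, 1, 100)
  expect_equal(boundary_inlet_po2(10, bc), 60)
  expect_equal(boundary_inlet_po2(200, bc), 100)
  expect_equal(boundary_inlet_po2(1e-9, bc), 50, tolerance = 1e-6)
  expect_equal(boundary_inlet_po2(c(5, 75), bc), c(55, 100))
})

test_that("transvascular flux follows the Sherwood law", {
  expect_equal(transvascular_flux(40, 40, 5, params_m), 0)
  j1 <- transvascular_flux(60, 30, 5, params_m)
  j2 <- transvascular_flux(60, 30, 10, params_m)
  expect_equal(j1 / j2, 2, tolerance = 1e-12)
  expect_lt(transvascular_flux(20, 50, 5, params_m), 0)
  # unit-tracked hand evaluation: Sh D_p alpha_p dP / (2 r), SI then uM um/s
  d_p_um2 <- 1.85e-5 * 1e8      # cm^2/s -> um^2/s
  alpha_um <- 1.71e-3 * 1e3     # mol/(m^3 mmHg) -> uM/mmHg
  expect_equal(j1, 3.66 * d_p_um2 * alpha_um * (60 - 30) / (2 * 5),
               tolerance = 1e-12)
})

test_that("segment integration limits and analytic plasma-only decay", {
  comp <- host_blood("mouse")
  # flat profile when blood already equals tissue
  res <- integrate_segment_po2(5, 100, 40, 40, comp, 1e5, params_m)
  expect_equal(res$outlet_po2, 40)
  expect_true(all(abs(res$profile$po2 - 40) < 1e-12))
  # infinite-flow limit: outlet -> inlet
  res_fast <- integrate_segment_po2(5, 100, 70, 20, comp, 1e12, params_m)
  expect_equal(res_fast$outlet_po2, 70, tolerance = 1e-4)
  # plasma-only blood: exact exponential relaxation
  plasma <- blood_composition(hct = 0)
  q <- 2e4; len <- 150
  res_p <- integrate_segment_po2(5, len, 80, 20, plasma, q, params_m,
                                 hct = 0, c_hboc = 0)
  lam <- pi * 3.66 * params_m$d_plasma / q   # alpha cancels
  expect_equal(res_p$outlet_po2, 20 + 60 * exp(-lam * len),
               tolerance = 1e-6 * 60)
  # monotone relaxation toward the tissue value, no overshoot (the tail may
  # sit exactly at the tissue value once the exponential underflows)
  expect_true(all(diff(res_p$profile$po2) <= 0))
  above <- res_p$profile$po2 > 20
  expect_true(all(diff(res_p$profile$po2[above]) < 0))
  expect_true(all(res_p$profile$po2 >= 20))
  # outlet below inlet whenever tissue is below inlet
  res_c <- integrate_segment_po2(4, 60, 60, 25, comp, 5e3, params_m)
  expect_lt(res_c$outlet_po2, 60)
  expect_gt(res_c$outlet_po2, 25)
})

test_that("node mixing: identity, symmetry and grid-scan oracle", {
  comp <- host_blood("mouse")
  one <- tibble::tibble(q = 1e4, hct = 0.45, c_hboc = 0, po2 = 47.3)
  expect_equal(mix_at_node(one, comp), 47.3)
  two_same <- tibble::tibble(q = c(2e4, 2e4), hct = 0.45, c_hboc = 0,
                             po2 = c(55, 55))
  expect_equal(mix_at_node(two_same, comp), 55, tolerance = 1e-6)
  # two equal flows at 30 and 70: root of C(p) = (C(30) + C(70)) / 2
  two <- tibble::tibble(q = c(1e4, 1e4), hct = 0.45, c_hboc = 0,
                        po2 = c(30, 70))
  got <- mix_at_node(two, comp)
  grid <- seq(30, 70, by = 1e-4)
  target <- (blood_o2_content(30, comp) + blood_o2_content(70, comp)) / 2
  oracle <- grid[which.min(abs(blood_o2_content(grid, comp) - target))]
  expect_equal(got, oracle, tolerance = 1e-3)
  expect_error(mix_at_node(tibble::tibble(q = 0, hct = 0.45, c_hboc = 0,
                                          po2 = 50), comp),
               "degenerate")
})

test_that("tissue solver: Laplace identity and splat conservation", {
  grid <- inert_grid(c(6, 6, 6), 30)
  sol <- solve_tissue_field(grid, 0, params_m,
                            po2_init = array(33, c(6, 6, 6)))
  expect_true(sol$converged)
  expect_true(all(abs(sol$po2 - 33) < 1e-9))
  # trilinear deposit conserves the deposited amounts exactly
  set.seed(4)
  pts <- cbind(runif(200, 0, 180), runif(200, 0, 180), runif(200, 0, 180))
  amt <- runif(200)
  dep <- deposit_points <- hbocsim:::deposit_points(amt, pts, grid)
  expect_equal(sum(dep), sum(amt), tolerance = 1e-10)
})

test_that("tissue solver reproduces the Krogh annulus in the zeroth-order limit", {
  # z-invariant line source through the domain center: effectively the 2D
  # annulus problem with an equal-area outer radius. The source is set just
  # below the saturated consumption so a steady state exists.
  nn <- 49L
  h <- 1.7
  shape <- c(nn, nn, 3L)
  params <- transport_params("mouse")
  grid <- tissue_grid(h, shape, phi_normal = array(1, shape),
                      phi_tumor = array(0, shape),
                      phi_necrotic = array(0, shape), params = params)
  grid$k_m <- array(0.1, shape)        # near-zeroth-order consumption
  grid$v_m <- array(30, shape)
  ctr <- nn * h / 2
  zs <- (seq_len(shape[3]) - 0.5) * h
  total_sink <- 0.995 * 30 * prod(shape) * h^3
  src <- hbocsim:::deposit_points(rep(total_sink / length(zs), length(zs)),
                                  cbind(ctr, ctr, zs), grid) / h^3
  sol <- solve_tissue_field(grid, src, params,
                            po2_init = array(30, shape))
  expect_true(sol$converged)
  mid <- sol$po2[, , 2]
  cx <- (seq_len(nn) - 0.5) * h
  rr <- sqrt(outer((cx - ctr)^2, (cx - ctr)^2, "+"))
  rt <- sqrt(nn^2 * h^2 / pi)          # equal-area outer radius
  r0 <- 10
  sel <- rr > r0 & rr < 0.6 * rt
  ana <- function(r) krogh_annulus_po2(r, r0, rt, 0, 30, params)
  # compare profile differences (eliminates the wall constant)
  base_num <- mean(mid[abs(rr - r0) < h / 2])
  diff_num <- mid[sel] - base_num
  diff_ana <- ana(rr[sel]) - ana(r0)
  rng <- diff(range(diff_ana))
  rms <- sqrt(mean((diff_num - diff_ana)^2)) / rng
  expect_lt(rms, 0.02)
})

test_that("coupled solve: sink direction and consumption monotonicity", {
  net <- single_tube_network(radius = 6, length = 300)
  params <- transport_params("mouse", max_outer_iter = 80)
  run_vm <- function(vm_scale) {
    shape <- c(10, 8, 8)
    grid <- tissue_grid(30, shape, phi_normal = array(1, shape),
                        phi_tumor = array(0, shape),
                        phi_necrotic = array(0, shape), params = params)
    grid$v_m <- grid$v_m * vm_scale
    comp <- host_blood("mouse")
    fl <- solve_flow(net, comp, root_conductance = 2000)
    solve_coupled(net, grid, fl, comp, boundary_model(), params)
  }
  ox1 <- run_vm(1)
  expect_true(ox1$converged)
  expect_lt(ox1$segments$outlet_po2[1], ox1$segments$inlet_po2[1])
  ox2 <- run_vm(2)
  expect_lt(mean(ox2$grid$po2), mean(ox1$grid$po2))
})

test_that("tissue grid round-trips through the JSON container", {
  ph <- standard_fixture()
  dir <- withr::local_tempdir()
  f <- file.path(dir, "grid.json")
  write_tissue_grid(ph$grid, f)
  back <- read_tissue_grid(f)
  expect_equal(back$v_m, ph$grid$v_m)
  expect_equal(back$spacing, ph$grid$spacing)
  expect_equal(back$shape, ph$grid$shape)
})
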