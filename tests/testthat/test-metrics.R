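# Bulk metrics, OEF decomposition, MRO2, hypoxic fractions, percent change.

test_that("single-vessel RBV and MVD are exact", {
  net <- single_tube_network(radius = 10, length = 200)
  grid <- inert_grid(c(5, 4, 4), 50)   # 250 x 200 x 200 um box
  flow_stub <- structure(list(
    segments = tibble::tibble(id = 1L, flow = 1e4, hct = 0.45, c_hboc = 0,
                              viscosity = 1.3, shear = 5),
    nodes = tibble::tibble(id = 1:2, pressure = c(60, 15))),
    class = "flow_solution")
  m <- vascular_bulk_metrics(net, flow_stub, NULL, grid, "whole", step = 1)
  v <- prod(c(250, 200, 200))
  expect_equal(m$rbv, pi * 100 * 200 / v, tolerance = 1e-9)
  expect_equal(m$mvd, 200 / v * 1e6, tolerance = 1e-9)
  expect_error(vascular_bulk_metrics(net, flow_stub, NULL, grid, "tumor"),
               "empty region")
})

test_that("fixture metrics agree with a voxel-rasterised oracle", {
  ph <- standard_fixture()
  net <- ph$network
  grid <- ph$grid
  flow_stub <- structure(list(
    segments = tibble::tibble(id = net$segments$id, flow = 1, hct = 0.45,
                              c_hboc = 0, viscosity = 1, shear = 1),
    nodes = tibble::tibble(id = net$nodes$id, pressure = 1)),
    class = "flow_solution")
  m <- vascular_bulk_metrics(net, flow_stub, NULL, grid, "tumor", step = 2)
  # brute force: rasterise every segment at 1 um steps onto voxels
  mask <- region_mask(grid, "tumor")
  td <- tidy(net)
  tot_len <- 0
  tot_vol <- 0
  for (i in seq_len(nrow(td))) {
    npt <- max(2L, ceiling(td$length[i]))
    tt <- (seq_len(npt) - 0.5) / npt
    px <- td$xa[i] + (td$xb[i] - td$xa[i]) * tt
    py <- td$ya[i] + (td$yb[i] - td$ya[i]) * tt
    pz <- td$za[i] + (td$zb[i] - td$za[i]) * tt
    ijk <- cbind(pmin(pmax(floor(px / grid$spacing), 0), grid$shape[1] - 1),
                 pmin(pmax(floor(py / grid$spacing), 0), grid$shape[2] - 1),
                 pmin(pmax(floor(pz / grid$spacing), 0), grid$shape[3] - 1))
    inm <- mask[ijk + 1]
    l_in <- sum(inm) * td$length[i] / npt
    tot_len <- tot_len + l_in
    tot_vol <- tot_vol + pi * td$radius[i]^2 * l_in
  }
  v_reg <- sum(mask) * grid$spacing^3
  expect_equal(m$mvd, tot_len / v_reg * 1e6, tolerance = 0.02)
  expect_equal(m$rbv, tot_vol / v_reg, tolerance = 0.02)
})

test_that("OEF decomposition on a hand-computed single-vessel system", {
  net <- single_tube_network(radius = 8, length = 100)
  comp <- host_blood("mouse")
  flow_stub <- structure(list(
    segments = tibble::tibble(id = 1L, flow = 1e4, hct = 0.45, c_hboc = 0,
                              viscosity = 1.3, shear = 5),
    nodes = tibble::tibble(id = 1:2, pressure = c(60, 15))),
    class = "flow_solution")
  ox_stub <- structure(list(
    segments = tibble::tibble(id = 1L, inlet_po2 = 100, outlet_po2 = 40,
                              mean_po2 = 70, tissue_po2 = 30,
                              o2_transfer = 0, equilibrated = FALSE),
    comp = comp), class = "oxygen_solution")
  oef <- oef_breakdown(net, flow_stub, ox_stub, comp)
  y <- function(p) hill_saturation(p, comp$rbc_carrier)
  expect_equal(oef$oef_hb, (y(100) - y(40)) / y(100), tolerance = 1e-12)
  expect_equal(oef$oef_plas, (100 - 40) / 100, tolerance = 1e-12)
  expect_true(is.na(oef$oef_hboc))
  # decomposition identity
  expect_equal(oef$oef_total * (oef$j_in_pls + oef$j_in_hb + oef$j_in_hboc),
               oef$oef_plas * oef$j_in_pls + oef$oef_hb * oef$j_in_hb,
               tolerance = 1e-12)
  # zero extraction when outlet state equals inlet state
  ox_same <- ox_stub
  ox_same$segments$outlet_po2 <- 100
  oef0 <- oef_breakdown(net, flow_stub, ox_same, comp)
  expect_equal(oef0$oef_total, 0, tolerance = 1e-12)
})

test_that("MRO2 analytic limits", {
  params <- transport_params("mouse")
  shape <- c(6, 6, 6)
  grid <- tissue_grid(30, shape, phi_normal = array(1, shape),
                      phi_tumor = array(0, shape),
                      phi_necrotic = array(0, shape), params = params)
  # uniform P = K_M gives V_M / 2 exactly
  expect_equal(mro2(grid, "whole", tissue_po2 = array(5, shape)), 45 / 2)
  # saturation limit
  expect_equal(mro2(grid, "whole", tissue_po2 = array(1e9, shape)), 45,
               tolerance = 1e-6)
  # necrotic-only region consumes nothing
  gridn <- tissue_grid(30, shape, phi_normal = array(0, shape),
                       phi_tumor = array(0, shape),
                       phi_necrotic = array(1, shape), params = params)
  expect_equal(mro2(gridn, "tumor", tissue_po2 = array(50, shape)), 0)
  # monotone in the field
  lo <- mro2(grid, "whole", tissue_po2 = array(3, shape))
  hi <- mro2(grid, "whole", tissue_po2 = array(8, shape))
  expect_gt(hi, lo)
})

test_that("hypoxic fractions exclude necrotic tissue and match counting", {
  params <- transport_params("mouse")
  shape <- c(4, 4, 4)
  phi_nec <- array(0, shape)
  phi_nec[1:2, 1, 1] <- 1
  phi_tum <- array(0, shape)
  phi_tum[3:4, 1, 1] <- 1
  grid <- tissue_grid(30, shape, phi_normal = 1 - phi_nec - phi_tum,
                      phi_tumor = phi_tum, phi_necrotic = phi_nec,
                      params = params)
  # all voxels warm: nothing hypoxic
  h <- hypoxic_fractions(grid, 5, tissue_po2 = array(10, shape))
  expect_equal(h$total_fraction, 0)
  # all cold: every non-necrotic voxel counts, necrotic ones never do
  h1 <- hypoxic_fractions(grid, 5, tissue_po2 = array(1, shape))
  expect_equal(h1$total_fraction, 1)
  expect_equal(h1$boundary_fraction, 1)
  # checkerboard vs direct count
  set.seed(2)
  p <- array(sample(c(1, 10), prod(shape), replace = TRUE), shape)
  h2 <- hypoxic_fractions(grid, 5, tissue_po2 = p)
  nonnec <- phi_nec == 0
  expect_equal(h2$total_fraction, sum(p[nonnec] < 5) / sum(nonnec))
})

test_that("percent change formula", {
  expect_equal(percent_change(1, 1), 0)
  expect_equal(percent_change(2, 1), 100)
  expect_equal(percent_change(0.9 * 7, 7), -10)
  expect_warning(out <- percent_change(3, 0), "zero baseline")
  expect_true(is.na(out))
})
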