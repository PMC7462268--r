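# Poiseuille flow, viscosity law, phase separation, shear adaptation.

test_that("viscosity law has the right limits and monotonicity", {
  expect_equal(effective_viscosity(20, 0, 1.26), 1.26, tolerance = 1e-12)
  expect_equal(effective_viscosity(20, 0, 1.51), 1.51, tolerance = 1e-12)
  for (r in c(3, 8, 25, 100)) {
    mu <- effective_viscosity(r, seq(0, 0.7, by = 0.05))
    expect_true(all(diff(mu) >= 0))
  }
  # plasma viscosity scales the whole curve proportionally at hct = 0
  expect_equal(effective_viscosity(10, 0, 1.51) /
                 effective_viscosity(10, 0, 1.26), 1.51 / 1.26)
})

test_that("single tube reproduces the Poiseuille closed form", {
  net <- single_tube_network(radius = 10, length = 200)
  comp <- blood_composition(hct = 0, plasma_viscosity = 1.26)
  fl <- solve_flow(net, comp, root_pressures(60, 15),
                   viscosity_model = "plasma")
  q_expected <- pi * (60 - 15) * 133.322 * 10^4 / (8 * 1.26e-3 * 200)
  expect_equal(fl$segments$flow, q_expected, tolerance = 1e-12)
})

test_that("symmetric bifurcation splits flow evenly", {
  net <- y_bifurcation_network()
  fl <- solve_flow(net, host_blood("mouse"))
  q <- fl$segments$flow
  expect_equal(abs(q[2]), abs(q[3]), tolerance = 1e-12)
  expect_equal(abs(q[1]), abs(q[2]) + abs(q[3]),
               tolerance = 1e-12 * abs(q[1]))
  expect_equal(fl$segments$hct[2], fl$segments$hct[3], tolerance = 1e-12)
})

test_that("random tree flows match a dense linear-algebra oracle", {
  net <- random_tree_network(50, seed = 3)
  comp <- blood_composition(hct = 0, plasma_viscosity = 1.1)
  fl <- solve_flow(net, comp, viscosity_model = "plasma")
  # independent dense solve of the same conductance system
  nod <- net$nodes; seg <- net$segments
  n <- nrow(nod)
  ia <- match(seg$a, nod$id); ib <- match(seg$b, nod$id)
  g <- pi * seg$radius^4 * 133.322 / (8 * 1.1e-3 * seg$length)
  A <- matrix(0, n, n)
  for (e in seq_along(ia)) {
    A[ia[e], ia[e]] <- A[ia[e], ia[e]] + g[e]
    A[ib[e], ib[e]] <- A[ib[e], ib[e]] + g[e]
    A[ia[e], ib[e]] <- A[ia[e], ib[e]] - g[e]
    A[ib[e], ia[e]] <- A[ib[e], ia[e]] - g[e]
  }
  b <- numeric(n)
  fixed <- nod$kind != "interior"
  pf <- ifelse(nod$kind == "arterial_root", 60, 15)
  for (i in which(fixed)) {
    A[i, ] <- 0; A[i, i] <- 1; b[i] <- pf[i]
  }
  p_dense <- solve(A, b)
  expect_equal(fl$nodes$pressure, as.numeric(p_dense),
               tolerance = 1e-10)
  expect_equal(fl$segments$flow, g * (p_dense[ia] - p_dense[ib]),
               tolerance = 1e-10)
})

test_that("flow and RBC/HBOC fluxes are conserved at interior nodes", {
  net <- generate_av_network(360, 60, 4, 230, seed = 5)
  comp <- blood_composition(hct = 0.45,
                            hboc_carrier = carrier_preset("t_state_35"),
                            c_hboc = 500)
  for (model in c("pries", "proportional")) {
    fl <- solve_flow(net, comp, hct_model = model)
    seg <- net$segments
    ia <- match(seg$a, net$nodes$id); ib <- match(seg$b, net$nodes$id)
    q <- fl$segments$flow
    from <- ifelse(q >= 0, ia, ib); to <- ifelse(q >= 0, ib, ia)
    qa <- abs(q)
    for (u in which(net$nodes$kind == "interior")) {
      fin <- sum(qa[to == u]); fout <- sum(qa[from == u])
      if (fin + fout == 0) next
      expect_lt(abs(fin - fout), 1e-9 * max(fin, fout))
      rin <- sum((qa * fl$segments$hct)[to == u])
      rout <- sum((qa * fl$segments$hct)[from == u])
      expect_lt(abs(rin - rout), 1e-10 * max(rin, rout, 1e-12))
      bin <- sum((qa * fl$segments$c_hboc)[to == u])
      bout <- sum((qa * fl$segments$c_hboc)[from == u])
      expect_lt(abs(bin - bout), 1e-10 * max(bin, bout, 1e-12))
    }
    expect_true(all(fl$segments$hct >= 0 & fl$segments$hct < 1))
  }
})

test_that("proportional split reproduces flux-weighted mixing at a junction", {
  # two branches converging into one, hand-computed
  nodes <- tibble::tibble(
    id = 1:4, x = c(0, 0, 100, 200), y = c(60, -60, 0, 0), z = 0,
    kind = c("arterial_root", "arterial_root", "interior", "venous_root"))
  segments <- tibble::tibble(
    id = 1:3, a = c(1L, 2L, 3L), b = c(3L, 3L, 4L),
    radius = c(8, 6, 10),
    length = c(sqrt(100^2 + 60^2), sqrt(100^2 + 60^2), 100),
    wall_type = "capillary", region = "host")
  net <- vascular_network(nodes, segments, c(200, 200, 100))
  fl <- solve_flow(net, host_blood("mouse"), hct_model = "proportional",
                   viscosity_model = "plasma")
  q <- abs(fl$segments$flow)
  h_out_expected <- (q[1] * fl$segments$hct[1] + q[2] * fl$segments$hct[2]) /
    q[3]
  expect_equal(fl$segments$hct[3], h_out_expected, tolerance = 1e-12)
})

test_that("hemodilution increases total network flow", {
  net <- generate_av_network(360, 60, 4, 230, seed = 5)
  q_tot <- function(hct) {
    fl <- solve_flow(net, blood_composition(hct = hct))
    nod <- net$nodes
    ia <- match(net$segments$a, nod$id); ib <- match(net$segments$b, nod$id)
    q <- fl$segments$flow
    from <- ifelse(q >= 0, ia, ib)
    sum(abs(q)[nod$kind[from] != "interior"])
  }
  expect_gt(q_tot(0.35), q_tot(0.45))
})

test_that("adaptation is inert at step zero and contracts under reduced k_s", {
  net <- generate_av_network(360, 60, 4, 230, seed = 5)
  comp <- host_blood("mouse")
  fl <- solve_flow(net, comp)
  same <- adapt_radii(net, fl, adaptation_params(step = 0), comp)
  expect_identical(same$segments$radius, net$segments$radius)

  ad1 <- adapt_radii(net, fl, adaptation_params(k_s = 1, n_iter = 8), comp)
  ad9 <- adapt_radii(net, fl, adaptation_params(k_s = 0.9, n_iter = 8), comp)
  expect_true(all(ad9$segments$radius <= ad1$segments$radius + 1e-9))
  expect_lt(mean(ad9$segments$radius), mean(ad1$segments$radius))
})

test_that("adaptation approaches a fixed point", {
  net <- generate_av_network(360, 60, 2, 220, seed = 11)
  comp <- host_blood("mouse")
  fl <- solve_flow(net, comp)
  ad <- suppressWarnings(
    adapt_radii(net, fl, adaptation_params(n_iter = 300, step = 0.05), comp))
  fl2 <- solve_flow(ad, comp)
  ad2 <- adapt_radii(ad, fl2, adaptation_params(n_iter = 3, step = 0.05),
                     comp)
  expect_lt(max(abs(ad2$segments$radius - ad$segments$radius) /
                  ad$segments$radius), 1e-3)
})
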