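# Hill saturation curves, blood oxygen content and per-heme delivery.

mouse <- carrier_preset("mouse_rbc")
human <- carrier_preset("human_rbc")
t_state <- carrier_preset("t_state_35")
r_state <- carrier_preset("r_state_30")

test_that("Hill saturation hits its anchor points", {
  expect_equal(hill_saturation(42.1, mouse), 0.5)
  expect_equal(hill_saturation(29.3, human), 0.5)
  expect_equal(hill_saturation(0, mouse), 0)
  # direct high-precision evaluation of the Hill formula
  expect_equal(hill_saturation(100, mouse),
               100^2.2 / (100^2.2 + 42.1^2.2), tolerance = 1e-12)
  expect_equal(round(hill_saturation(100, mouse), 4), 0.8703)
})

test_that("saturation is bounded, monotone in pO2 and in P50", {
  po2 <- seq(0, 150, by = 0.5)
  for (ca in list(mouse, human, t_state, r_state)) {
    y <- hill_saturation(po2, ca)
    expect_true(all(y >= 0 & y <= 1))
    expect_true(all(diff(y) > 0))
  }
  for (p in c(1, 10, 40, 90)) {
    y_by_p50 <- vapply(c(5, 15, 30, 60), function(p50) {
      hill_saturation(p, oxygen_carrier("x", p50, 2))
    }, numeric(1))
    expect_true(all(diff(y_by_p50) < 0))
  }
  expect_error(hill_saturation(-1, mouse), "pO2")
})

test_that("hill_slope matches closed forms and finite differences", {
  n1 <- oxygen_carrier("n1", p50 = 25, n_hill = 1)
  po2 <- c(5, 25, 80)
  expect_equal(hill_slope(po2, n1), 25 / (po2 + 25)^2, tolerance = 1e-12)
  # midpoint slope n / (4 P50)
  expect_equal(hill_slope(42.1, mouse), 2.2 / (4 * 42.1), tolerance = 1e-12)
  # Richardson-extrapolated central differences over the tabled carriers
  for (ca in list(mouse, human, t_state, r_state)) {
    for (p in seq(0.5, 150, length.out = 40)) {
      h <- 1e-3 * max(p, 1)
      fd1 <- (hill_saturation(p + h, ca) - hill_saturation(p - h, ca)) /
        (2 * h)
      fd2 <- (hill_saturation(p + h / 2, ca) -
                hill_saturation(p - h / 2, ca)) / h
      fd <- (4 * fd2 - fd1) / 3
      expect_equal(hill_slope(p, ca), fd, tolerance = 1e-8)
    }
  }
  expect_true(all(hill_slope(seq(0.1, 150, by = 0.7), mouse) > 0))
})

test_that("blood O2 content sums the three species terms", {
  plasma_only <- blood_composition(hct = 0, rbc_carrier = mouse)
  expect_equal(blood_o2_content(50, plasma_only), 1.71 * 50)  # 0.0855 mol/m^3
  expect_equal(blood_o2_content(0, host_blood("mouse")), 0)
  comp <- host_blood("mouse")
  expect_equal(blood_o2_content(100, comp),
               1.71 * 100 + 0.45 * 21100 * hill_saturation(100, mouse),
               tolerance = 1e-12)
  # additivity with an HBOC present, term by term
  hb <- blood_composition(hct = 0.35, rbc_carrier = mouse,
                          hboc_carrier = t_state,
                          c_hboc = hboc_heme_concentration(14))
  po2 <- c(3, 27, 61, 99)
  expected <- 1.71 * po2 + 0.35 * 21100 * hill_saturation(po2, mouse) +
    hboc_heme_concentration(14) * hill_saturation(po2, t_state)
  expect_identical(blood_o2_content(po2, hb), expected)
  expect_true(all(diff(blood_o2_content(seq(0, 120, 0.5), hb)) > 0))
})

test_that("capacitance equals the content derivative and peaks near P50", {
  comp <- host_blood("mouse")
  expect_equal(o2_capacitance(37, blood_composition(hct = 0)), 1.71)
  for (p in c(5, 20, 42.1, 70, 110)) {
    h <- 1e-3 * p
    fd1 <- (blood_o2_content(p + h, comp) -
              blood_o2_content(p - h, comp)) / (2 * h)
    fd2 <- (blood_o2_content(p + h / 2, comp) -
              blood_o2_content(p - h / 2, comp)) / h
    expect_equal(o2_capacitance(p, comp), (4 * fd2 - fd1) / 3,
                 tolerance = 1e-8)
  }
  grid <- seq(1, 150, by = 0.25)
  peak <- grid[which.max(o2_capacitance(grid, comp))]
  # the Hill inflection sits at P50 ((n-1)/(n+1))^(1/n)
  peak_expected <- 42.1 * (1.2 / 3.2)^(1 / 2.2)
  expect_lt(abs(peak - peak_expected), 0.5)
  expect_true(all(o2_capacitance(grid, comp) >= 1.71))
})

test_that("carriers store no kinetic state", {
  for (ca in list(mouse, human, t_state, r_state)) {
    expect_named(ca, c("name", "p50", "n_hill", "basis"))
  }
})

test_that("per-heme delivery deficit reproduces the T/R-State figures", {
  expect_equal(per_heme_delivery_deficit(t_state, mouse), 45, tolerance = 0.02)
  expect_equal(per_heme_delivery_deficit(r_state, mouse), 96, tolerance = 0.01)
  expect_equal(per_heme_delivery_deficit(mouse, mouse, 80, 20), 0)
  # a reference carrier fully saturated across the window releases nothing
  flat <- oxygen_carrier("flat", p50 = 1e-300, n_hill = 1)
  expect_error(per_heme_delivery_deficit(mouse, flat), "deficit undefined")
})

test_that("HBOC mass-to-heme conversion", {
  expect_equal(hboc_heme_concentration(14), 14 / 64500 * 4 * 1e6,
               tolerance = 1e-12)  # 868.2 uM = 0.868 mol/m^3
  expect_equal(hboc_heme_concentration(0), 0)
})

test_that("OEC table and plot cover the shipped carriers", {
  tab <- oec_table(pO2 = seq(0, 100, by = 10))
  expect_s3_class(tab, "tbl_df")
  expect_setequal(unique(tab$carrier),
                  c("mouse_rbc", "human_rbc", "t_state_35", "r_state_30"))
  p <- plot_oec()
  expect_s3_class(p, "ggplot")
})
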