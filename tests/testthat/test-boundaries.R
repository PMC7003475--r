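test_that("inflow waveforms validate, interpolate and round-trip", {
  ts <- seq(0, 0.8, length.out = 81)
  Q <- 2 + sin(2 * pi * ts / 0.8)
  wf <- inflow_waveform(ts, Q, state = "resting",
                        diastole_onset_fraction = 0.35)
  expect_equal(wf$period, 0.8)
  # exact at grid points, periodic wrap
  expect_equal(waveform_at(wf, ts), Q)
  expect_equal(waveform_at(wf, ts + 3 * 0.8), Q, tolerance = 1e-9)
  expect_equal(waveform_at(wf, 0), Q[1])
  # quadrature mean preserved on refinement
  tq <- seq(0, 0.8, length.out = 4001)
  expect_equal(trapz(tq, waveform_at(wf, tq)) / 0.8,
               trapz(ts, Q) / 0.8, tolerance = 1e-12)
  f <- tempfile(fileext = ".csv")
  write_waveform(wf, f)
  back <- read_waveform(f)
  expect_equal(back$Q, wf$Q, tolerance = 1e-12)
  expect_identical(back$state, "resting")
  expect_equal(back$diastole_onset_fraction, 0.35)
  expect_error(inflow_waveform(ts, Q - 5, state = "resting",
                               diastole_onset_fraction = 0.3), "positive")
  expect_error(inflow_waveform(ts, c(Q[-81], 99), state = "resting",
                               diastole_onset_fraction = 0.3), "periodic")
})

test_that("branch resistance follows the mean-pressure/flow rule", {
  # 115/74 mmHg at 1 cm3/s (hand evaluation incl. unit conversion)
  expect_equal(total_branch_resistance(115, 74, 1), 116878.95333333334,
               tolerance = 1e-12)
  expect_equal(total_branch_resistance(115, 74, 2),
               total_branch_resistance(115, 74, 1) / 2)
  # degenerate mean-pressure case
  expect_equal(total_branch_resistance(90, 90, 1.5), mmhg_to_cgs(90) / 1.5)
  expect_error(total_branch_resistance(115, 74, 0), "flow")
})

test_that("Murray distribution recombines exactly in parallel", {
  expect_equal(distribute_resistance_murray(123, 0.3), 123)
  R <- distribute_resistance_murray(100, c(0.3, 0.2))
  expect_equal(unname(R), c(139.83573566962343, 351.0308855077944),
               tolerance = 1e-10)
  expect_equal(1 / sum(1 / R), 100, tolerance = 1e-12)
  expect_equal(distribute_resistance_murray(50, rep(0.2, 4)), rep(200, 4))
  # property: random terminal sets recombine to the branch total <= 1e-12
  set.seed(9)
  for (i in 1:20) {
    d <- runif(sample(2:8, 1), 0.08, 0.4)
    Rb <- runif(1, 1e3, 1e6)
    Rk <- distribute_resistance_murray(Rb, d)
    expect_lt(abs(1 / sum(1 / Rk) - Rb) / Rb, 1e-12)
    expect_true(all(diff(Rk[order(d)]) <= 0))  # larger vessel, lower R
  }
  expect_error(distribute_resistance_murray(10, numeric(0)), "terminal")
})

test_that("terminal bed obeys the DC circuit law and RC limit", {
  bed <- terminal_bed(1e5, side = "left")
  expect_equal(bed$Ra + bed$Rm + bed$Rv, 1e5)
  # steady state with Pim = 0: P_in - Pv = Q (Ra + Rm + Rv)
  Pin <- mmhg_to_cgs(90)
  tgrid <- seq(0, 3, by = 1e-3)
  sim <- bed_simulate(bed, tgrid, rep(Pin, length(tgrid)))
  Qs <- utils::tail(sim$Q_in, 1)
  expect_equal(Pin - bed$Pv, Qs * 1e5, tolerance = 1e-6 * Pin)
  # Cim -> 0: three-element Windkessel step response, analytic RC oracle
  bed3 <- terminal_bed(1e5, side = "left", tau_im = 1e-9, pim_scale = 0)
  tg <- seq(0, 0.5, by = 2e-4)
  sim3 <- bed_simulate(bed3, tg, rep(Pin, length(tg)))
  R2 <- bed3$Rm + bed3$Rv
  tau <- bed3$Ca_bed / (1 / bed3$Ra + 1 / R2)
  P1inf <- (Pin / bed3$Ra + bed3$Pv / R2) / (1 / bed3$Ra + 1 / R2)
  P1an <- P1inf + (Pin - P1inf) * exp(-tg / tau)
  expect_equal(sim3$P1[-1], P1an[-1], tolerance = 0.01 * Pin)
})

test_that("systolic Pim spike impedes terminal inflow", {
  bed <- terminal_bed(8e4, side = "left")
  T <- 0.9
  tg <- seq(0, T, by = 1e-3)
  Pin <- mmhg_to_cgs(95) + mmhg_to_cgs(10) * sin(2 * pi * tg / T)
  # ventricular-like systolic pulse over the first 35% of the cycle
  Pim <- mmhg_to_cgs(115) * pmax(0, sin(pi * tg / (0.35 * T)))^2 *
    (tg < 0.35 * T)
  sim <- bed_simulate(bed, tg, Pin, Pim, n_cycles = 6)
  tmin <- tg[which.min(sim$Q_in[-1]) + 1]
  expect_lt(tmin, 0.35 * T)          # flow minimum falls in systole
  # compression visibly depresses systolic inflow (>= 10% below the mean)
  expect_lt(min(sim$Q_in[-1]), 0.9 * mean(sim$Q_in[-1]))
})

test_that("ventricular traces validate ordering", {
  tg <- seq(0, 0.9, length.out = 10)
  expect_error(ventricular_traces(tg, rep(10, 10), rep(20, 10)), "P_LV")
  vt <- ventricular_traces(tg, rep(1e5, 10), rep(3e4, 10))
  expect_equal(ventricular_at(vt, 0.45, "right"), 3e4)
})
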