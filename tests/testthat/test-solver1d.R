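test_that("solver config validates", {
  expect_s3_class(solver_config(), "solver_config")
  expect_error(solver_config(dt = -1))
  expect_error(solver_config(theta = 0.2))
})

test_that("uniform rest state is an equilibrium fixed point", {
  net <- fx_single_vessel()
  wp <- wall_params(P0 = mmhg_to_cgs(74))
  ts <- seq(0, 0.9, length.out = 10)
  wf <- inflow_waveform(ts, rep(1e-9, 10) + 1e-12, state = "resting",
                        diastole_onset_fraction = 0.35)
  bnd <- network_boundaries(wf, resistances = c(v1 = 1e5), P_out = wp$P0)
  sys <- coroflow_system(net, wp, bnd,
                         solver_config(dx_target = 0.1, dt = 1e-3))
  x0 <- initial_state(sys)
  x1 <- advance_step(sys, x0, 0)
  expect_lt(max(abs(x1[sys$iP] - x0[sys$iP])), 1e-4)   # dyn/cm2
  expect_lt(max(abs(x1[sys$iQ])), 1e-8)
})

test_that("steady solve reproduces the Poiseuille drop and circuit limits", {
  net <- fx_single_vessel(L = 5, D = 0.3)
  wp <- wall_params(P0 = mmhg_to_cgs(74))
  ss <- steady_solve(net, wp, inflow_Q = 1, outlet_resistances = c(v1 = 1e5),
                     P_out = mmhg_to_cgs(70), rigid = TRUE)
  A <- pi * 0.15^2
  expect_equal(ss$P_inlet - (mmhg_to_cgs(70) + 1e5),
               22 * 0.04 * pi * 1 * 5 / A^2, tolerance = 1e-10)
  # zero inflow: uniform pressure
  ss0 <- steady_solve(net, wp, 0, c(v1 = 1e5), P_out = mmhg_to_cgs(80))
  expect_equal(unname(ss0$P), rep(mmhg_to_cgs(80), length(ss0$P)),
               tolerance = 1e-8)
  # bifurcation: flow split inversely proportional to downstream resistance
  tree <- fx_bifurcation(Da = 0.25, Db = 0.25, La = 2, Lb = 2)
  Router <- c(a = 2e5, b = 4e5)
  st <- steady_solve(tree, wp, 1, Router, P_out = 0, rigid = TRUE)
  Ra_tot <- st$R_segment["a"] + 2e5
  Rb_tot <- st$R_segment["b"] + 4e5
  expect_equal(st$Q[["a"]] / st$Q[["b"]], unname(Rb_tot / Ra_tot),
               tolerance = 1e-10)
  expect_equal(st$Q[["a"]] + st$Q[["b"]], 1, tolerance = 1e-12)
})

test_that("identical twin daughters split the parent flow equally", {
  tree <- fx_bifurcation()          # symmetric daughters
  bd <- fx_boundary_data()
  st <- bd$resting$state
  wp <- wall_params(P0 = mmhg_to_cgs(st$diastolic))
  beds <- assign_terminal_beds(tree, st, 2.5)
  bnd <- network_boundaries(bd$resting$inflow_left, beds = beds,
                            ventricular = bd$resting$ventricular)
  res <- run_to_periodic(tree, wp, bnd,
                         fx_coarse_config(max_cycles = 4,
                                          periodic_tol = 5e-3))
  Qa <- probe_trace(res, "a", 0.5, "Q")
  Qb <- probe_trace(res, "b", 0.5, "Q")
  expect_equal(Qa, Qb, tolerance = 1e-8)
})

test_that("converged run conserves mass and balances junctions", {
  fx <- fx_resting_run()
  res <- fx$res; net <- fx$net
  expect_true(res$converged)
  expect_true(all(res$A > 0))
  Qin <- probe_trace(res, net$root, 0, "Q")
  Vin <- trapz(res$t, Qin)
  Vout <- sum(vapply(net$terminals, function(s)
    trapz(res$t, probe_trace(res, s, 1, "Q")), numeric(1)))
  expect_lt(abs(Vin - Vout) / Vin, 1e-3)
  m <- res$mesh
  for (j in names(net$children)) {
    fin <- m$seg_info[[j]]$face0 + m$seg_info[[j]]$n + 1
    fout <- vapply(net$children[[j]], function(ch)
      m$seg_info[[ch]]$face0 + 1L, integer(1))
    resid <- res$Q[fin, ] - colSums(res$Q[fout, , drop = FALSE])
    expect_lt(max(abs(resid)), 1e-10 * max(abs(res$Q[fin, ])))
  }
  # energy: mean pressure must fall from inlet to every terminal
  Pin <- mean(probe_trace(res, net$root, 0))
  for (s in net$terminals)
    expect_lt(mean(probe_trace(res, s, 1)), Pin)
})

test_that("result CSV summary carries probe traces and provenance", {
  fx <- fx_resting_run()
  f <- tempfile(fileext = ".csv")
  write_result_csv(fx$res, f)
  expect_match(readLines(f, n = 1), "coroflow-result cycles=")
  df <- utils::read.csv(f, comment.char = "#")
  expect_equal(nrow(df), length(fx$res$t))
  root <- fx$net$root
  expect_equal(df[[paste0("P_", root, "_prox_mmHg")]],
               cgs_to_mmhg(probe_trace(fx$res, root, 0)), tolerance = 1e-6)
})

test_that("a small pressure pulse propagates at the reference wave speed", {
  r <- fx_pulse_run(200, 2e-5, 1e-3)
  i <- which.max(r$P)
  xs <- r$xc[(i - 1):(i + 1)]; ys <- r$P[(i - 1):(i + 1)]
  co <- stats::coef(stats::lm(ys ~ stats::poly(xs, 2, raw = TRUE)))
  xpk <- -co[2] / (2 * co[3])
  speed <- (xpk - 1.5) / 1e-3
  expect_lt(abs(speed - r$c0) / r$c0, 0.02)
})

test_that("left-tree terminal flow is diastole-dominant under Pim", {
  fx <- fx_resting_run()
  bd <- fx_boundary_data()
  td <- bd$resting$inflow_left$diastole_onset_fraction * fx$res$period
  for (s in fx$net$terminals) {
    Qt <- probe_trace(fx$res, s, 1, "Q")
    expect_gt(mean(Qt[fx$res$t >= td]), mean(Qt[fx$res$t < td]))
  }
})

test_that("solver failure modes carry diagnostics", {
  net <- fx_single_vessel()
  wp <- wall_params(P0 = mmhg_to_cgs(74), k3 = 8.65e8, k1 = 2e10)
  ts <- seq(0, 0.5, length.out = 11)
  wf <- inflow_waveform(ts, rep(50, 11), state = "resting",
                        diastole_onset_fraction = 0.5)
  bnd <- network_boundaries(wf, resistances = c(v1 = 1e3), P_out = wp$P0)
  sys <- coroflow_system(net, wp, bnd, solver_config(dx_target = 0.1,
                                                     dt = 1e-3))
  # cold start with a stiff wall and a violent inflow: collapse is detected
  # and names the segment
  expect_error(
    {x <- initial_state(sys); for (k in 1:50) x <- advance_step(sys, x, k * 1e-3)},
    "v1")
})
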