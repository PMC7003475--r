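# shared fixtures; expensive objects are memoized for the whole test session
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# tier-1 boundary data (one calibration pass shared by every test file)
fx_boundary_data <- function() memo("bd", cached_boundary_data())

# single uniform vessel network
fx_single_vessel <- function(L = 5, D = 0.3, id = "v1", ...)
  build_network(list(vessel_segment(id, L, diameter = D, ...)))

# smallest bifurcating tree: root -> {a, b}
fx_bifurcation <- function(Droot = 0.35, Da = 0.28, Db = 0.28,
                           Lroot = 3, La = 3, Lb = 3) {
  build_network(
    list(vessel_segment("root", Lroot, diameter = Droot),
         vessel_segment("a", La, diameter = Da),
         vessel_segment("b", Lb, diameter = Db)),
    list(root = c("a", "b")))
}

# coarse solver settings used by the physiological test runs (scaled down
# from the defaults to keep the suite fast; accuracy checks use their own)
fx_coarse_config <- function(dx_target = 0.15, dt = 2e-3, max_cycles = 8,
                             periodic_tol = 2e-3, ...)
  solver_config(dx_target = dx_target, dt = dt, max_cycles = max_cycles,
                periodic_tol = periodic_tol, ...)

# converged resting run on a small synthetic tree (reused by several tests)
fx_resting_run <- function() memo("resting_run", {
  bd <- fx_boundary_data()
  net <- generate_synthetic_tree(seed = 7, n_generations = 3,
                                 root_diameter = 0.35)
  st <- bd$resting$state
  wall <- wall_params(P0 = mmhg_to_cgs(st$diastolic))
  beds <- assign_terminal_beds(net, st,
                               unname(bd$resting$mean_inflow["left"]))
  bnd <- network_boundaries(bd$resting$inflow_left, beds = beds,
                            ventricular = bd$resting$ventricular)
  list(net = net, res = run_to_periodic(net, wall, bnd, fx_coarse_config()))
})

# trapezoid integral
trapz <- function(t, y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)

# gaussian-pulse single-vessel run used by the wave/convergence tests;
# elastic wall (Gamma = 0) so the pulse is not smeared by wall viscosity
fx_pulse_run <- function(ncell, dt, t_end, L = 4, D = 0.3, amp_mmHg = 2,
                         x0_pulse = 1.5, sigma = 0.3) {
  seg <- vessel_segment("v", L, diameter = D, n_points = ncell + 1)
  net <- build_network(list(seg))
  wp <- wall_params(P0 = mmhg_to_cgs(74), gamma_slope = 0,
                    gamma_intercept = 0)
  cfg <- solver_config(dx_target = L / ncell, dt = dt, picard_tol = 1e-11,
                       max_picard = 30, max_cycles = 1)
  A0 <- pi * (D / 2)^2
  c0 <- reference_wave_speed(D, wp)
  ts <- seq(0, 1, length.out = 11)
  wf <- inflow_waveform(ts, rep(1e-9, 11) + 1e-12, state = "resting",
                        diastole_onset_fraction = 0.35)
  Z <- wp$rho * c0 / A0
  bnd <- network_boundaries(wf, resistances = c(v = Z), P_out = wp$P0)
  sys <- coroflow_system(net, wp, bnd, cfg)
  x <- initial_state(sys)
  xc <- sys$mesh$seg_info$v$xc
  xf <- sys$mesh$seg_info$v$xf
  dP <- amp_mmHg * 1333.22 * exp(-(xc - x0_pulse)^2 / (2 * sigma^2))
  dPf <- amp_mmHg * 1333.22 * exp(-(xf - x0_pulse)^2 / (2 * sigma^2))
  x[sys$iP] <- wp$P0 + dP
  x[sys$iQ] <- A0 * dPf / (wp$rho * c0)
  for (s in seq_len(round(t_end / dt)))
    x <- advance_step(sys, x, (s - 1) * dt)
  list(xc = xc, xf = xf, P = x[sys$iP], Q = x[sys$iQ], c0 = c0, sys = sys,
       wp = wp)
}
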