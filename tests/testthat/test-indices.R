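# fabricate a minimal corosim_result on a single vessel with prescribed
# pressure fields (for index arithmetic that needs no fluid dynamics)
fake_result <- function(Pfun, T = 0.9, nt = 91, L = 5, D = 0.3) {
  net <- fx_single_vessel(L = L, D = D)
  wp <- wall_params(P0 = mmhg_to_cgs(74))
  mesh <- build_mesh(net, wp, solver_config(dx_target = 0.1))
  tg <- seq(0, T, length.out = nt)
  xc <- mesh$seg_info$v1$xc
  P <- outer(xc, tg, Pfun)
  structure(list(t = tg, P = P,
                 Q = matrix(1, mesh$NF, nt),
                 A = matrix(pi * (D / 2)^2, mesh$NC, nt),
                 mesh = mesh, period = T, converged = TRUE),
            class = "corosim_result")
}

test_that("wave-free window follows the one-fifth rule", {
  expect_equal(unname(wave_free_window(0.5, 1.0)), c(0.6, 1.0))
  # algebraic identity: window length is 0.8 (T - t_d)
  for (td in c(0.2, 0.33, 0.5, 0.7)) {
    w <- wave_free_window(td, 1.0)
    expect_equal(w[["t_end"]] - w[["t_start"]], 0.8 * (1 - td))
  }
  expect_error(wave_free_window(1.2, 1.0), "inside the cycle")
  expect_error(wave_free_window(0.98, 1.0), "degenerate")
})

test_that("index ratios reduce to constants for constant-ratio fields", {
  # Pd identical to Pp: both indices exactly 1
  res <- fake_result(function(x, t) mmhg_to_cgs(90 + 10 * sin(2 * pi * t / 0.9)))
  pr <- probe_pair(list(segment = "v1", fraction = 0.2),
                   list(segment = "v1", fraction = 0.2))
  expect_equal(compute_cffr(res, pr)$cffr, 1, tolerance = 1e-12)
  expect_equal(compute_cifr(res, pr, 0.4)$cifr, 1, tolerance = 1e-12)
  # constant spatial attenuation: cFFR = ciFR = the constant, any window
  res2 <- fake_result(function(x, t)
    mmhg_to_cgs(90 + 10 * sin(2 * pi * t / 0.9)) * (1 - 0.04 * x))
  pr2 <- probe_pair(list(segment = "v1", fraction = 0),
                    list(segment = "v1", fraction = 1))
  xs <- res2$mesh$seg_info$v1$xc
  expected <- (1 - 0.04 * max(xs)) / (1 - 0.04 * min(xs))
  expect_equal(compute_cffr(res2, pr2)$cffr, expected, tolerance = 1e-12)
  for (td in c(0.3, 0.5))
    expect_equal(compute_cifr(res2, pr2, td)$cifr, expected,
                 tolerance = 1e-12)
})

test_that("wave separation is exact algebra", {
  set.seed(5)
  n <- 200
  P <- mmhg_to_cgs(90) + cumsum(rnorm(n, 0, 50))
  Q <- 2 + cumsum(rnorm(n, 0, 0.01))
  A <- rep(0.07, n)
  ws <- separate_waves(P, Q, A, c = 900)
  # additivity to round-off
  expect_equal(ws$P_forward + ws$P_backward, P - P[1], tolerance = 1e-12)
  expect_equal(ws$dP_forward + ws$dP_backward, diff(P), tolerance = 1e-12)
  # reversing the sign of the velocity increments swaps forward/backward
  ws2 <- separate_waves(P, 2 * Q[1] - Q, A, c = 900)
  expect_equal(ws2$dP_forward, ws$dP_backward, tolerance = 1e-10)
  expect_equal(ws2$dP_backward, ws$dP_forward, tolerance = 1e-10)
})

test_that("diastole-onset detector finds the notch on a synthetic trace", {
  T <- 0.9
  tg <- seq(0, T, length.out = 901)
  sys_part <- mmhg_to_cgs(115) * sin(pi * tg / 0.35)^2 * (tg < 0.35)
  dias <- mmhg_to_cgs(80) * exp(-(tg - 0.35) / 1.5) * (tg >= 0.35)
  P <- mmhg_to_cgs(74) + sys_part + dias   # discontinuous drop = notch
  td <- detect_diastole_onset(tg, P)
  expect_lt(abs(td - 0.35), 0.05)
})

test_that("probe placement sits downstream of the throat, clamped", {
  net <- fx_single_vessel(L = 6, D = 0.3)
  sten <- list(segment_id = "v1", center_fraction = 0.5,
               stenosed_length = 1, area_reduction = 0.6)
  net2 <- apply_stenosis(net, "v1", 0.5, 1, 0.6)
  pr <- place_probes(net2, list(sten))
  expect_identical(pr$proximal$segment, net$root)
  expect_equal(pr$proximal$fraction, 0)
  # 1 cm beyond the 3 cm throat (3 throat diameters < 1 cm)
  expect_equal(pr$distal$fraction, 4 / 6, tolerance = 1e-9)
  # clamped at the segment end for a distal lesion
  pr2 <- place_probes(net2, list(modifyList(sten,
                                            list(center_fraction = 0.95))))
  expect_equal(pr2$distal$fraction, 1)
})

test_that("terminal bed assignment honours the branch total", {
  net <- generate_synthetic_tree(seed = 5, n_generations = 3)
  st <- physiological_state("resting")
  beds <- assign_terminal_beds(net, st, 2.5)
  expect_setequal(names(beds), net$terminals)
  Rtot <- vapply(beds, function(b) b$R_total, numeric(1))
  expect_equal(1 / sum(1 / Rtot), total_branch_resistance(115, 74, 2.5),
               tolerance = 1e-10)
  expect_true(all(vapply(beds, function(b) b$side == "left", logical(1))))
})

test_that("an unobstructed short vessel gives near-unity indices", {
  # a 2 cm, 0.4 cm calibre conduit: friction predicts a drop of ~2 mmHg at
  # hyperaemic branch flow, so both indices must stay within 3% of 1
  net <- fx_single_vessel(L = 2, D = 0.4)
  bd <- fx_boundary_data()
  rec <- run_case(net, list(), boundary_data = bd,
                  config = fx_coarse_config(dx_target = 0.1),
                  case_id = "clean")
  expect_gt(rec$cffr, 0.97); expect_lte(rec$cffr, 1.005)
  expect_gt(rec$cifr, 0.97); expect_lte(rec$cifr, 1.005)
  expect_gt(rec$cifr, rec$cffr)
  # record serialization round-trips the scalars
  f <- tempfile(fileext = ".json")
  write_record(rec, f)
  back <- read_record(f)
  expect_equal(back$cffr, rec$cffr, tolerance = 1e-12)
  expect_equal(back$cifr, rec$cifr, tolerance = 1e-12)
  expect_identical(back$case_id, "clean")
})
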