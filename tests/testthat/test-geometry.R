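test_that("segment construction validates and derives diameters", {
  seg <- vessel_segment("s", 5, diameter = 0.3)
  expect_equal(seg$area_profile, rep(pi * 0.15^2, seg$n_points))
  d <- segment_diameters(seg)
  expect_equal(d, rep(0.3, seg$n_points), tolerance = 1e-14)
  # D0 consistent with A0 to round-off for an explicit profile
  seg2 <- vessel_segment("s2", 2, area_profile = c(0.08, 0.06, 0.05))
  expect_equal(pi * (segment_diameters(seg2) / 2)^2, seg2$area_profile,
               tolerance = 1e-14)
  expect_error(vessel_segment("bad", -1, diameter = 0.3), "length")
  expect_error(vessel_segment("bad", 2, area_profile = c(0.1, -0.1)), "> 0")
})

test_that("build_network handles degenerate and bifurcating trees", {
  net1 <- fx_single_vessel()
  expect_identical(net1$root, "v1")
  expect_identical(net1$terminals, "v1")
  net3 <- fx_bifurcation()
  expect_identical(net3$root, "root")
  expect_setequal(net3$terminals, c("a", "b"))
  expect_length(net3$children, 1)
})

test_that("build_network rejects malformed connectivity naming the culprit", {
  segs <- list(vessel_segment("r", 2, diameter = 0.3),
               vessel_segment("c", 2, diameter = 0.25))
  expect_error(build_network(segs, list(r = "c", c = "r")), "cycle")
  # a disconnected segment with no parent reads as a second root
  extra <- c(segs, list(vessel_segment("o", 1, diameter = 0.2)))
  expect_error(build_network(extra, list(r = "c")), "multiple roots")
  # a disconnected cycle is unreachable from the root: orphaned
  orphan <- c(segs, list(vessel_segment("o1", 1, diameter = 0.2),
                         vessel_segment("o2", 1, diameter = 0.2)))
  expect_error(build_network(orphan, list(r = "c", o1 = "o2", o2 = "o1")),
               "orphan.*o1")
  expect_error(build_network(segs, list()), "multiple roots")
  expect_error(build_network(list(segs[[1]], segs[[1]]), list()), "duplicate")
  expect_error(build_network(segs, list(r = "nope")), "'nope'")
})

test_that("apply_stenosis shapes the area profile as specified", {
  net <- fx_single_vessel(L = 4, D = 0.3)
  a0 <- net$segments$v1$area_profile
  # identity at zero reduction
  net0 <- apply_stenosis(net, "v1", 0.5, 1, 0)
  expect_identical(net0$segments$v1$area_profile, a0)
  # cosine throat reaches 1 - r at the centre
  net6 <- apply_stenosis(net, "v1", 0.5, 1, 0.6)
  ratio <- net6$segments$v1$area_profile / a0
  expect_equal(min(ratio), 0.4, tolerance = 1e-12)
  x <- seq(0, 4, length.out = net$segments$v1$n_points)
  expect_equal(x[which.min(ratio)], 2, tolerance = 0.05)
  # untouched outside the window
  outside <- abs(x - 2) > 0.5
  expect_identical(net6$segments$v1$area_profile[outside], a0[outside])
  # stacked stenoses compose multiplicatively
  netA <- apply_stenosis(net6, "v1", 0.5, 1, 0.3)
  netB_ratio <- ratio * (apply_stenosis(net, "v1", 0.5, 1, 0.3)$
                           segments$v1$area_profile / a0)
  expect_equal(netA$segments$v1$area_profile / a0, netB_ratio,
               tolerance = 1e-12)
  # window overflow is rejected
  expect_error(apply_stenosis(net, "v1", 0.05, 1, 0.5), "exceeds segment")
  # trapezoid has a flat throat
  nt <- apply_stenosis(net, "v1", 0.5, 2, 0.5, shape = "trapezoid")
  rt <- nt$segments$v1$area_profile / a0
  expect_equal(sum(abs(rt - 0.5) < 1e-9) / sum(rt < 1),
               0.5, tolerance = 0.1)
})

test_that("synthetic trees are deterministic and Murray-consistent", {
  n1 <- generate_synthetic_tree(seed = 3, n_generations = 4)
  n2 <- generate_synthetic_tree(seed = 3, n_generations = 4)
  f1 <- tempfile(); f2 <- tempfile()
  write_network(n1, f1); write_network(n2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # single generation degenerates to one segment
  n0 <- generate_synthetic_tree(seed = 1, n_generations = 1)
  expect_length(n0$segments, 1)
  expect_identical(unname(n0$terminals), n0$root)
  # generalized Murray relation at every junction, several seeds
  for (seed in 1:5) {
    net <- generate_synthetic_tree(seed = seed, n_generations = 4)
    for (p in names(net$children)) {
      dp <- utils::tail(segment_diameters(net$segments[[p]]), 1)
      dk <- vapply(net$children[[p]], function(k)
        segment_diameters(net$segments[[k]])[1], numeric(1))
      expect_lt(abs(dp^2.27 - sum(dk^2.27)) / dp^2.27, 1e-12)
    }
  }
  # gamma = 3 symmetric split: closed-form daughter ratio 2^(-1/3)
  sym <- generate_synthetic_tree(seed = 2, n_generations = 2, gamma = 3,
                                 asymmetry_range = c(1, 1),
                                 taper_range = c(1, 1))
  dp <- segment_diameters(sym$segments[[sym$root]])[1]
  dk <- segment_diameters(sym$segments[[sym$children[[sym$root]][1]]])[1]
  expect_equal(dk / dp, 2^(-1 / 3), tolerance = 1e-12)
  expect_error(generate_synthetic_tree(seed = 1, root_diameter = 1), "0.6")
})

test_that("network files round-trip and reject unknown schemas", {
  net <- generate_synthetic_tree(seed = 11, n_generations = 3)
  f <- tempfile(fileext = ".json")
  write_network(net, f)
  back <- read_network(f)
  expect_identical(network_order(back), network_order(net))
  expect_identical(back$side, net$side)
  for (sid in names(net$segments)) {
    expect_equal(back$segments[[sid]]$area_profile,
                 net$segments[[sid]]$area_profile, tolerance = 1e-15)
    expect_equal(back$segments[[sid]]$length, net$segments[[sid]]$length,
                 tolerance = 1e-15)
  }
  bad <- jsonlite::read_json(f)
  bad$schema <- "coroflow-network-999"
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_network(f2), "schema")
  writeLines("not json {", f3 <- tempfile())
  expect_error(read_network(f3), "malformed")
})
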