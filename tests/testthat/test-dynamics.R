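test_that("trajectories started at fixed points stay there", {
  p <- params_at_beta(10)
  nc <- noncooperative_fixed_points(p)
  tr <- integrate_model(nc$pure_a$state, p, t_end = 50, n_samples = 11L,
                        early_exit = FALSE)
  dev <- apply(abs(sweep(tr$states, 2, nc$pure_a$state)), 1, max)
  expect_lt(max(dev), 1e-8)
})

test_that("the symmetric subspace is forward-invariant under integration", {
  p <- params_at_beta(10)
  s0 <- catalytic_state(a = 0.05, b = 0.3, a_bar = 0.05, b_bar = 0.3,
                        M = 10, M_bar = 10)
  tr <- integrate_model(s0, p, t_end = 100, n_samples = 51L,
                        early_exit = FALSE)
  asym <- abs(tr$states[, c("a", "b", "aL", "aR", "M")] -
              tr$states[, c("a_bar", "b_bar", "aL_bar", "aR_bar", "M_bar")])
  expect_lt(max(asym), 1e-9)
})

test_that("endpoint classification labels the basins and flags
          non-converged runs", {
  p <- params_at_beta(10)
  census <- fixed_point_census(p)
  ## substrate-only start: no catalyst can ever arise
  tr_a <- integrate_model(catalytic_state(a = 0.1, a_bar = 0.1, M = 5,
                                          M_bar = 5), p)
  expect_identical(classify_endpoint(tr_a, census), "pure_a")
  ## zero state stays extinct
  tr_0 <- integrate_model(catalytic_state(), p, t_end = 10)
  expect_identical(classify_endpoint(tr_0, census), "extinct")
  ## a seeded pure-b start above threshold reaches the cooperative state
  b0 <- census$pure_b$state
  s <- b0
  s[["a"]] <- 0.05 * b0[["b"]]
  s[["a_bar"]] <- 0.05 * b0[["b"]]
  tr_c <- integrate_model(s, p, t_end = 400, n_samples = 2L)
  expect_identical(classify_endpoint(tr_c, census), "cooperative")
  ## a truncated run is undecided
  tr_short <- integrate_model(s, p, t_end = 2, n_samples = 2L)
  expect_identical(classify_endpoint(tr_short, census), "undecided")
})

test_that("phase portraits show two basins off the window and three in it", {
  grid <- exp(seq(log(0.005), log(0.4), length.out = 4))
  pp6 <- phase_portrait(params_at_beta(6), grid, grid)
  expect_true(all(pp6$label %in% c("pure_a", "pure_b", "undecided")))
  expect_true(all(c("pure_a", "pure_b") %in% pp6$label))
  pp18 <- phase_portrait(params_at_beta(18), grid, grid)
  expect_true(all(pp18$label %in% c("pure_a", "pure_b", "undecided")))
  pp10 <- phase_portrait(params_at_beta(10), grid, grid)
  expect_true("cooperative" %in% pp10$label)
})

test_that("the cooperative basin boundary in seed fraction is a single
          flip below the overshoot region", {
  p <- params_at_beta(10)
  sr <- minimal_seeding_ratio(p, eps_range = c(1e-6, 0.1), n_scan = 20L)
  flips <- sum(diff(sr$scan$cooperative) != 0)
  expect_identical(flips, 1L)
  expect_false(sr$scan$cooperative[1])
  ## the bisected threshold sits inside the scan bracket
  expect_gt(sr$eps, max(sr$scan$eps[!sr$scan$cooperative &
                                    sr$scan$eps < sr$eps]))
  expect_lt(sr$eps, min(sr$scan$eps[sr$scan$cooperative]) * 1.001)
})

test_that("only the catalyst-first emergence pathway reaches the
          cooperative basin", {
  p <- params_at_beta(10)
  ## catalysts losing their insert: a few percent substrate seed suffices
  a_into_b <- minimal_seeding_ratio(p)
  expect_gt(a_into_b$eps, 0)
  expect_lt(a_into_b$eps, 0.1)
  ## the reverse pathway (catalysts arising amid resident substrates)
  ## never crosses into the cooperative basin along this ray — even an
  ## equal-concentration catalyst seed relaxes back to the pure-a state,
  ## which is what makes catalyst-first emergence the plausible pathway
  expect_error(minimal_seeding_ratio(p, direction = "b_into_a"),
               "no seed fraction")
})

test_that("seeding analysis refuses parameters without a cooperative
          state", {
  expect_error(minimal_seeding_ratio(params_at_beta(6)),
               "no stable cooperative")
})

test_that("chain-bound monomer changes balance elongation inflow against
          dilution outflow along trajectories", {
  p <- params_at_beta(10)
  s0 <- catalytic_state(a = 0.02, b = 0.25, a_bar = 0.02, b_bar = 0.25,
                        M = 18, M_bar = 18)
  tr <- integrate_model(s0, p, t_end = 40, n_samples = 3201L,
                        early_exit = FALSE)
  st <- tr$states
  dq <- t(apply(st, 1, function(s) derived_quantities(s, p)))
  grow <- coef(p)[["r"]] * dq[, "m"] *
    (dq[, "chi"] * dq[, "c"] + dq[, "chi_bar"] * dq[, "c_bar"])
  dil <- coef(p)[["delta"]] * (st[, "M"] + st[, "M_bar"])
  simpson <- function(y) {  # uniform grid, odd number of samples
    h <- diff(tr$times[1:2])
    n <- length(y)
    h / 3 * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, 2)]) +
               2 * sum(y[seq(3, n - 2, 2)]))
  }
  dM <- unname((st[nrow(st), "M"] + st[nrow(st), "M_bar"]) -
                 (st[1, "M"] + st[1, "M_bar"]))
  expect_equal(dM, simpson(grow) - simpson(dil), tolerance = 1e-6)
  ## and the free-monomer account closes identically: m + M + M_bar = m0
  expect_equal(unname(dq[, "m"] + st[, "M"] + st[, "M_bar"]),
               rep(100, nrow(st)), tolerance = 1e-12)
})

test_that("integration tolerances do not change basin labels away from
          separatrices", {
  p <- params_at_beta(10)
  g <- c(0.01, 0.2)
  pp1 <- phase_portrait(p, g, g, rtol = 1e-9)
  pp2 <- phase_portrait(p, g, g, rtol = 1e-10)
  expect_false(any(pp1$label == "undecided"))
  expect_identical(pp1$label, pp2$label)
})
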