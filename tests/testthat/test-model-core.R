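test_that("parameter constructors validate their invariants", {
  expect_s3_class(default_chemostat(), "chemostat_params")
  expect_error(chemostat_params(m0 = -1), "positive")
  expect_error(chemostat_params(delta = 0), "positive")
  expect_error(catalytic_params(beta = 10, lam = 0.5), ">= 1")
  expect_error(catalytic_params(beta = -1), "non-negative")
  p <- catalytic_params(beta = 10)
  expect_identical(p$beta_bar, p$beta)  # symmetric default
})

test_that("free monomers are the feed minus chain-bound monomers", {
  p <- default_chemostat()
  expect_identical(free_monomer(p, 0, 0), 100)
  expect_identical(free_monomer(p, 50, 50), 0)
  ## at the random-model steady state, m equals the analytic m*
  expect_equal(free_monomer(p, 50 / 3, 50 / 3), 200 / 3)
})

test_that("primer-fate probabilities follow first-encounter ratios", {
  expect_equal(primer_fate(1, 0, 1, 0), c(phi = 0, phi_bar = 0))
  expect_equal(primer_fate(1, 1, 1, 1), c(phi = 0.5, phi_bar = 0.5))
  expect_equal(primer_fate(3, 1, 1, 3), c(phi = 0.75, phi_bar = 0.25))
  ## empty template family contributes probability 0, not NaN
  expect_equal(primer_fate(1, 1, 0, 0), c(phi = 0, phi_bar = 0.5))
  expect_error(primer_fate(0, 0, 0, 0), "degenerate")
})

test_that("duplex availability is limited by the scarcer strand family", {
  expect_equal(duplex_fractions(1, 1, 1, 1), c(chi = 1, chi_bar = 1))
  expect_equal(duplex_fractions(2, 0, 1, 0), c(chi = 0.5, chi_bar = 1))
  expect_equal(duplex_fractions(0, 1, 0, 3), c(chi = 1, chi_bar = 1 / 3))
  ## the balanced family always has factor 1
  set.seed(42)
  for (k in 1:25) {
    v <- stats::runif(4, 0, 5)
    expect_equal(max(duplex_fractions(v[1], v[2], v[3], v[4])), 1)
  }
})

test_that("random-cleavage derivatives match hand evaluation and vanish at
          the analytic steady state", {
  p <- default_chemostat()
  s <- random_state(c = 1, c_bar = 1, M = 10, M_bar = 10)  # m = 80
  d <- random_rhs(s, p)
  expect_equal(d[["M"]], 80 * 1 - 10)       # r*m*min(c,c_bar) - delta*M
  expect_equal(d[["c"]], 0.015 * 10 - 1)    # beta0*M - delta*c
  expect_equal(d[["M_bar"]], 70)
  ## fixed points: extinct and the analytic coexistence state
  expect_equal(unname(random_rhs(random_state(), p)), rep(0, 4))
  fp <- random_steady_state(p)
  expect_lt(max(abs(random_rhs(fp$state, p))), 1e-10)
})

test_that("catalytic derivatives obey the chain-total balance identity", {
  ## d(c)/dt = beta0*M + beta*phi*a - delta*c must hold algebraically
  set.seed(7)
  p <- params_at_beta(10)
  fl <- coef(p)
  for (k in 1:30) {
    s <- rand_catalytic_state()
    d <- catalytic_rhs(s, p)
    dq <- derived_quantities(s, p)
    lhs <- d[["a"]] + d[["b"]] + d[["aL"]] + d[["aR"]]
    rhs <- fl[["beta0"]] * s[["M"]] + fl[["beta"]] * dq[["phi"]] *
      s[["a"]] - fl[["delta"]] * dq[["c"]]
    expect_equal(lhs, rhs, tolerance = 1e-12)
    lhs_bar <- d[["a_bar"]] + d[["b_bar"]] + d[["aL_bar"]] + d[["aR_bar"]]
    rhs_bar <- fl[["beta0"]] * s[["M_bar"]] + fl[["beta_bar"]] *
      dq[["phi_bar"]] * s[["a_bar"]] - fl[["delta"]] * dq[["c_bar"]]
    expect_equal(lhs_bar, rhs_bar, tolerance = 1e-12)
  }
})

test_that("catalyst-free states reduce exactly to the random-cleavage model", {
  set.seed(11)
  p <- params_at_beta(10)
  for (k in 1:20) {
    cc <- stats::runif(2, 0, 2)
    Ms <- stats::runif(2, 0, 40)
    s <- catalytic_state(a = cc[1], a_bar = cc[2], M = Ms[1], M_bar = Ms[2])
    d <- catalytic_rhs(s, p)
    dr <- random_rhs(random_state(c = cc[1], c_bar = cc[2],
                                  M = Ms[1], M_bar = Ms[2]),
                     p$chemostat)
    expect_equal(d[["a"]], dr[["c"]])
    expect_equal(d[["a_bar"]], dr[["c_bar"]])
    expect_equal(d[["M"]], dr[["M"]])
    expect_equal(d[["M_bar"]], dr[["M_bar"]])
    expect_equal(unname(d[c("b", "aL", "aR", "b_bar", "aL_bar",
                            "aR_bar")]), rep(0, 6))
  }
})

test_that("mirror symmetry closes: swapped states give swapped derivatives", {
  set.seed(13)
  p <- params_at_beta(10)  # beta_bar = beta
  for (k in 1:20) {
    s <- rand_catalytic_state()
    expect_equal(catalytic_rhs(mirror_state(s), p),
                 mirror_state(catalytic_rhs(s, p)), tolerance = 1e-12)
  }
  ## a symmetric state has exactly symmetric derivatives
  s <- catalytic_state(a = 1, b = 2, aL = 0.1, aR = 0.2, a_bar = 1,
                       b_bar = 2, aL_bar = 0.1, aR_bar = 0.2,
                       M = 20, M_bar = 20)
  d <- catalytic_rhs(s, p)
  expect_identical(d[["a"]], d[["a_bar"]])
  expect_identical(d[["b"]], d[["b_bar"]])
  expect_identical(d[["M"]], d[["M_bar"]])
})

test_that("elongation alone conserves chain number and only consumes
          monomers", {
  ## with negligible dilution and cleavage, d(c)/dt ~ 0 and dM/dt >= 0
  p <- catalytic_params(beta = 1e-14, lam = 2,
                        chemostat = chemostat_params(m0 = 100,
                                                     delta = 1e-14,
                                                     r = 1, beta0 = 1e-14))
  set.seed(17)
  for (k in 1:10) {
    s <- rand_catalytic_state()
    d <- catalytic_rhs(s, p)
    expect_lt(abs(d[["a"]] + d[["b"]] + d[["aL"]] + d[["aR"]]), 1e-10)
    expect_gt(d[["M"]], -1e-10)
  }
})

test_that("no field flows negative: boundary derivatives are inflow-only", {
  set.seed(19)
  p <- params_at_beta(10)
  nm <- names(catalytic_state())
  for (k in 1:40) {
    s <- rand_catalytic_state()
    zero_out <- sample(nm, sample(1:4, 1))
    s[zero_out] <- 0
    d <- catalytic_rhs(s, p)
    expect_true(all(d[zero_out] >= -1e-12))
  }
})

test_that("state constructors reject unphysical values", {
  expect_error(random_state(c = -1), "non-negative")
  expect_error(catalytic_state(M = -0.1), "non-negative")
  expect_error(random_state(c = NaN), "finite")
})
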