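## Shared fixtures: the reference study conditions (printed rates beta0 =
## 0.015, delta = 1, lambda = 2; unprinted chemostat defaults r = 1,
## m0 = 100) and small generators for property-style tests.

default_chemostat <- function() chemostat_params(m0 = 100, delta = 1,
                                                 r = 1, beta0 = 0.015)

params_at_beta <- function(beta, lam = 2, beta0 = 0.015, m0 = 100,
                           delta = 1, r = 1) {
  catalytic_params(beta = beta, lam = lam,
                   chemostat = chemostat_params(m0 = m0, delta = delta,
                                                r = r, beta0 = beta0))
}

## random physical catalytic states (m >= 0 guaranteed)
rand_catalytic_state <- function(m0 = 100) {
  conc <- stats::runif(8, 0, 2)
  Ms <- stats::runif(2, 0, m0 / 2)
  catalytic_state(a = conc[1], b = conc[2], aL = conc[3], aR = conc[4],
                  a_bar = conc[5], b_bar = conc[6], aL_bar = conc[7],
                  aR_bar = conc[8], M = Ms[1], M_bar = Ms[2])
}

## mirror swap of a catalytic state
mirror_state <- function(s) {
  stats::setNames(s[c("a_bar", "b_bar", "aL_bar", "aR_bar",
                      "a", "b", "aL", "aR", "M_bar", "M")], names(s))
}
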