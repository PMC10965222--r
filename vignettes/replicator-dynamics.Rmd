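---
title: "Cleavage-driven replicator dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleavage-driven replicator dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligocleave)
```

## The system

`oligocleave` models a chemostat pool of information-coding oligomers
(proto-RNA-like heteropolymers) that replicate without enzymes: during
"night" phases chains hybridize with complementary partners and primers
are extended by templated polymerization; "day" phases melt all duplexes.
The central observation is that *cleavage creates primers*: every
scission of a chain adds one new growing end, so breakup promotes
proliferation. All lengths and concentrations are renormalized so that
the minimal hybridization (primer) length $l_0$ is 1; monomer-type
quantities ($m_0$, $M$, $m$) are measured in units of $l_0$-mers.

### Random cleavage

Two mutually templating families (fragments of a master sequence, total
concentration $c$, and of its complement, $\bar c$) grow at rate
$r\,m\,\min(c,\bar c)$ — only duplexed chains elongate, and the scarcer
family limits pairing — and fragment spontaneously at rate $\beta_0$ per
bond ($M$ bonds per unit volume). With dilution $\delta$ and feed $m_0$:

$$\dot M = r m \min(c, \bar c) - \delta M, \qquad
  \dot c = \beta_0 M - \delta c, \qquad m = m_0 - M - \bar M.$$

The steady state is symmetric with mean chain length
$\langle L\rangle = M/c = \delta/\beta_0 = r m^*/\delta$, free monomers
pinned at $m^* = \delta^2/(\beta_0 r)$, and
$c = \tfrac12(\beta_0 m_0/\delta - \delta/r)$; survival requires
$\beta_0 m_0 r > \delta^2$ (`survival_condition()`). These closed forms
are `random_steady_state()` and serve as the oracle for the integrators
throughout the test suite.

### Catalyzed cleavage

A hammerhead-like catalyst is modelled as a sister subpopulation $b$
(and complement $\bar b$) of the substrate $a$ ($\bar a$), distinguished
by a short catalytic insert: $\bar b$ cleaves $a$ at rate $\beta$ at a
specific site, producing a left fragment $a_L$ (which can only mature
back into $a$) and a right fragment $a_R$ whose fate depends on its
first hybridization partner: with probability $\phi = \bar b/(\bar a +
\bar b)$ it matures into a catalyst $b$, else into a substrate. The
catalyst route is slowed by the asymmetry factor $\lambda \ge 1$ (extra
insert length, hairpin unzipping). Duplex availability enters through
$\chi = \min(a+b, \bar a+\bar b)/(a+b) \le 1$. The ten-variable system
(`catalytic_rhs()`) follows; the substrate equation is fixed by
requiring the family total to obey
$\dot c = \beta_0 M + \beta\phi a - \delta c$ (each cleavage event adds
exactly one primer).

## Fixed-point machinery

All steady-state work runs on the mirror-symmetric subspace
($a=\bar a$, ..., $M = \bar M$; forward-invariant when
$\beta = \bar\beta$), where $\chi = \bar\chi = 1$ and the system
reduces to five coordinates. Choices that matter:

* **Root finding.** Damped Newton with a central-difference Jacobian
  (step $10^{-7}\max(1,|x_i|)$). Residuals are judged relative to the
  natural rate scale $\delta \max(1, |x_i|)$ with tolerance $10^{-10}$,
  so convergence is attainable at any concentration scale. Stability is
  classified from the reduced $5\times5$ spectrum (eigenvalue real
  parts vs. $10^{-8}\delta$); the full $10\times10$ spectrum — stability
  against symmetry-breaking perturbations — is computed and stored
  alongside, and is confirmed negative for the cooperative state at the
  reference conditions.
* **Bootstrap seeding.** The cooperative point at the reference
  conditions ($\beta_0=0.015$, $\lambda=2$, $\delta=1$, $\beta=10$) is
  strongly catalyst-dominated ($b \approx 7a$). A seemingly natural
  Newton seed with $a = b$ lies in the pure-$a$ basin and fails;
  `cooperative_fixed_point()` therefore bootstraps by *relaxation along
  the emergence pathway*: integrate from the pure-$b$ state plus a few
  percent substrate seed, then Newton-polish the endpoint. Several seed
  fractions are tried because too large a seed overshoots into the
  pure-$a$ basin.
* **Continuation.** `continuation_in_beta()` and `existence_window()`
  track branches by warm-started Newton (natural-parameter
  continuation) with adaptive step factors that shrink toward the
  requested edge resolution ($10^{-4}$ relative by default). The saddle
  branch is tracked from its own seed family (cooperative shape with
  the catalytic part shrunk).
* **Disappearance threshold.** `disappearance_threshold()` walks
  $\beta_0$ upward with an adaptive relative step while keeping a live
  stable-branch solution; on failure the step halves, down to $10^{-3}$
  relative. Tracking matters: near the closing point the window is
  narrow and fresh detection from fixed seeds loses the branch well
  before the true threshold (naive re-detection underestimates it by
  ~30%). The result at $\lambda = 2$ is $\beta_0/\delta \approx 0.056$,
  and it is verified (as a property test) to be independent of $m_0$
  and $r$ — only $\beta/\delta$, $\beta_0/\delta$ and $\lambda$ enter,
  as a scaling of the symmetric steady-state equations shows. The
  procedural resolution of the tracked threshold is $\sim 1$–$2\%$
  (adaptive continuation keeps or loses the branch slightly differently
  depending on the concentration scale), so the independence property is
  asserted at that resolution.
  The asymptotic bounds $4\lambda < \beta/\delta <
  (\lambda-1)\delta/(4\beta_0)$ (`approx_bounds()`) are recovered by
  the numeric window to better than 1% at $\beta_0/\delta = 10^{-4}$.

## Dynamics and basins

`integrate_model()` uses `deSolve`'s lsoda/lsodar (relative tolerance
$10^{-9}$, absolute $10^{-12}$) with an optional early-exit event when
the RHS norm drops below $10^{-8}$. Reported states are clamped at
zero; solver internals are not, keeping the right-hand side smooth.
The $\min()$ kink in $\chi$ is inactive at the symmetric fixed points
we classify.

A structural subtlety drives two choices. At a pure (one-type)
steady state the linearized growth rate of the missing type is
$\beta_0 M^*/c^* = \delta$ — exactly the dilution rate — so invasion is
*marginal at linear order* and the invader decays only algebraically
($\sim 1/t$). Endpoint classification (`classify_endpoint()`) therefore
defaults to strict tolerances (per-coordinate $10^{-3}$, RHS norm
$10^{-6}$) suitable for the exponentially approached states, while
`phase_portrait()` uses a longer horizon ($1000/\delta$) and looser
labels ($2\times10^{-2}$, $10^{-2}$), validated by robustness under
tolerance refinement.

`minimal_seeding_ratio()` measures the basin boundary along the
emergence pathway: pure-$b$ state plus symmetric seed
$a = \bar a = \varepsilon b$. The cooperative classification along
$\varepsilon$ is an *interval*, not a half-line — seeds above
$\sim 0.2$ overshoot into the pure-$a$ basin — so the scan brackets the
lower flip and bisects there (to ~1%, i.e. two significant figures).
At the reference conditions the threshold is $\varepsilon^* \approx
0.02$, and it moves only weakly with $m_0$ and $r$. The reverse
direction (`b_into_a`: catalysts arising amid resident substrates)
never crosses into the cooperative basin along its seeding ray at these
conditions — even an equal-concentration catalyst seed relaxes back to
the pure-substrate state — which is what makes catalyst-first emergence
the plausible pathway.

## Evolutionary dynamics

Fitness is $m^*/m^*_{\rm coop}$: the steady state leaving the lowest
free-monomer level competitively excludes all rivals. It is exactly 1
without a cooperative state and $>2$ with one (the cooperative monomer
level is below $m^*/2$ wherever it exists). `fitness_landscape()`
computes rows by warm-started continuation; its ridge sits, for each
$\lambda$, at the smallest cooperative $\beta$.

`metropolis_evolve()` models catalyst evolution as a Metropolis walk in
$(\lambda, \beta)$ with fitness as negative energy. The temperature
(0.05 fitness units), multiplicative uniform proposals (half-width 0.1
in log space) and 500 steps are package defaults chosen to follow the
ridge without freezing; all are arguments. Proposals leaving the
cooperative region keep fitness 1 (survival by random cleavage) rather
than being rejected. During the walk the cooperative solve is
warm-started Newton from the last cooperative state — full
(integration-bootstrapped) detection happens only at step 0 — so a walk
started outside the cooperative region sees a flat landscape. A single
seeded generator drives each run; the caller's RNG stream is restored
afterwards.

## Study conditions and problem sizes

The reference conditions fix the printed rates $\beta_0 = 0.015$,
$\delta = 1$, $\lambda = 2$ and $\beta \in \{6, 10, 18\}$ for the three
regimes. The chemostat constants $m_0$ and $r$ are not determined by
these; the package defaults are $r = 1$ and $m_0 = 100$, which satisfy
the survival condition ($\beta_0 m_0 r = 1.5 > \delta^2$) with a
comfortable margin while keeping concentrations $O(10^{-1})$–$O(10^1)$.
Every quantity advertised as scale-free (existence windows, the
disappearance threshold, the fitness bound) is property-tested for
invariance under doubling $m_0$ or $r$; basin geometry (portraits,
seeding ratios) is reported at the defaults, with the $m_0$/$r$
sensitivity checked to be mild. Small-$\beta_0$ convergence checks
scale $m_0 \propto 1/\beta_0$ so the random-model state survives to
seed the bootstrap.

Test and example problem sizes are kept modest by design — basin grids
of $4\times4$, continuation grids of a few dozen points, 20 Monte Carlo
replicates of 500 steps — because every quantity of interest is either
a fixed-point property (cheap Newton solves) or a bisection whose cost
grows only logarithmically with precision.

## Limitations

* Chains are not sequence-resolved; hybridization thermodynamics,
  complexes of more than two strands, and finite night-length effects
  are outside the model.
* The asymmetric case $\beta \ne \bar\beta$ is implemented (the barred
  equations use $\bar\beta, \bar\phi, \bar\chi$) but all quantitative
  results here use the symmetric $\bar\beta = \beta$.
* Fixed points are located numerically on the symmetric subspace; no
  closed-form parametric solution of the cooperative branch is used.
* The marginal invasion mode makes "time to settle" ill-defined near
  the pure states; classifications there are tolerance-based, as
  described above.

```{r example, eval = FALSE}
p <- catalytic_params(beta = 10)           # beta0 0.015, lambda 2, delta 1
summary(cooperative_fixed_point(p))        # the four-population state
existence_window(p)                        # beta range of cooperation
fitness(p)                                 # m*/m_coop* ~ 6.8
minimal_seeding_ratio(p)$eps               # ~ 0.02
disappearance_threshold(lam = 2)$beta0_over_delta  # ~ 0.056
```
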