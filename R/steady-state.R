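## Fixed points: location, classification, stability.

.new_fixed_point <- function(state, kind, params, eigenvalues = NULL,
                             eigenvalues_full = NULL, residual = NA_real_) {
  p <- .flat_params(params)
  stable <- if (is.null(eigenvalues)) NA else
    all(Re(eigenvalues) < 1e-8 * p$delta)
  stable_full <- if (is.null(eigenvalues_full)) NA else
    all(Re(eigenvalues_full) < 1e-8 * p$delta)
  structure(list(state = state, kind = kind, params = params,
                 eigenvalues = eigenvalues,
                 eigenvalues_full = eigenvalues_full,
                 stable = stable, stable_full = stable_full,
                 residual = residual),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("Fixed point (%s)%s\n", x$kind,
              if (isTRUE(x$stable)) ", stable"
              else if (isFALSE(x$stable)) ", unstable" else ""))
  print(signif(x$state, 6))
  if (!is.null(x$eigenvalues))
    cat("  leading eigenvalue Re:",
        signif(max(Re(x$eigenvalues)), 4), "\n")
  invisible(x)
}

#' @export
summary.fixed_point <- function(object, ...) {
  p <- .flat_params(object$params)
  m <- if ("M_bar" %in% names(object$state))
    p$m0 - object$state[["M"]] - object$state[["M_bar"]]
  else p$m0 - 2 * object$state[["M"]]
  out <- list(kind = object$kind, state = object$state, m = m,
              stable = object$stable, stable_full = object$stable_full,
              eigenvalues = object$eigenvalues,
              eigenvalues_full = object$eigenvalues_full,
              residual = object$residual,
              m_star = p$delta^2 / (p$beta0 * p$r))
  class(out) <- "summary.fixed_point"
  out
}

#' @export
print.summary.fixed_point <- function(x, ...) {
  cat(sprintf("Fixed point: %s (stable on symmetric subspace: %s, full: %s)\n",
              x$kind, x$stable, x$stable_full))
  print(signif(x$state, 6))
  cat(sprintf("  free monomers m = %.6g (random-model m* = %.6g)\n",
              x$m, x$m_star))
  invisible(x)
}

#' Residuals of a fixed point
#'
#' The right-hand side of the governing equations evaluated at the stored
#' state — zero (to solver tolerance) for a genuine fixed point.
#' @param object a `fixed_point`.
#' @param ... unused.
#' @export
residuals.fixed_point <- function(object, ...) {
  if (length(object$state) == 4L)
    random_rhs(object$state, .chemostat_of(object$params))
  else catalytic_rhs(object$state, object$params)
}

#' Survival condition of mutually templating chains
#'
#' Replication by random cleavage sustains the population only when
#' cleavage and elongation outpace dilution: `beta0 * m0 * r > delta^2`,
#' equivalently `m0 > m*` with `m* = delta^2 / (beta0 * r)`.
#'
#' @param params [chemostat_params()] (or [catalytic_params()], whose
#'   chemostat part is used).
#' @return `TRUE` if the surviving steady state exists (strict inequality).
#' @export
survival_condition <- function(params) {
  p <- .flat_params(params)
  p$beta0 * p$m0 * p$r > p$delta^2
}

#' Analytic steady state of the random-cleavage model
#'
#' In the surviving regime the steady state is a symmetric mixture
#' `c = c_bar` with free monomers pinned at `m* = delta^2 / (beta0 * r)`,
#' mean chain length `<L> = M/c = delta/beta0 = r*m*/delta`, and
#' `c = (beta0*m0/delta - delta/r) / 2`. Below the survival threshold
#' (`m0 <= m*`) the only steady state is extinction.
#'
#' @param params a [chemostat_params()] object.
#' @return A `fixed_point` whose `state` is a [random_state()]; `kind` is
#'   `"random_coexistence"` or `"extinct"`.
#' @export
random_steady_state <- function(params) {
  params <- .chemostat_of(params)
  p <- .flat_params(params)
  m_star <- p$delta^2 / (p$beta0 * p$r)
  if (p$m0 > m_star) {
    cc <- 0.5 * (p$beta0 * p$m0 / p$delta - p$delta / p$r)
    M <- cc * p$delta / p$beta0
    st <- random_state(c = cc, c_bar = cc, M = M, M_bar = M)
    kind <- "random_coexistence"
  } else {
    st <- random_state()
    kind <- "extinct"
  }
  ev <- eigen(.num_jacobian(function(x, pp) random_rhs(x, pp), st, params),
              only.values = TRUE)$values
  fp <- .new_fixed_point(st, kind, params, eigenvalues = ev,
                         residual = max(abs(random_rhs(st, params))))
  fp$m <- if (kind == "extinct") p$m0 else m_star
  fp$mean_length <- if (kind == "extinct") NA_real_ else p$delta / p$beta0
  fp
}

#' Non-cooperative fixed points of the catalytic model
#'
#' With only one chain type present (pure `a`/`a_bar` or pure `b`/`b_bar`)
#' no catalytic cleavage can occur and the system reduces to the
#' random-cleavage model: both points inherit its analytic steady state.
#'
#' @param params a [catalytic_params()] object.
#' @return List with elements `pure_a` and `pure_b` (class `fixed_point`).
#'   In the extinct regime both carry the extinct state and are flagged by
#'   `kind = "extinct"`.
#' @export
noncooperative_fixed_points <- function(params) {
  rs <- random_steady_state(params$chemostat)
  surviving <- rs$kind == "random_coexistence"
  cc <- if (surviving) rs$state[["c"]] else 0
  M <- if (surviving) rs$state[["M"]] else 0
  mk <- function(which) {
    st <- if (which == "a")
      catalytic_state(a = cc, a_bar = cc, M = M, M_bar = M)
    else catalytic_state(b = cc, b_bar = cc, M = M, M_bar = M)
    ev_full <- eigen(.num_jacobian(function(x, pp) catalytic_rhs(x, pp),
                                   st, params), only.values = TRUE)$values
    ev_red <- eigen(.num_jacobian(.reduced_rhs, .sym_restrict(st),
                                  .flat_params(params)),
                    only.values = TRUE)$values
    .new_fixed_point(st, if (surviving) paste0("pure_", which) else "extinct",
                     params, eigenvalues = ev_red,
                     eigenvalues_full = ev_full,
                     residual = max(abs(catalytic_rhs(st, params))))
  }
  list(pure_a = mk("a"), pure_b = mk("b"))
}

#' Extinct fixed point of the catalytic model
#' @param params a [catalytic_params()] object.
#' @return A `fixed_point` with the zero state.
#' @export
extinct_fixed_point <- function(params) {
  st <- catalytic_state()
  ev_full <- eigen(.num_jacobian(function(x, pp) catalytic_rhs(x, pp),
                                 st, params), only.values = TRUE)$values
  .new_fixed_point(st, "extinct", params, eigenvalues_full = ev_full,
                   eigenvalues = eigen(.num_jacobian(
                     .reduced_rhs, stats::setNames(numeric(5), .SYM_NAMES),
                     .flat_params(params)), only.values = TRUE)$values,
                   residual = 0)
}

## Newton-polish a symmetric 5-coordinate seed into a classified fixed
## point; NULL when Newton fails, leaves the positive orthant, or the root
## is not truly four-population (a or b absent).
.coop_from_seed <- function(params, seed) {
  p <- .flat_params(params)
  sol <- .newton(.reduced_rhs, seed, p, rate = p$delta)
  if (!sol$converged) return(NULL)
  x <- sol$x
  if (any(x < -1e-12)) return(NULL)
  x <- pmax(x, 0)
  if (min(x[1:2]) < 1e-6 || any(x[3:5] < 1e-10)) return(NULL)
  ev_red <- eigen(.num_jacobian(.reduced_rhs, x, p),
                  only.values = TRUE)$values
  ## The pure states are marginal against invasion (near-zero eigenvalue
  ## along the missing type), so Newton can stall on a pseudo-root that is
  ## a pure state plus a noise-level minority (everything but the majority
  ## type below ~1e-6 relative; the stall displacement along the marginal
  ## mode is ~sqrt(residual tol)). A genuine interior point keeps its
  ## minority type and fragments well above that; a genuine saddle is
  ## decisively unstable.
  stable_red <- all(Re(ev_red) < 1e-8 * p$delta)
  if ((min(x[1:2]) + x[[3L]] + x[[4L]]) < 1e-5 * max(x[1:2]))
    return(NULL)
  if (!stable_red && max(Re(ev_red)) <= 1e-6 * p$delta) return(NULL)
  full <- .sym_expand(x)
  ev_full <- eigen(.num_jacobian(function(s, pp) catalytic_rhs(s, pp),
                                 full, params), only.values = TRUE)$values
  stable <- all(Re(ev_red) < 1e-8 * p$delta)
  fp <- .new_fixed_point(full, if (stable) "cooperative" else "saddle",
                         params, eigenvalues = ev_red,
                         eigenvalues_full = ev_full,
                         residual = sol$residual)
  fp$reduced_state <- stats::setNames(x, .SYM_NAMES)
  fp$m <- p$m0 - 2 * x[[5L]]
  fp
}

## Integrate the reduced system from a seed and Newton-polish the endpoint.
.coop_by_relaxation <- function(params, seed, t_end = NULL) {
  p <- .flat_params(params)
  if (is.null(t_end)) t_end <- 1000 / p$delta
  out <- tryCatch(
    deSolve::ode(y = seed, times = c(0, t_end),
                 func = function(t, y, pp) list(.reduced_rhs(y, pp)),
                 parms = p, method = "lsoda",
                 rtol = 1e-10, atol = 1e-12, maxsteps = 5e4),
    warning = function(w) NULL, error = function(e) NULL)
  if (is.null(out)) return(NULL)
  .coop_from_seed(params, pmax(out[nrow(out), -1L], 0))
}

## Default physically-motivated bootstrap seeds: the pure-b state plus a
## small substrate subpopulation (the emergence pathway), at several seed
## fractions because too large a seed overshoots into the pure-a basin.
.coop_bootstrap_seeds <- function(params) {
  p <- .flat_params(params)
  cc <- 0.5 * (p$beta0 * p$m0 / p$delta - p$delta / p$r)
  if (cc <= 0) return(list())
  M <- cc * p$delta / p$beta0
  lapply(c(0.1, 0.03, 0.3),
         function(eps) c(a = eps * cc, b = cc, aL = 0, aR = 0, M = M))
}

#' Cooperative fixed point of the catalytic model
#'
#' Locates the steady state in which all four subpopulations (`a`, `b` and
#' their complements) coexist, sustained by catalyzed cleavage. The root is
#' found by damped Newton iteration on the mirror-symmetric five-coordinate
#' reduction (`a`, `b`, `aL`, `aR`, `M`); with no usable `guess` the search
#' first relaxes the system by time integration from the pure-b state
#' seeded with a small substrate subpopulation — the pathway by which the
#' cooperative state is reached dynamically. Stability is classified from
#' the reduced Jacobian spectrum; the full ten-variable spectrum (stability
#' against symmetry-breaking perturbations) is computed and stored
#' alongside.
#'
#' @param params a [catalytic_params()] object.
#' @param guess optional symmetric seed: either a 5-vector
#'   `(a, b, aL, aR, M)` or a 10-element [catalytic_state()].
#' @param relax if `TRUE` (default) fall back to integrate-then-polish when
#'   direct Newton fails.
#' @return A `fixed_point` with `kind` `"cooperative"` (stable) or
#'   `"saddle"`, or `NULL` when no positive four-population root is found.
#' @examples
#' \donttest{
#' fp <- cooperative_fixed_point(catalytic_params(beta = 10))
#' summary(fp)
#' }
#' @export
cooperative_fixed_point <- function(params, guess = NULL, relax = TRUE) {
  if (!is.null(guess)) {
    if (length(guess) == 10L) guess <- .sym_restrict(guess)
    fp <- .coop_from_seed(params, guess)
    if (!is.null(fp)) return(fp)
    if (!relax) return(NULL)
    fp <- .coop_by_relaxation(params, guess)
    if (!is.null(fp)) return(fp)
  }
  if (!relax && is.null(guess)) return(NULL)
  for (seed in .coop_bootstrap_seeds(params)) {
    fp <- .coop_by_relaxation(params, seed)
    if (!is.null(fp) && fp$kind == "cooperative") return(fp)
  }
  NULL
}

#' All fixed points of the catalytic model at one parameter set
#'
#' Census of the extinct, pure-a, pure-b and (when present) cooperative and
#' saddle fixed points. The saddle on the symmetric subspace is searched by
#' Newton from seeds interpolating between the cooperative point (or a
#' nominal interior shape) and the non-cooperative states.
#'
#' @param params a [catalytic_params()] object.
#' @param find_saddle also attempt to locate the interior saddle point.
#' @return Named list of `fixed_point` objects: `extinct`, `pure_a`,
#'   `pure_b`, optionally `cooperative` and `saddle`.
#' @export
fixed_point_census <- function(params, find_saddle = TRUE) {
  out <- c(list(extinct = extinct_fixed_point(params)),
           noncooperative_fixed_points(params))
  coop <- cooperative_fixed_point(params)
  if (!is.null(coop) && coop$kind == "cooperative") out$cooperative <- coop
  if (find_saddle) {
    sad <- .find_saddle(params, coop)
    if (!is.null(sad)) out$saddle <- sad
  }
  out
}

## interior saddle: Newton from seeds shrinking the catalyst/fragment part
## of the cooperative shape toward the pure-b and pure-a corners
.find_saddle <- function(params, coop = NULL) {
  p <- .flat_params(params)
  cc <- 0.5 * (p$beta0 * p$m0 / p$delta - p$delta / p$r)
  if (cc <= 0) return(NULL)
  M <- cc * p$delta / p$beta0
  seeds <- list()
  if (!is.null(coop)) {
    x <- coop$reduced_state
    for (f in c(0.3, 0.1, 0.03, 0.01))
      seeds <- c(seeds, list(c(f * x[[1L]], x[[2L]], f * x[[3L]],
                               f * x[[4L]], x[[5L]])))
  }
  for (eps in c(0.01, 0.003, 0.03, 0.1))
    seeds <- c(seeds, list(c(eps * cc, cc, eps * cc * 0.1, eps * cc * 0.1,
                             M)))
  for (s in seeds) {
    fp <- .coop_from_seed(params, stats::setNames(s, .SYM_NAMES))
    if (!is.null(fp) && fp$kind == "saddle") return(fp)
  }
  NULL
}
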