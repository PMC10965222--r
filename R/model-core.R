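## State layouts. States are plain named numeric vectors (deSolve style).
.RANDOM_NAMES <- c("c", "c_bar", "M", "M_bar")
.CAT_NAMES <- c("a", "b", "aL", "aR", "a_bar", "b_bar", "aL_bar", "aR_bar",
                "M", "M_bar")
.SYM_NAMES <- c("a", "b", "aL", "aR", "M")

#' State vector of the random-cleavage model
#'
#' @param c,c_bar fragment concentrations of the master-sequence
#'   subpopulation and its complement.
#' @param M,M_bar monomers incorporated in chains of each subpopulation
#'   (l0-mer units).
#' @return Named numeric vector with elements `c`, `c_bar`, `M`, `M_bar`.
#' @export
random_state <- function(c = 0, c_bar = 0, M = 0, M_bar = 0) {
  s <- c(c = c, c_bar = c_bar, M = M, M_bar = M_bar)
  if (any(!is.finite(s)) || any(s < 0))
    stop("all state components must be finite and non-negative",
         call. = FALSE)
  s
}

#' State vector of the catalyzed-cleavage model
#'
#' Ten concentrations: uncleaved substrate chains `a`, catalyst chains `b`,
#' left and right cleavage-fragment primers `aL`, `aR`, their complementary
#' counterparts (`*_bar`), and the chain-bound monomer densities `M`,
#' `M_bar` of the two strand families.
#'
#' @param a,b,aL,aR concentrations in the master-sequence family.
#' @param a_bar,b_bar,aL_bar,aR_bar complementary-family counterparts.
#' @param M,M_bar chain-bound monomer densities (l0-mer units).
#' @return Named numeric vector of length 10.
#' @export
catalytic_state <- function(a = 0, b = 0, aL = 0, aR = 0,
                            a_bar = 0, b_bar = 0, aL_bar = 0, aR_bar = 0,
                            M = 0, M_bar = 0) {
  s <- c(a = a, b = b, aL = aL, aR = aR, a_bar = a_bar, b_bar = b_bar,
         aL_bar = aL_bar, aR_bar = aR_bar, M = M, M_bar = M_bar)
  if (any(!is.finite(s)) || any(s < 0))
    stop("all state components must be finite and non-negative",
         call. = FALSE)
  s
}

#' Free monomer concentration
#'
#' Monomers not incorporated into any chain: `m = m0 - M - M_bar`. The value
#' may go (transiently) negative inside a solver step; callers that enforce
#' physicality clamp reported states, not solver internals.
#'
#' @param params [chemostat_params()] or [catalytic_params()].
#' @param M,M_bar chain-bound monomer densities.
#' @return Free monomer concentration (may be negative; pure arithmetic).
#' @export
free_monomer <- function(params, M, M_bar) {
  .chemostat_of(params)$m0 - M - M_bar
}

#' Primer-fate probabilities
#'
#' A right cleavage fragment matures into a catalyst chain if its first
#' templating partner carries the catalytic insert: `phi = b_bar /
#' (a_bar + b_bar)` for the master family and `phi_bar = b / (a + b)` for
#' the complementary family. A probability whose template family is empty is
#' defined as 0 (no conversion can occur).
#'
#' @param a,b,a_bar,b_bar subpopulation concentrations.
#' @return Named numeric vector `c(phi, phi_bar)`.
#' @export
primer_fate <- function(a, b, a_bar, b_bar) {
  if (a + b <= 0 && a_bar + b_bar <= 0)
    stop("degenerate state: both strand families are empty", call. = FALSE)
  phi <- if (a_bar + b_bar > 0) b_bar / (a_bar + b_bar) else 0
  phi_bar <- if (a + b > 0) b / (a + b) else 0
  c(phi = phi, phi_bar = phi_bar)
}

#' Duplex-availability factors
#'
#' When the two strand families are unbalanced, only the scarcer one is
#' fully paired: `chi = min(a + b, a_bar + b_bar) / (a + b)` and the barred
#' analogue. A factor with an empty denominator family is vacuously 1.
#' At least one of the two factors always equals 1.
#'
#' @inheritParams primer_fate
#' @return Named numeric vector `c(chi, chi_bar)`.
#' @export
duplex_fractions <- function(a, b, a_bar, b_bar) {
  tot <- a + b
  tot_bar <- a_bar + b_bar
  mn <- min(tot, tot_bar)
  c(chi = if (tot > 0) mn / tot else 1,
    chi_bar = if (tot_bar > 0) mn / tot_bar else 1)
}

#' Derived quantities of a catalytic state
#'
#' @param state a [catalytic_state()] vector.
#' @param params a [catalytic_params()] object.
#' @return Named vector with `m`, `phi`, `phi_bar`, `chi`, `chi_bar`, and
#'   the family totals `c` and `c_bar`.
#' @export
derived_quantities <- function(state, params) {
  p <- .flat_params(params)
  m <- p$m0 - state[["M"]] - state[["M_bar"]]
  tot <- state[["a"]] + state[["b"]]
  tot_bar <- state[["a_bar"]] + state[["b_bar"]]
  pf <- c(phi = if (tot_bar > 0) state[["b_bar"]] / tot_bar else 0,
          phi_bar = if (tot > 0) state[["b"]] / tot else 0)
  df <- duplex_fractions(state[["a"]], state[["b"]],
                         state[["a_bar"]], state[["b_bar"]])
  c(m = m, pf, df,
    c = tot + state[["aL"]] + state[["aR"]],
    c_bar = tot_bar + state[["aL_bar"]] + state[["aR_bar"]])
}

#' Time derivatives of the random-cleavage model
#'
#' Elongation consumes free monomers at rate `r * m * min(c, c_bar)` (only
#' duplexed chains elongate, and the scarcer family limits pairing); chains
#' fragment at rate `beta0` per bond, each scission adding one primer; the
#' chemostat dilutes everything at rate `delta`:
#' `dM/dt = r*m*min(c, c_bar) - delta*M`, `dc/dt = beta0*M - delta*c`,
#' with the barred equations obtained by swapping the two families.
#'
#' @param state a [random_state()] vector.
#' @param params a [chemostat_params()] object.
#' @return Named numeric vector of derivatives of `c`, `c_bar`, `M`, `M_bar`.
#' @export
random_rhs <- function(state, params) {
  p <- .flat_params(params)
  m <- p$m0 - state[["M"]] - state[["M_bar"]]
  grow <- p$r * m * min(state[["c"]], state[["c_bar"]])
  c(c = p$beta0 * state[["M"]] - p$delta * state[["c"]],
    c_bar = p$beta0 * state[["M_bar"]] - p$delta * state[["c_bar"]],
    M = grow - p$delta * state[["M"]],
    M_bar = grow - p$delta * state[["M_bar"]])
}

#' Time derivatives of the catalyzed-cleavage model
#'
#' The full ten-variable system. For the master family (complementary
#' family by the substitution `a <-> a_bar`, ..., `(beta, phi, chi) ->
#' (beta_bar, phi_bar, chi_bar)`):
#' \describe{
#' \item{left fragments}{`daL/dt = beta*phi*a - r*m*chi*aL - delta*aL`}
#' \item{right fragments}{`daR/dt = beta*phi*a - r*m*chi*(1-phi)*aR -
#'   r*m*chi*(phi/lam)*aR - delta*aR`}
#' \item{catalysts}{`db/dt = beta0*M*phi_bar + r*m*chi*(phi/lam)*aR -
#'   delta*b`}
#' \item{substrates}{`da/dt = beta0*M*(1-phi_bar) + r*m*chi*aL +
#'   r*m*chi*(1-phi)*aR - beta*phi*a - delta*a`}
#' \item{chain-bound monomers}{`dM/dt = r*m*chi*c - delta*M`, with
#'   `c = a + b + aL + aR`.}
#' }
#' The substrate equation is fixed by requiring that the family total obeys
#' `dc/dt = beta0*M + beta*phi*a - delta*c` (random cleavage plus catalyzed
#' cleavage each add one primer per event; dilution removes chains).
#'
#' @param state a [catalytic_state()] vector.
#' @param params a [catalytic_params()] object.
#' @return Named numeric vector of the ten derivatives.
#' @export
catalytic_rhs <- function(state, params) {
  p <- .flat_params(params)
  a <- state[["a"]]; b <- state[["b"]]
  aL <- state[["aL"]]; aR <- state[["aR"]]
  ab <- state[["a_bar"]]; bb <- state[["b_bar"]]
  aLb <- state[["aL_bar"]]; aRb <- state[["aR_bar"]]
  M <- state[["M"]]; Mb <- state[["M_bar"]]

  m <- p$m0 - M - Mb
  tot <- a + b
  tot_bar <- ab + bb
  phi <- if (tot_bar > 0) bb / tot_bar else 0
  phi_bar <- if (tot > 0) b / tot else 0
  mn <- min(tot, tot_bar)
  chi <- if (tot > 0) mn / tot else 1
  chi_bar <- if (tot_bar > 0) mn / tot_bar else 1
  rm_ <- p$r * m * chi
  rm_bar <- p$r * m * chi_bar

  c(a = p$beta0 * M * (1 - phi_bar) + rm_ * aL + rm_ * (1 - phi) * aR -
      p$beta * phi * a - p$delta * a,
    b = p$beta0 * M * phi_bar + rm_ * (phi / p$lam) * aR - p$delta * b,
    aL = p$beta * phi * a - rm_ * aL - p$delta * aL,
    aR = p$beta * phi * a - rm_ * (1 - phi) * aR - rm_ * (phi / p$lam) * aR -
      p$delta * aR,
    a_bar = p$beta0 * Mb * (1 - phi) + rm_bar * aLb +
      rm_bar * (1 - phi_bar) * aRb - p$beta_bar * phi_bar * ab -
      p$delta * ab,
    b_bar = p$beta0 * Mb * phi + rm_bar * (phi_bar / p$lam) * aRb -
      p$delta * bb,
    aL_bar = p$beta_bar * phi_bar * ab - rm_bar * aLb - p$delta * aLb,
    aR_bar = p$beta_bar * phi_bar * ab - rm_bar * (1 - phi_bar) * aRb -
      rm_bar * (phi_bar / p$lam) * aRb - p$delta * aRb,
    M = rm_ * (a + b + aL + aR) - p$delta * M,
    M_bar = rm_bar * (ab + bb + aLb + aRb) - p$delta * Mb)
}

## --- symmetric reduced system --------------------------------------------
## On the mirror-symmetric subspace (a = a_bar, ..., M = M_bar, beta =
## beta_bar) the two families coincide, chi = chi_bar = 1 and phi = phi_bar,
## leaving 5 coordinates (a, b, aL, aR, M) with m = m0 - 2M. All fixed-point
## work runs here; the subspace is forward-invariant.
.reduced_rhs <- function(x, p) {
  a <- x[[1L]]; b <- x[[2L]]; aL <- x[[3L]]; aR <- x[[4L]]; M <- x[[5L]]
  m <- p$m0 - 2 * M
  tot <- a + b
  phi <- if (tot > 0) b / tot else 0
  rm_ <- p$r * m
  c(p$beta0 * M * (1 - phi) + rm_ * aL + rm_ * (1 - phi) * aR -
      p$beta * phi * a - p$delta * a,
    p$beta0 * M * phi + rm_ * (phi / p$lam) * aR - p$delta * b,
    p$beta * phi * a - rm_ * aL - p$delta * aL,
    p$beta * phi * a - rm_ * (1 - phi) * aR - rm_ * (phi / p$lam) * aR -
      p$delta * aR,
    rm_ * (a + b + aL + aR) - p$delta * M)
}

.sym_expand <- function(x) {
  catalytic_state(a = max(x[[1L]], 0), b = max(x[[2L]], 0),
                  aL = max(x[[3L]], 0), aR = max(x[[4L]], 0),
                  a_bar = max(x[[1L]], 0), b_bar = max(x[[2L]], 0),
                  aL_bar = max(x[[3L]], 0), aR_bar = max(x[[4L]], 0),
                  M = max(x[[5L]], 0), M_bar = max(x[[5L]], 0))
}

.sym_restrict <- function(state) {
  stats::setNames(0.5 * c(state[["a"]] + state[["a_bar"]],
                          state[["b"]] + state[["b_bar"]],
                          state[["aL"]] + state[["aL_bar"]],
                          state[["aR"]] + state[["aR_bar"]],
                          state[["M"]] + state[["M_bar"]]), .SYM_NAMES)
}

## --- numerics shared across modules --------------------------------------

## central-difference Jacobian, step h = 1e-7 * max(1, |x_i|)
.num_jacobian <- function(f, x, ...) {
  n <- length(x)
  f0 <- f(x, ...)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    h <- 1e-7 * max(1, abs(x[[i]]))
    xp <- x; xm <- x
    xp[[i]] <- x[[i]] + h
    xm[[i]] <- x[[i]] - h
    J[, i] <- (f(xp, ...) - f(xm, ...)) / (2 * h)
  }
  J
}

## damped Newton on f(x, ...) = 0. Residuals are judged relative to the
## natural rate scale `rate * max(1, |x_i|)` so convergence is attainable
## whatever the concentration scale (components of f carry units of
## concentration/time).
.newton <- function(f, x0, ..., tol = 1e-12, maxit = 80L, rate = 1) {
  res_of <- function(fx, x) max(abs(fx) / (rate * pmax(1, abs(x))))
  x <- x0
  fx <- f(x, ...)
  for (k in seq_len(maxit)) {
    if (res_of(fx, x) < tol) break
    J <- .num_jacobian(f, x, ...)
    dx <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(dx)) return(list(x = x, converged = FALSE,
                                 residual = res_of(fx, x)))
    step <- 1
    repeat {
      xn <- x + step * dx
      fn <- f(xn, ...)
      if (res_of(fn, xn) < res_of(fx, x) || step < 1e-4) break
      step <- step / 2
    }
    x <- xn
    fx <- fn
  }
  list(x = x, converged = res_of(fx, x) < 1e-10,
       residual = res_of(fx, x))
}
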