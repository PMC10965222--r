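#' Chemostat and kinetic parameters of the random-cleavage model
#'
#' The shared environment of both models: a well-mixed reservoir supplied
#' with fresh monomers at concentration `m0` and uniformly diluted at rate
#' `delta`. Chains elongate by templated polymerization at rate `r * m`
#' (with `m` the free monomer concentration) and break spontaneously at rate
#' `beta0` per breakable bond. All lengths and concentrations are
#' renormalized so that the minimal hybridization (primer) length l0 equals
#' 1; monomer-type concentrations are therefore measured in units of
#' l0-mers.
#'
#' @param m0 feed monomer concentration (l0-mer units), > 0.
#' @param delta dilution rate (1/time), > 0.
#' @param r elongation rate constant (1/(concentration * time)), > 0.
#' @param beta0 spontaneous cleavage rate per breakable bond (1/time), > 0.
#'
#' @return An object of class `"chemostat_params"`.
#' @seealso [catalytic_params()], [random_steady_state()],
#'   [survival_condition()]
#' @examples
#' p <- chemostat_params(m0 = 100, delta = 1, r = 1, beta0 = 0.015)
#' survival_condition(p)
#' @export
chemostat_params <- function(m0 = 100, delta = 1, r = 1, beta0 = 0.015) {
  for (nm in c("m0", "delta", "r", "beta0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single strictly positive number",
           call. = FALSE)
  }
  structure(list(m0 = m0, delta = delta, r = r, beta0 = beta0),
            class = "chemostat_params")
}

#' Parameters of the catalyzed-cleavage model
#'
#' Extends [chemostat_params()] with the catalytic constants of the
#' four-subpopulation model: substrate chains `a` are cleaved at rate `beta`
#' when hybridized with complementary catalysts `b_bar`, and complementary
#' substrates `a_bar` at rate `beta_bar` by catalysts `b`. Maturation of a
#' right cleavage fragment into a catalyst chain is slowed by the elongation
#' asymmetry factor `lam` (>= 1), reflecting the extra catalytic insert and
#' hairpin unzipping.
#'
#' @param beta catalyzed cleavage rate of `a` chains by `b_bar` (1/time).
#' @param beta_bar catalyzed cleavage rate of `a_bar` chains by `b`
#'   (1/time); defaults to `beta` (the symmetric case used throughout).
#' @param lam elongation asymmetry factor, dimensionless, >= 1.
#' @param chemostat a [chemostat_params()] object with the shared constants.
#' @inheritParams chemostat_params
#'
#' @return An object of class `"catalytic_params"` with fields `chemostat`,
#'   `beta`, `beta_bar` and `lam`.
#' @examples
#' p <- catalytic_params(beta = 10)
#' p
#' @export
catalytic_params <- function(beta, beta_bar = beta, lam = 2,
                             chemostat = chemostat_params(m0, delta, r, beta0),
                             m0 = 100, delta = 1, r = 1, beta0 = 0.015) {
  if (!inherits(chemostat, "chemostat_params"))
    stop("'chemostat' must be a chemostat_params object", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("'beta' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(beta_bar) || length(beta_bar) != 1L || beta_bar < 0)
    stop("'beta_bar' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(lam) || length(lam) != 1L || lam < 1)
    stop("'lam' must be a single number >= 1", call. = FALSE)
  structure(list(chemostat = chemostat, beta = beta, beta_bar = beta_bar,
                 lam = lam),
            class = "catalytic_params")
}

## flat named list of all kinetic constants, whichever params class comes in
.flat_params <- function(params) {
  if (inherits(params, "catalytic_params"))
    c(params$chemostat[c("m0", "delta", "r", "beta0")],
      params[c("beta", "beta_bar", "lam")])
  else if (inherits(params, "chemostat_params"))
    params[c("m0", "delta", "r", "beta0")]
  else stop("expected chemostat_params or catalytic_params", call. = FALSE)
}

.chemostat_of <- function(params) {
  if (inherits(params, "catalytic_params")) params$chemostat else params
}

#' @export
print.chemostat_params <- function(x, ...) {
  cat("Chemostat parameters (l0 = 1 units):\n")
  cat(sprintf("  m0 = %g, delta = %g, r = %g, beta0 = %g\n",
              x$m0, x$delta, x$r, x$beta0))
  cat(sprintf("  survival condition beta0*m0*r > delta^2: %s (%.4g vs %.4g)\n",
              survival_condition(x), x$beta0 * x$m0 * x$r, x$delta^2))
  invisible(x)
}

#' @export
print.catalytic_params <- function(x, ...) {
  ch <- x$chemostat
  cat("Catalyzed-cleavage model parameters (l0 = 1 units):\n")
  cat(sprintf("  m0 = %g, delta = %g, r = %g, beta0 = %g\n",
              ch$m0, ch$delta, ch$r, ch$beta0))
  cat(sprintf("  beta = %g, beta_bar = %g, lambda = %g\n",
              x$beta, x$beta_bar, x$lam))
  invisible(x)
}

#' @export
coef.chemostat_params <- function(object, ...) unlist(object)

#' @export
coef.catalytic_params <- function(object, ...) unlist(.flat_params(object))

## convenience used everywhere: replace beta (and optionally others)
.with_beta <- function(params, beta, beta_bar = beta, lam = params$lam) {
  catalytic_params(beta = beta, beta_bar = beta_bar, lam = lam,
                   chemostat = params$chemostat)
}
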