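## Fitness, fitness landscape, Metropolis co-evolution of (lam, beta).

#' Ecosystem fitness of a parameter set
#'
#' Competition for monomers drives selection: the steady state that leaves
#' the lowest residual free-monomer level excludes all rivals. Fitness is
#' quantified as `m*/m_coop*`, the random-model monomer level divided by
#' that of the stable cooperative state — exactly 1 when no cooperative
#' state exists (the system then survives on random cleavage alone), and
#' above 2 whenever it does.
#'
#' @param params a [catalytic_params()] object; the survival condition
#'   must hold.
#' @param warm optional symmetric 5-coordinate seed for the cooperative
#'   solve (used for warm-started sweeps); `relax = FALSE` with a warm seed
#'   skips the integration bootstrap.
#' @param relax passed to [cooperative_fixed_point()].
#' @return Numeric fitness >= 1.
#' @examples
#' \donttest{
#' fitness(catalytic_params(beta = 10))  # ~ 6.8
#' fitness(catalytic_params(beta = 6))   # 1
#' }
#' @export
fitness <- function(params, warm = NULL, relax = TRUE) {
  p <- .flat_params(params)
  if (!survival_condition(params))
    stop("extinct regime: survival condition beta0*m0*r > delta^2 fails",
         call. = FALSE)
  m_star <- p$delta^2 / (p$beta0 * p$r)
  fp <- cooperative_fixed_point(params, guess = warm, relax = relax)
  if (is.null(fp) || fp$kind != "cooperative") return(1)
  m_star / fp$m
}

#' Fitness landscape over catalytic rate enhancement and asymmetry
#'
#' Evaluates `m*/m_coop*` on a grid of catalytic cleavage enhancement
#' `beta/beta0` and elongation asymmetry `lam`. Rows are computed by
#' warm-started continuation along increasing `beta` (with an integration
#' bootstrap for each row's first cooperative cell), so the cooperative
#' region is tracked rather than re-detected cell by cell. Cells outside
#' the cooperative region have fitness exactly 1; the landscape's ridge
#' sits, for each `lam`, at the smallest `beta` admitting a cooperative
#' state.
#'
#' @param beta_over_beta0_grid increasing grid of `beta/beta0`.
#' @param lam_grid grid of asymmetry factors (>= 1).
#' @param base a [chemostat_params()] object.
#' @return Matrix of fitness values (rows: `lam_grid`, columns:
#'   `beta_over_beta0_grid`), class `"fitness_landscape"`.
#' @export
fitness_landscape <- function(beta_over_beta0_grid, lam_grid,
                              base = chemostat_params()) {
  stopifnot(all(beta_over_beta0_grid > 0), all(lam_grid >= 1))
  bgrid <- sort(beta_over_beta0_grid) * base$beta0
  F <- matrix(1, length(lam_grid), length(bgrid),
              dimnames = list(lam = signif(lam_grid, 6),
                              beta_over_beta0 = signif(bgrid / base$beta0,
                                                       6)))
  for (i in seq_along(lam_grid)) {
    lam <- lam_grid[i]
    if (lam <= 1) next  # no cooperative state without elongation asymmetry
    params <- catalytic_params(beta = bgrid[1], lam = lam, chemostat = base)
    w <- existence_window(params)
    if (w$empty) next
    inside <- which(bgrid >= w$beta_min & bgrid <= w$beta_max)
    if (!length(inside)) next
    ## continuation outward from the anchor
    j0 <- inside[which.min(abs(bgrid[inside] - w$beta_anchor))]
    for (dir in list(seq(j0, max(inside)),
                     if (j0 > min(inside)) seq(j0 - 1L, min(inside))
                     else integer())) {
      warm <- w$x_anchor
      for (j in dir) {
        fp <- .coop_warm(params, bgrid[j], warm)
        if (is.null(fp)) break
        warm <- fp$reduced_state
        F[i, j] <- (base$delta^2 / (base$beta0 * base$r)) / fp$m
      }
    }
  }
  structure(F, class = c("fitness_landscape", class(F)))
}

#' @export
plot.fitness_landscape <- function(x, ...) {
  lam <- as.numeric(rownames(x))
  bb0 <- as.numeric(colnames(x))
  graphics::image(bb0, lam, t(unclass(x)), log = "x",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = expression(beta / beta[0]), ylab = expression(lambda),
                  ...)
  invisible(x)
}

#' Metropolis Monte Carlo co-evolution of the catalytic parameters
#'
#' Models evolution of the catalyst as a Metropolis walk in `(lam, beta)`
#' with fitness playing the role of negative energy. At each step both
#' parameters receive independent multiplicative proposals `exp(eta)`,
#' `eta ~ Uniform(-proposal_scale, proposal_scale)`; the move is accepted
#' with probability `min(1, exp((F' - F)/temperature))`. Proposals that
#' leave the cooperative region are not rejected outright — the system
#' survives on random cleavage with fitness 1. Under selection both `lam`
#' and `beta` climb the fitness ridge together.
#'
#' The cooperative solve is warm-started from the last accepted
#' cooperative state, so a step's fitness is evaluated by Newton
#' continuation rather than fresh detection.
#'
#' @param start numeric `c(lam, beta)` starting point (fitness must be
#'   computable there).
#' @param n_steps number of Monte Carlo steps.
#' @param temperature selection temperature in fitness units.
#' @param proposal_scale half-width of the uniform log-step proposals.
#' @param seed integer RNG seed; runs are reproducible given the seed.
#' @param base a [chemostat_params()] object.
#' @return Data frame of class `"evolution_path"`: one row per step with
#'   `step`, `lam`, `beta`, `fitness`, `accepted`; the starting point is
#'   row 0. Attribute `seed` records the RNG seed.
#' @examples
#' \donttest{
#' ev <- metropolis_evolve(c(lam = 2, beta = 9), n_steps = 50, seed = 1)
#' }
#' @export
metropolis_evolve <- function(start, n_steps = 500L, temperature = 0.05,
                              proposal_scale = 0.1, seed = 1L,
                              base = chemostat_params()) {
  stopifnot(length(start) == 2L, all(start > 0), start[[1L]] >= 1)
  lam <- start[[1L]]
  beta <- start[[2L]]
  pfun <- function(lam, beta)
    catalytic_params(beta = beta, lam = lam, chemostat = base)
  ## private RNG stream; caller's RNG state is untouched
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  ## Full (integration-bootstrapped) detection only at step 0; inside the
  ## walk the cooperative solve is warm-started Newton from the last
  ## cooperative state. Starting outside the cooperative region is allowed
  ## but then the walk sees a flat fitness of 1.
  fp0 <- cooperative_fixed_point(pfun(lam, beta))
  warm <- if (!is.null(fp0) && fp0$kind == "cooperative")
    fp0$reduced_state else NULL
  m_star <- base$delta^2 / (base$beta0 * base$r)
  fit_at <- function(lam, beta) {
    if (is.null(warm)) return(1)
    fp <- .coop_warm(pfun(lam, beta), beta, warm)
    if (!is.null(fp)) {
      warm <<- fp$reduced_state
      return(m_star / fp$m)
    }
    1
  }
  F <- if (is.null(warm)) 1 else m_star / fp0$m
  n <- n_steps + 1L
  lam_v <- numeric(n); beta_v <- numeric(n)
  fit_v <- numeric(n); acc_v <- logical(n)
  lam_v[1L] <- lam; beta_v[1L] <- beta; fit_v[1L] <- F; acc_v[1L] <- TRUE
  for (k in seq_len(n_steps)) {
    lam_p <- max(1, lam * exp(stats::runif(1, -proposal_scale,
                                           proposal_scale)))
    beta_p <- beta * exp(stats::runif(1, -proposal_scale, proposal_scale))
    warm_bak <- warm
    F_p <- fit_at(lam_p, beta_p)
    acc <- stats::runif(1) < exp(min(0, (F_p - F) / temperature))
    if (acc) {
      lam <- lam_p
      beta <- beta_p
      F <- F_p
    } else {
      warm <- warm_bak  # proposal discarded; keep the resident's seed
    }
    lam_v[k + 1L] <- lam; beta_v[k + 1L] <- beta
    fit_v[k + 1L] <- F; acc_v[k + 1L] <- acc
  }
  structure(data.frame(step = 0:n_steps, lam = lam_v, beta = beta_v,
                       fitness = fit_v, accepted = acc_v),
            class = c("evolution_path", "data.frame"),
            seed = seed, temperature = temperature,
            proposal_scale = proposal_scale)
}

#' @export
plot.evolution_path <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$step, x$fitness, type = "l", xlab = "step",
                 ylab = "fitness", ...)
  graphics::plot(x$beta, x$lam, type = "l", log = "xy",
                 xlab = expression(beta), ylab = expression(lambda), ...)
  graphics::points(x$beta[1], x$lam[1], pch = 16, col = "blue")
  graphics::points(x$beta[nrow(x)], x$lam[nrow(x)], pch = 16, col = "red")
  invisible(x)
}
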