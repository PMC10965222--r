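## Time integration, basin classification, phase portraits, seeding ratio.

#' Integrate a model trajectory
#'
#' Stiff-capable integration (lsoda) of either the four-variable
#' random-cleavage model (when `params` is a [chemostat_params()]) or the
#' full ten-variable catalyzed-cleavage system (when `params` is a
#' [catalytic_params()]). An optional early-exit event stops the run once
#' the right-hand-side norm falls below `rhs_tol` (fixed points are
#' approached exponentially at rate ~ `delta`, so the default horizon
#' `200/delta` is generous).
#'
#' @param state0 initial [random_state()] or [catalytic_state()].
#' @param params model parameters; their class selects the model.
#' @param t_end integration horizon (default `200/delta`).
#' @param n_samples number of sampled time points (>= 2).
#' @param rtol,atol solver tolerances.
#' @param early_exit stop when the RHS infinity-norm drops below `rhs_tol`.
#' @param rhs_tol early-exit threshold on the RHS norm.
#' @return Object of class `"trajectory"`: list with `times`, `states`
#'   (matrix, one row per sample; reported states clamped at 0), `params`,
#'   and `terminal_label` (`NA` until classified).
#' @examples
#' p <- catalytic_params(beta = 10)
#' tr <- integrate_model(catalytic_state(b = 0.25, b_bar = 0.25,
#'                                       M = 5, M_bar = 5), p, t_end = 20)
#' @export
integrate_model <- function(state0, params, t_end = NULL, n_samples = 101L,
                            rtol = 1e-9, atol = 1e-12, early_exit = TRUE,
                            rhs_tol = 1e-8) {
  p <- .flat_params(params)
  if (is.null(t_end)) t_end <- 200 / p$delta
  stopifnot(t_end > 0, n_samples >= 2L)
  catalytic <- inherits(params, "catalytic_params")
  rhs <- if (catalytic) catalytic_rhs else random_rhs
  func <- function(t, y, pp) list(rhs(y, params))
  times <- seq(0, t_end, length.out = n_samples)
  args <- list(y = state0, times = times, func = func, parms = NULL,
               rtol = rtol, atol = atol, maxsteps = 1e5)
  if (early_exit) {
    args$method <- "lsodar"
    args$rootfunc <- function(t, y, pp)
      max(abs(rhs(y, params))) - rhs_tol
  } else {
    args$method <- "lsoda"
  }
  out <- tryCatch(do.call(deSolve::ode, args), error = function(e) e)
  if (inherits(out, "error"))
    stop("integration failed: ", conditionMessage(out), call. = FALSE)
  states <- pmax(unclass(out)[, -1L, drop = FALSE], 0)
  structure(list(times = unclass(out)[, 1L], states = states,
                 params = params, terminal_label = NA_character_),
            class = "trajectory")
}

#' Simulate method for model parameter objects
#'
#' `simulate()` on a parameter object integrates the corresponding model
#' from `state0` — the models are deterministic, so `nsim`/`seed` are
#' ignored.
#' @param object a [chemostat_params()] or [catalytic_params()] object.
#' @param nsim,seed ignored (deterministic dynamics).
#' @param state0 initial state; defaults to a small symmetric inoculum.
#' @param ... passed to [integrate_model()].
#' @return A `"trajectory"` object.
#' @export
simulate.catalytic_params <- function(object, nsim = 1, seed = NULL,
                                      state0 = NULL, ...) {
  if (is.null(state0)) {
    p <- .flat_params(object)
    state0 <- catalytic_state(a = 0.01, b = 0.01, a_bar = 0.01,
                              b_bar = 0.01, M = 0.04 * p$delta / p$beta0,
                              M_bar = 0.04 * p$delta / p$beta0)
  }
  integrate_model(state0, object, ...)
}

#' @rdname simulate.catalytic_params
#' @export
simulate.chemostat_params <- function(object, nsim = 1, seed = NULL,
                                      state0 = NULL, ...) {
  if (is.null(state0)) {
    p <- .flat_params(object)
    state0 <- random_state(c = 0.01, c_bar = 0.01,
                           M = 0.01 * p$delta / p$beta0,
                           M_bar = 0.01 * p$delta / p$beta0)
  }
  integrate_model(state0, object, ...)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d samples on [0, %.4g]%s\n", length(x$times),
              max(x$times),
              if (is.na(x$terminal_label)) ""
              else paste0(", endpoint: ", x$terminal_label)))
  cat("final state:\n")
  print(signif(x$states[nrow(x$states), ], 6))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, log = "", ...) {
  st <- x$states
  keep <- setdiff(colnames(st), c("M", "M_bar"))
  graphics::matplot(x$times, st[, keep, drop = FALSE], type = "l", lty = 1,
                    xlab = "time", ylab = "concentration", log = log, ...)
  graphics::legend("topright", legend = keep, col = seq_along(keep),
                   lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

#' Classify the endpoint of a trajectory
#'
#' Labels the terminal state with the nearest fixed point, provided every
#' coordinate agrees within a scale-aware relative tolerance and the
#' right-hand side has essentially vanished; otherwise `"undecided"`.
#'
#' @param traj a `"trajectory"`.
#' @param fixed_points list of `fixed_point` objects (e.g. from
#'   [fixed_point_census()]) computed at the same parameters.
#' @param state_tol per-coordinate relative tolerance (default `1e-3`).
#' @param rhs_tol maximum RHS infinity-norm at the endpoint.
#' @return Character label: a `kind` from `fixed_points` or `"undecided"`.
#' @export
classify_endpoint <- function(traj, fixed_points, state_tol = 1e-3,
                              rhs_tol = 1e-6) {
  end <- traj$states[nrow(traj$states), ]
  catalytic <- inherits(traj$params, "catalytic_params")
  rhs <- if (catalytic) catalytic_rhs else random_rhs
  if (max(abs(rhs(end, traj$params))) > rhs_tol) return("undecided")
  best <- "undecided"
  best_d <- Inf
  for (fp in fixed_points) {
    f <- fp$state[names(end)]
    thr <- state_tol * pmax(abs(f), 1e-2)
    d <- max(abs(end - f) / pmax(abs(f), 1e-2))
    if (all(abs(end - f) <= thr) && d < best_d) {
      best <- fp$kind
      best_d <- d
    }
  }
  best
}

#' Phase portrait over a grid of initial compositions
#'
#' For every pair `(a0, b0)` on the grid, a mirror-symmetric initial state
#' is built (`a = a_bar = a0`, `b = b_bar = b0`, no fragments) with
#' chain-bound monomers at the random-model steady-state mean length,
#' `M = M_bar = (a0 + b0) * delta / beta0`; the system is integrated and
#' the endpoint classified against the fixed-point census. In the
#' cooperative regime three basins appear; outside it only the two
#' non-cooperative labels.
#'
#' Classification tolerances are looser than [classify_endpoint()]'s
#' defaults because the non-cooperative states are only marginally stable
#' against invasion by the missing chain type (the linearized invasion
#' rate cancels against dilution), so the invader decays algebraically and
#' strict convergence is impractically slow; the looser labels are
#' validated by their robustness under tolerance refinement.
#'
#' @param params a [catalytic_params()] object.
#' @param a_grid,b_grid positive initial concentrations of substrate and
#'   catalyst chains.
#' @param M_mode `"mean_length"` (default, see above) or `"unit"` for
#'   `M = a0 + b0`.
#' @param t_end integration horizon (default `1000/delta`; the marginal
#'   invasion mode needs a long runway).
#' @param state_tol,rhs_tol classification tolerances, see
#'   [classify_endpoint()].
#' @param ... passed to [integrate_model()].
#' @return Data frame of class `"phase_portrait"` with columns `a0`, `b0`,
#'   `label`.
#' @examples
#' \donttest{
#' pp <- phase_portrait(catalytic_params(beta = 10),
#'                      a_grid = c(0.01, 0.3), b_grid = c(0.01, 0.3))
#' }
#' @export
phase_portrait <- function(params, a_grid, b_grid,
                           M_mode = c("mean_length", "unit"),
                           t_end = NULL, state_tol = 2e-2, rhs_tol = 1e-2,
                           ...) {
  M_mode <- match.arg(M_mode)
  stopifnot(all(a_grid > 0), all(b_grid > 0))
  p <- .flat_params(params)
  if (is.null(t_end)) t_end <- 1000 / p$delta
  census <- fixed_point_census(params)
  grid <- expand.grid(a0 = a_grid, b0 = b_grid)
  grid$label <- vapply(seq_len(nrow(grid)), function(i) {
    a0 <- grid$a0[i]
    b0 <- grid$b0[i]
    M0 <- if (M_mode == "mean_length") (a0 + b0) * p$delta / p$beta0
          else a0 + b0
    s0 <- catalytic_state(a = a0, b = b0, a_bar = a0, b_bar = b0,
                          M = M0, M_bar = M0)
    tr <- integrate_model(s0, params, t_end = t_end, n_samples = 2L, ...)
    classify_endpoint(tr, census, state_tol = state_tol,
                      rhs_tol = rhs_tol)
  }, character(1L))
  class(grid) <- c("phase_portrait", "data.frame")
  attr(grid, "params") <- params
  grid
}

#' @export
plot.phase_portrait <- function(x, ...) {
  labs <- sort(unique(x$label))
  cols <- stats::setNames(
    grDevices::hcl.colors(max(3L, length(labs)), "Dark 3")[seq_along(labs)],
    labs)
  graphics::plot(x$a0, x$b0, log = "xy", pch = 15, col = cols[x$label],
                 xlab = expression(a[0]), ylab = expression(b[0]), ...)
  graphics::legend("topleft", legend = labs, col = cols, pch = 15,
                   cex = 0.8, bg = "white")
  invisible(x)
}

#' Minimal seeding ratio for reaching the cooperative state
#'
#' Starting from one non-cooperative steady state, how large a seed of the
#' missing chain type is needed to cross the saddle into the cooperative
#' basin? For `direction = "a_into_b"` the pure-b state is seeded with
#' `a = a_bar = eps * b` (the emergence pathway: catalysts losing their
#' insert by a copying error); `"b_into_a"` is the reverse. The lower
#' basin-boundary value of `eps` is bracketed on a log-spaced scan and then
#' bisected. (Too large a seed can overshoot into the seeded type's own
#' basin, so the cooperative range of `eps` is an interval; the minimal
#' ratio is its lower edge.)
#'
#' @param params a [catalytic_params()] object with a stable cooperative
#'   point.
#' @param direction `"a_into_b"` (default) or `"b_into_a"`.
#' @param eps_range search interval for the seed fraction.
#' @param n_scan log-spaced scan points used to bracket the flip.
#' @param t_end integration horizon per trial (default `400/delta`;
#'   trajectories linger near the saddle close to the threshold).
#' @param tol relative bisection tolerance (default 1%, i.e. ~2 significant
#'   figures).
#' @return List with `eps` (the minimal ratio), `bracket`, `direction`.
#' @examples
#' \donttest{
#' minimal_seeding_ratio(catalytic_params(beta = 10))  # ~ 0.02
#' }
#' @export
minimal_seeding_ratio <- function(params, direction = c("a_into_b",
                                                        "b_into_a"),
                                  eps_range = c(1e-6, 1), n_scan = 20L,
                                  t_end = NULL, tol = 0.01) {
  direction <- match.arg(direction)
  p <- .flat_params(params)
  if (is.null(t_end)) t_end <- 400 / p$delta
  census <- fixed_point_census(params, find_saddle = FALSE)
  if (is.null(census$cooperative))
    stop("no stable cooperative fixed point at these parameters",
         call. = FALSE)
  nc <- noncooperative_fixed_points(params)
  resident <- if (direction == "a_into_b") nc$pure_b else nc$pure_a
  cc <- if (direction == "a_into_b") resident$state[["b"]]
        else resident$state[["a"]]
  trial <- function(eps) {
    s0 <- resident$state
    if (direction == "a_into_b") {
      s0[["a"]] <- eps * cc
      s0[["a_bar"]] <- eps * cc
    } else {
      s0[["b"]] <- eps * cc
      s0[["b_bar"]] <- eps * cc
    }
    tr <- integrate_model(s0, params, t_end = t_end, n_samples = 2L)
    classify_endpoint(tr, census) == "cooperative"
  }
  ## bracket the lower flip on a log-spaced scan
  eps_scan <- exp(seq(log(eps_range[1]), log(eps_range[2]),
                      length.out = n_scan))
  hits <- vapply(eps_scan, trial, logical(1L))
  if (!any(hits))
    stop("no seed fraction in 'eps_range' reaches the cooperative state",
         call. = FALSE)
  i_hi <- which(hits)[1L]
  if (i_hi == 1L)
    stop("cooperative already at the smallest scanned seed; ",
         "extend 'eps_range' downward", call. = FALSE)
  lo <- eps_scan[i_hi - 1L]
  hi <- eps_scan[i_hi]
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (trial(mid)) hi <- mid else lo <- mid
  }
  list(eps = signif(sqrt(lo * hi), 3), bracket = c(lo, hi),
       direction = direction, scan = data.frame(eps = eps_scan,
                                                cooperative = hits))
}
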