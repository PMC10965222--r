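## Continuation in beta, existence windows, disappearance threshold.

## Walk the stable cooperative branch in beta from a known point, updating
## the warm seed at every accepted step. `fac` shrinks toward 1 near the
## branch end, giving edge resolution ~ (final fac - 1) * beta.
.walk_branch <- function(params, beta_start, x_start, direction,
                         fac0 = 1.02, fac_min = 1 + 1e-5,
                         want = "cooperative") {
  b <- beta_start
  x <- x_start
  fac <- fac0
  path <- list()
  while (fac > fac_min) {
    b2 <- b * fac^direction
    fp <- .coop_from_seed(.with_beta(params, b2), x)
    if (!is.null(fp) && fp$kind == want) {
      b <- b2
      x <- fp$reduced_state
      path[[length(path) + 1L]] <- fp
    } else {
      fac <- sqrt(fac)
    }
  }
  list(beta_end = b, x_end = x, path = path)
}

## Stable cooperative point at `beta` given a live warm seed; NULL if lost.
.coop_warm <- function(params, beta, warm) {
  fp <- .coop_from_seed(.with_beta(params, beta), warm)
  if (!is.null(fp) && fp$kind == "cooperative") fp else NULL
}

#' Asymptotic existence bounds of the cooperative state
#'
#' Small-`beta0` closed-form bounds: the cooperative solution requires
#' `4*lam < beta/delta < (lam - 1) * delta / (4 * beta0)`, and its monomer
#' level obeys `m_coop*/m* < 1/2`. Valid asymptotically for
#' `beta0/delta << 1/lam`; the bounds cross (empty prediction) when
#' `beta0/delta` is too large or `lam` is 1.
#'
#' @param params a [catalytic_params()] object.
#' @return List with `beta_over_delta_low`, `beta_over_delta_high`,
#'   `ratio_high` (= 1/2) and logical `empty`.
#' @export
approx_bounds <- function(params) {
  p <- .flat_params(params)
  lo <- 4 * p$lam
  hi <- (p$lam - 1) * p$delta / (4 * p$beta0)
  list(beta_over_delta_low = lo, beta_over_delta_high = hi,
       ratio_high = 0.5, empty = hi <= lo)
}

#' Continuation of the cooperative branch in the catalytic rate
#'
#' Tracks the cooperative fixed point across a grid of `beta` values by
#' natural-parameter continuation: each solution seeds the Newton solve at
#' the next grid point. The stable branch and the interior saddle branch
#' are tracked from distinct seeds; losing a branch at a fold is recorded
#' as a branch end, not an error.
#'
#' @param params a [catalytic_params()] object (its `beta` is ignored).
#' @param beta_grid sorted vector of catalytic cleavage rates.
#' @return A data frame of class `"branch_table"`: one row per (grid point,
#'   branch) with columns `beta`, `branch` (`"stable"`/`"saddle"`),
#'   `m_coop`, `ratio` (= `m_coop/m*`), `stable`, and the five symmetric
#'   coordinates.
#' @examples
#' \donttest{
#' tab <- continuation_in_beta(catalytic_params(beta = 10), seq(8, 16, 1))
#' }
#' @export
continuation_in_beta <- function(params, beta_grid) {
  beta_grid <- sort(beta_grid)
  p <- .flat_params(params)
  m_star <- p$delta^2 / (p$beta0 * p$r)
  rows <- list()
  add <- function(beta, fp, branch) {
    x <- fp$reduced_state
    rows[[length(rows) + 1L]] <<- data.frame(
      beta = beta, branch = branch, m_coop = fp$m,
      ratio = fp$m / m_star, stable = isTRUE(fp$stable),
      a = x[[1L]], b = x[[2L]], aL = x[[3L]], aR = x[[4L]], M = x[[5L]])
  }

  ## anchor: first grid beta with a stable point (bootstrap by relaxation)
  anchor <- NULL
  for (i in seq_along(beta_grid)) {
    fp <- cooperative_fixed_point(.with_beta(params, beta_grid[i]))
    if (!is.null(fp) && fp$kind == "cooperative") {
      anchor <- i
      anchor_fp <- fp
      break
    }
  }
  if (!is.null(anchor)) {
    warm <- anchor_fp$reduced_state
    for (i in anchor:length(beta_grid)) {
      fp <- .coop_warm(params, beta_grid[i], warm)
      if (is.null(fp)) break
      warm <- fp$reduced_state
      add(beta_grid[i], fp, "stable")
    }
    if (anchor > 1L) {
      warm <- anchor_fp$reduced_state
      for (i in (anchor - 1L):1L) {
        fp <- .coop_warm(params, beta_grid[i], warm)
        if (is.null(fp)) break
        warm <- fp$reduced_state
        add(beta_grid[i], fp, "stable")
      }
    }
    ## saddle branch from its own seed family
    sad <- .find_saddle(.with_beta(params, beta_grid[anchor]), anchor_fp)
    if (!is.null(sad)) {
      for (dir in list(anchor:length(beta_grid),
                       if (anchor > 1L) (anchor - 1L):1L else integer())) {
        warm <- sad$reduced_state
        for (i in dir) {
          fp <- .coop_from_seed(.with_beta(params, beta_grid[i]), warm)
          if (is.null(fp) || fp$kind != "saddle") break
          warm <- fp$reduced_state
          add(beta_grid[i], fp, "saddle")
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(beta = numeric(), branch = character(), m_coop = numeric(),
               ratio = numeric(), stable = logical(), a = numeric(),
               b = numeric(), aL = numeric(), aR = numeric(), M = numeric())
  out <- out[!duplicated(out[c("beta", "branch")]), ]
  out <- out[order(out$branch, out$beta), ]
  rownames(out) <- NULL
  class(out) <- c("branch_table", "data.frame")
  attr(out, "params") <- params
  out
}

#' @export
plot.branch_table <- function(x, ...) {
  st <- x[x$branch == "stable", ]
  sa <- x[x$branch == "saddle", ]
  graphics::plot(st$beta, st$ratio, type = "l", lwd = 2,
                 xlab = expression(beta), ylab = expression(m["coop"]^"*" / m^"*"),
                 xlim = range(x$beta), ylim = range(x$ratio), ...)
  if (nrow(sa)) graphics::lines(sa$beta, sa$ratio, lty = 2)
  invisible(x)
}

#' Existence window of the cooperative state in beta
#'
#' Determines the range of catalytic cleavage rates `beta` over which a
#' stable cooperative fixed point exists, for fixed `beta0`, `lam`,
#' `delta`. An interior point is first found (bootstrap by relaxation from
#' the seeding pathway, scanning candidate `beta` values), then each window
#' edge is approached by an adaptive continuation walk whose step factor is
#' refined toward the requested resolution.
#'
#' @param params a [catalytic_params()] object (its `beta` is used as the
#'   first interior candidate).
#' @param beta_range search range for `beta`; defaults to
#'   `c(delta, 100 * delta)` widened to cover the asymptotic bounds.
#' @param edge_tol relative edge resolution (default `1e-4`).
#' @param warm optional known interior solution: list with `beta` and the
#'   5-coordinate `x` (skips the bootstrap scan).
#' @return An object of class `"existence_window"`: list with `beta_min`,
#'   `beta_max`, `empty`, and the interior anchor (`beta_anchor`,
#'   `x_anchor`).
#' @examples
#' \donttest{
#' w <- existence_window(catalytic_params(beta = 10))
#' }
#' @export
existence_window <- function(params, beta_range = NULL, edge_tol = 1e-4,
                             warm = NULL) {
  p <- .flat_params(params)
  ab <- approx_bounds(params)
  if (is.null(beta_range)) {
    beta_range <- c(p$delta, 100 * p$delta)
    if (!ab$empty)
      beta_range <- range(beta_range, 0.5 * ab$beta_over_delta_low * p$delta,
                          2 * ab$beta_over_delta_high * p$delta)
  }
  empty_window <- function() structure(
    list(beta_min = NA_real_, beta_max = NA_real_, empty = TRUE,
         beta_anchor = NA_real_, x_anchor = NULL, params = params),
    class = "existence_window")

  anchor <- NULL
  if (!is.null(warm)) {
    fp <- .coop_warm(params, warm$beta, warm$x)
    if (!is.null(fp)) anchor <- list(beta = warm$beta,
                                     x = fp$reduced_state)
  }
  if (is.null(anchor)) {
    cands <- unique(c(
      params$beta,
      if (!ab$empty) p$delta * sqrt(ab$beta_over_delta_low *
                                      ab$beta_over_delta_high),
      if (!ab$empty) p$delta * ab$beta_over_delta_low * 1.5,
      exp(seq(log(max(beta_range[1], 1e-6)), log(beta_range[2]),
              length.out = 9L))))
    cands <- cands[cands >= beta_range[1] & cands <= beta_range[2]]
    for (b in cands) {
      fp <- cooperative_fixed_point(.with_beta(params, b))
      if (!is.null(fp) && fp$kind == "cooperative") {
        anchor <- list(beta = b, x = fp$reduced_state)
        break
      }
    }
  }
  if (is.null(anchor)) return(empty_window())

  up <- .walk_branch(params, anchor$beta, anchor$x, direction = 1,
                     fac_min = 1 + edge_tol)
  dn <- .walk_branch(params, anchor$beta, anchor$x, direction = -1,
                     fac_min = 1 + edge_tol)
  structure(list(beta_min = dn$beta_end, beta_max = up$beta_end,
                 empty = FALSE, beta_anchor = anchor$beta,
                 x_anchor = anchor$x, params = params),
            class = "existence_window")
}

#' @export
print.existence_window <- function(x, ...) {
  if (x$empty) cat("Existence window: empty",
                   "(no stable cooperative fixed point found)\n")
  else cat(sprintf("Existence window: beta in (%.6g, %.6g)\n",
                   x$beta_min, x$beta_max))
  invisible(x)
}

#' Disappearance threshold of the cooperative state in beta0/delta
#'
#' The existence window in `beta` shrinks as the spontaneous cleavage rate
#' `beta0` grows (relative to the dilution rate) and closes entirely at a
#' critical `beta0/delta`. The threshold is located by two-parameter
#' continuation: `beta0` is walked upward with an adaptive relative step
#' while a live stable-branch solution `(beta, state)` is tracked; when a
#' step loses the branch (even after an adaptive walk in `beta`), the step
#' is halved, until the requested relative precision is reached. Tracking
#' the solution through the narrowing window is essential: re-detection
#' from fixed seeds loses the branch well before the true closing point.
#'
#' @param lam elongation asymmetry factor, > 1.
#' @param delta dilution rate.
#' @param base a [chemostat_params()] supplying `m0`, `r` (its `beta0` is
#'   the continuation start, its `delta` is overridden by `delta`).
#' @param rel_tol relative precision of the threshold (default `1e-3`).
#' @param beta0_start starting `beta0/delta` (must lie inside the region
#'   with a non-empty window; default `(lam - 1)/(32 * lam)`, half the
#'   small-`beta0` self-consistency point of the asymptotic bounds).
#' @return List with `beta0_over_delta` (the threshold),
#'   `beta0_over_delta_approx` (= `(lam-1)/(16*lam)`, where the asymptotic
#'   bounds cross), and the last tracked `beta`, `state`.
#' @examples
#' \donttest{
#' disappearance_threshold(lam = 2)  # ~ 0.056
#' }
#' @export
disappearance_threshold <- function(lam, delta = 1,
                                    base = chemostat_params(delta = delta),
                                    rel_tol = 1e-3, beta0_start = NULL) {
  if (lam <= 1) stop("'lam' must exceed 1", call. = FALSE)
  if (is.null(beta0_start)) beta0_start <- (lam - 1) / (32 * lam) * delta
  par0 <- function(b0) catalytic_params(
    beta = 1, lam = lam,
    chemostat = chemostat_params(m0 = base$m0, delta = delta, r = base$r,
                                 beta0 = b0))
  ## bootstrap interior solution at beta0_start
  w <- existence_window(par0(beta0_start))
  if (w$empty)
    stop("no cooperative state at the starting beta0; ",
         "supply a smaller 'beta0_start'", call. = FALSE)
  cur <- list(beta = w$beta_anchor, x = w$x_anchor)
  b0 <- beta0_start
  step <- 0.1
  while (step > rel_tol / 2) {
    b0_try <- b0 * (1 + step)
    pr <- par0(b0_try)
    res <- .track_window_interior(pr, cur)
    if (!is.null(res)) {
      cur <- res
      b0 <- b0_try
    } else {
      step <- step / 2
    }
  }
  list(beta0_over_delta = b0 / delta,
       beta0_over_delta_approx = (lam - 1) / (16 * lam),
       beta = cur$beta, state = cur$x, lam = lam)
}

## After a beta0 step, re-acquire the stable branch: warm Newton at the
## current beta, else an adaptive walk in beta keeping the seed live.
## Returns a window-interior point (geometric middle of the tracked span).
.track_window_interior <- function(params, cur) {
  fp <- .coop_warm(params, cur$beta, cur$x)
  found <- list()
  if (!is.null(fp)) {
    found[[1L]] <- list(beta = cur$beta, x = fp$reduced_state)
    start <- found[[1L]]
  } else {
    ## search small adaptive steps away from cur$beta in both directions
    for (dir in c(1, -1)) {
      b <- cur$beta
      fac <- 1.05
      while (fac > 1 + 1e-4) {
        b2 <- b * fac^dir
        fp2 <- .coop_warm(params, b2, cur$x)
        if (!is.null(fp2)) {
          found[[length(found) + 1L]] <- list(beta = b2,
                                              x = fp2$reduced_state)
          break
        }
        fac <- sqrt(fac)
      }
      if (length(found)) break
    }
    if (!length(found)) {
      ## last resort: short relaxation pulls the stale seed back onto the
      ## attractor before polishing (Newton radius shrinks near the fold)
      fp3 <- .coop_by_relaxation(.with_beta(params, cur$beta), cur$x,
                                 t_end = 200)
      if (is.null(fp3) || fp3$kind != "cooperative") return(NULL)
      found[[1L]] <- list(beta = cur$beta, x = fp3$reduced_state)
    }
    start <- found[[length(found)]]
  }
  ## walk both directions to bracket the current window, then return a
  ## mid-window anchor so later beta0 steps stay away from the edges
  up <- .walk_branch(params, start$beta, start$x, 1, fac_min = 1 + 1e-3)
  dn <- .walk_branch(params, start$beta, start$x, -1, fac_min = 1 + 1e-3)
  bmid <- sqrt(up$beta_end * dn$beta_end)
  fp_mid <- .coop_warm(params, bmid,
                       if (bmid > start$beta) up$x_end else dn$x_end)
  if (!is.null(fp_mid)) return(list(beta = bmid, x = fp_mid$reduced_state))
  list(beta = start$beta, x = start$x)
}
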