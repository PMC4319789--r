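## One-parameter bifurcation analysis of the frozen-mass network.
## Cell mass is the control parameter: the growth equation is removed and
## every mass-scaled flux keeps the frozen value.  Brute-force multi-start
## root finding plus grid continuation is used instead of pseudo-arclength
## continuation: the diagram has at most three coexisting branches and
## fold bisection reaches the needed accuracy.

## frozen-mass residual: species derivatives at fixed mass
.frozen_rhs <- function(x, mass, params, nmpp1 = 0) {
  y <- c(x, mass)
  .rhs_r(0, y, c(unclass(params), nmpp1 = nmpp1))[[1]][1:9]
}

.frozen_jacobian <- function(x, mass, params, nmpp1 = 0, rel_step = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  f0 <- .frozen_rhs(x, mass, params, nmpp1)
  for (i in seq_len(n)) {
    h <- rel_step * max(abs(x[i]), 1e-4)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (.frozen_rhs(xp, mass, params, nmpp1) -
                 .frozen_rhs(xm, mass, params, nmpp1)) / (2 * h)
  }
  J
}

## damped Newton iteration from one start; NULL if no convergence
.newton_root <- function(x0, mass, params, nmpp1 = 0, tol = 1e-11,
                         maxit = 60) {
  x <- x0
  f <- .frozen_rhs(x, mass, params, nmpp1)
  for (it in seq_len(maxit)) {
    nf <- sqrt(sum(f^2))
    if (nf < tol) break
    J <- .frozen_jacobian(x, mass, params, nmpp1)
    dx <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    lambda <- 1
    ok <- FALSE
    while (lambda >= 1e-6) {
      xn <- x + lambda * dx
      fn <- .frozen_rhs(xn, mass, params, nmpp1)
      if (all(is.finite(fn)) && sqrt(sum(fn^2)) < nf * (1 - 1e-4 * lambda)) {
        ok <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!ok) return(NULL)      # stalled far from a root
    x <- xn; f <- fn
  }
  if (sqrt(sum(f^2)) >= 1e-9) return(NULL)
  if (any(x < -1e-8) || any(x[6:9] > 1 + 1e-6)) return(NULL)
  pmax(x, 0)
}

## candidate equilibrium states from pseudo-transient integration of the
## frozen-mass model: the endpoint (stable attractors) and the mean over
## the settled window (interior equilibria of oscillatory regimes)
.relaxation_candidates <- function(x0, mass, params, t_relax = 3000) {
  pfro <- params
  pfro$mu <- 0
  y0 <- c(pmin(pmax(x0, 0), c(Inf, Inf, Inf, Inf, Inf, 1, 1, 1, 1)),
          mass = mass)
  names(y0) <- .state_names
  sol <- tryCatch(
    .integrate_span(y0, seq(0, t_relax, by = t_relax / 80), pfro),
    error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  n <- nrow(sol)
  keep <- sol[, 1] >= t_relax / 2
  rbind(sol[n, 2:10],
        colMeans(sol[keep, 2:10, drop = FALSE]))
}

#' Steady states of the frozen-mass network
#'
#' Finds the equilibria of the model with cell mass frozen at a given
#' value (the growth equation removed), by damped Newton iteration from a
#' set of deterministic starting points spanning the physiological corners
#' of state space (Rum1-dominated, Wee1-dominated, high-activity) plus
#' seeded random starts.  Equilibria closer than \code{dedup_tol} in
#' scaled coordinates are merged; each returned equilibrium has residual
#' norm below 1e-9.
#'
#' @param mass frozen cell mass (> 0).
#' @param params an \code{\link{mcn_parameters}} object.
#' @param genotype optional genotype applied first.
#' @param n_starts number of additional random starts.
#' @param seed RNG seed for the random starts.
#' @param starts optional matrix of extra starting states (rows).
#' @param dedup_tol merge distance in scaled coordinates.
#' @param explore run the pseudo-transient exploration from all cold
#'   starts (\code{TRUE}); \code{FALSE} keeps only two corner starts and
#'   relies on continuation seeds (used by \code{\link{trace_branches}}
#'   between exploration points).
#' @return A list of equilibria; each is a list with \code{state} (named
#'   9-vector), \code{mpf_activity} (effective activity), \code{residual},
#'   \code{stability} (\code{"STABLE"}, \code{"SADDLE"} or
#'   \code{"UNSTABLE"}) and \code{eigenvalues}.
#' @export
find_steady_states <- function(mass, params, genotype = NULL, n_starts = 12,
                               seed = 1, starts = NULL, dedup_tol = 1e-6,
                               explore = TRUE) {
  stopifnot(mass > 0)
  if (!is.null(genotype)) params <- apply_genotype(params, genotype)
  fp <- params$k_smpf * mass / max(params$k_dmpf, 1e-3)
  det_starts <- rbind(
    c(1e-4, 1e-4, 0.2, 0.3, 1e-3, 0.95, 0.01, 0.01, 0.5),   # Rum1-held L
    c(0.02, fp, 1e-3, 1e-3, 1e-4, 0.95, 0.02, 0.02, 0.02),  # Wee1-held I
    c(fp, 0.05, 1e-3, 1e-3, 1e-4, 0.05, 0.95, 0.9, 0.9),    # high H
    c(1e-3, 1e-3, 0.05, 0.1, 1e-3, 0.5, 0.1, 0.1, 0.9),
    rep(1e-6, 9))
  if (n_starts > 0) {
    rs <- withr_seed(seed, {
      matrix(stats::runif(9 * n_starts), n_starts, 9)
    })
    scale <- c(fp, fp, fp, 1, 0.2, 1, 1, 1, 1)
    rs <- sweep(rs, 2, scale, "*")
    det_starts <- rbind(det_starts, rs)
  }
  ## refine the cold starts by pseudo-transient relaxation; continuation
  ## seeds (`starts`) are already near a root and go straight to Newton
  if (!explore) det_starts <- det_starts[c(1, 3), , drop = FALSE]
  cand <- list()
  for (i in seq_len(nrow(det_starts))) {
    cc <- .relaxation_candidates(det_starts[i, ], mass, params)
    if (!is.null(cc)) cand[[length(cand) + 1]] <- cc
  }
  cand <- do.call(rbind, cand)
  if (!is.null(starts)) cand <- rbind(cand, starts)

  eqs <- list()
  sc <- pmax(c(rep(max(fp, 0.1), 5), rep(1, 4)), 1e-3)
  for (i in seq_len(nrow(cand))) {
    x <- .newton_root(cand[i, ], mass, params)
    if (is.null(x)) next
    dup <- any(vapply(eqs, function(e)
      sqrt(sum(((e$state - x) / sc)^2)) < dedup_tol * sqrt(9) * 1e3,
      logical(1)))
    if (dup) next
    res <- sqrt(sum(.frozen_rhs(x, mass, params)^2))
    names(x) <- .state_names[1:9]
    eq <- list(state = x, mass = mass,
               mpf_activity = unname(x[1] + params$alpha * x[2]),
               residual = res)
    st <- stability_of(eq, params)
    eq$stability <- st$stability
    eq$eigenvalues <- st$eigenvalues
    eqs[[length(eqs) + 1]] <- eq
  }
  eqs[order(vapply(eqs, function(e) e$mpf_activity, numeric(1)))]
}

## run code with a local RNG seed without touching the global stream
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Linear stability of a frozen-mass equilibrium
#'
#' Computes the Jacobian by central finite differences (relative step
#' 1e-6) and classifies the equilibrium by the eigenvalue real parts:
#' \code{STABLE} if all are below -1e-8, \code{SADDLE} if exactly one
#' eigenvalue has positive real part, otherwise \code{UNSTABLE}.
#'
#' @param equilibrium a list with \code{state} and \code{mass} (as
#'   returned by \code{\link{find_steady_states}}).
#' @param params an \code{\link{mcn_parameters}} object.
#' @return List with \code{stability}, \code{eigenvalues}, and
#'   \code{leading} (largest real part).
#' @export
stability_of <- function(equilibrium, params) {
  x <- equilibrium$state
  J <- .frozen_jacobian(x, equilibrium$mass, params)
  ev <- eigen(J, only.values = TRUE)$values
  re <- sort(Re(ev), decreasing = TRUE)
  kappa <- tryCatch(kappa(J), error = function(e) Inf)
  if (!is.finite(kappa) || kappa > 1e12)
    warning("ill-conditioned Jacobian (kappa = ", signif(kappa, 3), ")")
  stab <- if (all(re < -1e-8)) "STABLE"
          else if (sum(re > 1e-8) == 1) "SADDLE"
          else "UNSTABLE"
  list(stability = stab, eigenvalues = ev, leading = re[1])
}

#' Trace steady-state branches over a mass range
#'
#' Computes equilibria on a mass grid and strings them into branches by
#' nearest-state continuation.  A fold (saddle-node) is flagged where a
#' branch terminates between grid points, and its mass is localised by
#' bisection (continuing Newton from the last branch state) to about
#' 1e-4.
#'
#' @param mass_range length-2 vector, within (0, 4].
#' @param mass_step grid step; 0.005 or smaller keeps the
#'   nearest-neighbour matching unambiguous.
#' @param params an \code{\link{mcn_parameters}} object.
#' @param genotype optional genotype applied first.
#' @param n_starts random starts per grid point (continuation seeds from
#'   the previous grid point are always added).
#' @return An object of class \code{bifurcation_diagram}: list with
#'   \code{points} (data frame: mass, branch, mpf_activity, stability,
#'   leading eigenvalue real part), \code{folds} (data frame: mass,
#'   branch, type), \code{params}, \code{mass_step}.  The envelope slot is
#'   filled by \code{\link{limit_cycle_envelope}}.
#' @export
trace_branches <- function(mass_range, mass_step = 0.005, params,
                           genotype = NULL, n_starts = 6) {
  stopifnot(length(mass_range) == 2, all(mass_range > 0),
            all(mass_range <= 4), mass_step > 0)
  if (!is.null(genotype)) params <- apply_genotype(params, genotype)
  grid <- seq(mass_range[1], mass_range[2], by = mass_step)
  prev <- NULL
  rows <- list()
  states <- list()
  i_grid <- 0
  for (m in grid) {
    i_grid <- i_grid + 1
    extra <- if (!is.null(prev) && length(prev))
      do.call(rbind, lapply(prev, function(e) e$state)) else NULL
    eqs <- find_steady_states(m, params, n_starts = n_starts,
                              starts = extra,
                              explore = (i_grid %% 25 == 1))
    for (e in eqs)
      rows[[length(rows) + 1]] <-
        data.frame(mass = m, mpf_activity = e$mpf_activity,
                   mpf = unname(e$state[1]),
                   rum1_total = unname(e$state[3] + e$state[4] + e$state[5]),
                   stability = e$stability,
                   leading = max(Re(e$eigenvalues)))
    states[[length(states) + 1]] <- eqs
    prev <- eqs
  }
  pts <- do.call(rbind, rows)

  ## assemble branches by nearest-activity continuation across the grid
  pts$branch <- NA_integer_
  branch_last <- list()   # branch id -> last (mass, activity)
  next_id <- 1L
  for (m in grid) {
    idx <- which(pts$mass == m)
    used <- logical(length(branch_last))
    for (k in idx) {
      best <- NA_integer_; bestd <- Inf
      for (b in seq_along(branch_last)) {
        bl <- branch_last[[b]]
        if (used[b] || is.null(bl) || m - bl$mass > 2.5 * mass_step) next
        d <- abs(log10(pmax(pts$mpf_activity[k], 1e-12)) -
                   log10(pmax(bl$act, 1e-12)))
        if (d < bestd) { bestd <- d; best <- b }
      }
      if (!is.na(best) && bestd < 0.5) {
        pts$branch[k] <- best
        used[best] <- TRUE
        branch_last[[best]] <- list(mass = m, act = pts$mpf_activity[k])
      } else {
        pts$branch[k] <- next_id
        if (next_id <= length(used)) used[next_id] <- TRUE
        branch_last[[next_id]] <- list(mass = m, act = pts$mpf_activity[k])
        next_id <- next_id + 1L
      }
    }
  }

  ## folds: branch endpoints interior to the scanned range
  folds <- list()
  for (b in unique(pts$branch)) {
    sub <- pts[pts$branch == b, ]
    mend <- max(sub$mass)
    if (mend < mass_range[2] - mass_step / 2) {
      mf <- .bisect_fold(sub, mend, mass_step, params)
      folds[[length(folds) + 1]] <-
        data.frame(mass = mf, branch = b, type = "SADDLE_NODE",
                   side = "upper")
    }
    mstart <- min(sub$mass)
    if (mstart > mass_range[1] + mass_step / 2) {
      folds[[length(folds) + 1]] <-
        data.frame(mass = mstart, branch = b, type = "SADDLE_NODE",
                   side = "lower")
    }
  }
  folds <- if (length(folds)) do.call(rbind, folds) else
    data.frame(mass = numeric(0), branch = integer(0),
               type = character(0), side = character(0))

  structure(list(points = pts, folds = folds, envelope = NULL,
                 params = params, mass_step = mass_step,
                 mass_range = mass_range),
            class = "bifurcation_diagram")
}

## bisection on the existence of the branch equilibrium past its last
## grid point
.bisect_fold <- function(sub, mend, mass_step, params, tol = 1e-4) {
  xlast <- NULL
  ## re-solve at the endpoint to get the state
  eqs <- find_steady_states(mend, params, n_starts = 4)
  act <- sub$mpf_activity[sub$mass == mend][1]
  for (e in eqs)
    if (abs(log10(pmax(e$mpf_activity, 1e-12)) -
              log10(pmax(act, 1e-12))) < 0.2) xlast <- e$state
  if (is.null(xlast)) return(mend)
  lo <- mend; hi <- mend + mass_step
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    x <- .newton_root(xlast, mid, params)
    ok <- !is.null(x) &&
      abs(log10(pmax(x[1] + params$alpha * x[2], 1e-12)) -
            log10(pmax(act, 1e-12))) < 0.3
    if (ok) { lo <- mid; xlast <- x } else hi <- mid
  }
  (lo + hi) / 2
}

#' Envelope of sustained oscillations of the frozen-mass model
#'
#' For each mass on the grid, integrates the frozen-mass model for
#' \code{t_sim} minutes, discards the first half as transient, and reports
#' the oscillation envelope of the effective MPF activity.  A mass counts
#' as oscillatory when the retained window shows a peak-to-trough
#' amplitude above \code{min_amplitude} and at least three maxima (these
#' thresholds reject solver ripple while catching the small-amplitude
#' cycles of Wee1-less genotypes); the mean peak spacing is recorded as
#' the period.
#'
#' @param mass_range length-2 vector or explicit mass grid
#'   (length > 2).
#' @param params an \code{\link{mcn_parameters}} object.
#' @param genotype optional genotype.
#' @param mass_step grid step when \code{mass_range} has length 2.
#' @param t_sim integration time per mass (min).
#' @param dt sampling step (min).
#' @param min_amplitude oscillation acceptance threshold.
#' @return Data frame with \code{mass}, \code{oscillatory},
#'   \code{mpf_min}, \code{mpf_max}, \code{period} (NA when not
#'   oscillatory).
#' @export
limit_cycle_envelope <- function(mass_range, params, genotype = NULL,
                                 mass_step = 0.01, t_sim = 2000, dt = 0.25,
                                 min_amplitude = 1e-3) {
  if (!is.null(genotype)) params <- apply_genotype(params, genotype)
  grid <- if (length(mass_range) == 2)
    seq(mass_range[1], mass_range[2], by = mass_step) else mass_range
  pfro <- params
  pfro$mu <- 0
  y0 <- unclass(cdk_state(mass = 1))[.state_names]
  out <- lapply(grid, function(m) {
    y0["mass"] <- m
    sol <- .integrate_span(y0, seq(0, t_sim, by = dt), pfro)
    a <- sol[, "A"]
    keep <- sol[, 1] >= t_sim / 2
    a <- a[keep]
    amp <- max(a) - min(a)
    pk <- which(diff(sign(diff(a))) == -2) + 1
    pk <- pk[a[pk] - min(a) > 0.25 * amp]    # peaks of the main oscillation
    osc <- amp > min_amplitude && length(pk) >= 3
    data.frame(mass = m, oscillatory = osc,
               mpf_min = if (osc) min(a) else NA_real_,
               mpf_max = if (osc) max(a) else NA_real_,
               period = if (osc) mean(diff(sol[keep, 1][pk])) else NA_real_)
  })
  do.call(rbind, out)
}

#' Relabel folds adjacent to the oscillatory regime as SNIC points
#'
#' A saddle-node fold is a SNIC ("saddle-node on an invariant circle")
#' when the oscillatory region starts within \code{adjacency} mass units
#' above the fold and the oscillation period diverges approaching it: the
#' period measured at \code{fold + 0.002} must exceed twice the period at
#' \code{fold + 0.02}.
#'
#' @param diagram a \code{bifurcation_diagram} from
#'   \code{\link{trace_branches}} (its \code{params} are reused).
#' @param envelope optional envelope table (computed if missing).
#' @param adjacency maximum gap between fold and oscillation onset.
#' @param t_sim integration time for the targeted period measurements.
#' @return The diagram with its \code{folds} table relabelled
#'   (\code{type = "SNIC"} where the criterion holds) and the envelope
#'   attached.
#' @export
classify_snic <- function(diagram, envelope = NULL, adjacency = 0.01,
                          t_sim = 4000) {
  stopifnot(inherits(diagram, "bifurcation_diagram"))
  params <- diagram$params
  if (is.null(envelope))
    envelope <- limit_cycle_envelope(diagram$mass_range, params,
                                     mass_step = 0.01)
  diagram$envelope <- envelope
  osc_masses <- envelope$mass[envelope$oscillatory]
  if (!nrow(diagram$folds) || !length(osc_masses)) return(diagram)
  for (i in seq_len(nrow(diagram$folds))) {
    if (diagram$folds$side[i] != "upper") next
    mf <- diagram$folds$mass[i]
    onset <- suppressWarnings(min(osc_masses[osc_masses > mf - 1e-6]))
    if (!is.finite(onset) || onset - mf > adjacency + 0.01) next
    per <- function(m) {
      e <- limit_cycle_envelope(c(m, m), params, mass_step = 1,
                                t_sim = t_sim)
      e$period[1]
    }
    p_near <- per(mf + 0.002)
    p_far <- per(mf + 0.02)
    ## a period too long for three maxima in the measurement window is
    ## itself divergence evidence (the defining SNIC signature defeats
    ## the peak counter arbitrarily close to the fold)
    if (!is.na(p_far) && (is.na(p_near) || p_near > 2 * p_far))
      diagram$folds$type[i] <- "SNIC"
  }
  diagram
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("Bifurcation diagram over mass [%.2f, %.2f] (step %.3f): %d equilibrium points, %d branches\n",
              x$mass_range[1], x$mass_range[2], x$mass_step,
              nrow(x$points), length(unique(x$points$branch))))
  if (nrow(x$folds)) print(x$folds, row.names = FALSE)
  invisible(x)
}

#' @export
plot.bifurcation_diagram <- function(x, overlay = NULL, ylim = NULL, ...) {
  pts <- x$points
  if (is.null(ylim)) ylim <- c(0, max(pts$mpf_activity,
                                      x$envelope$mpf_max, na.rm = TRUE))
  graphics::plot(NA, xlim = x$mass_range, ylim = ylim,
                 xlab = "cell mass", ylab = "MPF activity", ...)
  for (b in unique(pts$branch)) {
    sub <- pts[pts$branch == b, ]
    stable <- sub$stability == "STABLE"
    graphics::lines(sub$mass[stable], sub$mpf_activity[stable],
                    col = "black", lwd = 2)
    graphics::lines(sub$mass[!stable], sub$mpf_activity[!stable],
                    col = "red", lty = 2)
  }
  if (!is.null(x$envelope)) {
    env <- x$envelope[x$envelope$oscillatory, ]
    graphics::lines(env$mass, env$mpf_min, col = "blue")
    graphics::lines(env$mass, env$mpf_max, col = "blue")
  }
  graphics::abline(h = c(x$params$theta_s, x$params$theta_m),
                   col = "orange", lty = 3)
  if (!is.null(overlay))
    graphics::lines(overlay$mass, overlay$a, col = "darkgreen")
  invisible(x)
}
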