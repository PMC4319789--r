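#' Integrate the growing-dividing cell to its limit cycle
#'
#' Integrates the model through repeated growth-division cycles.  Division
#' occurs when the effective MPF activity crosses the mitotic threshold
#' \code{theta_m} downward; only mass is halved (species concentrations are
#' intensive and continuous across division).  Cycling is continued until
#' the mass at division converges, and the returned object carries one full
#' converged cycle, starting immediately after a division.
#'
#' On the balanced cycle the period equals the mass doubling time
#' \code{log(2)/mu}, so genotypes differ in how the fixed period is
#' partitioned among G1, S/G2 and M, and in the absolute size at division.
#'
#' @param params an \code{\link{mcn_parameters}} object.
#' @param genotype an \code{\link{mcn_genotype}} or preset name; applied to
#'   \code{params} first.
#' @param convergence_tol relative difference between consecutive division
#'   masses below which the cycle is considered converged.
#' @param max_cycles maximum number of divisions before giving up with an
#'   error (non-convergence).
#' @param dt output sampling interval (min).
#' @param horizon time allowed for a single cycle before the cell is
#'   reported as arrested (min).
#' @param rtol,atol solver tolerances (stiff-capable \code{lsodar} with
#'   event localisation by its built-in root finder).
#' @param nmpp1 constant inhibitor level (analog-sensitive kinase).
#' @param y0 optional initial \code{\link{cdk_state}}.
#' @return An object of class \code{cycle_trajectory}: a list with
#'   \code{time}, \code{states} (data frame including the derived columns
#'   \code{fp_total}, \code{rum1_total} and effective activity \code{a}),
#'   \code{events} (see \code{\link{detect_events}}), \code{divisions}
#'   (all division times/masses of the transient), \code{arrested},
#'   (when the division-mass sequence does not settle - some mutant
#'   combinations cycle through several division sizes - a warning is
#'   issued, \code{converged} is \code{FALSE} and the final cycle is
#'   returned; \code{\link{classify_phases}} then reports the trailing
#'   mean division mass),
#'   \code{converged}, \code{n_cycles}, \code{period}, and the applied
#'   parameter set.  Arrested cells (no division within \code{horizon})
#'   are returned with \code{arrested = TRUE} rather than an error.
#' @export
#' @examples
#' \donttest{
#' cyc <- integrate_to_limit_cycle(mcn_parameters(), genotype())
#' classify_phases(cyc)
#' }
integrate_to_limit_cycle <- function(params, genotype = NULL,
                                     convergence_tol = 1e-4,
                                     max_cycles = 60, dt = 0.25,
                                     horizon = 1500, rtol = 1e-8,
                                     atol = 1e-10, nmpp1 = 0, y0 = NULL) {
  if (!is.null(genotype)) params <- apply_genotype(params, genotype)
  validate_parameters(params)
  stopifnot(convergence_tol > 0)
  if (is.null(y0)) y0 <- cdk_state()
  y <- unclass(y0)[.state_names]

  div_mass <- numeric(0)
  div_time <- numeric(0)
  t_abs <- 0
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    step <- .advance_one_cycle(y, params, nmpp1, dt, horizon, rtol, atol)
    if (step$arrested) {
      return(.cycle_trajectory(step$sol, params, nmpp1, dt,
                               divisions = data.frame(time = div_time,
                                                      mass = div_mass),
                               arrested = TRUE, converged = FALSE,
                               n_cycles = cycle))
    }
    t_abs <- t_abs + step$t_div
    div_time <- c(div_time, t_abs)
    div_mass <- c(div_mass, step$mass_div)
    y <- step$y_end
    y["mass"] <- y["mass"] / 2
    n <- length(div_mass)
    if (n >= 2 &&
        abs(div_mass[n] - div_mass[n - 1]) < convergence_tol * div_mass[n]) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("division masses did not settle within ", max_cycles,
            " cycles (multi-cycle attractor); reporting the final cycle")

  final <- .advance_one_cycle(y, params, nmpp1, dt, horizon, rtol, atol,
                              keep_sol = TRUE)
  .cycle_trajectory(final$sol, params, nmpp1, dt,
                    divisions = data.frame(time = div_time, mass = div_mass),
                    arrested = FALSE, converged = converged,
                    n_cycles = length(div_mass) + 1,
                    t_div = final$t_div)
}

## integrate from post-division state to the next division (downward
## theta_m root); returns end state and the dense solution
.advance_one_cycle <- function(y, params, nmpp1, dt, horizon, rtol, atol,
                               keep_sol = TRUE) {
  t0 <- 0
  sols <- list()
  repeat {
    times <- seq(0, horizon - t0, by = dt)
    if (length(times) < 2)
      return(list(arrested = TRUE, sol = do.call(rbind, sols)))
    sol <- .integrate_span(y, times, params, nmpp1, rtol, atol,
                           root_m = TRUE)
    troot <- attr(sol, "troot")
    yend <- sol[nrow(sol), 1 + seq_along(.state_names)]
    sol[, 1] <- sol[, 1] + t0
    sols[[length(sols) + 1]] <- sol
    if (is.null(troot) || length(troot) == 0)
      return(list(arrested = TRUE, sol = do.call(rbind, sols)))
    ## crossing direction from the RHS at the root
    dy <- .rhs_r(troot, yend, c(unclass(params), nmpp1 = nmpp1))[[1]]
    dA <- (dy[1] + params$alpha * dy[2]) / (1 + nmpp1)
    t0 <- t0 + troot
    y <- yend
    if (dA < 0) {
      return(list(arrested = FALSE, t_div = t0,
                  mass_div = unname(y["mass"]), y_end = y,
                  sol = if (keep_sol) do.call(rbind, sols)))
    }
    ## upward crossing: nudge past the root so the root does not re-fire
    s2 <- .integrate_span(y, c(0, 1e-6), params, nmpp1, rtol, atol)
    y <- s2[2, 1 + seq_along(.state_names)]
    t0 <- t0 + 1e-6
  }
}

.cycle_trajectory <- function(sol, params, nmpp1, dt, divisions, arrested,
                              converged, n_cycles, t_div = NA_real_) {
  states <- as.data.frame(sol)
  names(states)[1] <- "time"
  states$fp_total <- fp_total(states)
  states$rum1_total <- rum1_total(states)
  names(states)[names(states) == "A"] <- "a"
  obj <- structure(list(time = states$time, states = states,
                        events = NULL, divisions = divisions,
                        params = params, nmpp1 = nmpp1,
                        arrested = arrested, converged = converged,
                        n_cycles = n_cycles, period = t_div),
                   class = "cycle_trajectory")
  obj$events <- detect_events(obj, params$theta_s, params$theta_m)
  ## the trajectory ends exactly on the division surface, so the final
  ## downward crossing has no samples beyond it; add it explicitly
  if (!arrested && is.finite(t_div) &&
      !any(obj$events$type == "M_EXIT_DIVISION" &
             abs(obj$events$time - t_div) < 1)) {
    obj$events <- rbind(obj$events,
                        data.frame(type = "M_EXIT_DIVISION", time = t_div,
                                   mass = states$mass[nrow(states)]))
    obj$events <- obj$events[order(obj$events$time), ]
  }
  obj
}

#' @export
print.cycle_trajectory <- function(x, ...) {
  if (x$arrested) {
    cat("Arrested trajectory (no division within the horizon);",
        nrow(x$states), "samples\n")
  } else {
    cat(sprintf("Converged cell cycle: period %.2f min, division mass %.4f (%d cycles to converge)\n",
                x$period, x$divisions$mass[nrow(x$divisions)], x$n_cycles))
    print(x$events, row.names = FALSE)
  }
  invisible(x)
}

#' Detect threshold-crossing events of the effective MPF activity
#'
#' Scans a trajectory for upward crossings of the S threshold
#' (\code{S_ENTRY}), upward crossings of the M threshold (\code{M_ENTRY})
#' and downward crossings of the M threshold
#' (\code{M_EXIT_DIVISION}).  Crossing times are located by interpolation
#' between the bracketing samples; when the trajectory carries a
#' closed-form activity function (toy fixtures,
#' \code{\link{make_toy_trajectory}}), crossings are refined against it by
#' root bracketing to near machine precision.  A crossing is accepted only
#' if the activity stays on the far side of the threshold for at least
#' \code{debounce} minutes, which suppresses solver ripple near
#' \code{theta_s}.
#'
#' @param trajectory a \code{cycle_trajectory}, or any data frame with a
#'   \code{time} column and either an effective-activity column \code{a} or
#'   an \code{mpf} column.
#' @param theta_s,theta_m activity thresholds.
#' @param debounce minimum dwell time (min) on the far side.
#' @return Data frame with columns \code{type}, \code{time}, \code{mass}
#'   (interpolated mass at the crossing, \code{NA} if the trajectory has no
#'   mass column), ordered by time.
#' @export
detect_events <- function(trajectory, theta_s = 0.01, theta_m = 0.2,
                          debounce = 1) {
  df <- if (inherits(trajectory, "cycle_trajectory")) trajectory$states
        else as.data.frame(trajectory)
  afun <- attr(trajectory, "activity_fun")
  tt <- df$time
  a <- if ("a" %in% names(df)) df$a else df$mpf
  if (is.null(a)) stop("trajectory has no activity ('a') or 'mpf' column")
  mass <- if ("mass" %in% names(df)) df$mass else rep(NA_real_, length(tt))

  one <- function(theta, up) {
    s <- a - theta
    idx <- if (up) which(s[-length(s)] < 0 & s[-1] >= 0)
           else which(s[-length(s)] >= 0 & s[-1] < 0)
    keep <- vapply(idx, function(k) {
      tcross <- tt[k] + (tt[k + 1] - tt[k]) * s[k] / (s[k] - s[k + 1])
      win <- tt > tcross & tt <= tcross + debounce
      if (!any(win)) TRUE else if (up) all(s[win] >= 0) else all(s[win] < 0)
    }, logical(1))
    idx <- idx[keep]
    tcr <- vapply(idx, function(k) {
      t0 <- tt[k] + (tt[k + 1] - tt[k]) * s[k] / (s[k] - s[k + 1])
      if (!is.null(afun))
        t0 <- stats::uniroot(function(z) afun(z) - theta,
                             lower = tt[k], upper = tt[k + 1],
                             tol = 1e-12)$root
      t0
    }, numeric(1))
    mcr <- vapply(seq_along(idx), function(i) {
      k <- idx[i]
      if (is.na(mass[k])) NA_real_
      else stats::approx(tt[c(k, k + 1)], mass[c(k, k + 1)], tcr[i])$y
    }, numeric(1))
    data.frame(type = character(length(idx)), time = tcr, mass = mcr)
  }

  ev_s <- one(theta_s, up = TRUE);  ev_s$type <- rep("S_ENTRY", nrow(ev_s))
  ev_m <- one(theta_m, up = TRUE);  ev_m$type <- rep("M_ENTRY", nrow(ev_m))
  ev_d <- one(theta_m, up = FALSE)
  ev_d$type <- rep("M_EXIT_DIVISION", nrow(ev_d))
  ev <- rbind(ev_s, ev_m, ev_d)
  ev[order(ev$time), c("type", "time", "mass")]
}

#' Classify cell-cycle phases of one converged cycle
#'
#' Phases are defined by the effective MPF activity thresholds:
#' G1 runs from division to \code{S_ENTRY}, S/G2 from \code{S_ENTRY} to
#' \code{M_ENTRY}, and M from \code{M_ENTRY} to the next division.
#' The re-licensing time is the total time within the cycle during which
#' the activity is below \code{theta_s} (replication origins can only be
#' re-licensed while Cdk activity is essentially absent).
#'
#' @param trajectory a converged \code{cycle_trajectory} (one full
#'   division-to-division cycle), or a plain data frame with \code{time}
#'   and activity columns plus an explicit \code{events} argument.
#' @param events optional pre-computed event table.
#' @param mass_reference reference division mass for the relative
#'   \code{mass_at_division}; typically the converged MCN value computed
#'   with the same parameter file (\code{NA} leaves the ratio unset).
#' @return An object of class \code{phase_report}: a list with
#'   \code{g1_min}, \code{sg2_min}, \code{m_min}, \code{relicensing_min},
#'   \code{period_min}, \code{mass_at_division} (absolute),
#'   \code{relative_mass} (vs \code{mass_reference}), \code{mpf_min},
#'   \code{viable}, \code{catastrophe}, \code{limiting_defect}; phase
#'   durations are \code{NA} with \code{limiting_defect = "ARRESTED"} if
#'   the cycle has no division.
#' @seealso \code{\link{assess_viability}}
#' @export
classify_phases <- function(trajectory, events = NULL,
                            mass_reference = NA_real_) {
  traj <- trajectory
  df <- if (inherits(traj, "cycle_trajectory")) traj$states
        else as.data.frame(traj)
  if (is.null(events))
    events <- if (inherits(traj, "cycle_trajectory")) traj$events
              else stop("events must be supplied for a plain data frame")
  a <- if ("a" %in% names(df)) df$a else df$mpf
  tt <- df$time
  period <- if (inherits(traj, "cycle_trajectory") && !is.na(traj$period))
    traj$period else max(tt) - min(tt)

  arrested <- inherits(traj, "cycle_trajectory") && traj$arrested
  s_entry <- events$time[events$type == "S_ENTRY"][1]
  m_entry <- events$time[events$type == "M_ENTRY"]
  m_entry <- m_entry[m_entry > ifelse(is.na(s_entry), -Inf, s_entry)][1]
  t0 <- min(tt)

  ## time below theta_s, trapezoid on the sampling grid
  theta_s <- if (inherits(traj, "cycle_trajectory")) traj$params$theta_s
             else 0.01
  below <- a[-length(a)] < theta_s
  relic <- sum(diff(tt)[below])

  mass_div <- if (inherits(traj, "cycle_trajectory") && !traj$arrested) {
    dm <- traj$divisions$mass
    if (isTRUE(traj$converged)) dm[length(dm)]
    else mean(utils::tail(dm, 10))   # cycling attractor: trailing mean
  } else NA_real_

  rep <- structure(list(
    g1_min = if (arrested || is.na(s_entry)) NA_real_ else s_entry - t0,
    sg2_min = if (arrested || is.na(s_entry) || is.na(m_entry)) NA_real_
              else m_entry - s_entry,
    m_min = if (arrested || is.na(m_entry)) NA_real_
            else t0 + period - m_entry,
    relicensing_min = relic,
    period_min = if (arrested) NA_real_ else period,
    mass_at_division = mass_div,
    relative_mass = if (is.na(mass_reference)) NA_real_
                    else mass_div / mass_reference,
    mpf_min = min(a),
    viable = NA, catastrophe = NA,
    limiting_defect = if (arrested) "ARRESTED" else "NONE"),
    class = "phase_report")
  assess_viability(rep)
}

#' Viability and mitotic-catastrophe assessment
#'
#' A cycle is inviable with defect \code{NO_RELICENSING} when the
#' re-licensing window (activity below \code{theta_s}) is not longer than
#' \code{relicensing_min}: without a licensing window the daughter cannot
#' re-replicate its genome.  It is flagged as a mitotic catastrophe
#' (\code{SHORT_S_TO_M}) when the S-to-M interval is shorter than the time
#' needed to complete DNA replication, \code{t_replication} (default
#' 20 min, the lower edge of the S-phase duration in fission yeast): the
#' cell then divides with incompletely replicated chromosomes.
#'
#' @param report a \code{phase_report} from \code{\link{classify_phases}}.
#' @param t_replication minimum S-to-M interval for complete replication
#'   (min).
#' @param relicensing_min minimum licensing window (min).
#' @return The updated \code{phase_report}.
#' @export
assess_viability <- function(report, t_replication = 20,
                             relicensing_min = 1) {
  stopifnot(inherits(report, "phase_report"))
  if (identical(report$limiting_defect, "ARRESTED")) {
    report$viable <- FALSE
    report$catastrophe <- FALSE
    return(report)
  }
  report$viable <- TRUE
  report$catastrophe <- FALSE
  report$limiting_defect <- "NONE"
  if (report$relicensing_min <= relicensing_min) {
    report$viable <- FALSE
    report$limiting_defect <- "NO_RELICENSING"
  } else if (!is.na(report$sg2_min) && report$sg2_min < t_replication) {
    report$viable <- FALSE
    report$catastrophe <- TRUE
    report$limiting_defect <- "SHORT_S_TO_M"
  }
  report
}

#' @export
print.phase_report <- function(x, ...) {
  cat(sprintf("G1 %.1f | S/G2 %.1f | M %.1f min; re-licensing %.1f min\n",
              x$g1_min, x$sg2_min, x$m_min, x$relicensing_min))
  cat(sprintf("mass at division %.4f%s; %s\n", x$mass_at_division,
              if (!is.na(x$relative_mass))
                sprintf(" (%.2f relative)", x$relative_mass) else "",
              if (isTRUE(x$viable)) "viable"
              else paste0("NOT viable (", x$limiting_defect, ")")))
  invisible(x)
}

#' Simulate a G1-reset inhibitor protocol
#'
#' For strains carrying the analog-sensitive kinase, the effective MPF
#' activity is \code{MPF/(1 + nmpp1)}.  The protocol integrates the cell at
#' zero inhibitor from birth until S entry, then applies each scheduled
#' inhibitor step in turn, and finally releases the cell into
#' inhibitor-free medium until it divides (or \code{tail} minutes elapse).
#' The canonical schedule - an intermediate dose to block the cell in G2
#' while fusion protein accumulates, then a high dose to reset it to G1 and
#' re-license origins, then release - produces an abrupt rise in activity
#' that crosses both thresholds in quick succession: a conditional mitotic
#' catastrophe.
#'
#' @param params an \code{\link{mcn_parameters}} object.
#' @param genotype genotype with \code{cdc2as = TRUE}.
#' @param schedule two-column matrix/data frame (or list of length-2
#'   vectors) of \code{(nmpp1_level, duration_min)} applied after S entry.
#' @param tail minutes of inhibitor-free integration after the schedule.
#' @param dt sampling interval (min).
#' @param rtol,atol solver tolerances.
#' @return A list of class \code{g1_reset} with the combined \code{states}
#'   data frame (including the inhibitor level column \code{nmpp1}),
#'   \code{events} on the effective activity, \code{release_time}, and
#'   \code{post_release_lag} (first S entry to first M entry after
#'   release, min; \code{NA} if either is missing).
#' @export
run_g1_reset <- function(params, genotype, schedule, tail = 150, dt = 0.1,
                         rtol = 1e-8, atol = 1e-10) {
  if (is.character(genotype)) genotype <- genotype_preset(genotype)
  if (!genotype$cdc2as)
    stop("the G1-reset protocol requires an analog-sensitive kinase ",
         "(genotype cdc2as flag)")
  params <- apply_genotype(params, genotype)
  sched <- do.call(rbind, lapply(unclass(schedule), function(s)
    c(as.numeric(s[[1]]), as.numeric(s[[2]]))))
  sched <- matrix(as.numeric(sched), ncol = 2)
  if (any(!is.finite(sched)) || any(sched[, 1] < 0))
    stop("schedule levels must be finite and non-negative")
  if (any(sched[, 2] <= 0)) stop("schedule durations must be positive")

  ## converge at zero inhibitor, then restart the final cycle and stop at
  ## S entry
  base <- integrate_to_limit_cycle(params, convergence_tol = 1e-4, dt = dt,
                                   rtol = rtol, atol = atol)
  if (base$arrested) stop("cell is arrested at zero inhibitor")
  s_entry <- base$events$time[base$events$type == "S_ENTRY"][1]
  if (is.na(s_entry)) stop("no S entry found at zero inhibitor")
  pre <- base$states[base$states$time <= s_entry, ]
  y <- unlist(pre[nrow(pre), .state_names])

  segs <- list(cbind(pre[, c("time", .state_names, "a")],
                     nmpp1 = 0))
  t0 <- pre$time[nrow(pre)]
  run_seg <- function(y, level, duration, t0) {
    sol <- .integrate_span(y, seq(0, duration, by = dt), params,
                           nmpp1 = level, rtol = rtol, atol = atol)
    df <- as.data.frame(sol)
    names(df)[1] <- "time"
    names(df)[names(df) == "A"] <- "a"
    df$time <- df$time + t0
    df$nmpp1 <- level
    df
  }
  for (i in seq_len(nrow(sched))) {
    df <- run_seg(y, sched[i, 1], sched[i, 2], t0)
    y <- unlist(df[nrow(df), .state_names])
    t0 <- df$time[nrow(df)]
    segs[[length(segs) + 1]] <- df[, c("time", .state_names, "a", "nmpp1")]
  }
  release_time <- t0
  df <- run_seg(y, 0, tail, t0)
  segs[[length(segs) + 1]] <- df[, c("time", .state_names, "a", "nmpp1")]

  states <- do.call(rbind, segs)
  states <- states[!duplicated(states$time), ]
  states$fp_total <- fp_total(states)
  states$rum1_total <- rum1_total(states)
  events <- detect_events(states, params$theta_s, params$theta_m)
  post_s <- events$time[events$type == "S_ENTRY" &
                          events$time > release_time][1]
  post_m <- events$time[events$type == "M_ENTRY" &
                          events$time > release_time][1]
  structure(list(states = states, events = events,
                 release_time = release_time,
                 post_release_lag = post_m - post_s,
                 params = params),
            class = "g1_reset")
}

#' @export
print.g1_reset <- function(x, ...) {
  cat(sprintf("G1-reset protocol: release at t = %.1f min, post-release S-to-M lag %.1f min\n",
              x$release_time, x$post_release_lag))
  invisible(x)
}

#' Wee1 activity titration
#'
#' Scans total Wee1+Mik1 activity over a grid of fractions of the
#' wild-type level and records, for each level, the converged size at
#' division, the size at S entry, and viability.  Sizes are reported
#' relative to the 100 percent (wild-type) point of the same scan.
#'
#' @param params an \code{\link{mcn_parameters}} object.
#' @param wee1_grid fractions of wild-type Wee1 total, in [0, 1].
#' @param ccp_level background CCP activity for the scan (0 emulates the
#'   minimal-network background, 1 a wild-type cyclin complement).
#' @param genotype_base base genotype modified by the scan.
#' @param t_replication,relicensing_min viability rules, see
#'   \code{\link{assess_viability}}.
#' @param ... passed to \code{\link{integrate_to_limit_cycle}}.
#' @return Data frame with columns \code{wee1_fraction},
#'   \code{mass_division}, \code{mass_s_entry} (both relative to the
#'   wee1_fraction = 1 row), \code{mass_division_abs}, \code{viable},
#'   \code{limiting_defect}.  Non-converging grid points are recorded as
#'   arrested and the scan continues.
#' @export
wee1_titration <- function(params, wee1_grid = seq(0, 1, by = 0.05),
                           ccp_level = 0, genotype_base = genotype(),
                           t_replication = 20, relicensing_min = 1, ...) {
  stopifnot(all(wee1_grid >= 0 & wee1_grid <= 1))
  base <- apply_genotype(params, genotype_base)
  base$ccp <- ccp_level
  one <- function(f) {
    p <- base
    p$wee1_total <- params$wee1_total * f
    cyc <- tryCatch(integrate_to_limit_cycle(p, ...),
                    error = function(e) NULL)
    if (is.null(cyc) || cyc$arrested)
      return(data.frame(wee1_fraction = f, mass_division_abs = NA_real_,
                        mass_s_entry_abs = NA_real_, viable = FALSE,
                        limiting_defect = "ARRESTED"))
    rep <- classify_phases(cyc)
    rep <- assess_viability(rep, t_replication, relicensing_min)
    ms <- cyc$events$mass[cyc$events$type == "S_ENTRY"][1]
    data.frame(wee1_fraction = f,
               mass_division_abs = rep$mass_at_division,
               mass_s_entry_abs = if (length(ms)) ms else NA_real_,
               viable = rep$viable,
               limiting_defect = rep$limiting_defect)
  }
  out <- do.call(rbind, lapply(wee1_grid, one))
  ref <- one(1)
  out$mass_division <- out$mass_division_abs / ref$mass_division_abs
  out$mass_s_entry <- out$mass_s_entry_abs / ref$mass_division_abs
  out[, c("wee1_fraction", "mass_division", "mass_s_entry",
          "mass_division_abs", "mass_s_entry_abs", "viable",
          "limiting_defect")]
}
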