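#' Toy activity trajectories with analytically known crossings
#'
#' Generates closed-form MPF-activity traces (linear ramp, raised
#' sinusoid, or a train of smooth pulses) together with their exact
#' threshold-crossing times, for exercising the event-detection machinery
#' against ground truth.  The returned data frame carries the closed-form
#' activity function as attribute \code{"activity_fun"} (used by
#' \code{\link{detect_events}} for near machine-precision refinement) and
#' the exact event list as attribute \code{"events_true"}.
#'
#' @param kind \code{"ramp"}, \code{"sinusoid"} or \code{"pulse"}.
#' @param params list of shape parameters with defaults:
#'   ramp: \code{slope} (0.001/min), \code{t_end} (250);
#'   sinusoid: \code{amplitude} (0.12), \code{period} (140),
#'   \code{n_periods} (2); pulse: \code{period} (140), \code{width} (8),
#'   \code{peak} (0.5), \code{n_pulses} (3).
#' @param theta_s,theta_m thresholds used for the ground-truth events.
#' @param dt sampling interval (min).
#' @return Data frame with columns \code{time}, \code{mpf}, \code{a}, of
#'   class \code{toy_trajectory}.
#' @export
#' @examples
#' toy <- make_toy_trajectory("ramp")
#' attr(toy, "events_true")   # S at 10 min, M at 200 min
make_toy_trajectory <- function(kind = c("ramp", "sinusoid", "pulse"),
                                params = list(), theta_s = 0.01,
                                theta_m = 0.2, dt = 0.25) {
  kind <- match.arg(kind)
  p <- switch(kind,
    ramp = utils::modifyList(list(slope = 0.001, t_end = 250), params),
    sinusoid = utils::modifyList(list(amplitude = 0.12, period = 140,
                                      n_periods = 2), params),
    pulse = utils::modifyList(list(period = 140, width = 8, peak = 0.5,
                                   n_pulses = 3), params))

  if (kind == "ramp") {
    f <- function(t) p$slope * t
    t_end <- p$t_end
    ev <- data.frame(type = c("S_ENTRY", "M_ENTRY"),
                     time = c(theta_s, theta_m) / p$slope)
    ev <- ev[ev$time <= t_end, ]
  } else if (kind == "sinusoid") {
    f <- function(t) p$amplitude * (1 + sin(2 * pi * t / p$period))
    t_end <- p$n_periods * p$period
    cross_up <- function(theta) {
      ## a(t) = theta  =>  sin(2 pi t / P) = theta/amp - 1
      s <- theta / p$amplitude - 1
      if (abs(s) >= 1) return(numeric(0))   # tangency is not a crossing
      base_up <- p$period * asin(s) / (2 * pi)       # rising crossing
      tt <- base_up + p$period * (0:(p$n_periods))
      tt[tt >= 0 & tt <= t_end]
    }
    cross_down <- function(theta) {
      s <- theta / p$amplitude - 1
      if (abs(s) >= 1) return(numeric(0))   # tangency is not a crossing
      base_dn <- p$period * (0.5 - asin(s) / (2 * pi))  # falling crossing
      tt <- base_dn + p$period * (0:(p$n_periods))
      tt[tt >= 0 & tt <= t_end]
    }
    ev <- rbind(
      data.frame(type = "S_ENTRY", time = cross_up(theta_s)),
      data.frame(type = "M_ENTRY", time = cross_up(theta_m)),
      data.frame(type = "M_EXIT_DIVISION", time = cross_down(theta_m)))
  } else {
    ## gaussian pulse train centred at (k + 1/2) * period
    f <- function(t) {
      k <- floor(t / p$period)
      tc <- (k + 0.5) * p$period
      p$peak * exp(-(t - tc)^2 / (2 * p$width^2))
    }
    t_end <- p$n_pulses * p$period
    half <- function(theta) p$width * sqrt(-2 * log(theta / p$peak))
    centres <- ((seq_len(p$n_pulses)) - 0.5) * p$period
    ev <- rbind(
      data.frame(type = "S_ENTRY", time = centres - half(theta_s)),
      data.frame(type = "M_ENTRY", time = centres - half(theta_m)),
      data.frame(type = "M_EXIT_DIVISION", time = centres + half(theta_m)))
  }
  ev <- ev[order(ev$time), ]
  tt <- seq(0, t_end, by = dt)
  traj <- data.frame(time = tt, mpf = f(tt), a = f(tt))
  attr(traj, "activity_fun") <- f
  attr(traj, "events_true") <- ev
  class(traj) <- c("toy_trajectory", "data.frame")
  traj
}

#' Synthetic reference population of division sizes
#'
#' Statistical stand-in for a measured population of dividing cells:
#' draws \code{n} division sizes from a normal distribution with the
#' requested mean and coefficient of variation.  The shipped labels
#' mirror the qualitative ordering of the modelled strains - the strain
#' without inhibitory phosphorylation has the broader distribution - and
#' regeneration from the same seed is bit-identical.
#'
#' @param genotype_label label recorded in the metadata; the defaults
#'   below are used when \code{noise_spec} is \code{NULL}.
#' @param n sample size.
#' @param seed RNG seed.
#' @param noise_spec optional list with \code{mean} and \code{cv}.
#' @return Numeric vector of class \code{reference_population} with
#'   attribute \code{meta} (generator metadata sufficient to regenerate).
#' @export
make_reference_population <- function(genotype_label = "mcn", n = 500,
                                      seed = 1, noise_spec = NULL) {
  stopifnot(n >= 1)
  if (is.null(noise_spec)) {
    noise_spec <- switch(genotype_label,
                         "mcn" = list(mean = 1, cv = 0.07),
                         "mcn-drum1" = list(mean = 0.94, cv = 0.07),
                         "mcn-af" = list(mean = 1, cv = 0.14),
                         "mcn-dwee1dmik1" = list(mean = 1.05, cv = 0.14),
                         list(mean = 1, cv = 0.1))
  }
  x <- withr_seed(seed, stats::rnorm(n, noise_spec$mean,
                                     noise_spec$cv * noise_spec$mean))
  structure(x, meta = list(genotype_label = genotype_label, n = n,
                           seed = seed, mean = noise_spec$mean,
                           cv = noise_spec$cv),
            class = c("reference_population", "numeric"))
}

#' The frozen default parameter file
#'
#' Writes the package's reference parameter set as a flat YAML key-value
#' file with a per-key provenance comment (\code{transcribed}: stated
#' constant; \code{derived}: forced by a stated relation;
#' \code{calibrated}: fitted once against the MCN reference cycle).  A
#' copy of this file ships with the package under \code{extdata}.
#'
#' @param path destination; default is a file in \code{tempdir()}.
#' @return The path, invisibly; read it back with
#'   \code{\link{read_parameters}}.
#' @export
#' @examples
#' f <- default_parameter_file()
#' identical(unclass(read_parameters(f)), unclass(mcn_parameters()))
default_parameter_file <- function(path = file.path(tempdir(),
                                                    "mcn_parameters.yaml")) {
  write_parameters(mcn_parameters(), path)
  invisible(path)
}
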