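#' Goldbeter-Koshland activation rate
#'
#' Rate of change of the active fraction of a covalent-modification cycle
#' operating in the zero-order ultrasensitive regime:
#' \deqn{v_a (1-a)/(J_a + 1 - a) - v_i a/(J_i + a).}
#' With small Michaelis constants the steady-state activity switches
#' sharply as \code{v_act/v_inact} crosses 1.  The model uses this form for
#' the Wee1, Cdc25, IE and APC:Slp1 modules, with the kinase-dependent leg
#' scaled by the effective MPF activity.
#'
#' @param active current active fraction, in [0, 1].
#' @param v_act,v_inact activation and inactivation rates (1/min, >= 0).
#' @param j_act,j_inact Michaelis constants (> 0, relative to the total).
#' @return d(active)/dt (1/min).  Positive at \code{active = 0} when
#'   \code{v_act > 0} and negative at \code{active = 1} when
#'   \code{v_inact > 0}, so trajectories remain inside [0, 1].
#' @export
#' @examples
#' gk_rate(0, 1, 1, 0.01, 0.01)    # ~0.990
#' uniroot(function(a) gk_rate(a, 1, 1, 0.01, 0.01), c(0, 1))$root  # 0.5
gk_rate <- function(active, v_act, v_inact, j_act, j_inact) {
  args <- list(active = active, v_act = v_act, v_inact = v_inact,
               j_act = j_act, j_inact = j_inact)
  for (nm in names(args))
    if (!all(is.finite(args[[nm]])))
      stop("non-finite value for argument '", nm, "'")
  if (any(active < 0 | active > 1)) stop("'active' must lie in [0, 1]")
  if (any(c(v_act, v_inact) < 0)) stop("rates must be non-negative")
  if (any(c(j_act, j_inact) <= 0)) stop("Michaelis constants must be > 0")
  v_act * (1 - active) / (j_act + 1 - active) -
    v_inact * active / (j_inact + active)
}

#' Right-hand side of the minimal Cdk network ODEs
#'
#' Computes the time derivative of every component of a
#' \code{\link{cdk_state}}.  The effective kinase activity
#' \code{A = (mpf + alpha*mpf_p)/(1 + nmpp1)} drives Wee1 inactivation,
#' Cdc25/IE activation, APC activation (through IE) and the second Rum1
#' phosphorylation; the first Rum1 phosphorylation by the phosphorylated
#' fusion protein is mass action on the \code{mpf_p * rum1} product
#' (MPF_P is the "starter kinase": it binds Rum1 only weakly, so it is not
#' sequestered, and its phosphorylation of Rum1 marks the inhibitor for
#' degradation).  The Rum1 motif is a two-step distributive phosphorylation
#' with tight binding to MPF: association (\code{k_ass}), slow in-complex
#' conversion to Rum1_P (\code{k_irum1}), fast dephosphorylation back
#' (\code{k_arum1}), and a mass-action second phosphorylation
#' (\code{k_drum1p * A}) followed by immediate degradation.  A background
#' CCP kinase activity degrades all three Rum1 pools at \code{k_dx * ccp},
#' releasing MPF from the complex.  Mass grows exponentially,
#' \code{d(mass)/dt = mu * mass}.
#'
#' @param state a \code{\link{cdk_state}} vector (validated).
#' @param params an \code{\link{mcn_parameters}} object.
#' @param genotype optional \code{\link{mcn_genotype}} applied to
#'   \code{params} before evaluation (a genotype must be chosen; pass the
#'   default \code{genotype()} for the unmodified network).
#' @param nmpp1 ATP-analog inhibitor level in IC50 units (only meaningful
#'   for analog-sensitive kinase; activity is divided by \code{1 + nmpp1}).
#' @return Named numeric vector of derivatives, one per state component.
#' @seealso \code{\link{gk_rate}}, \code{\link{integrate_to_limit_cycle}}
#' @export
cdk_rhs <- function(state, params, genotype = NULL, nmpp1 = 0) {
  if (!is.null(genotype)) params <- apply_genotype(params, genotype)
  validate_state(state)
  if (!is.finite(nmpp1) || nmpp1 < 0) stop("nmpp1 must be >= 0")
  dy <- .rhs_r(0, unclass(state)[.state_names], c(unclass(params),
                                                  nmpp1 = nmpp1))[[1]]
  names(dy) <- .state_names
  dy
}

## deSolve-form R implementation; reference for the compiled version
.rhs_r <- function(t, y, p) {
  mpf <- y[1]; mpf_p <- y[2]; c_ <- y[3]; r <- y[4]; rp <- y[5]
  w <- y[6]; d25 <- y[7]; ie <- y[8]; apc <- y[9]; mass <- y[10]
  inh <- 1 + p[["nmpp1"]]
  A <- (mpf + p[["alpha"]] * mpf_p) / inh
  mpfp_eff <- mpf_p / inh
  vwee <- if (p[["af"]] > 0) 0 else p[["k_wee"]] * p[["wee1_total"]] * w
  v25 <- p[["k_25b"]] + p[["k_25"]] * d25
  deg <- p[["k_dmpf"]] + p[["k_dmpf_apc"]] * apc
  ccpd <- p[["k_dx"]] * p[["ccp"]]
  j <- p[["j_gk"]]
  gk <- function(a, va, vi) va * (1 - a) / (j + 1 - a) - vi * a / (j + a)
  list(c(
    p[["k_smpf"]] * mass - vwee * mpf + v25 * mpf_p - deg * mpf -
      p[["k_ass"]] * mpf * r + (p[["k_diss"]] + p[["k_irum1"]] + ccpd) * c_,
    vwee * mpf - v25 * mpf_p - deg * mpf_p,
    p[["k_ass"]] * mpf * r -
      (p[["k_diss"]] + p[["k_irum1"]] + deg + p[["k_dc"]] + ccpd) * c_,
    p[["v_srum1"]] - p[["k_ass"]] * mpf * r + p[["k_diss"]] * c_ +
      p[["k_arum1"]] * rp - p[["k_i2rum1"]] * mpfp_eff * r -
      (ccpd + p[["k_dbr"]]) * r + (deg + p[["k_dc"]]) * c_,
    p[["k_irum1"]] * c_ + p[["k_i2rum1"]] * mpfp_eff * r -
      p[["k_arum1"]] * rp - p[["k_drum1p"]] * A * rp -
      (ccpd + p[["k_dbr"]]) * rp,
    gk(w, p[["va_wee"]], p[["vi_wee"]] * A),
    gk(d25, p[["va_25"]] * A, p[["vi_25"]]),
    gk(ie, p[["va_ie"]] * A, p[["vi_ie"]]),
    gk(apc, p[["va_apc"]] * ie, p[["vi_apc"]]),
    p[["mu"]] * mass))
}

## canonical order of the parameter vector handed to compiled code
.cparam_names <- c("k_smpf", "alpha", "k_irum1", "k_arum1", "k_drum1p",
                   "k_i2rum1", "k_ass", "k_diss", "k_dx", "ccp", "mu",
                   "wee1_total", "af", "nmpp1", "v_srum1", "k_dmpf",
                   "k_dmpf_apc", "k_dc", "k_dbr", "k_wee", "k_25", "k_25b",
                   "va_wee", "vi_wee", "va_25", "vi_25", "va_ie", "vi_ie",
                   "va_apc", "vi_apc", "j_gk", "theta_s", "theta_m")

.cparams <- function(params, nmpp1 = 0) {
  p <- c(unclass(params), nmpp1 = nmpp1)
  v <- vapply(.cparam_names, function(nm) as.numeric(p[[nm]]), numeric(1))
  v
}

## ODE integration over a fixed span with the compiled RHS; returns the
## deSolve matrix (time, states, A)
.integrate_span <- function(y, times, params, nmpp1 = 0,
                            rtol = 1e-8, atol = 1e-10, root_m = FALSE) {
  pv <- .cparams(params, nmpp1)
  if (root_m)
    deSolve::lsodar(y = y, times = times, func = "cdk_derivs", parms = pv,
                    dllname = "mcncycle", initfunc = "cdk_initmod",
                    rootfunc = "cdk_root_m", nroot = 1, nout = 1,
                    outnames = "A", rtol = rtol, atol = atol)
  else
    deSolve::lsoda(y = y, times = times, func = "cdk_derivs", parms = pv,
                   dllname = "mcncycle", initfunc = "cdk_initmod",
                   nout = 1, outnames = "A", rtol = rtol, atol = atol)
}
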