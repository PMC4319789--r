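#' Instantaneous state of the minimal Cdk network
#'
#' The state holds the nine molecular variables of the network plus cell
#' mass.  \code{mpf}, \code{mpf_p}, \code{mpf_rum1}, \code{rum1} and
#' \code{rum1_p} are concentrations in CU; \code{wee1}, \code{cdc25},
#' \code{ie} and \code{apc_slp1} are active fractions of their (constant)
#' totals, in [0, 1].  The doubly phosphorylated Rum1 species is not a
#' state variable: its degradation is treated as immediate.
#'
#' @param mpf active, unphosphorylated fusion protein (CU).
#' @param mpf_p Tyr/Thr-phosphorylated fusion protein (CU); retains
#'   \code{alpha} (5 percent) of MPF kinase activity.
#' @param mpf_rum1 stoichiometric MPF:Rum1 complex (CU).
#' @param rum1 free unphosphorylated Rum1 (CU).
#' @param rum1_p mono-phosphorylated Rum1 (CU).
#' @param wee1,cdc25,ie,apc_slp1 active fractions in [0, 1].
#' @param mass cell mass (dimensionless, > 0).
#' @return A named numeric vector of class \code{cdk_state}.
#' @seealso \code{\link{cdk_rhs}}, \code{\link{fp_total}},
#'   \code{\link{rum1_total}}
#' @export
#' @examples
#' s <- cdk_state(mass = 0.6)
#' fp_total(s)
cdk_state <- function(mpf = 0.01, mpf_p = 0.01, mpf_rum1 = 0.01,
                      rum1 = 0.05, rum1_p = 0, wee1 = 0.9, cdc25 = 0.1,
                      ie = 0.1, apc_slp1 = 0.1, mass = 0.5) {
  y <- c(mpf = mpf, mpf_p = mpf_p, mpf_rum1 = mpf_rum1, rum1 = rum1,
         rum1_p = rum1_p, wee1 = wee1, cdc25 = cdc25, ie = ie,
         apc_slp1 = apc_slp1, mass = mass)
  validate_state(y)
  structure(y, class = "cdk_state")
}

.state_names <- c("mpf", "mpf_p", "mpf_rum1", "rum1", "rum1_p", "wee1",
                  "cdc25", "ie", "apc_slp1", "mass")

#' @rdname cdk_state
#' @param y a state vector to validate.
#' @export
validate_state <- function(y) {
  if (!all(.state_names %in% names(y)))
    stop("state must contain: ", paste(.state_names, collapse = ", "))
  y <- y[.state_names]
  if (!all(is.finite(y)))
    stop("non-finite state component(s): ",
         paste(.state_names[!is.finite(y)], collapse = ", "))
  if (any(y < 0))
    stop("negative state component(s): ",
         paste(.state_names[y < 0], collapse = ", "))
  frac <- c("wee1", "cdc25", "ie", "apc_slp1")
  if (any(y[frac] > 1 + 1e-9))
    stop("activation fraction(s) above 1: ",
         paste(frac[y[frac] > 1 + 1e-9], collapse = ", "))
  if (y["mass"] <= 0) stop("mass must be positive")
  invisible(y)
}

#' Conserved totals and effective kinase activity
#'
#' \code{fp_total} is the total fusion protein
#' (MPF + MPF_P + MPF:Rum1); \code{rum1_total} is total Rum1
#' (Rum1 + Rum1_P + MPF:Rum1).  \code{effective_mpf} is the effective Cdk
#' kinase activity \code{(mpf + alpha * mpf_p) / (1 + nmpp1)} that drives
#' every catalytic step in the model and is compared against the S and M
#' thresholds.
#'
#' @param state a \code{\link{cdk_state}} vector, or a data frame of
#'   trajectory rows with the state columns.
#' @return Numeric vector.
#' @export
fp_total <- function(state) {
  .col(state, "mpf") + .col(state, "mpf_p") + .col(state, "mpf_rum1")
}

#' @rdname fp_total
#' @export
rum1_total <- function(state) {
  .col(state, "rum1") + .col(state, "rum1_p") + .col(state, "mpf_rum1")
}

#' @rdname fp_total
#' @param alpha relative activity of MPF_P.
#' @param nmpp1 inhibitor level in IC50 units (for analog-sensitive
#'   kinase).
#' @export
effective_mpf <- function(state, alpha = 0.05, nmpp1 = 0) {
  (.col(state, "mpf") + alpha * .col(state, "mpf_p")) / (1 + nmpp1)
}

.col <- function(x, nm) if (is.data.frame(x) || is.matrix(x)) x[, nm] else
  unname(x[nm])
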