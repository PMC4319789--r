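#' Configuration of the stochastic model
#'
#' The stochastic version runs Gillespie's direct method over integer
#' molecule counts at fixed system size: a count \code{n} represents
#' concentration \code{n / omega}, and growth enters only through the
#' mass-scaled synthesis flux, exactly as in the ODE model.  At division
#' mass is halved while counts are intensive: a daughter inherits
#' Binomial(n, 1/2) molecules in half the volume, which on the fixed
#' omega scale is the mean-preserving draw \code{2 * Binomial(n, 1/2)}
#' (variance \code{n}); with \code{binomial_partition = FALSE} counts
#' pass unchanged, the deterministic division rule used for regression
#' against the ODE.  Parametric (cell-to-cell) noise multiplies the two
#' synthesis rates by \code{1 + sigma * r}, with \code{r} uniform on
#' [-1, 1], redrawn at every birth.
#'
#' @param omega system size (molecules per CU at unit mass).
#' @param sigma_smpf half-width of the multiplicative noise on
#'   \code{k_smpf}.
#' @param sigma_srum1 half-width of the multiplicative noise on
#'   \code{v_srum1}.
#' @param seed RNG seed used by the population helpers (lineage \code{i}
#'   of a population runs on a stream seeded with \code{seed + i}, so the
#'   lineages are order-independent).
#' @param n_cells population sample size.
#' @param record_dt trajectory recording interval (min).
#' @param binomial_partition apply binomial partition noise at division;
#'   \code{FALSE} leaves counts unchanged (regression against the ODE).
#' @param max_step maximum time advance without a propensity refresh
#'   (min); bounds the error of the deterministic-growth coupling.
#' @return An object of class \code{ssa_config}.
#' @export
stochastic_config <- function(omega = 1000, sigma_smpf = 0.1,
                              sigma_srum1 = 0.25, seed = 1L,
                              n_cells = 500, record_dt = 0.5,
                              binomial_partition = TRUE, max_step = 0.5) {
  stopifnot(omega >= 1, sigma_smpf >= 0, sigma_smpf < 1,
            sigma_srum1 >= 0, sigma_srum1 < 1, n_cells >= 1,
            record_dt > 0, max_step > 0)
  structure(list(omega = omega, sigma_smpf = sigma_smpf,
                 sigma_srum1 = sigma_srum1, seed = as.integer(seed),
                 n_cells = n_cells, record_dt = record_dt,
                 binomial_partition = isTRUE(binomial_partition),
                 max_step = max_step),
            class = "ssa_config")
}

.rxn_labels <- c(
  "fp_synthesis", "wee1_phosphorylation", "cdc25_dephosphorylation",
  "mpf_degradation", "mpf_p_degradation", "rum1_association",
  "rum1_dissociation", "rum1_first_phosphorylation_in_complex",
  "fusion_degradation_in_complex", "ccp_degradation_of_complex_rum1",
  "rum1_synthesis", "rum1_first_phosphorylation_by_mpf_p",
  "rum1_basal_turnover", "ccp_degradation_of_rum1",
  "rum1_p_dephosphorylation", "rum1_second_phosphorylation",
  "rum1_p_basal_turnover", "ccp_degradation_of_rum1_p",
  "wee1_activation", "wee1_inactivation", "cdc25_activation",
  "cdc25_inactivation", "ie_activation", "ie_inactivation",
  "apc_activation", "apc_inactivation")

#' Reaction system of the stochastic model
#'
#' Builds the reaction list used by the stochastic simulator: one reaction
#' per elementary flux of the deterministic right-hand side, with the
#' standard concentration-to-count conversion at system size \code{omega}
#' (first-order constants unchanged, second-order divided by
#' \code{omega}, zero-order multiplied by \code{omega}; the
#' Goldbeter-Koshland fluxes are treated as single lumped reactions
#' evaluated on counts/omega and multiplied by \code{omega}).  The
#' deterministic and stochastic term inventories are in bijection:
#' summing state-change vectors weighted by propensities and dividing by
#' \code{omega} recovers the deterministic species derivatives exactly.
#'
#' @param params an \code{\link{mcn_parameters}} object.
#' @param genotype optional genotype applied first.
#' @param omega system size.
#' @return An object of class \code{ssa_reactions}: list with
#'   \code{stoichiometry} (9 x 26 integer matrix, species by reactions),
#'   \code{labels}, \code{propensity(counts, mass)} returning the 26
#'   propensities, and \code{drift(counts, mass)} returning the implied
#'   concentration derivatives (the mean-field right-hand side).
#' @export
build_reactions <- function(params, genotype = NULL, omega = 1000) {
  if (!is.null(genotype)) params <- apply_genotype(params, genotype)
  validate_parameters(params)
  pv <- .cparams(params)
  S <- .Call("C_ssa_stoich", PACKAGE = "mcncycle")
  rownames(S) <- .state_names[1:9]
  colnames(S) <- .rxn_labels
  propensity <- function(counts, mass) {
    stopifnot(length(counts) == 9, all(counts >= 0), mass > 0)
    a <- .Call("C_ssa_propensities", as.numeric(counts), as.numeric(mass),
               pv, as.numeric(omega), PACKAGE = "mcncycle")
    names(a) <- .rxn_labels
    a
  }
  structure(list(stoichiometry = S, labels = .rxn_labels,
                 propensity = propensity,
                 drift = function(counts, mass)
                   drop(S %*% propensity(counts, mass)) / omega,
                 omega = omega, params = params),
            class = "ssa_reactions")
}

#' Draw per-birth synthesis parameters
#'
#' At each birth the fusion-protein and Rum1 synthesis rates are drawn
#' independently as \code{base * (1 + sigma * r)} with \code{r} uniform on
#' [-1, 1]; all other parameters are untouched.  Uses the current R RNG
#' stream.
#'
#' @param base_params an \code{\link{mcn_parameters}} object.
#' @param config an \code{\link{stochastic_config}}.
#' @return A modified copy of \code{base_params}.
#' @export
draw_birth_parameters <- function(base_params, config) {
  stopifnot(inherits(config, "ssa_config"))
  p <- base_params
  p$k_smpf <- p$k_smpf * (1 + config$sigma_smpf * stats::runif(1, -1, 1))
  p$v_srum1 <- p$v_srum1 *
    (1 + config$sigma_srum1 * stats::runif(1, -1, 1))
  p
}

#' Stochastic simulation of one cell lineage
#'
#' Runs the exact direct-method SSA with deterministic exponential mass
#' growth between jumps (propensities refreshed at every firing and at
#' least every \code{max_step} minutes).  When the effective MPF activity
#' crosses the mitotic threshold downward - after having stayed above it
#' for at least one minute, which debounces count fluctuations - the cell
#' divides: mass is halved, counts receive mean-preserving binomial
#' partition noise (see \code{\link{stochastic_config}}), birth
#' parameters are redrawn, and one daughter is followed.
#'
#' @param params an \code{\link{mcn_parameters}} object.
#' @param genotype optional genotype applied first.
#' @param config an \code{\link{stochastic_config}}; its \code{seed} is
#'   applied before the run unless \code{NULL}.
#' @param t_end simulated time (min).
#' @param y0 optional initial \code{\link{cdk_state}} converted to counts.
#' @param max_divisions stop after this many divisions (0 = no limit).
#' @param nmpp1 constant inhibitor level.
#' @return An object of class \code{stochastic_run}: list with
#'   \code{time}, \code{counts} (matrix, one column per species),
#'   \code{concentrations} (counts / omega), \code{mass},
#'   \code{divisions} (data frame: time, mass_before, k_smpf, v_srum1,
#'   birth_time, relicensing_min, s_entry_min, m_entry_min), \code{omega}
#'   and \code{nsteps}.
#' @export
ssa_lineage <- function(params, genotype = NULL, config = stochastic_config(),
                        t_end = 2000, y0 = NULL, max_divisions = 0,
                        nmpp1 = 0) {
  if (!is.null(genotype)) params <- apply_genotype(params, genotype)
  validate_parameters(params)
  stopifnot(t_end > 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(y0)) y0 <- cdk_state()
  y <- unclass(y0)[.state_names]
  counts0 <- as.integer(round(y[1:9] * config$omega))
  res <- .Call("C_ssa_lineage", counts0, as.numeric(y[["mass"]]),
               .cparams(params, nmpp1), as.numeric(config$omega),
               as.numeric(t_end), as.numeric(config$record_dt),
               as.numeric(c(config$sigma_smpf, config$sigma_srum1)),
               config$binomial_partition, as.numeric(config$max_step),
               as.integer(max_divisions), PACKAGE = "mcncycle")
  counts <- res$counts
  colnames(counts) <- .state_names[1:9]
  div <- as.data.frame(res$divisions)
  names(div) <- c("time", "mass_before", "k_smpf", "v_srum1", "birth_time",
                  "relicensing_min", "s_entry_min", "m_entry_min")
  structure(list(time = res$time, counts = counts,
                 concentrations = counts / config$omega,
                 mass = res$mass, divisions = div, omega = config$omega,
                 config = config, params = params, nsteps = res$nsteps),
            class = "stochastic_run")
}

#' @export
print.stochastic_run <- function(x, ...) {
  cat(sprintf("Stochastic run: %.0f min, %d divisions, %.3g reaction events (omega = %g)\n",
              max(x$time), nrow(x$divisions), x$nsteps, x$omega))
  invisible(x)
}

#' Simulate a population of independent lineages
#'
#' Runs \code{config$n_cells} single-cell lineages, each on its own RNG
#' stream (\code{config$seed + i}), each followed for \code{discard +
#' n_divisions} divisions; the first \code{discard} divisions of every
#' lineage are dropped as burn-in.
#'
#' @param params an \code{\link{mcn_parameters}} object.
#' @param genotype optional genotype applied first.
#' @param config an \code{\link{stochastic_config}}.
#' @param n_divisions retained divisions per lineage.
#' @param discard burn-in divisions per lineage.
#' @param t_max per-lineage time cap (min).
#' @return Data frame of pooled division records (as in
#'   \code{\link{ssa_lineage}}, plus \code{cell}).
#' @export
run_population <- function(params, genotype = NULL,
                           config = stochastic_config(), n_divisions = 10,
                           discard = 3, t_max = NULL) {
  if (!is.null(genotype)) params <- apply_genotype(params, genotype)
  if (is.null(t_max))
    t_max <- (n_divisions + discard + 2) * 2 * log(2) / params$mu
  out <- lapply(seq_len(config$n_cells), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    run <- ssa_lineage(params, config = cfg, t_end = t_max,
                       max_divisions = n_divisions + discard)
    div <- run$divisions
    if (nrow(div) > discard) {
      div <- div[(discard + 1):nrow(div), ]
      div$cell <- i
      div
    } else NULL
  })
  do.call(rbind, out)
}

#' Division-size statistics of a simulated population
#'
#' Histogram and moments of cell size at division, pooled over the
#' division records of a population run.
#'
#' @param divisions data frame from \code{\link{run_population}} (or any
#'   data frame with a \code{mass_before} column), or a numeric vector of
#'   division sizes.
#' @param bin_width histogram bin width (mass units).
#' @return List with \code{n}, \code{mean}, \code{sd}, \code{cv},
#'   \code{histogram} (data frame: bin_left, bin_right, proportion) and
#'   \code{low_confidence} (fewer than 50 divisions).
#' @export
population_statistics <- function(divisions, bin_width = 0.05) {
  m <- if (is.numeric(divisions)) divisions else divisions$mass_before
  m <- m[is.finite(m)]
  n <- length(m)
  if (n == 0) stop("no division records")
  lo <- floor(min(m) / bin_width) * bin_width
  breaks <- seq(lo, max(m) + bin_width, by = bin_width)
  h <- graphics::hist(m, breaks = breaks, plot = FALSE)
  list(n = n, mean = mean(m), sd = stats::sd(m),
       cv = stats::sd(m) / mean(m),
       histogram = data.frame(bin_left = h$breaks[-length(h$breaks)],
                              bin_right = h$breaks[-1],
                              proportion = h$counts / n),
       low_confidence = n < 50)
}

#' Per-division outcome census
#'
#' Classifies every division record of a population run with the shared
#' viability rules: \code{NO_RELICENSING} when the licensing window
#' (activity below the S threshold) did not exceed
#' \code{relicensing_min}; \code{SHORT_S_TO_M} when S-to-M was shorter
#' than \code{t_replication} (or S/M entries were never cleanly
#' established); \code{VIABLE} otherwise.
#'
#' @param divisions data frame from \code{\link{run_population}}.
#' @param t_replication,relicensing_min see
#'   \code{\link{assess_viability}}.
#' @return List with \code{counts} (named integer vector),
#'   \code{frequencies}, and the annotated \code{divisions} table
#'   (column \code{outcome}).
#' @export
catastrophe_census <- function(divisions, t_replication = 20,
                               relicensing_min = 1) {
  lag <- divisions$m_entry_min - divisions$s_entry_min
  outcome <- ifelse(divisions$relicensing_min <= relicensing_min,
                    "NO_RELICENSING",
                    ifelse(is.na(lag) | lag < t_replication,
                           "SHORT_S_TO_M", "VIABLE"))
  counts <- table(factor(outcome, levels = c("VIABLE", "NO_RELICENSING",
                                             "SHORT_S_TO_M")))
  divisions$outcome <- outcome
  list(counts = counts, frequencies = counts / sum(counts),
       divisions = divisions)
}
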