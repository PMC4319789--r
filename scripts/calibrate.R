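#!/usr/bin/env Rscript
## Calibration of the unprinted rate constants of the minimal Cdk network.
##
## The stated constants (synthesis rate of the fusion protein, the Rum1
## phosphorylation/binding constants, alpha, k_dx, the thresholds, and the
## growth rate implied by the 138.6-min balanced period) are held fixed.
## The remaining module rates - Goldbeter-Koshland activation/inactivation
## rates, degradation constants, Rum1 synthesis and turnover, and the
## Wee1/Cdc25 catalytic constants - are fitted by Nelder-Mead on
## log-parameters against the computed phenotype table: the wild-type
## minimal-network (MCN) cycle is the anchor row, and the mutant rows
## (rum1-null, wee1-null, AF, and the CCP variants), the post-division
## activity minimum and the G1-phase total-Rum1 scale (~0.4 CU) constrain
## the rest.  The result is frozen in R/parameters-defaults.R and in
## inst/extdata/mcn_parameters.yaml; this script reproduces that fit.
##
## Usage: Rscript scripts/calibrate.R [maxit] [out.yaml]
## Runtime: hours at the default maxit; this is an offline tool, not part
## of the test or acceptance runs.

suppressPackageStartupMessages(library(mcncycle))

args <- commandArgs(trailingOnly = TRUE)
maxit <- if (length(args) >= 1) as.integer(args[1]) else 3000
outfile <- if (length(args) >= 2) args[2] else "calibrated_parameters.yaml"

FREE <- c("v_srum1", "k_dmpf", "k_dmpf_apc", "k_dc", "k_dbr", "k_wee",
          "k_25", "k_25b", "va_wee", "vi_wee", "va_25", "vi_25", "va_ie",
          "vi_ie", "va_apc", "vi_apc")

## targets: phenotype table rows (G1, S/G2, M, re-licensing in minutes;
## mass at division relative to the MCN row; NA = row is inviable with
## re-licensing 0)
targets <- list(
  mcn            = c(31.8, 98.5, 8.3, 27.1, 1.00),
  "mcn-drum1"    = c(21.5, 108.6, 8.5, 13.8, 0.94),
  "mcn-dwee1dmik1" = c(75.0, 46.7, 16.9, 68.7, 1.05),
  "fusion-ccp1"  = c(25.7, 104.5, 8.4, 19.9, 0.98),
  "af-ccp1"      = c(50.3, 63.1, 25.2, 42.3, 0.59),
  "fusion-ccp2"  = c(23.5, 106.7, 8.4, 16.9, 0.97),
  "af-ccp2"      = c(NA, NA, NA, 0, 0.41),
  "af-drum1"     = c(NA, NA, NA, 0, 0.18))
weights <- list(
  mcn = c(3, 3, 2, 3, 1), "mcn-drum1" = c(3, 1, 1, 2, 3),
  "mcn-dwee1dmik1" = c(3, 2, 1.5, 3, 4), "fusion-ccp1" = c(2, 1, 1, 2, 2),
  "af-ccp1" = c(2, 1, 1, 2, 3), "fusion-ccp2" = c(1, 1, 1, 1, 1),
  "af-ccp2" = c(0, 0, 0, 0, 2), "af-drum1" = c(0, 0, 0, 0, 2))

sqlr <- function(x, target) if (!is.finite(x) || x <= 0) 25 else
  log(x / target)^2

phenotypes <- function(params) {
  out <- list()
  ref <- NA_real_
  for (g in names(targets)) {
    rep <- tryCatch({
      cyc <- integrate_to_limit_cycle(params, g, dt = 0.5,
                                      convergence_tol = 5e-4,
                                      max_cycles = 25)
      classify_phases(cyc)
    }, error = function(e) NULL)
    if (g == "mcn" && !is.null(rep)) ref <- rep$mass_at_division
    out[[g]] <- rep
  }
  attr(out, "ref_mass") <- ref
  out
}

loss <- function(params) {
  ph <- phenotypes(params)
  ref <- attr(ph, "ref_mass")
  if (!is.finite(ref)) return(500)
  L <- 0
  for (g in names(targets)) {
    rep <- ph[[g]]
    tg <- targets[[g]]; w <- weights[[g]]
    if (is.null(rep) || identical(rep$limiting_defect, "ARRESTED")) {
      L <- L + 100; next
    }
    inviable_target <- is.na(tg[1])
    if (inviable_target) {
      if (rep$relicensing_min > 0.5) L <- L + 10 + rep$relicensing_min
      L <- L + w[5] * sqlr(rep$mass_at_division / ref, tg[5])
    } else {
      if (rep$relicensing_min < 2) {
        L <- L + 30 + 5 * sqlr(rep$mpf_min, 0.004)
        next
      }
      L <- L + w[1] * sqlr(rep$g1_min, tg[1]) +
        w[2] * sqlr(rep$sg2_min, tg[2]) + w[3] * sqlr(rep$m_min, tg[3]) +
        w[4] * sqlr(rep$relicensing_min, tg[4]) +
        w[5] * sqlr(rep$mass_at_division / ref, tg[5])
    }
    if (g == "mcn") {
      L <- L + 1.5 * sqlr(rep$mpf_min, 0.0035) +
        1 * sqlr(rep$mass_at_division, 0.97) +
        1.5 * sqlr(max(rum1_total(
          integrate_to_limit_cycle(params, "mcn", dt = 1,
                                   convergence_tol = 5e-4)$states)), 0.45)
    }
  }
  L
}

p0 <- mcn_parameters()
obj <- function(theta) {
  p <- p0
  p[FREE] <- as.list(exp(theta))
  tryCatch(loss(p), error = function(e) 1000)
}

cat("initial loss:", obj(log(unlist(p0[FREE]))), "\n")
fit <- optim(log(unlist(p0[FREE])), obj, method = "Nelder-Mead",
             control = list(maxit = maxit, reltol = 1e-11, trace = 1,
                            REPORT = 100))
p1 <- p0
p1[FREE] <- as.list(exp(fit$par))
cat("final loss:", fit$value, "\n")
write_parameters(p1, outfile)
cat("written:", outfile, "\n")
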