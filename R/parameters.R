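#' Model parameters for the minimal Cdk network
#'
#' Builds the full rate-constant set of the minimal Cdk network model: a
#' single Cdc13-L-Cdc2 fusion protein (MPF) regulated by inhibitory
#' phosphorylation (Wee1/Mik1, lumped as one Wee1 pool), the activating
#' phosphatase Cdc25, APC:Slp1-mediated degradation with an intermediary
#' enzyme (IE) providing the time delay, and the stoichiometric inhibitor
#' Rum1, which is itself a distributively two-step-phosphorylated substrate
#' of the kinase.
#'
#' Concentrations are in arbitrary concentration units (CU), time in
#' minutes, and cell mass is dimensionless; the fusion-protein synthesis
#' flux \code{k_smpf * mass} is the only mass-scaled term, which couples the
#' network to cell growth.  The defaults are the frozen reference set used
#' throughout the package: the constants with a stated literature value
#' (\code{k_smpf}, \code{alpha}, \code{k_irum1}, \code{k_arum1},
#' \code{k_drum1p}, \code{k_i2rum1}, \code{k_ass}, \code{k_diss},
#' \code{k_dx}, \code{mu}, \code{theta_s}, \code{theta_m}) are transcribed
#' directly, and the remaining module rates were calibrated once against the
#' wild-type (MCN) reference cycle; see the package vignette and
#' \code{\link{default_parameter_file}} for per-key provenance.
#'
#' @param ... named overrides of individual parameters (e.g.
#'   \code{mcn_parameters(wee1_total = 0.5)}).
#'
#' @return An object of class \code{mcn_parameters}: a named list with
#'   components
#' \describe{
#'   \item{k_smpf}{fusion-protein synthesis rate constant (1/min); the flux
#'     is \code{k_smpf * mass}.}
#'   \item{v_srum1}{Rum1 synthesis rate (CU/min).}
#'   \item{wee1_total}{total Wee1(+Mik1) level relative to wild type.}
#'   \item{alpha}{relative kinase activity of Tyr-phosphorylated MPF_P.}
#'   \item{k_irum1}{turnover number of the MPF:Rum1 complex for the first
#'     Rum1 phosphorylation (1/min).}
#'   \item{k_arum1}{Rum1_P dephosphorylation rate constant (1/min).}
#'   \item{k_drum1p}{mass-action constant for the second Rum1
#'     phosphorylation by Cdk activity (1/(CU min)); the doubly
#'     phosphorylated form is degraded immediately.}
#'   \item{k_i2rum1}{mass-action constant for the first Rum1
#'     phosphorylation by MPF_P (1/(CU min)).}
#'   \item{k_ass, k_diss}{MPF + Rum1 association/dissociation constants;
#'     the Michaelis constant \code{(k_diss + k_irum1)/k_ass} is about
#'     0.02 CU.}
#'   \item{k_dx}{CCP-dependent Rum1 degradation constant (1/(CU min)).}
#'   \item{ccp}{generic Cdc2:CCP background kinase activity (0, 1 or 2).}
#'   \item{af}{1 if the fusion protein cannot be inhibitory-phosphorylated.}
#'   \item{mu}{specific growth rate (1/min); the balanced cycle period is
#'     \code{log(2)/mu}.}
#'   \item{theta_s, theta_m}{MPF-activity thresholds for S entry and for
#'     M entry/exit.}
#'   \item{k_dmpf}{basal fusion-protein degradation (1/min).}
#'   \item{k_dmpf_apc}{APC:Slp1-mediated fusion-protein degradation
#'     (1/min at full APC activity).}
#'   \item{k_dc}{degradation of the fusion moiety inside the MPF:Rum1
#'     complex, releasing Rum1 (1/min); carries the G1-specific,
#'     Rum1-dependent destruction of the fusion protein.}
#'   \item{k_dbr}{basal turnover of free Rum1 and Rum1_P (1/min).}
#'   \item{k_wee}{Wee1-catalysed MPF inhibitory phosphorylation
#'     (1/min at full Wee1 activity).}
#'   \item{k_25, k_25b}{Cdc25-catalysed and basal MPF_P dephosphorylation
#'     (1/min).}
#'   \item{va_wee, vi_wee, va_25, vi_25, va_ie, vi_ie, va_apc, vi_apc}{
#'     activation/inactivation rates of the Goldbeter-Koshland modules for
#'     Wee1, Cdc25, IE and APC:Slp1 (1/min); the MPF-dependent legs are
#'     multiplied by the effective kinase activity.}
#'   \item{j_gk}{Michaelis constant shared by all Goldbeter-Koshland
#'     modules (dimensionless, relative to the module total).}
#' }
#' @seealso \code{\link{genotype}}, \code{\link{apply_genotype}},
#'   \code{\link{read_parameters}}, \code{\link{default_parameter_file}}
#' @export
#' @examples
#' p <- mcn_parameters()
#' (p$k_diss + p$k_irum1) / p$k_ass   # ~ 0.02 CU Michaelis constant
mcn_parameters <- function(...) {
  p <- .mcn_defaults
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  p <- structure(p, class = "mcn_parameters")
  validate_parameters(p)
  p
}

## provenance: "transcribed" = stated value; "derived" = forced by a stated
## relation; "calibrated" = fitted once against the MCN reference cycle.
.mcn_provenance <- c(
  k_smpf = "transcribed", v_srum1 = "calibrated", wee1_total = "transcribed",
  alpha = "transcribed", k_irum1 = "transcribed", k_arum1 = "transcribed",
  k_drum1p = "transcribed", k_i2rum1 = "transcribed", k_ass = "derived",
  k_diss = "derived", k_dx = "transcribed", ccp = "transcribed",
  af = "transcribed", mu = "derived", theta_s = "transcribed",
  theta_m = "transcribed", k_dmpf = "calibrated", k_dmpf_apc = "calibrated",
  k_dc = "calibrated", k_dbr = "calibrated", k_wee = "calibrated",
  k_25 = "calibrated", k_25b = "calibrated", va_wee = "calibrated",
  vi_wee = "calibrated", va_25 = "calibrated", vi_25 = "calibrated",
  va_ie = "calibrated", vi_ie = "calibrated", va_apc = "calibrated",
  vi_apc = "calibrated", j_gk = "calibrated")

#' @rdname mcn_parameters
#' @param params object to validate.
#' @export
validate_parameters <- function(params) {
  stopifnot(is.list(params))
  need <- names(.mcn_defaults)
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  v <- unlist(params[need])
  if (!all(is.finite(v)))
    stop("non-finite parameter(s): ",
         paste(need[!is.finite(v)], collapse = ", "))
  if (any(v < 0))
    stop("negative parameter(s): ", paste(need[v < 0], collapse = ", "))
  if (params$theta_s >= params$theta_m)
    stop("theta_s must be below theta_m")
  if (params$mu <= 0)
    stop("mu must be positive for a growing cell")
  km <- (params$k_diss + params$k_irum1) / params$k_ass
  if (is.finite(km) && km > 0 && abs(km / 0.02 - 1) > 0.10)
    warning("Rum1 binding Michaelis constant (k_diss + k_irum1)/k_ass = ",
            signif(km, 3), " deviates >10% from 0.02 CU")
  invisible(params)
}

#' @export
print.mcn_parameters <- function(x, ...) {
  cat("Minimal Cdk network parameters (CU, min)\n")
  v <- unlist(x)
  prov <- .mcn_provenance[names(v)]
  for (i in seq_along(v))
    cat(sprintf("  %-11s %9.6g  [%s]\n", names(v)[i], v[i], prov[i]))
  invisible(x)
}

#' Genotype presets for strains built on the minimal Cdk network
#'
#' A genotype is a small set of switches that modify the wild-type (MCN)
#' parameter set: loss of Rum1, loss of Wee1+Mik1, a non-phosphorylatable
#' (AF) fusion protein, a background Cdc2:CCP kinase activity (the G1/S
#' cyclins Cig1, Cig2 and Puc1 acting on Rum1), and analog-sensitivity of
#' the kinase to the ATP-analog inhibitor NmPP1.
#'
#' @param rum1_null no Rum1 synthesis (\code{v_srum1 = 0}).
#' @param wee1_null no Wee1/Mik1 (\code{wee1_total = 0}).
#' @param af_fusion fusion protein lacks the inhibitory phosphorylation
#'   sites (T14A/Y15F); the Wee1 flux on the fusion protein is zero.
#' @param ccp_level background Cdc2:CCP activity: 0 (no CCP cyclins),
#'   1 (wild-type CCP), or 2 (CCP complexes additionally insensitive to
#'   Wee1).
#' @param cdc2as kinase carries the analog-sensitive (Shokat) mutation, so
#'   its activity is divided by \code{1 + nmpp1} during simulations with
#'   inhibitor.
#' @return An object of class \code{mcn_genotype}.
#' @export
#' @examples
#' genotype_preset("mcn-dwee1dmik1")
genotype <- function(rum1_null = FALSE, wee1_null = FALSE, af_fusion = FALSE,
                     ccp_level = 0, cdc2as = FALSE) {
  if (!ccp_level %in% c(0, 1, 2))
    stop("ccp_level must be 0, 1 or 2")
  structure(list(rum1_null = isTRUE(rum1_null), wee1_null = isTRUE(wee1_null),
                 af_fusion = isTRUE(af_fusion), ccp_level = ccp_level,
                 cdc2as = isTRUE(cdc2as)),
            class = "mcn_genotype")
}

#' @rdname genotype
#' @param name preset name, one of \code{"mcn"}, \code{"mcn-drum1"},
#'   \code{"mcn-dwee1dmik1"}, \code{"mcn-af"}, \code{"fusion-ccp1"},
#'   \code{"af-ccp1"}, \code{"af-ccp2"}, \code{"af-drum1"},
#'   \code{"mcn-cdc2as"}.
#' @export
genotype_preset <- function(name) {
  name <- match.arg(name, .genotype_presets)
  switch(name,
         mcn = genotype(),
         "mcn-drum1" = genotype(rum1_null = TRUE),
         "mcn-dwee1dmik1" = genotype(wee1_null = TRUE),
         "mcn-af" = genotype(af_fusion = TRUE),
         "fusion-ccp1" = genotype(ccp_level = 1),
         "fusion-ccp2" = genotype(ccp_level = 2),
         "af-ccp1" = genotype(af_fusion = TRUE, ccp_level = 1),
         "af-ccp2" = genotype(af_fusion = TRUE, ccp_level = 2),
         "af-drum1" = genotype(af_fusion = TRUE, rum1_null = TRUE),
         "mcn-cdc2as" = genotype(cdc2as = TRUE))
}

.genotype_presets <- c("mcn", "mcn-drum1", "mcn-dwee1dmik1", "mcn-af",
                       "fusion-ccp1", "fusion-ccp2", "af-ccp1", "af-ccp2",
                       "af-drum1", "mcn-cdc2as")

#' @export
print.mcn_genotype <- function(x, ...) {
  on <- c(if (x$rum1_null) "rum1-null", if (x$wee1_null) "wee1/mik1-null",
          if (x$af_fusion) "AF fusion", if (x$ccp_level > 0)
            paste0("CCP=", x$ccp_level), if (x$cdc2as) "cdc2-as")
  cat("Genotype:", if (length(on)) paste(on, collapse = ", ") else
    "MCN (wild-type minimal network)", "\n")
  invisible(x)
}

#' Apply a genotype to a parameter set
#'
#' Returns a modified copy of \code{params}: \code{rum1_null} zeroes
#' \code{v_srum1}, \code{wee1_null} zeroes \code{wee1_total},
#' \code{af_fusion} sets the \code{af} switch (the Wee1 flux on the fusion
#' protein is dropped; any CCP heterodimers are untouched, their
#' Wee1-insensitivity being encoded in \code{ccp_level = 2}), and
#' \code{ccp_level} sets \code{ccp}.  The input object is not modified.
#'
#' @param params an \code{\link{mcn_parameters}} object.
#' @param genotype an \code{\link{mcn_genotype}} object or preset name.
#' @return A new \code{mcn_parameters} object.
#' @export
apply_genotype <- function(params, genotype) {
  if (is.character(genotype)) genotype <- genotype_preset(genotype)
  stopifnot(inherits(genotype, "mcn_genotype"))
  p <- unclass(params)
  if (genotype$rum1_null) p$v_srum1 <- 0
  if (genotype$wee1_null) p$wee1_total <- 0
  if (genotype$af_fusion) p$af <- 1
  p$ccp <- genotype$ccp_level
  structure(p, class = "mcn_parameters")
}

#' Read and write parameter configuration files
#'
#' Parameter sets are serialised as flat key-value maps, either JSON or
#' YAML (chosen by file extension).  Keys are exactly the field names of
#' \code{\link{mcn_parameters}}.
#'
#' @param path file path ending in \code{.json}, \code{.yaml} or
#'   \code{.yml}.
#' @return \code{read_parameters} returns an \code{mcn_parameters} object;
#'   \code{write_parameters} returns \code{path} invisibly.
#' @export
read_parameters <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  vals <- vals[!startsWith(names(vals), "_")]
  do.call(mcn_parameters, as.list(vals))
}

#' @rdname read_parameters
#' @param params an \code{\link{mcn_parameters}} object.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  vals <- unclass(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    lines <- c("# minimal Cdk network parameter set (CU, min)",
               sprintf("%s: %.17g  # %s", names(vals), unlist(vals),
                       .mcn_provenance[names(vals)]))
    writeLines(lines, path)
  }
  invisible(path)
}
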