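#' Computed phenotype table across genotype presets
#'
#' Runs every genotype to its converged limit cycle, classifies phases and
#' viability, and assembles the phenotype table: G1, S/G2 and M durations,
#' re-licensing time, and size at division relative to the wild-type
#' minimal-network (MCN) row computed with the same parameter set.
#'
#' @param params an \code{\link{mcn_parameters}} object.
#' @param genotype_list character vector of preset names (see
#'   \code{\link{genotype_preset}}) or a list of \code{mcn_genotype}
#'   objects (named).
#' @param ... passed to \code{\link{integrate_to_limit_cycle}}.
#' @return Data frame with one row per genotype: \code{genotype},
#'   \code{g1_min}, \code{sg2_min}, \code{m_min},
#'   \code{relicensing_min}, \code{relative_mass}, \code{viable},
#'   \code{limiting_defect}.  Per-genotype failures are recorded in the
#'   row and the table is still produced.
#' @export
#' @examples
#' \donttest{
#' build_phenotype_table(mcn_parameters(), c("mcn", "mcn-drum1"))
#' }
build_phenotype_table <- function(params,
                                  genotype_list = c("mcn", "mcn-drum1",
                                                    "mcn-dwee1dmik1",
                                                    "mcn-af", "fusion-ccp1",
                                                    "af-ccp1", "fusion-ccp2",
                                                    "af-ccp2", "af-drum1"),
                                  ...) {
  if (length(genotype_list) == 0)
    return(data.frame(genotype = character(0), g1_min = numeric(0),
                      sg2_min = numeric(0), m_min = numeric(0),
                      relicensing_min = numeric(0),
                      relative_mass = numeric(0), viable = logical(0),
                      limiting_defect = character(0)))
  nms <- if (is.character(genotype_list)) genotype_list
         else names(genotype_list)
  ref_mass <- tryCatch({
    cyc <- integrate_to_limit_cycle(params, genotype_preset("mcn"), ...)
    if (cyc$arrested) NA_real_
    else cyc$divisions$mass[nrow(cyc$divisions)]
  }, error = function(e) NA_real_)

  one <- function(g, nm) {
    res <- tryCatch({
      cyc <- integrate_to_limit_cycle(params, g, ...)
      rep <- classify_phases(cyc, mass_reference = ref_mass)
      data.frame(genotype = nm, g1_min = rep$g1_min,
                 sg2_min = rep$sg2_min, m_min = rep$m_min,
                 relicensing_min = rep$relicensing_min,
                 relative_mass = rep$relative_mass, viable = rep$viable,
                 limiting_defect = rep$limiting_defect)
    }, error = function(e)
      data.frame(genotype = nm, g1_min = NA_real_, sg2_min = NA_real_,
                 m_min = NA_real_, relicensing_min = NA_real_,
                 relative_mass = NA_real_, viable = NA,
                 limiting_defect = paste("ERROR:",
                                         conditionMessage(e))))
    res
  }
  out <- do.call(rbind, lapply(seq_along(genotype_list), function(i)
    one(if (is.character(genotype_list)) genotype_list[[i]]
        else genotype_list[[i]], nms[i])))
  rownames(out) <- NULL
  out
}

#' Write a trajectory as tidy CSV
#'
#' @param trajectory a \code{cycle_trajectory} (or \code{g1_reset}).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- trajectory$states
  names(df)[names(df) == "a"] <- "effective_mpf"
  names(df)[1] <- "time_min"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Command-line dispatcher
#'
#' Thin command-line front end over the package functions; invoked by the
#' \code{mcncycle} script in \code{inst/scripts}.  Subcommands:
#' \code{simulate}, \code{bifurcate}, \code{ssa}, \code{table2},
#' \code{g1reset}, \code{titrate}, \code{histogram}.  Common flags:
#' \code{--config FILE} (parameter file), \code{--genotype NAME},
#' \code{--seed N}, \code{--out PATH}, \code{--log-level LEVEL},
#' \code{--cycles N}, \code{--cells N}, \code{--omega N},
#' \code{--ccp N}.  Every artifact is accompanied by a JSON provenance
#' sidecar (parameter hash, seed, package version) sufficient to
#' regenerate it.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status, invisibly: 0 success, 2 usage error,
#'   3 numerical failure, 4 non-convergence.
#' @export
cli_dispatch <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: mcncycle <simulate|bifurcate|ssa|table2|g1reset|titrate|histogram> [options]\n",
        "options: --config FILE --genotype NAME --seed N --out PATH\n",
        "         --log-level info|debug --cycles N --cells N --omega N --ccp N\n",
        sep = "")
  }
  if (length(argv) < 1) { usage(); return(invisible(2L)) }
  cmd <- argv[1]
  opts <- list(config = NULL, genotype = "mcn", seed = 1L, out = NULL,
               log_level = "info", cycles = 10L, cells = 50L,
               omega = 1000, ccp = 0)
  args <- argv[-1]
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opts) || i == length(args)) {
      message("unknown or incomplete option: ", args[i]); usage()
      return(invisible(2L))
    }
    val <- args[i + 1]
    opts[[key]] <- if (key %in% c("seed", "cycles", "cells"))
      as.integer(val) else if (key %in% c("omega", "ccp")) as.numeric(val)
    else val
    i <- i + 2
  }
  log_info <- function(...) if (opts$log_level %in% c("info", "debug"))
    message("[mcncycle] ", ...)

  params <- tryCatch(
    if (is.null(opts$config) || identical(opts$config, "default"))
      mcn_parameters() else read_parameters(opts$config),
    error = function(e) { message("config error: ",
                                  conditionMessage(e)); NULL })
  if (is.null(params)) return(invisible(2L))
  out <- if (is.null(opts$out)) file.path(getwd(),
                                          paste0("mcncycle-", cmd)) else
    opts$out
  set.seed(opts$seed)

  provenance <- function(artifact) {
    tmp <- tempfile()
    jsonlite::write_json(unclass(params), tmp, auto_unbox = TRUE,
                         digits = NA)
    side <- paste0(artifact, ".provenance.json")
    jsonlite::write_json(list(
      command = cmd, genotype = opts$genotype, seed = opts$seed,
      ccp = opts$ccp, omega = opts$omega,
      parameter_hash = unname(tools::md5sum(tmp)),
      parameters = unclass(params),
      package_version = as.character(utils::packageVersion("mcncycle"))),
      side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    unlink(tmp)
    side
  }

  run <- function(expr) tryCatch(expr, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("converge", conditionMessage(e))) 4L else 3L
  })

  status <- switch(cmd,
    simulate = run({
      cyc <- integrate_to_limit_cycle(params, opts$genotype,
                                      max_cycles = max(opts$cycles, 40))
      f <- paste0(out, ".csv")
      write_trajectory_csv(cyc, f)
      rep <- classify_phases(cyc)
      jsonlite::write_json(unclass(rep), paste0(out, ".report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      provenance(f)
      log_info("trajectory written to ", f)
      0L
    }),
    table2 = run({
      tab <- build_phenotype_table(params)
      f <- if (grepl("\\.csv$", out)) out else paste0(out, ".csv")
      utils::write.csv(tab, f, row.names = FALSE)
      provenance(f)
      print(tab, row.names = FALSE, digits = 4)
      0L
    }),
    bifurcate = run({
      g <- genotype_preset(opts$genotype)
      diag <- trace_branches(c(0.15, 1.6), 0.005, params, g)
      diag <- classify_snic(diag)
      f <- paste0(out, ".csv")
      utils::write.csv(diag$points, f, row.names = FALSE)
      jsonlite::write_json(diag$folds, paste0(out, ".folds.json"),
                           digits = NA, pretty = TRUE)
      grDevices::png(paste0(out, ".png"), 800, 600)
      plot(diag, main = opts$genotype)
      grDevices::dev.off()
      provenance(f)
      0L
    }),
    ssa = run({
      cfg <- stochastic_config(omega = opts$omega, seed = opts$seed,
                               n_cells = opts$cells)
      div <- run_population(params, genotype_preset(opts$genotype), cfg,
                            n_divisions = opts$cycles)
      stats <- population_statistics(div)
      f <- paste0(out, ".divisions.csv")
      utils::write.csv(div, f, row.names = FALSE)
      utils::write.csv(stats$histogram, paste0(out, ".histogram.csv"),
                       row.names = FALSE)
      provenance(f)
      log_info(sprintf("division size mean %.3f, CV %.3f (n = %d)",
                       stats$mean, stats$cv, stats$n))
      0L
    }),
    g1reset = run({
      g <- genotype(cdc2as = TRUE)
      res <- run_g1_reset(params, g,
                          schedule = list(c(1, 100), c(20, 70)))
      f <- paste0(out, ".csv")
      write_trajectory_csv(res, f)
      jsonlite::write_json(list(release_time = res$release_time,
                                post_release_lag = res$post_release_lag),
                           paste0(out, ".json"), auto_unbox = TRUE,
                           digits = NA)
      provenance(f)
      log_info(sprintf("post-release S-to-M lag: %.1f min",
                       res$post_release_lag))
      0L
    }),
    titrate = run({
      tab <- wee1_titration(params, ccp_level = opts$ccp)
      f <- if (grepl("\\.csv$", out)) out else paste0(out, ".csv")
      utils::write.csv(tab, f, row.names = FALSE)
      provenance(f)
      0L
    }),
    histogram = run({
      pop <- make_reference_population(opts$genotype, n = opts$cells,
                                       seed = opts$seed)
      stats <- population_statistics(as.numeric(pop))
      f <- if (grepl("\\.csv$", out)) out else paste0(out, ".csv")
      utils::write.csv(stats$histogram, f, row.names = FALSE)
      provenance(f)
      0L
    }),
    { message("unknown subcommand: ", cmd); usage(); 2L })
  invisible(as.integer(status))
}
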