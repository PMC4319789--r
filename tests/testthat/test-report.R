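test_that("an empty genotype list yields an empty table", {
  tab <- build_phenotype_table(mcn_parameters(), character(0))
  expect_s3_class(tab, "data.frame")
  expect_equal(nrow(tab), 0)
})

test_that("the phenotype table normalises masses to the MCN row", {
  tab <- cached("table2_small",
                build_phenotype_table(mcn_parameters(),
                                      c("mcn", "mcn-drum1")))
  expect_equal(tab$relative_mass[tab$genotype == "mcn"], 1,
               tolerance = 1e-6)
  expect_true(all(c("g1_min", "sg2_min", "m_min", "relicensing_min",
                    "viable") %in% names(tab)))
})

test_that("trajectory CSV export carries the tidy column set", {
  cyc <- cached_cycle("mcn")
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(cyc, f)
  df <- read.csv(f)
  expect_true(all(c("time_min", "mpf", "mpf_p", "mpf_rum1", "rum1",
                    "rum1_p", "wee1", "cdc25", "ie", "apc_slp1", "mass",
                    "fp_total", "rum1_total", "effective_mpf")
                  %in% names(df)))
  expect_gt(nrow(df), 100)
})

test_that("the command line front end dispatches and reports usage errors", {
  owd <- setwd(tempdir())
  on.exit(setwd(owd))
  expect_equal(cli_dispatch(character(0)), 2L)
  expect_equal(cli_dispatch("frobnicate"), 2L)
  expect_equal(cli_dispatch(c("simulate", "--bad-flag", "1")), 2L)

  out <- file.path(tempdir(), "cli-sim")
  st <- cli_dispatch(c("simulate", "--genotype", "mcn-drum1",
                       "--out", out))
  expect_equal(st, 0L)
  expect_true(file.exists(paste0(out, ".csv")))
  expect_true(file.exists(paste0(out, ".report.json")))
  prov <- jsonlite::read_json(paste0(out, ".csv.provenance.json"))
  expect_equal(prov$genotype, "mcn-drum1")
  expect_true(nzchar(prov$parameter_hash))
})

test_that("stochastic histograms are reproducible from the seed", {
  owd <- setwd(tempdir())
  on.exit(setwd(owd))
  o1 <- file.path(tempdir(), "ssa1")
  o2 <- file.path(tempdir(), "ssa2")
  st1 <- cli_dispatch(c("ssa", "--genotype", "mcn", "--seed", "7",
                        "--cells", "3", "--cycles", "3", "--omega", "400",
                        "--out", o1))
  st2 <- cli_dispatch(c("ssa", "--genotype", "mcn", "--seed", "7",
                        "--cells", "3", "--cycles", "3", "--omega", "400",
                        "--out", o2))
  expect_equal(st1, 0L)
  expect_equal(st2, 0L)
  h1 <- readLines(paste0(o1, ".histogram.csv"))
  h2 <- readLines(paste0(o2, ".histogram.csv"))
  expect_identical(h1, h2)
})
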