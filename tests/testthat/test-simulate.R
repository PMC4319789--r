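test_that("the converged cycle has exactly one event of each kind", {
  cyc <- cached_cycle("mcn")
  expect_false(cyc$arrested)
  expect_true(cyc$converged)
  expect_equal(sum(cyc$events$type == "S_ENTRY"), 1)
  expect_equal(sum(cyc$events$type == "M_ENTRY"), 1)
  expect_equal(sum(cyc$events$type == "M_EXIT_DIVISION"), 1)
  ev <- cyc$events
  expect_lt(ev$time[ev$type == "S_ENTRY"], ev$time[ev$type == "M_ENTRY"])
})

test_that("the balanced-growth period equals the mass doubling time", {
  p <- mcn_parameters()
  for (preset in c("mcn", "mcn-dwee1dmik1")) {
    cyc <- cached_cycle(preset)
    expect_equal(cyc$period, log(2) / p$mu, tolerance = 1e-3)
  }
})

test_that("mass is halved at division while concentrations are continuous", {
  cyc <- cached_cycle("mcn")
  st <- cyc$states
  m_end <- st$mass[nrow(st)]
  expect_equal(st$mass[1], m_end / 2, tolerance = 1e-3)
  # periodicity: the post-division state maps to itself after one period
  y0 <- unlist(st[1, c("mpf", "mpf_p", "mpf_rum1", "rum1", "rum1_p",
                       "wee1", "cdc25", "ie", "apc_slp1")])
  y1 <- unlist(st[nrow(st), c("mpf", "mpf_p", "mpf_rum1", "rum1",
                              "rum1_p", "wee1", "cdc25", "ie",
                              "apc_slp1")])
  expect_equal(y1, y0, tolerance = 5e-3)
})

test_that("tightening the convergence tolerance leaves the period fixed", {
  p <- mcn_parameters()
  c1 <- integrate_to_limit_cycle(p, "mcn", convergence_tol = 2e-4)
  c2 <- integrate_to_limit_cycle(p, "mcn", convergence_tol = 1e-4)
  expect_lt(abs(c1$period - c2$period), 0.01)
})

test_that("solver refinement does not move the phase boundaries", {
  p <- mcn_parameters()
  c1 <- integrate_to_limit_cycle(p, "mcn")
  c2 <- integrate_to_limit_cycle(p, "mcn", rtol = 5e-9, atol = 5e-11)
  r1 <- classify_phases(c1)
  r2 <- classify_phases(c2)
  for (f in c("g1_min", "sg2_min", "m_min", "relicensing_min",
              "mass_at_division"))
    expect_equal(r1[[f]], r2[[f]], tolerance = 0.01)
})

test_that("a zero-inhibitor schedule reproduces the free-running cycle", {
  p <- mcn_parameters()
  res <- run_g1_reset(p, genotype(cdc2as = TRUE),
                      schedule = list(c(0, 30)), tail = 40, dt = 0.25)
  base <- cached_cycle("mcn")
  # overlapping window: activity along the protocol equals the base cycle
  sel <- res$states$time <= base$period
  tt <- res$states$time[sel]
  a_base <- approx(base$states$time, base$states$a, tt)$y
  keep <- !is.na(a_base)
  expect_equal(res$states$a[sel][keep], a_base[keep], tolerance = 1e-4)
})

test_that("g1 reset validates its inputs", {
  p <- mcn_parameters()
  expect_error(run_g1_reset(p, genotype(), list(c(1, 100))), "cdc2as")
  expect_error(run_g1_reset(p, genotype(cdc2as = TRUE),
                            list(c(-1, 100))), "non-negative")
  expect_error(run_g1_reset(p, genotype(cdc2as = TRUE),
                            list(c(1, 0))), "positive")
})

test_that("an arrested cell is reported, not raised", {
  # without fusion-protein synthesis the activity never reaches theta_m
  p <- mcn_parameters(k_smpf = 1e-5)
  cyc <- integrate_to_limit_cycle(p, "mcn", horizon = 400, max_cycles = 3)
  expect_true(cyc$arrested)
  rep <- classify_phases(cyc)
  expect_false(rep$viable)
  expect_identical(rep$limiting_defect, "ARRESTED")
})
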