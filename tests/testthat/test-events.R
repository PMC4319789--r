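test_that("ramp trajectory crosses the thresholds at the closed-form times", {
  toy <- make_toy_trajectory("ramp")
  ev <- detect_events(toy)
  expect_equal(ev$time[ev$type == "S_ENTRY"], 10, tolerance = 1e-9)
  expect_equal(ev$time[ev$type == "M_ENTRY"], 200, tolerance = 1e-9)
})

test_that("sinusoid crossings match the arcsin solution to 1e-6", {
  toy <- make_toy_trajectory("sinusoid")
  ev <- detect_events(toy)
  truth <- attr(toy, "events_true")
  for (type in unique(truth$type)) {
    got <- sort(ev$time[ev$type == type])
    want <- sort(truth$time[truth$type == type])
    expect_length(got, length(want))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("pulse train yields exactly one M entry per pulse", {
  toy <- make_toy_trajectory("pulse", params = list(n_pulses = 3))
  ev <- detect_events(toy)
  expect_equal(sum(ev$type == "M_ENTRY"), 3)
  expect_equal(sum(ev$type == "M_EXIT_DIVISION"), 3)
  expect_equal(sort(ev$time),
               sort(attr(toy, "events_true")$time), tolerance = 1e-6)
})

test_that("sub-debounce chatter across a threshold is ignored", {
  # rises through theta_s, dips back within 0.5 min, then rises for good
  tt <- seq(0, 40, by = 0.1)
  a <- 0.002 + 0.0005 * tt                     # crosses 0.01 at t = 16
  blip <- tt >= 8 & tt <= 8.4
  a[blip] <- 0.012                             # short excursion above
  traj <- data.frame(time = tt, mpf = a)
  ev <- detect_events(traj, theta_s = 0.01, theta_m = 0.2, debounce = 1)
  s <- ev[ev$type == "S_ENTRY", ]
  expect_equal(nrow(s), 1)
  expect_equal(s$time, 16, tolerance = 0.2)
})

test_that("phase classification from a hand-built event list", {
  tt <- seq(0, 60, by = 0.5)
  events <- data.frame(type = c("S_ENTRY", "M_ENTRY", "M_EXIT_DIVISION"),
                       time = c(10, 50, 60), mass = NA_real_)
  traj <- data.frame(time = tt, a = 0.05)   # activity column only
  rep <- classify_phases(traj, events = events)
  expect_equal(rep$g1_min, 10)
  expect_equal(rep$sg2_min, 40)
  expect_equal(rep$m_min, 10)
})

test_that("viability rules flag the failure classes", {
  base <- structure(list(g1_min = 30, sg2_min = 98, m_min = 10,
                         relicensing_min = 27, period_min = 138,
                         mass_at_division = 1, relative_mass = 1,
                         mpf_min = 0.003, viable = NA, catastrophe = NA,
                         limiting_defect = "NONE"),
                    class = "phase_report")
  ok <- assess_viability(base)
  expect_true(ok$viable)
  expect_identical(ok$limiting_defect, "NONE")

  no_lic <- base; no_lic$relicensing_min <- 0
  no_lic <- assess_viability(no_lic)
  expect_false(no_lic$viable)
  expect_identical(no_lic$limiting_defect, "NO_RELICENSING")

  fast <- base; fast$sg2_min <- 16
  fast <- assess_viability(fast, t_replication = 20)
  expect_false(fast$viable)
  expect_true(fast$catastrophe)
  expect_identical(fast$limiting_defect, "SHORT_S_TO_M")
})

test_that("toy fixtures regenerate bit-identically", {
  a <- make_toy_trajectory("sinusoid")
  b <- make_toy_trajectory("sinusoid")
  expect_identical(a$mpf, b$mpf)
  p1 <- make_reference_population("mcn-af", n = 200, seed = 9)
  p2 <- make_reference_population("mcn-af", n = 200, seed = 9)
  expect_identical(as.numeric(p1), as.numeric(p2))
})

test_that("reference populations honour the requested moments and ordering", {
  pop <- make_reference_population("custom", n = 1e4, seed = 3,
                                   noise_spec = list(mean = 1, cv = 0.08))
  expect_equal(sd(pop) / mean(pop), 0.08, tolerance = 0.05)
  z <- make_reference_population("custom", n = 500, seed = 1,
                                 noise_spec = list(mean = 1, cv = 0))
  expect_true(all(z == 1))
  cv_mcn <- attr(make_reference_population("mcn"), "meta")$cv
  cv_af <- attr(make_reference_population("mcn-af"), "meta")$cv
  expect_gt(cv_af, cv_mcn)
})
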