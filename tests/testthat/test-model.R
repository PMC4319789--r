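test_that("Goldbeter-Koshland rate matches closed forms at the boundaries", {
  # active = 0: rate = v_act * 1 / (j + 1)
  expect_equal(gk_rate(0, 1, 1, 0.01, 0.01), 1 / 1.01, tolerance = 1e-12)
  # symmetric rates balance at active = 0.5
  expect_equal(uniroot(function(a) gk_rate(a, 1, 1, 0.01, 0.01),
                       c(0.01, 0.99), tol = 1e-12)$root, 0.5,
               tolerance = 1e-9)
  # sign structure keeps trajectories inside [0, 1]
  expect_gt(gk_rate(0, 0.3, 2, 0.01, 0.01), 0)
  expect_lt(gk_rate(1, 0.3, 2, 0.01, 0.01), 0)
})

test_that("GK steady state agrees with an independent bisection oracle", {
  v_act <- 2; v_inact <- 1; j <- 0.01
  # oracle: bisection on the balance equation written out independently
  f <- function(a) v_act * (1 - a) / (j + 1 - a) - v_inact * a / (j + a)
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  oracle <- (lo + hi) / 2
  impl <- uniroot(function(a) gk_rate(a, v_act, v_inact, j, j),
                  c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  expect_equal(impl, oracle, tolerance = 1e-10)
})

test_that("gk_rate rejects bad input with a diagnostic naming the argument", {
  expect_error(gk_rate(NaN, 1, 1, 0.01, 0.01), "active")
  expect_error(gk_rate(0.5, Inf, 1, 0.01, 0.01), "v_act")
  expect_error(gk_rate(0.5, 1, 1, 0, 0.01), "Michaelis")
  expect_error(gk_rate(1.5, 1, 1, 0.01, 0.01), "\\[0, 1\\]")
})

test_that("with all synthesis and activation fluxes off, only mass grows", {
  p <- mcn_parameters(k_smpf = 0, v_srum1 = 0, va_wee = 0, va_25 = 0,
                      va_ie = 0, va_apc = 0)
  s <- cdk_state(mpf = 0, mpf_p = 0, mpf_rum1 = 0, rum1 = 0, rum1_p = 0,
                 wee1 = 0, cdc25 = 0, ie = 0, apc_slp1 = 0, mass = 1)
  dy <- cdk_rhs(s, p, genotype())
  expect_equal(unname(dy[c("mpf", "mpf_p", "mpf_rum1", "rum1", "rum1_p",
                           "wee1", "cdc25", "ie", "apc_slp1")]),
               rep(0, 9))
  expect_equal(unname(dy["mass"]), p$mu)
})

test_that("Rum1 and fusion-protein totals obey term-by-term bookkeeping", {
  p <- mcn_parameters()
  for (g in list(genotype(), genotype(ccp_level = 1),
                 genotype(af_fusion = TRUE, ccp_level = 2))) {
    pg <- apply_genotype(p, g)
    for (s in random_states(25)) {
      dy <- cdk_rhs(s, pg)
      a <- effective_mpf(s, pg$alpha)
      deg <- pg$k_dmpf + pg$k_dmpf_apc * s[["apc_slp1"]]
      # total Rum1 changes only through synthesis and its explicit sinks
      d_rum1t <- dy[["rum1"]] + dy[["rum1_p"]] + dy[["mpf_rum1"]]
      sinks <- pg$k_drum1p * a * s[["rum1_p"]] +
        pg$k_dx * pg$ccp * (s[["rum1"]] + s[["rum1_p"]] +
                              s[["mpf_rum1"]]) +
        pg$k_dbr * (s[["rum1"]] + s[["rum1_p"]])
      expect_equal(d_rum1t, pg$v_srum1 - sinks, tolerance = 1e-10)
      # total fusion protein: synthesis minus degradation only
      d_fpt <- dy[["mpf"]] + dy[["mpf_p"]] + dy[["mpf_rum1"]]
      expect_equal(d_fpt,
                   pg$k_smpf * s[["mass"]] -
                     deg * (s[["mpf"]] + s[["mpf_p"]] + s[["mpf_rum1"]]) -
                     pg$k_dc * s[["mpf_rum1"]],
                   tolerance = 1e-10)
    }
  }
})

test_that("MPF_P acts only through its dedicated routes", {
  # with alpha = 0 and the dedicated starter-kinase constant off, the
  # phosphorylated form exerts no catalytic effect: derivatives of all
  # components other than the interconversion pair are unchanged when
  # mpf_p is varied
  p <- mcn_parameters(alpha = 0, k_i2rum1 = 0)
  s1 <- cdk_state(mpf = 0.05, mpf_p = 0.1, rum1 = 0.2, mass = 1)
  s2 <- cdk_state(mpf = 0.05, mpf_p = 0.7, rum1 = 0.2, mass = 1)
  d1 <- cdk_rhs(s1, p)
  d2 <- cdk_rhs(s2, p)
  same <- c("mpf_rum1", "rum1", "rum1_p", "wee1", "cdc25", "ie",
            "apc_slp1", "mass")
  expect_equal(d1[same], d2[same], tolerance = 1e-12)
})

test_that("genotype application modifies only the flagged parameters", {
  p <- mcn_parameters()
  expect_identical(unclass(apply_genotype(p, genotype())), unclass(p))
  pd <- apply_genotype(p, "mcn-drum1")
  expect_equal(pd$v_srum1, 0)
  pd$v_srum1 <- p$v_srum1
  expect_identical(unclass(pd), unclass(p))
  pw <- apply_genotype(p, "mcn-dwee1dmik1")
  expect_equal(pw$wee1_total, 0)
  expect_equal(apply_genotype(p, "af-ccp2")$ccp, 2)
})

test_that("AF fusion and Wee1 deletion give identical dynamics at CCP = 0", {
  p <- mcn_parameters()
  paf <- apply_genotype(p, "mcn-af")
  pdw <- apply_genotype(p, "mcn-dwee1dmik1")
  for (s in random_states(10)) {
    expect_equal(cdk_rhs(s, paf), cdk_rhs(s, pdw), tolerance = 1e-12)
  }
})

test_that("compiled and R right-hand sides integrate identically", {
  p <- mcn_parameters()
  for (s in random_states(5, seed = 7)) {
    y <- unclass(s)
    times <- c(0, 5)
    solC <- mcncycle:::.integrate_span(y, times, p)
    solR <- deSolve::lsoda(y, times, mcncycle:::.rhs_r,
                           c(unclass(p), nmpp1 = 0),
                           rtol = 1e-10, atol = 1e-12)
    expect_equal(unname(solC[2, 2:11]), unname(solR[2, 2:11]),
                 tolerance = 1e-6)
  }
})

test_that("trajectories stay non-negative with fractions in [0, 1]", {
  p <- mcn_parameters()
  for (s in random_states(8, seed = 11)) {
    sol <- mcncycle:::.integrate_span(unclass(s), seq(0, 400, by = 1), p)
    expect_true(all(sol[, 2:11] > -1e-7))
    expect_true(all(sol[, 7:10] < 1 + 1e-7))
  }
})

test_that("state and parameter validation reject bad values", {
  expect_error(cdk_state(mpf = -1), "negative")
  expect_error(cdk_state(wee1 = 1.5), "fraction")
  expect_error(cdk_state(mass = 0), "mass")
  expect_error(mcn_parameters(theta_s = 0.5), "theta_s")
  expect_error(mcn_parameters(k_wee = -1), "negative")
  expect_error(mcn_parameters(bogus = 1), "unknown")
  expect_warning(validate_parameters(mcn_parameters(k_ass = 50)),
                 "10%")
})
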