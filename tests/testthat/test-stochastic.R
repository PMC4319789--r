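test_that("reaction drift reproduces the deterministic right-hand side", {
  # the core stochastic correctness check: summing state-change vectors
  # weighted by propensities, divided by system volume, must equal the
  # ODE species derivatives at matching concentrations, for every
  # genotype preset
  p <- mcn_parameters()
  omega <- 1000
  for (preset in c("mcn", "mcn-drum1", "mcn-dwee1dmik1", "mcn-af",
                   "fusion-ccp1", "af-ccp1", "af-ccp2", "af-drum1")) {
    pg <- apply_genotype(p, preset)
    rx <- build_reactions(pg, omega = omega)
    for (s in random_states(12, seed = 5)) {
      counts <- round(unclass(s)[1:9] * omega)
      conc <- unname(counts / omega)
      drift <- rx$drift(counts, s[["mass"]])
      sc <- cdk_state(conc[1], conc[2], conc[3], conc[4], conc[5],
                      min(conc[6], 1), min(conc[7], 1), min(conc[8], 1),
                      min(conc[9], 1), s[["mass"]])
      dy <- cdk_rhs(sc, pg)
      expect_equal(unname(drift), unname(dy[1:9]), tolerance = 1e-10)
    }
  }
})

test_that("only synthesis reactions fire from the empty state", {
  rx <- build_reactions(mcn_parameters(), omega = 1000)
  a <- rx$propensity(rep(0, 9), mass = 1)
  pos <- names(a)[a > 0]
  expect_setequal(pos, c("fp_synthesis", "rum1_synthesis",
                         "wee1_activation"))
})

test_that("with all rates zero the state is frozen", {
  p <- mcn_parameters()
  for (nm in setdiff(names(unclass(p)),
                     c("mu", "theta_s", "theta_m", "alpha", "j_gk",
                       "wee1_total")))
    p[[nm]] <- 0
  p$theta_s <- 0.01; p$theta_m <- 0.2; p$j_gk <- 0.01; p$mu <- 0.005
  p <- do.call(mcn_parameters, unclass(p))
  run <- ssa_lineage(p, config = stochastic_config(seed = 2, omega = 500),
                     t_end = 50)
  expect_equal(run$nsteps, 0)
  expect_true(all(apply(run$counts, 2, function(x) length(unique(x))) == 1))
})

test_that("identical config and seed reproduce the run bit-for-bit", {
  p <- mcn_parameters()
  cfg <- stochastic_config(omega = 300, seed = 42)
  r1 <- ssa_lineage(p, config = cfg, t_end = 300)
  r2 <- ssa_lineage(p, config = cfg, t_end = 300)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$divisions, r2$divisions)
  expect_gt(r1$nsteps, 1000)
})

test_that("per-birth parameter draws have the uniform-noise moments", {
  p <- mcn_parameters()
  cfg0 <- stochastic_config(sigma_smpf = 0, sigma_srum1 = 0)
  expect_identical(unclass(draw_birth_parameters(p, cfg0)), unclass(p))
  cfg <- stochastic_config(sigma_smpf = 0.1, sigma_srum1 = 0.25)
  draws <- withr::with_seed(1, replicate(1e5, {
    d <- draw_birth_parameters(p, cfg)
    c(d$k_smpf, d$v_srum1)
  }))
  # mean = base; variance = (sigma * base)^2 / 3 for uniform on [-1, 1]
  se <- 0.1 * 0.05 / sqrt(3) / sqrt(1e5)
  expect_lt(abs(mean(draws[1, ]) - 0.05), 3 * se)
  expect_equal(var(draws[1, ]), (0.1 * 0.05)^2 / 3, tolerance = 0.05)
  expect_equal(var(draws[2, ]), (0.25 * p$v_srum1)^2 / 3, tolerance = 0.05)
})

test_that("large-omega noise-free lineages converge to the ODE cycle", {
  p <- mcn_parameters()
  # oracle: the ODE division-mass sequence from the same initial state
  det <- cached_cycle("mcn")
  det_masses <- det$divisions$mass
  cfg <- stochastic_config(omega = 1e5, sigma_smpf = 0, sigma_srum1 = 0,
                           seed = 11, binomial_partition = FALSE)
  run <- ssa_lineage(p, config = cfg, t_end = 800, max_divisions = 5)
  div <- run$divisions
  expect_gte(nrow(div), 4)
  periods <- diff(div$time)
  expect_equal(mean(periods[-1]), log(2) / p$mu, tolerance = 0.02)
  k <- seq_len(min(nrow(div), length(det_masses)))
  expect_equal(div$mass_before[k], det_masses[k], tolerance = 0.02)
})

test_that("division-size variance shrinks with system size", {
  p <- mcn_parameters()
  masses <- lapply(c(300, 3000), function(om) {
    cfg <- stochastic_config(omega = om, sigma_smpf = 0, sigma_srum1 = 0,
                             seed = 7)
    run <- ssa_lineage(p, config = cfg, t_end = 4500, max_divisions = 30)
    run$divisions$mass_before[-(1:3)]
  })
  expect_gt(sd(masses[[1]]), sd(masses[[2]]))
})

test_that("population statistics summarise division sizes", {
  x <- c(rep(1, 10), rep(1.2, 10))
  st <- population_statistics(x, bin_width = 0.1)
  expect_equal(st$n, 20)
  expect_equal(st$mean, 1.1)
  expect_true(st$low_confidence)
  expect_equal(sum(st$histogram$proportion), 1)
  z <- population_statistics(rep(1, 60))
  expect_equal(z$sd, 0)
  expect_false(z$low_confidence)
})

test_that("the outcome census applies the shared viability rules", {
  div <- data.frame(relicensing_min = c(0, 10, 10, 10),
                    s_entry_min = c(NA, 5, 5, NA),
                    m_entry_min = c(3, 90, 15, 40))
  cen <- catastrophe_census(div)
  expect_equal(unname(cen$counts["NO_RELICENSING"]), 1L)
  expect_equal(unname(cen$counts["VIABLE"]), 1L)
  expect_equal(unname(cen$counts["SHORT_S_TO_M"]), 2L)
})
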