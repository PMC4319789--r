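test_that("without synthesis the species-free state is a stable equilibrium", {
  # no fusion-protein or Rum1 synthesis: all five molecular species decay
  # to zero while the modification modules settle at their zero-activity
  # fixed points (Wee1 fully active, the rest off)
  p <- mcn_parameters(k_smpf = 0, v_srum1 = 0, k_25b = 0)
  eqs <- find_steady_states(0.5, p, n_starts = 6)
  conc <- vapply(eqs, function(e) sum(e$state[1:5]), numeric(1))
  expect_true(any(conc < 1e-8))
  e0 <- eqs[[which.min(conc)]]
  expect_identical(e0$stability, "STABLE")
  expect_equal(unname(e0$state[["wee1"]]), 1, tolerance = 1e-6)
})

test_that("finite-difference Jacobian matches a Richardson oracle", {
  p <- mcn_parameters()
  fr <- mcncycle:::.frozen_rhs
  for (s in random_states(6, seed = 21)) {
    x <- unclass(s)[1:9]
    m <- s[["mass"]]
    J <- mcncycle:::.frozen_jacobian(x, m, p)
    # independent oracle: 4th-order Richardson extrapolated differences
    J2 <- matrix(0, 9, 9)
    for (i in 1:9) {
      h <- 1e-4 * max(abs(x[i]), 1e-3)
      xp1 <- x; xp1[i] <- x[i] + h
      xm1 <- x; xm1[i] <- x[i] - h
      xp2 <- x; xp2[i] <- x[i] + 2 * h
      xm2 <- x; xm2[i] <- x[i] - 2 * h
      J2[, i] <- (8 * (fr(xp1, m, p) - fr(xm1, m, p)) -
                    (fr(xp2, m, p) - fr(xm2, m, p))) / (12 * h)
    }
    expect_equal(J, J2, tolerance = 1e-5)
  }
})

test_that("equilibria are verified and labelled consistently", {
  p <- mcn_parameters()
  for (m in c(0.6, 0.9)) {
    eqs <- find_steady_states(m, p, genotype_preset("mcn-dwee1dmik1"),
                              n_starts = 8)
    expect_gte(length(eqs), 1)
    expect_true(all(vapply(eqs, function(e) e$residual,
                           numeric(1)) < 1e-9))
    # deduplication: activities pairwise distinct
    acts <- vapply(eqs, function(e) e$mpf_activity, numeric(1))
    expect_equal(length(unique(round(acts, 8))), length(acts))
  }
  # stability labels agree with the eigenvalue sign pattern
  eqs <- find_steady_states(0.9, p, n_starts = 8)
  for (e in eqs) {
    re <- Re(e$eigenvalues)
    lab <- if (all(re < -1e-8)) "STABLE" else
      if (sum(re > 1e-8) == 1) "SADDLE" else "UNSTABLE"
    expect_identical(e$stability, lab)
  }
})

test_that("stable equilibria attract perturbed trajectories (integration oracle)", {
  p <- mcn_parameters()
  for (m in c(0.5, 0.7)) {
    eqs <- find_steady_states(m, p, n_starts = 8)
    stable <- Filter(function(e) e$stability == "STABLE", eqs)
    pfro <- p
    pfro$mu <- 0
    for (e in stable) {
      y0 <- pmax(e$state * (1 + 1e-4) + 1e-6, 0)
      y0 <- c(y0, mass = m)
      sol <- mcncycle:::.integrate_span(y0, c(0, 5000, 10000), pfro)
      expect_lt(max(abs(sol[3, 2:10] - e$state)), 1e-5)
    }
  }
})

test_that("the Wee1-less branch terminates at a fold adjacent to the cycles", {
  diag <- dwee_diagram()
  upper <- diag$folds[diag$folds$side == "upper", ]
  expect_gte(nrow(upper), 1)
  main <- upper[which.max(upper$mass), ]
  # the Rum1-held branch ends at a localised fold, and sustained
  # oscillations begin right above it
  env <- diag$envelope
  onset <- min(env$mass[env$oscillatory])
  expect_lt(abs(onset - main$mass), 0.05)
  # the SNIC label agrees with the period-divergence measurement
  pdw <- apply_genotype(mcn_parameters(), "mcn-dwee1dmik1")
  per <- function(m) limit_cycle_envelope(c(m, m), pdw, mass_step = 1,
                                          t_sim = 4000)$period[1]
  p_near <- per(main$mass + 0.002)
  p_far <- per(main$mass + 0.02)
  expect_false(is.na(p_far))
  diverges <- is.na(p_near) || p_near > 2 * p_far
  expect_identical(main$type, if (diverges) "SNIC" else "SADDLE_NODE")
  # the period does grow approaching the fold
  if (!is.na(p_near)) expect_gt(p_near, p_far)
})

test_that("oscillation envelope appears only beyond the fold", {
  diag <- dwee_diagram()
  env <- diag$envelope
  fold <- max(diag$folds$mass[diag$folds$side == "upper"])
  expect_false(any(env$oscillatory[env$mass < fold - 0.02]))
  above <- env[env$oscillatory, ]
  expect_gt(nrow(above), 0)
  # the newborn cycles right above the fold reach past the mitotic
  # threshold (smaller-amplitude cycles can appear far from it)
  near <- above[above$mass < fold + 0.1, ]
  expect_true(all(near$mpf_max > mcn_parameters()$theta_m))
})

test_that("low-mass cells relax to a stable state with no oscillations", {
  p <- mcn_parameters()
  env <- limit_cycle_envelope(c(0.2, 0.2), p, mass_step = 1, t_sim = 1500)
  expect_false(env$oscillatory[1])
})

test_that("fold location is stable under mass-step refinement", {
  p <- mcn_parameters()
  g <- genotype_preset("mcn-dwee1dmik1")
  diag <- dwee_diagram()
  fold <- max(diag$folds$mass[diag$folds$side == "upper"])
  win <- c(fold - 0.08, min(fold + 0.06, 1.3))
  d1 <- trace_branches(win, 0.01, p, g, n_starts = 3)
  d2 <- trace_branches(win, 0.005, p, g, n_starts = 3)
  f1 <- max(d1$folds$mass[d1$folds$side == "upper"])
  f2 <- max(d2$folds$mass[d2$folds$side == "upper"])
  expect_lt(abs(f1 - f2), 2e-3)
})
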