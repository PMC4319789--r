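test_that("transcribed constants carry their stated values", {
  p <- mcn_parameters()
  expect_equal(p$k_smpf, 0.05)
  expect_equal(p$alpha, 0.05)
  expect_equal(p$k_irum1, 2)
  expect_equal(p$k_arum1, 35)
  expect_equal(p$k_drum1p, 250)
  expect_equal(p$k_i2rum1, 50)
  expect_equal(p$k_dx, 1)
  expect_equal(p$theta_s, 0.01)
  expect_equal(p$theta_m, 0.2)
  # binding Michaelis constant ~ 0.02 CU
  expect_equal((p$k_diss + p$k_irum1) / p$k_ass, 0.02, tolerance = 0.01)
  # balanced-growth period log(2)/mu matches the phenotype-table period
  expect_equal(log(2) / p$mu, 138.6, tolerance = 0.001)
})

test_that("parameter files round-trip in both formats", {
  p <- mcn_parameters(wee1_total = 0.7)
  fy <- tempfile(fileext = ".yaml")
  fj <- tempfile(fileext = ".json")
  write_parameters(p, fy)
  write_parameters(p, fj)
  expect_equal(unclass(read_parameters(fy)), unclass(p),
               tolerance = 1e-12)
  expect_equal(unclass(read_parameters(fj)), unclass(p),
               tolerance = 1e-12)
})

test_that("the shipped default parameter file matches the code defaults", {
  shipped <- system.file("extdata", "mcn_parameters.yaml",
                         package = "mcncycle")
  expect_true(nzchar(shipped))
  expect_equal(unclass(read_parameters(shipped)),
               unclass(mcn_parameters()), tolerance = 1e-12)
  # and default_parameter_file() regenerates it
  f <- default_parameter_file(tempfile(fileext = ".yaml"))
  expect_identical(readLines(f), readLines(shipped))
})

test_that("genotype presets map to the documented parameter changes", {
  p <- mcn_parameters()
  expect_equal(apply_genotype(p, "mcn-drum1")$v_srum1, 0)
  expect_equal(apply_genotype(p, "mcn-dwee1dmik1")$wee1_total, 0)
  expect_equal(apply_genotype(p, "mcn-af")$af, 1)
  expect_equal(apply_genotype(p, "fusion-ccp1")$ccp, 1)
  expect_equal(apply_genotype(p, "af-ccp2")$ccp, 2)
  expect_error(genotype(ccp_level = 3), "ccp_level")
  expect_error(genotype_preset("nonsense"))
})
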