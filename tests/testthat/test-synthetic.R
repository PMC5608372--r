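test_that("a noiseless sensor map inverts exactly to the device profile", {
  cal <- calibrationCurve(1000, 0.05)
  prof <- deviceProfile()
  m <- genSensorMap(prof, cal, nx = 200, ny = 3, noiseSd = 0)
  inv <- intensityToOxygen(m$intensity, cal)
  truth <- matrix(rep(deviceOxygenAt(m$x, m$height, prof), each = 3),
                  nrow = 3)
  expect_lt(max(abs(inv - truth)), 1e-12)
})

test_that("rolling-averaged inversion of a noisy map tracks the profile", {
  cal <- calibrationCurve(1000, 0.05)
  prof <- deviceProfile()
  m <- genSensorMap(prof, cal, nx = 400, ny = 1, noiseSd = 0.01, seed = 11)
  inv <- rollingAverage(intensityToOxygen(as.numeric(m$intensity), cal), 20)
  expect_lt(max(abs(inv - deviceOxygenAt(m$x, m$height, prof))), 0.3)
})

test_that("the inverted map reaches the 3% and 20% plateaus", {
  cal <- calibrationCurve(1000, 0.05)
  m <- genSensorMap(deviceProfile(), cal, nx = 600, ny = 1,
                    xRange = c(-1500, 1500), noiseSd = 0)
  inv <- intensityToOxygen(as.numeric(m$intensity), cal)
  expect_equal(inv[1], 3, tolerance = 0.01)
  expect_equal(inv[length(inv)], 20, tolerance = 0.01)
})

test_that("synthetic trajectories carry their target 10-90 duration", {
  ref <- referenceDoseResponse()
  tr <- genTrajectory(NA, ref, frameInterval = 1, targetDuration = 80)
  expect_lt(abs(migrationTime1090(tr) - 80), 0.5)
  # replicated noisy tracks recover the curve-implied duration on average;
  # the first-crossing rule pulls the 10% crossing slightly early under
  # noise, so a small upward bias (~2-3% at sigma = 0.01 EL) is expected
  target <- invertDoseResponse(ref, 10)
  d <- vapply(1:20, function(s)
    migrationTime1090(genTrajectory(10, ref, frameInterval = 3,
                                    noiseSd = 0.01, seed = s)),
    numeric(1))
  expect_lt(abs(mean(d) - target) / target, 0.05)
})

test_that("oxygen below the asymptote arrests the synthetic track", {
  ref <- referenceDoseResponse()
  tr <- genTrajectory(3, ref)
  expect_gte(max(tr@times), 500 - 3)   # watch window, whole frames
  expect_error(migrationTime1090(tr), "zero net displacement")
})

test_that("a noiseless migration dataset refits its generating curve", {
  ref <- referenceDoseResponse()
  ds <- genMigrationDataset(20, ref, c(5.5, 20), noiseSd = 0, seed = 2)
  expect_false(any(ds$censored))
  fit <- fitDoseResponse(ds)
  expect_equal(fit@a, ref@a, tolerance = 1e-4)
  expect_equal(fit@c, ref@c, tolerance = 1e-4)
  expect_equal(fit@b * exp(-fit@c * fit@d), ref@b * exp(-ref@c * ref@d),
               tolerance = 1e-4)
})

test_that("sampling below the asymptote censors every observation", {
  ref <- referenceDoseResponse()
  ds <- genMigrationDataset(25, ref, c(3, 4.9), noiseSd = 0, seed = 4)
  expect_true(all(ds$censored))
  expect_true(all(ds$t_min == 500))
})

test_that("the censoring fraction matches the sub-asymptote mass", {
  ref <- referenceDoseResponse()
  ds <- genMigrationDataset(4000, ref, c(4, 6), noiseSd = 0.5, seed = 5)
  expect_equal(mean(ds$censored), (ref@a - 4) / 2, tolerance = 0.025)
})

test_that("generation is reproducible under a fixed seed", {
  ref <- referenceDoseResponse()
  cal <- calibrationCurve(1000, 0.05)
  expect_identical(genMigrationDataset(30, ref, seed = 9),
                   genMigrationDataset(30, ref, seed = 9))
  m1 <- genSensorMap(deviceProfile(), cal, nx = 50, ny = 4, seed = 9)
  m2 <- genSensorMap(deviceProfile(), cal, nx = 50, ny = 4, seed = 9)
  expect_identical(m1, m2)
  expect_identical(genTrajectory(12, ref, noiseSd = 0.01, seed = 9),
                   genTrajectory(12, ref, noiseSd = 0.01, seed = 9))
})

test_that("stripe passages encode the curve-implied interval", {
  ref <- referenceDoseResponse()
  sp <- genStripePassages(10, ref)
  expect_equal(nrow(sp), 14L)
  expect_equal(stripeMigrationTime(sp), invertDoseResponse(ref, 10))
  # arrested regime: the 10th/11th passages never happen
  spArr <- genStripePassages(4, ref)
  expect_false(any(spArr$stripe_index >= 10))
  expect_error(stripeMigrationTime(spArr), "data error")
  # intervals grow monotonically as oxygen drops
  iv <- vapply(c(15, 10, 8, 6),
               function(o2) stripeMigrationTime(genStripePassages(o2, ref)),
               numeric(1))
  expect_true(all(diff(iv) > 0))
})
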