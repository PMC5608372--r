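test_that("forward-generated constraints recover the generating E", {
  p <- transportParams()
  prof <- deviceProfile()
  # default embryo at two permeabilities spanning the plausible range
  grid <- defaultGrid()
  for (Estar in c(1e-5, 1e-4)) {
    target <- placementRegionAverage(placement("perpendicular", "AP"),
                                     Estar, p, grid, prof)
    est <- estimatePermeability(list(equivalenceConstraint("AP", target)),
                                p, grid, prof)
    expect_lt(abs(est@EHat - Estar) / Estar, 0.05)
  }
  # a smaller embryo at low permeability
  g <- smallGrid()
  Estar <- 3e-6
  target <- placementRegionAverage(placement("perpendicular", "PA"),
                                   Estar, p, g, prof)
  est <- estimatePermeability(list(equivalenceConstraint("PA", target)),
                              p, g, prof)
  expect_lt(abs(est@EHat - Estar) / Estar, 0.05)
})

test_that("the joint objective has a unique interior minimum in log E", {
  grid <- defaultGrid()
  p <- transportParams()
  prof <- deviceProfile()
  cons <- referenceConstraints()
  obj <- vapply(10^seq(-6.5, -3.5, by = 0.5), function(E) {
    sum(vapply(cons, function(cn)
      (placementRegionAverage(cn$placement, E, p, grid, prof) -
         cn$equivalentO2)^2, numeric(1)))
  }, numeric(1))
  k <- which.min(obj)
  expect_gt(k, 1L)
  expect_lt(k, length(obj))
  # decreasing before the minimum, increasing after: single trough
  expect_true(all(diff(obj[1:k]) < 0))
  expect_true(all(diff(obj[k:length(obj)]) > 0))
})

test_that("equivalent uniform oxygen formalizes the placement matching", {
  g <- smallGrid()
  prof <- deviceProfile()
  p <- transportParams()
  # with no consumption the problem is linear: the equivalent level equals
  # the perpendicular placement's boundary-driven interior mean exactly
  p0 <- transportParams(R = 0)
  perp <- placement("perpendicular", "AP")
  avg0 <- placementRegionAverage(perp, 1e-5, p0, g, prof)
  eq0 <- findEquivalentUniformOxygen(perp, 1e-5, p0, g, prof)
  expect_equal(eq0, avg0, tolerance = 1e-3)
  # mid-AP sees more oxygen at the posterior than mid-PA at any fixed E
  eqAP <- findEquivalentUniformOxygen(placement("perpendicular", "AP"),
                                      1e-5, p, g, prof)
  eqPA <- findEquivalentUniformOxygen(placement("perpendicular", "PA"),
                                      1e-5, p, g, prof)
  expect_gt(eqAP, eqPA)
  expect_error(findEquivalentUniformOxygen(perp, -1, p, g, prof), "E must")
})

test_that("sensitivity analysis reports exact null and monotone R effects", {
  g <- smallGrid()
  cons <- list(equivalenceConstraint("AP", 7))
  base <- transportParams()
  sens <- sensitivityAnalysis(base,
                              variations = list(
                                list(param = "R", value = 0.02),
                                list(param = "R", value = 0.04)),
                              constraints = cons, grid = g)
  expect_equal(nrow(sens), 3L)
  expect_equal(sens$foldChange[2], 1)          # null variation
  expect_equal(sens$percentChange[2], 0)
  expect_gt(sens$foldChange[3], 1)             # more consumption, more E
  expect_equal(sens$EHat[1], sens$EHat[2])
})

test_that("estimates carry residual diagnostics and unit conversion", {
  g <- smallGrid()
  est <- estimatePermeability(list(equivalenceConstraint("AP", 7)),
                              grid = g)
  expect_s4_class(est, "PermeabilityEstimate")
  expect_true(all(is.finite(est@residuals)))
  expect_lt(abs(est@residuals[1]), 0.05)       # attainable target
  expect_equal(est@params@E, permeability(est))
  out <- capture.output(show(est))
  expect_true(any(grepl("cm/s", out)))
})

test_that("an unattainable constraint is reported as a bracket problem", {
  g <- smallGrid()
  # above the large-E ceiling of the mid-AP regional average (~11.6%)
  expect_warning(
    est <- estimatePermeability(list(equivalenceConstraint("AP", 15)),
                                grid = g),
    "bracket")
  expect_gt(est@EHat, 1e-4)
})
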