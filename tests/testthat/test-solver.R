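test_that("zero consumption with uniform boundary gives a uniform field", {
  g <- smallGrid()
  p <- transportParams(R = 0, E = 1e-5)
  fld <- solveSteadyState(g, p, 20)
  expect_equal(fld@conc, rep(20 * p@kConv, nVoxels(g)), tolerance = 1e-10)
  expect_true(all(fld@active))
})

test_that("1D slab with end-face exchange matches the closed form", {
  sc <- slabCase(R = 0.02, E = 1e-4, ext = 20)
  fld <- solveSteadyState(sc$grid, sc$params, sc$external)
  p <- sc$params
  h <- 50e-6                      # half-thickness (m)
  l <- 5e-6
  Cext <- sc$ext * p@kConv
  xc <- (sc$grid@centers[, 1] - 50) * 1e-6
  # membrane-limited surface value, zero-order parabolic interior
  Cs <- Cext - p@R * h / p@E
  Cth <- Cs - p@R / (2 * p@D) * (h^2 - xc^2)
  expect_lt(max(abs(fld@conc - Cth) / Cth), 0.02)
  # and the exact discrete profile: the same parabola anchored at the
  # half-cell-shifted surface (finite-volume closure)
  Cexact <- Cs + p@R / (2 * p@D) * (xc^2 - (h - l / 2)^2)
  expect_lt(max(abs(fld@conc - Cexact) / Cexact), 1e-10)
})

test_that("sparse solver agrees with a dense direct solve on a 3x3x3 block", {
  g <- voxelize(embryoGeometry(30, 30, 10, shape = "box"))
  expect_equal(nVoxels(g), 27L)
  set.seed(3)
  ext <- runif(nrow(g@boundaryFaces), 5, 20)
  p <- transportParams(D = 1e-9, R = 0.005, E = 1e-5)
  fld <- solveSteadyState(g, p, ext)
  Cd <- denseOracle(g, p, ext)
  expect_true(all(Cd > 0))          # linear regime, oracle applicable
  expect_lt(max(abs(fld@conc - Cd) / abs(Cd)), 1e-10)
})

test_that("boundary influx balances consumption at steady state", {
  g <- smallGrid()
  p <- transportParams(E = 1e-4)
  fld <- solveSteadyState(g, p, 20)
  mb <- massBalance(fld, g, p, 20)
  expect_true(all(fld@active))
  expect_equal(mb$deadCoreFlux, 0)
  expect_lt(mb$relError, 1e-6)
})

test_that("severe hypoxia produces a consistent dead core", {
  sc <- slabCase(R = 0.05, E = 1e-4, ext = 5)
  fld <- solveSteadyState(sc$grid, sc$params, sc$external)
  expect_gt(sum(!fld@active), 0)
  expect_true(all(fld@conc[!fld@active] == 0))
  expect_true(all(fld@conc >= 0))
  # dead core sits in the slab centre, away from the supplied ends
  xc <- sc$grid@centers[, 1]
  expect_true(all(abs(xc[!fld@active] - 50) < 30))
  mb <- massBalance(fld, sc$grid, sc$params, sc$external)
  expect_lt(mb$relError, 1e-6)
})

test_that("an embryo with no oxygen supply is entirely anoxic", {
  sc <- slabCase(R = 0.02, E = 1e-7, ext = 0.01)
  fld <- solveSteadyState(sc$grid, sc$params, sc$external)
  expect_true(all(fld@conc == 0))
  expect_true(all(!fld@active))
})

test_that("minimum oxygen is monotone in E and fields monotone in R", {
  g <- smallGrid()
  mins <- vapply(c(1e-6, 1e-5, 1e-4), function(E)
    min(solveSteadyState(g, transportParams(E = E), 10)@conc), numeric(1))
  expect_true(all(diff(mins) >= -1e-12))
  fields <- lapply(c(0.01, 0.02, 0.04), function(R)
    solveSteadyState(g, transportParams(R = R, E = 1e-5), 10)@conc)
  expect_true(all(fields[[2]] <= fields[[1]] + 1e-12))
  expect_true(all(fields[[3]] <= fields[[2]] + 1e-12))
})

test_that("no interior concentration exceeds the external maximum", {
  g <- smallGrid()
  prof <- deviceProfile()
  ext <- externalFieldForPlacement(placement("perpendicular", "AP"),
                                   prof, g)
  p <- transportParams(E = 1e-5)
  fld <- solveSteadyState(g, p, ext)
  expect_lte(max(fld@conc), max(ext) * p@kConv)
})

test_that("mirroring the external field mirrors the solution", {
  g <- smallGrid()
  prof <- deviceProfile()
  p <- transportParams(E = 1e-5)
  fAP <- solveSteadyState(g, p, externalFieldForPlacement(
    placement("perpendicular", "AP"), prof, g))
  fPA <- solveSteadyState(g, p, externalFieldForPlacement(
    placement("perpendicular", "PA"), prof, g))
  mir <- mirrorPermutation(g)
  expect_equal(fAP@conc, fPA@conc[mir], tolerance = 1e-10)
})

test_that("region averages reduce correctly on analytic fields", {
  g <- voxelize(embryoGeometry(200, 60, 10, shape = "box"))
  p <- transportParams(E = 1e-5)
  uni <- new("OxygenField", conc = rep(10 * p@kConv, nVoxels(g)),
             active = rep(TRUE, nVoxels(g)))
  expect_equal(regionAverage(uni, g, p, 0.3), 10)
  expect_equal(regionAverage(uni, g, p, 1), 10)
  # linear ramp: 20% at the posterior pole falling to 0 at the anterior
  pct <- 20 * (1 - g@centers[, 1] / 200)
  ramp <- new("OxygenField", conc = pct * p@kConv,
              active = rep(TRUE, nVoxels(g)))
  expect_equal(regionAverage(ramp, g, p, 0.5, "posterior"), 15)
  expect_equal(regionAverage(ramp, g, p, 0.5, "anterior"), 5)
  expect_error(regionAverage(uni, g, p, 0), "apFraction")
})

test_that("the steady state is a fixed point of the transient solver", {
  g <- voxelize(embryoGeometry(100, 50, 10, shape = "box"))
  p <- transportParams(E = 1e-5)
  ss <- solveSteadyState(g, p, 15)
  tr <- solveTransient(g, p, 15, initialField = ss, dt = 0.5, tEnd = 20)
  expect_lt(max(abs(tr$finalField@conc - ss@conc)) / max(ss@conc), 1e-8)
})

test_that("the transient solution relaxes to the steady state", {
  g <- voxelize(embryoGeometry(100, 50, 10, shape = "box"))
  p <- transportParams(E = 1e-5)
  ss <- solveSteadyState(g, p, 15)
  tr <- solveTransient(g, p, 15, initialField = NULL, dt = 1, tEnd = 400)
  expect_lt(max(abs(tr$finalField@conc - ss@conc)) / max(ss@conc), 0.01)
  expect_true(all(diff(tr$meanConc) > -1e-12))   # monotone filling
})

test_that("explicit scheme enforces its stability bound and agrees", {
  g <- voxelize(embryoGeometry(100, 50, 10, shape = "box"))
  p <- transportParams(E = 1e-5)
  # l^2/(6D) = 1e-10/6e-9 s for 10 um voxels
  expect_error(solveTransient(g, p, 15, NULL, dt = 0.05, tEnd = 1,
                              scheme = "explicit"), "dt")
  te <- solveTransient(g, p, 15, NULL, dt = 0.01, tEnd = 5,
                       scheme = "explicit")
  ti <- solveTransient(g, p, 15, NULL, dt = 0.01, tEnd = 5)
  expect_lt(max(abs(te$finalField@conc - ti$finalField@conc)) /
              max(ti$finalField@conc), 0.01)
})

test_that("halving the voxel edge barely moves the regional average", {
  g10 <- defaultGrid()
  g5 <- voxelize(embryoGeometry(voxelEdge = 5))
  p <- transportParams(E = 1e-5)
  a10 <- regionAverage(solveSteadyState(g10, p, 20), g10, p)
  a5 <- regionAverage(solveSteadyState(g5, p, 20), g5, p)
  expect_lt(abs(a10 - a5) / a5, 0.02)
  # hypoxic condition: same absolute discretization offset
  b10 <- regionAverage(solveSteadyState(g10, p, 10), g10, p)
  b5 <- regionAverage(solveSteadyState(g5, p, 10), g5, p)
  expect_lt(abs(b10 - b5), 0.15)
})
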