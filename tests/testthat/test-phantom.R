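test_that("ground truth starts empty and reaches the analytic volume", {
  spec <- testSpec(noiseSd = 0, bgNoiseSd = 0)
  expect_equal(sum(gridValues(generateGroundTruth(spec, 0))), 0)
  gt <- generateGroundTruth(spec, spec@tEnd)
  analytic <- 4 / 3 * pi * prod(spec@semiAxesMax[1]^2 * spec@semiAxesMax[2])
  expect_lt(abs(sum(gridValues(gt)) * prod(spec@gridSpacing) - analytic) /
              analytic, 0.02)
})

test_that("ground truth grows monotonically and never shrinks", {
  spec <- testSpec(noiseSd = 0)
  prev <- gridValues(generateGroundTruth(spec, 0))
  for (t in c(200, 500, 900)) {
    cur <- gridValues(generateGroundTruth(spec, t))
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("vessel phantoms exclude the tube and stay connected", {
  spec <- testSpec(vessel = list(center = c(7, 0)), noiseSd = 0)
  gt <- generateGroundTruth(spec, spec@tEnd)
  vm <- vesselMask(spec)
  expect_equal(sum(gridValues(gt) * gridValues(vm)), 0)
  lab <- labelComponents(gridValues(gt))
  expect_equal(max(lab), 1L)       # single connected component
  expect_gt(sum(gridValues(vm)), 0)
})

test_that("noise-free field thresholded at the angular threshold equals the ground truth", {
  spec <- testSpec(noiseSd = 0, bgNoiseSd = 0)
  gt <- gridValues(generateGroundTruth(spec, spec@tEnd))
  tf <- gridValues(simulateTemperatureField(spec, spec@tEnd))
  axes <- gridAxes(phantomGrid(spec))
  # per-voxel threshold from the angular interpolation the simulator uses
  d <- dim(gt)
  th <- ThermoRecon:::thresholdAtAngle(
    spec, as.vector(ifelse(
      outer(axes$x, axes$y, function(x, y) sqrt(x^2 + y^2)) < 1e-12, 0,
      outer(axes$x, axes$y, function(x, y) atan2(y, x) * 180 / pi) %% 360)))
  mask <- array(as.numeric(tf >= array(th, dim = d)), dim = d)
  expect_lt(mean(mask != gt), 1e-3)  # agreement up to voxelization
  # far field decays to the baseline temperature
  expect_equal(tf[1, 1, 1], spec@baselineTemp, tolerance = 0.1)
})

test_that("the simulator is deterministic in the seed and only in the seed", {
  s1 <- testSpec(seed = 5); s2 <- testSpec(seed = 5); s3 <- testSpec(seed = 6)
  t1 <- sampleSliceSeries(s1, c(450, 900))
  t2 <- sampleSliceSeries(s2, c(450, 900))
  t3 <- sampleSliceSeries(s3, c(450, 900))
  expect_identical(lapply(t1@slices, function(s) s@pixels),
                   lapply(t2@slices, function(s) s@pixels))
  expect_false(identical(t1@slices[[1]]@pixels, t3@slices[[1]]@pixels))
  f1 <- simulateTemperatureField(s1, 900)
  f2 <- simulateTemperatureField(s2, 900)
  expect_identical(gridValues(f1), gridValues(f2))
})

test_that("slice sampling covers the fan uniformly and matches the field", {
  spec <- testSpec(noiseSd = 0, bgNoiseSd = 0)
  series <- sampleSliceSeries(spec, 900)
  expect_equal(sort(unique(sliceAngles(series))), seq(0, 157.5, by = 22.5))
  s <- series@slices[[which(sliceAngles(series) == 45)]]
  px <- cbind(c(10, 24, 30), c(5, 24, 40))
  w <- sliceToWorld(s, px, phantomAxis(spec))
  expect_equal(as.vector(s@pixels[px]),
               as.vector(ThermoRecon:::temperatureAt(spec, 900, w)),
               tolerance = 1e-12)
})

test_that("scheduled outlier slices inflate the thresholded area beyond the flagging rule", {
  spec <- testSpec(semiAxesMax = c(6, 12),
                   outlierSchedule = data.frame(orientation = 2L,
                                                timestamp = 900))
  series <- sampleSliceSeries(spec, c(810, 900))
  a2 <- orientationAngles(8)[2]
  sl <- Filter(function(s) abs(s@angle - a2) < 1e-9, series@slices)
  areas <- vapply(sl[order(vapply(sl, function(s) s@timestamp, numeric(1)))],
    function(s) {
      roi <- sliceRoiMask(s, spec@roiSizeMm, spec@centerZ)
      sum(thresholdSlice(s@pixels, 55, roi)) * prod(s@spacing)
    }, numeric(1))
  expect_true(isOutlierGrowth(relativeGrowth(areas[2], areas[1])))
})

test_that("resliced ground truth is symmetric and matches the conic section", {
  spec <- testSpec(noiseSd = 0, thresholds = rep(55, 8))
  gt <- generateGroundTruth(spec, 900)
  ax <- phantomAxis(spec)
  series <- resliceGroundTruth(gt, ax, 8)
  areas <- vapply(series@slices, function(s) sum(s@pixels), numeric(1))
  # axially-symmetric gt: all 8 slices carry the same area (within voxel
  # rounding along different rays)
  expect_lt(diff(range(areas)) / mean(areas), 0.03)
  # per-slice mask area vs the analytic ellipse cross-section pi * a * c
  analytic <- pi * spec@semiAxesMax[1] * spec@semiAxesMax[2]
  expect_lt(abs(mean(areas) - analytic) / analytic, 0.05)
  # full-grid gt -> all-ones slices
  full <- withGridValues(gt, array(1, dim = gridDim(gt)))
  expect_true(all(vapply(resliceGroundTruth(full, ax, 8)@slices,
                         function(s) all(s@pixels == 1), logical(1))))
})

test_that("phantom threshold envelope and validity are enforced", {
  expect_error(phantomSpec(thresholds = rep(72, 8)), "50")
  expect_error(phantomSpec(semiAxesMax = c(-1, 5)), "positive")
  spec <- testSpec()
  expect_true(all(spec@thresholds >= 50 & spec@thresholds <= 60))
})
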