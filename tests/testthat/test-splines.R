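test_that("contour extraction keeps the radial maximum per half-plane and row", {
  ax <- applicatorAxis(0, 0)
  m <- matrix(0, 21, 3)
  m[11:21, 2] <- 1          # run u in [0, 10] on one row
  m[1:6, 2] <- 1            # run u in [-10, -5] on the opposite half-plane
  s <- orientedSlice(m, angle = 0, spacing = c(1, 1))
  cont <- contourVoxels(list(s), ax)
  expect_equal(nrow(cont), 2)
  plus <- cont[cont$halfPlane == 0, ]
  minus <- cont[cont$halfPlane == 180, ]
  expect_equal(plus$r, 10)              # max of the run
  expect_equal(minus$r, 10)
  expect_equal(minus$x, -10)
  # circle mask: 16 contour points all near the radius
  spec <- testSpec(noiseSd = 0, thresholds = rep(55, 8))
  gt <- generateGroundTruth(spec, 900)
  series <- resliceGroundTruth(gt, phantomAxis(spec), 8)
  cc <- contourVoxels(series@slices, phantomAxis(spec))
  zmid <- unique(cc$z)[which.min(abs(unique(cc$z)))]
  mid <- cc[abs(cc$z - zmid) < 1e-9, ]
  expect_equal(nrow(mid), 16)           # one per half-plane
  expect_lte(max(abs(mid$r - spec@semiAxesMax[1])), 1.5)  # within a pixel
                                        # of the radius on oblique rays
})

test_that("cylindrical ordering sorts by angle with the documented tie-break", {
  ax <- applicatorAxis(0, 0)
  pts <- rbind(c(cos(200 * pi / 180), sin(200 * pi / 180)) * 5,
               c(cos(10 * pi / 180), sin(10 * pi / 180)) * 3,
               c(0, 4))
  got <- cylindricalOrder(pts, ax)
  expect_false(got$degenerate)
  th <- toCylindrical(cbind(got$points, 0), ax)$theta
  expect_equal(th, sort(th))            # (10, 90, 200)
  expect_identical(cylindricalOrder(got$points, ax)$points, got$points)
  # equal angles: inner radius first, checked against every permutation
  tied <- rbind(c(5, 0), c(8, 0), c(0, 3))
  for (perm in list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    o <- cylindricalOrder(tied[perm, ], ax)$points
    expect_equal(o[1, ], c(5, 0))
    expect_equal(o[2, ], c(8, 0))
  }
  expect_true(cylindricalOrder(rbind(c(1, 1)), ax)$degenerate)
})

test_that("the closed spline interpolates its vertices and closes the seam", {
  sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)) * 5
  cc <- closedSpline(sq[c(4, 2, 1, 3)[order(c(4, 2, 1, 3))], ])
  cc <- closedSpline(sq[c(1, 2, 3, 4), ])
  at <- contourPoint(cc, (0:3) / 4)
  expect_lt(max(abs(at - sq)), 1e-9)
  seam <- contourPoint(cc, c(0, 1 - 1e-12))
  expect_lt(max(abs(seam[1, ] - seam[2, ])), 1e-8)
  # 16 points on a circle: radial deviation below 2% of the radius
  th <- 2 * pi * (0:15) / 16
  circ <- closedSpline(cbind(cos(th), sin(th)) * 10)
  rs <- sqrt(rowSums(circ@polygon^2))
  expect_lt(max(abs(rs - 10)) / 10, 0.02)
  # coincident consecutive vertices are merged before fitting
  dup <- rbind(c(1, 0), c(1, 0), c(0, 1), c(-1, -1))
  expect_equal(nrow(closedSpline(dup)@vertices), 3)
  expect_error(closedSpline(rbind(c(0, 0), c(1, 1))), ">= 3")
})

test_that("de Boor evaluation equals naive basis summation", {
  set.seed(9)
  for (m in c(5, 16)) {
    V <- cbind(rnorm(m), rnorm(m))
    cc <- closedSpline(V)
    ts <- runif(100, 3, 3 + m - 1e-9)
    got <- deBoorEval(ts, cc@knots, cc@controls, 3L)
    want <- naiveBSplineEval(ts, cc@knots, cc@controls, 3L)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("winding numbers agree with ray casting off the boundary", {
  set.seed(23)
  checked <- 0L
  while (checked < 200) {
    poly <- randomSimplePolygon(sample(8:20, 1))
    p <- cbind(runif(20, -11, 11), runif(20, -11, 11))
    # discard points hugging an edge so both rules are well-defined
    dmin <- vapply(seq_len(nrow(p)), function(i)
      min(vapply(seq_len(nrow(poly)), function(e) {
        a <- poly[e, ]; b <- poly[(e %% nrow(poly)) + 1, ]
        ab <- b - a; t <- max(0, min(1, sum((p[i, ] - a) * ab) / sum(ab^2)))
        sqrt(sum((a + t * ab - p[i, ])^2))
      }, numeric(1))), numeric(1))
    keep <- dmin > 1e-3
    if (!any(keep)) next
    expect_identical(windingInside(p[keep, , drop = FALSE], poly),
                     rayCastInside(p[keep, , drop = FALSE], poly))
    checked <- checked + sum(keep)
  }
  # squares: center in, far point out, edge point in (inclusive boundary)
  sqr <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_true(windingInside(c(1, 1), sqr))
  expect_false(windingInside(c(9, 9), sqr))
  expect_true(windingInside(c(1, 0), sqr))
})

test_that("spline reconstruction matches cross-sections and dips into dents", {
  spec <- testSpec(noiseSd = 0, thresholds = rep(55, 8))
  gt <- generateGroundTruth(spec, 900)
  ax <- phantomAxis(spec); grid <- phantomGrid(spec)
  rec <- splineReconstruct(resliceGroundTruth(gt, ax, 8)@slices, ax, grid)
  v <- gridValues(rec$volume); g <- gridValues(gt)
  k <- gridDim(grid)[3] %/% 2
  inner <- abs(gridAxes(grid)$z) < 0.7 * spec@semiAxesMax[2]
  for (kk in which(inner))
    expect_gt(diceCoefficient(v[, , kk], g[, , kk]), 0.9)
  # concave behaviour: a vessel dent stays dented (less vessel intrusion
  # than the convex per-slice ellipse)
  vs <- testSpec(gridShape = c(64L, 64L, 64L), semiAxesMax = c(14, 26),
                 vessel = list(center = c(9, 0)), noiseSd = 0)
  vgt <- generateGroundTruth(vs, 900)
  vax <- phantomAxis(vs); vgrid <- phantomGrid(vs)
  masks <- resliceGroundTruth(vgt, vax, 8)@slices
  sp <- gridValues(splineReconstruct(masks, vax, vgrid)$volume)
  mv <- gridValues(mveeReconstruct(masks, vax, vgrid)$volume)
  tube <- gridValues(vesselMask(vs))
  expect_lt(sum(sp * tube), sum(mv * tube))
})

test_that("fill is invariant to the cyclic start and equivariant to mirroring", {
  spec <- testSpec(noiseSd = 0)
  gt <- generateGroundTruth(spec, 900)
  ax <- phantomAxis(spec)
  masks <- resliceGroundTruth(gt, ax, 8)@slices
  grid <- phantomGrid(spec)
  a <- gridValues(splineReconstruct(masks, ax, grid)$volume)
  b <- gridValues(splineReconstruct(rev(masks), ax, grid)$volume)
  expect_identical(a, b)
  # mirroring x -> -x maps plane angle a to 180 - a with u unchanged; the
  # 0-degree plane maps onto itself with u negated
  mirrored <- lapply(masks, function(s) {
    if (s@angle == 0) {
      p <- s@pixels[nrow(s@pixels):1, , drop = FALSE]
      orientedSlice(p, angle = 0, spacing = s@spacing,
                    thickness = s@thickness, timestamp = s@timestamp,
                    origin = c(-(nrow(p) - 1 - floor(nrow(p) / 2)) *
                                 s@spacing[1], s@origin[2]))
    } else {
      orientedSlice(s@pixels, angle = 180 - s@angle, spacing = s@spacing,
                    thickness = s@thickness, timestamp = s@timestamp,
                    origin = s@origin)
    }
  })
  m <- gridValues(splineReconstruct(mirrored, ax, grid)$volume)
  d1 <- dim(a)[1]
  flipped <- a[d1:1, , , drop = FALSE]
  expect_gt(sum(m * flipped) * 2 / (sum(m) + sum(flipped)), 0.98)
})

test_that("a single inflated half-plane only has local impact", {
  spec <- testSpec(noiseSd = 0, thresholds = rep(55, 8))
  gt <- generateGroundTruth(spec, 900)
  ax <- phantomAxis(spec); grid <- phantomGrid(spec)
  masks <- resliceGroundTruth(gt, ax, 8)@slices
  bumped <- masks
  s <- bumped[[3]]
  px <- s@pixels
  mid <- which(abs(s@origin[2] + (seq_len(ncol(px)) - 1) - 0) < 1)
  px[, mid] <- pmax(px[, mid],
                    as.numeric(seq_len(nrow(px)) >= floor(nrow(px) / 2) + 1 &
                               seq_len(nrow(px)) <= floor(nrow(px) / 2) + 19))
  bumped[[3]] <- orientedSlice(px, angle = s@angle, spacing = s@spacing,
                               thickness = s@thickness,
                               timestamp = s@timestamp, origin = s@origin)
  a <- gridValues(splineReconstruct(masks, ax, grid)$volume)
  b <- gridValues(splineReconstruct(bumped, ax, grid)$volume)
  changedLevels <- which(vapply(seq_len(dim(a)[3]),
                                function(k) any(a[, , k] != b[, , k]),
                                logical(1)))
  touched <- which(vapply(seq_len(ncol(px)), function(j)
    any(px[, j] != s@pixels[, j]), logical(1)))
  expect_true(all(changedLevels %in% (min(touched) - 2):(max(touched) + 2)))
  # angular locality on an affected level: the opposite sector is unchanged
  k <- changedLevels[1]
  xs <- gridAxes(grid)$x
  left <- xs < -2
  expect_identical(a[left, , k], b[left, , k])
})
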