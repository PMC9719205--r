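canonical_frame <- function() {
  tips <- rbind(MB = c(0.8, -1, 0), DB = c(-0.8, -1, 0),
                ML = c(0.8, 1, 0), DL = c(-0.8, 1, 0))
  quad <- rbind(tips, c(3, 0, 0), c(-3, 1, 0), c(2, -1, 0))
  lm <- LandmarkSet(tips, rbind(c(0, 0, -12)), Mm = c(1, 0, -0.5),
                    Md = c(-1, 0, -0.5), quadrantTips = quad)
  buildFrame(lm)
}

test_that("centroid is the per-coordinate arithmetic mean", {
  expect_equal(centroid(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(centroid(rbind(c(3, -1, 2))), c(3, -1, 2))
  set.seed(17)
  pts <- matrix(rnorm(300), ncol = 3)
  brute <- c(sum(pts[, 1]), sum(pts[, 2]), sum(pts[, 3])) / nrow(pts)
  expect_equal(centroid(pts), brute, tolerance = 1e-12)
  expect_error(centroid(matrix(numeric(0), ncol = 3)), "empty")
})

test_that("the tooth axis is the unit CA-to-CC direction", {
  expect_equal(toothAxis(c(0, 0, 0), c(0, 0, 3)), c(0, 0, 1))
  expect_equal(toothAxis(c(0, 0, 0), c(1, 1, 0)),
               c(sqrt(2) / 2, sqrt(2) / 2, 0))
  expect_error(toothAxis(c(1, 1, 1), c(1, 1, 1)), "axis")
  # a tipped phantom's axis is the rotated baseline axis
  ph <- generatePhantom(coarse_spec(), GroundTruthMotion(blTipDeg = 5),
                        voxelize = FALSE)
  axO <- toothAxis(centroid(apexes(ph$baseline$landmarks)),
                   centroid(cuspTips(ph$baseline$landmarks)))
  axN <- toothAxis(centroid(apexes(ph$followup$landmarks)),
                   centroid(cuspTips(ph$followup$landmarks)))
  want <- as.vector(oracle_rotation(c(-1, 0, 0), 5) %*% axO)
  expect_lt(max(abs(axN - want)), 1e-9)
})

test_that("pure occlusal translation gives equal per-cusp displacement", {
  f <- canonical_frame()
  lmTo <- canonical_landmarks()
  shift <- RigidTransform(diag(3), 0.5 * frameAxes(f)[, "z"])
  oe <- overeruption(lmTo, applyTransform(lmTo, shift), f)
  expect_equal(oe$oeMeanMm, 0.5, tolerance = 1e-12)
  expect_equal(oe$oeMaxMm, 0.5, tolerance = 1e-12)
  expect_equal(unname(oe$perCuspDzMm), rep(0.5, 4), tolerance = 1e-12)
  zero <- overeruption(lmTo, lmTo, f)
  expect_equal(zero$oeMeanMm, 0)
  expect_equal(zero$oeMaxMm, 0)
})

test_that("rotation about the mesio-distal axis produces the oracle's per-cusp pattern", {
  f <- canonical_frame()
  lmTo <- canonical_landmarks()
  CA <- centroid(apexes(lmTo))
  th <- 6
  # lingual tip: rotate about -x through CA (sends +z toward +y)
  R <- oracle_rotation(c(-1, 0, 0), th)
  tipsN <- oracle_rotate_about(cuspTips(lmTo), CA, c(-1, 0, 0), th)
  rownames(tipsN) <- rownames(cuspTips(lmTo))
  lmTn <- LandmarkSet(tipsN,
                      oracle_rotate_about(apexes(lmTo), CA, c(-1, 0, 0), th),
                      applyTransform(marginalCrestMidpoints(lmTo)$Mm,
                                     RigidTransform(R, CA - R %*% CA)),
                      applyTransform(marginalCrestMidpoints(lmTo)$Md,
                                     RigidTransform(R, CA - R %*% CA)),
                      quadrantTips(lmTo))
  oe <- overeruption(lmTo, lmTn, f)
  wantDz <- tipsN[, 3] - cuspTips(lmTo)[, 3]
  expect_equal(oe$perCuspDzMm, wantDz, tolerance = 1e-9)
  expect_equal(oe$oeMeanMm, mean(wantDz), tolerance = 1e-9)
  expect_equal(oe$oeMaxMm, max(wantDz), tolerance = 1e-9)
  # lingual tipping lifts the buccal side least; with a lingual rotation
  # the largest dz sits on a lingual cusp here, as the oracle predicts
  expect_identical(oe$oeMaxCusp, names(which.max(wantDz)))
  expect_error(overeruption(lmTo, canonical_landmarks(), canonical_frame()),
               NA)
  bad <- cuspTips(lmTn)
  rownames(bad) <- c("MB", "DB", "ML", "XX")
  lmBad <- LandmarkSet(bad, apexes(lmTn), c(4.2, 0, -1.5), c(-4.2, 0, -1.5),
                       quadrantTips(lmTn))
  expect_error(overeruption(lmTo, lmBad, f), "labels")
})

test_that("tipping angles follow the arcsin convention with signs", {
  f <- canonical_frame()
  z <- frameAxes(f)[, "z"]
  y <- frameAxes(f)[, "y"]
  a0 <- tippingAngles(z, f)
  expect_equal(a0$bltDeg, 0, tolerance = 1e-12)
  expect_equal(a0$mdtDeg, 0, tolerance = 1e-12)
  ax <- (z + tan(10 * pi / 180) * y)
  ax <- ax / sqrt(sum(ax^2))
  a10 <- tippingAngles(ax, f)
  expect_equal(a10$bltDeg, 10, tolerance = 1e-9)
  expect_equal(a10$mdtDeg, 0, tolerance = 1e-9)
  expect_equal(tippingAngles(y, f)$bltDeg, 90, tolerance = 1e-9)
})

test_that("tipping change recovers pure phantom rotations exactly", {
  f0 <- function(ph) buildFrame(ph$baseline$landmarks)
  phB <- generatePhantom(coarse_spec(), GroundTruthMotion(blTipDeg = -5),
                         voxelize = FALSE)
  tc <- tippingChange(phB$baseline$landmarks, phB$followup$landmarks,
                      f0(phB))
  expect_equal(tc$cBLTDeg, -5, tolerance = 1e-6)
  expect_equal(tc$cMDTDeg, 0, tolerance = 1e-6)
  phM <- generatePhantom(coarse_spec(), GroundTruthMotion(mdTipDeg = 3),
                         voxelize = FALSE)
  tcM <- tippingChange(phM$baseline$landmarks, phM$followup$landmarks,
                       f0(phM))
  expect_equal(tcM$cMDTDeg, 3, tolerance = 1e-6)
  expect_equal(tcM$cBLTDeg, 0, tolerance = 1e-6)
  same <- tippingChange(phB$baseline$landmarks, phB$baseline$landmarks,
                        f0(phB))
  expect_equal(same$cBLTDeg, 0)
  expect_equal(same$cMDTDeg, 0)
})

test_that("in-plane translation yields zero overeruption and zero tipping change", {
  f <- canonical_frame()
  lmTo <- canonical_landmarks()
  set.seed(18)
  for (i in 1:10) {
    d <- rnorm(2)
    shift <- RigidTransform(diag(3), d[1] * frameAxes(f)[, "x"] +
                              d[2] * frameAxes(f)[, "y"])
    lmTn <- applyTransform(lmTo, shift)
    dr <- measureDrift(lmTo, lmTn, f)
    expect_equal(dr@oeMeanMm, 0, tolerance = 1e-9)
    expect_equal(dr@oeMaxMm, 0, tolerance = 1e-9)
    expect_equal(dr@cBLTDeg, 0, tolerance = 1e-9)
    expect_equal(dr@cMDTDeg, 0, tolerance = 1e-9)
  }
})

test_that("the maximum per-cusp displacement dominates the mean", {
  set.seed(19)
  for (i in 1:50) {
    mo <- GroundTruthMotion(eruptionMm = runif(1, -2, 2),
                            blTipDeg = runif(1, -10, 10),
                            mdTipDeg = runif(1, -10, 10))
    m <- measurePhantomExact(coarse_spec(), mo)
    expect_gte(m$drift@oeMaxMm, m$drift@oeMeanMm - 1e-12)
    expect_equal(m$drift@oeMaxMm, max(m$drift@perCuspDzMm))
  }
})

test_that("cusp attribution ties break in the fixed label order", {
  dz <- c(DL = 1, ML = 1, MB = 0)
  expect_identical(molarDrift:::.argmax_cusp(dz), "ML")
})
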