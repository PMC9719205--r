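make_labelled_model <- function() {
  set.seed(21)
  n <- 900
  V <- matrix(rnorm(3 * n), ncol = 3)
  struct <- rep(c("neighbor_crown", "bone", "target_crown"), each = n / 3)
  zone <- rep("none", n)
  zone[struct == "bone"][1:60] <- "crest"
  zone[struct == "bone"][61:100] <- "window"
  zone[struct == "bone"][101:120] <- "boundary"
  SurfaceModel(V, matrix(c(1L, 2L, 3L), 1), struct, zone)
}

test_that("alignment-point selection follows the mask and never includes the target", {
  m <- make_labelled_model()
  full <- selectAlignmentPoints(m, AlignmentMask())
  # label bookkeeping: crowns + bone minus crest/window/boundary
  expect_identical(nrow(full), 300L + 300L - 120L)
  crownsOnly <- selectAlignmentPoints(
    m, AlignmentMask(includeStableBone = FALSE))
  expect_identical(nrow(crownsOnly), 300L)
  expect_identical(crownsOnly,
                   vertices(m)[vertexLabels(m)$structure == "neighbor_crown", ])
  noExcl <- selectAlignmentPoints(
    m, AlignmentMask(excludeCrestZone = FALSE, excludeWindowZone = FALSE))
  expect_identical(nrow(noExcl), 600L - 20L)  # boundary always dropped
  # an all-exclude mask cannot be constructed
  expect_error(AlignmentMask(includeCrownsExceptTarget = FALSE,
                             includeStableBone = FALSE), "include")
  # under-constrained selections error
  small <- SurfaceModel(matrix(rnorm(30), ncol = 3), matrix(1:3, 1),
                        "neighbor_crown")
  expect_error(selectAlignmentPoints(small, AlignmentMask()), "100")
})

test_that("icp recovers identity on identical clouds", {
  set.seed(2)
  pts <- matrix(rnorm(600), ncol = 3)
  r <- icpAlign(pts, pts)
  expect_true(r$converged)
  expect_lt(r$finalRmsMm, 1e-12)
  expect_lt(rotationAngleDeg(rotation(r$transform)), 1e-6)
  expect_lt(max(abs(translation(r$transform))), 1e-9)
})

test_that("icp recovers a known rigid transform from identity init", {
  set.seed(5)
  fixed <- matrix(rnorm(3000), ncol = 3) * c(10, 5, 3)
  truth <- RigidTransform(oracle_rotation(c(0.3, 0.8, 0.5), 5), c(1, 0, -0.4))
  moving <- applyTransform(fixed, truth)
  r <- icpAlign(moving, fixed)
  err <- transformError(r$transform, invertTransform(truth))
  expect_lt(err$rotationDeg, 0.01)
  expect_lt(err$translationMm, 0.01)
  # RMS is monotone non-increasing over iterations
  expect_true(all(diff(r$rms) <= 1e-12))
})

test_that("icp tolerates noise on a fraction of the moving points", {
  set.seed(6)
  fixed <- matrix(rnorm(6000), ncol = 3) * c(10, 5, 3)
  truth <- RigidTransform(oracle_rotation(c(1, 0.2, -0.4), 5), c(1, 0.5, 0))
  moving <- applyTransform(fixed, truth)
  noisy <- sample(nrow(moving), nrow(moving) %/% 10)
  moving[noisy, ] <- moving[noisy, ] + rnorm(3 * length(noisy), 0, 0.05)
  r <- icpAlign(moving, fixed)
  err <- transformError(r$transform, invertTransform(truth))
  expect_lt(err$rotationDeg, 0.1)
  expect_lt(err$translationMm, 0.05)
})

test_that("returned transforms always satisfy the rigidity invariants", {
  set.seed(8)
  for (i in 1:5) {
    fixed <- matrix(rnorm(900), ncol = 3) * runif(3, 1, 8)
    truth <- RigidTransform(random_rotation(), rnorm(3))
    r <- icpAlign(applyTransform(fixed, truth), fixed, preAlign = TRUE)
    R <- rotation(r$transform)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("applyTransform preserves distances and composes with its inverse", {
  set.seed(9)
  pts <- matrix(rnorm(300), ncol = 3)
  t1 <- RigidTransform(random_rotation(), rnorm(3))
  expect_identical(applyTransform(pts, RigidTransform()), pts)
  moved <- applyTransform(pts, t1)
  d0 <- dist(pts)
  expect_lt(max(abs(dist(moved) - d0)), 1e-9)
  back <- applyTransform(moved, invertTransform(t1))
  expect_lt(max(abs(back - pts)), 1e-9)
  # a known rotation of a unit vector matches the hand-computed product
  R <- oracle_rotation(c(0, 0, 1), 90)
  t2 <- RigidTransform(R, c(0, 0, 0))
  expect_equal(applyTransform(c(1, 0, 0), t2), c(0, 1, 0), tolerance = 1e-12)
})

test_that("grid nearest neighbour agrees with brute force", {
  set.seed(10)
  q <- matrix(rnorm(900), ncol = 3) * 4
  ref <- matrix(rnorm(4500), ncol = 3) * 4
  for (cell in c(0.4, 1, 3)) {
    a <- molarDrift:::.nn_grid(q, ref, cell)
    b <- molarDrift:::.nn_brute(q, ref)
    expect_identical(a$index, b$index)
    expect_equal(a$distance, b$distance, tolerance = 1e-12)
  }
})

test_that("masked registration is shielded from a grossly displaced target tooth", {
  spec <- coarse_spec(spacing = 0.4, seed = 31)
  ph <- generatePhantom(spec, GroundTruthMotion())
  thr <- defaultThresholds(spec, ph$baseline$windowCenterMm, 4.5)
  seg <- segmentVolume(ph$baseline$volume, thr, ph$baseline$labelVolume)
  mTo <- labelPhantomZones(seg$model, ph, "To", 2, 4.5)
  jaw <- RigidTransform(oracle_rotation(c(0.4, 1, 0.2), 3), c(1.5, -1, 0.8))
  # follow-up stand-in: jaw-move the whole model, then push the target
  # tooth a further 2 mm occlusally
  mTn <- applyTransform(mTo, jaw)
  isTarget <- vertexLabels(mTn)$structure %in% c("target_crown", "target_root")
  mTn@vertices[isTarget, 3] <- mTn@vertices[isTarget, 3] + 2
  fixed <- selectAlignmentPoints(mTo, AlignmentMask())
  moving <- selectAlignmentPoints(mTn, AlignmentMask())
  r <- icpAlign(moving, fixed, preAlign = TRUE)
  err <- transformError(r$transform, invertTransform(jaw))
  expect_lt(err$rotationDeg, 0.02)
  expect_lt(err$translationMm, 0.02)
})
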