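# builds a small analytic test volume: a sphere of one intensity inside a
# background, with a cubic block of a second intensity beside it
analytic_volume <- function(spacing = 0.5) {
  x <- seq(-10, 10, by = spacing)
  g <- as.matrix(expand.grid(x = x, y = x, z = x, KEEP.OUT.ATTRS = FALSE))
  inSphere <- rowSums(sweep(g, 2, c(-4, 0, 0))^2) <= 3^2
  inCube <- abs(g[, 1] - 5) <= 2.5 & abs(g[, 2]) <= 2.5 & abs(g[, 3]) <= 2.5
  vals <- ifelse(inSphere, 900, ifelse(inCube, 1600, 0))
  list(vol = VoxelVolume(array(vals, dim = rep(length(x), 3)), spacing,
                         rep(-10, 3)),
       nSphere = sum(inSphere), nCube = sum(inCube & !inSphere))
}

test_that("threshold masks are half-open and match analytic voxel counts", {
  av <- analytic_volume()
  expect_true(all(thresholdMask(av$vol, c(-1, 2000))))
  expect_warning(m0 <- thresholdMask(av$vol, c(5000, 6000)), "no voxels")
  expect_false(any(m0))
  mSphere <- thresholdMask(av$vol, c(450, 1250))
  mCube <- thresholdMask(av$vol, c(1250, 2000))
  expect_identical(sum(mSphere), av$nSphere)
  expect_identical(sum(mCube), av$nCube)
  # half-open: intensity exactly at hi is excluded, at lo included
  v <- VoxelVolume(array(c(1, 2, 3, 4, 2, 2, 2, 2), c(2, 2, 2)), 1)
  expect_identical(sum(thresholdMask(v, c(2, 3))), 5L)
})

test_that("mask union is an elementwise OR, idempotent, and monotone", {
  set.seed(4)
  a <- array(runif(27) > 0.5, c(3, 3, 3))
  b <- array(runif(27) > 0.5, c(3, 3, 3))
  expect_identical(unionMasks(list(a, !a)), array(TRUE, c(3, 3, 3)))
  expect_identical(unionMasks(list(a, a)), a)
  expect_identical(unionMasks(list(a, b)), a | b)
  expect_true(all(unionMasks(list(a, b)) >= a))
  expect_gte(sum(unionMasks(list(a, b))), max(sum(a), sum(b)))
  expect_error(unionMasks(list(a, array(TRUE, c(2, 3, 3)))), "dimensions")
})

test_that("the apical window clears an analytic sphere of voxels and honours edge cases", {
  av <- analytic_volume()
  mask <- thresholdMask(av$vol, c(-1, 2000))
  cfg0 <- ThresholdConfig(c(0, 1), c(1, 2), c(2, 3), c(0, 0, 0), 0)
  expect_identical(openApicalWindow(mask, av$vol, cfg0), mask)
  ctr <- c(-4, 0, 0); r <- 3
  cfg <- ThresholdConfig(c(0, 1), c(1, 2), c(2, 3), ctr, r)
  opened <- openApicalWindow(mask, av$vol, cfg)
  cleared <- sum(mask) - sum(opened)
  # oracle: count voxel centres inside the sphere
  x <- seq(-10, 10, by = 0.5)
  g <- as.matrix(expand.grid(x, x, x))
  expect_identical(cleared, sum(rowSums(sweep(g, 2, ctr)^2) <= r^2))
  cfgFar <- ThresholdConfig(c(0, 1), c(1, 2), c(2, 3), c(100, 0, 0), 2)
  expect_warning(far <- openApicalWindow(mask, av$vol, cfgFar), "outside")
  expect_identical(far, mask)
})

test_that("extracted meshes reproduce analytic areas and volumes", {
  sp <- 0.25
  x <- seq(-5, 5, by = sp)
  g <- as.matrix(expand.grid(x = x, y = x, z = x, KEEP.OUT.ATTRS = FALSE))
  vol <- VoxelVolume(array(0, rep(length(x), 3)), sp, rep(-5, 3))
  s <- 4  # nominal cube side
  cube <- array(abs(g[, 1]) <= s / 2 & abs(g[, 2]) <= s / 2 &
                  abs(g[, 3]) <= s / 2, rep(length(x), 3))
  mCube <- extractMesh(cube, vol)
  # the iso-0.5 surface of a binary mask sits half a voxel outside the
  # outermost inside centres: the effective side is nVoxels * spacing
  sEff <- sum(abs(x) <= s / 2) * sp
  expect_equal(meshArea(mCube), 6 * sEff^2, tolerance = 0.05)
  r <- 3.5
  sph <- array(rowSums(g^2) <= r^2, rep(length(x), 3))
  mSph <- extractMesh(sph, vol)
  expect_equal(meshVolume(mSph), 4 / 3 * pi * r^3, tolerance = 0.05)
  expect_error(extractMesh(array(FALSE, c(2, 2, 2)), vol), "empty")
})

test_that("mesh-enclosed volume matches voxel count times voxel volume for convex solids", {
  sp <- 0.25
  x <- seq(-5, 5, by = sp)
  g <- as.matrix(expand.grid(x = x, y = x, z = x, KEEP.OUT.ATTRS = FALSE))
  vol <- VoxelVolume(array(0, rep(length(x), 3)), sp, rep(-5, 3))
  sph <- array(rowSums(g^2) <= 3^2, rep(length(x), 3))
  m <- extractMesh(sph, vol)
  expect_equal(meshVolume(m), sum(sph) * sp^3, tolerance = 0.05)
})

test_that("crown-mask mesh vertices stay inside the dilated analytic crown", {
  spec <- coarse_spec(spacing = 0.4)
  ph <- generatePhantom(spec, GroundTruthMotion())
  crownMask <- ph$baseline$labelVolume == structureCodes()[["target_crown"]]
  m <- extractMesh(crownMask, ph$baseline$volume, ph$baseline$labelVolume)
  V <- vertices(m)
  diag_ <- sqrt(3) * 0.4
  g <- ph$geometry
  ctr <- g$crownCenter
  half <- g$crownHalf + diag_
  inCrown <- (abs(V[, 1] - ctr[1]) / half[1])^g$crownExp +
    (abs(V[, 2] - ctr[2]) / half[2])^g$crownExp +
    (abs(V[, 3] - ctr[3]) / half[3])^g$crownExp <= 1
  inCusp <- rep(FALSE, nrow(V))
  for (i in seq_len(nrow(g$cusps))) {
    cc <- c(g$cusps$dx[i], g$cusps$dy[i], g$cusps$cz[i])
    inCusp <- inCusp |
      rowSums(sweep(V, 2, cc)^2) <= (g$cuspR + diag_)^2
  }
  expect_true(all(inCrown | inCusp))
  # vertices carry the structure label of the voxels that produced them
  expect_setequal(unique(vertexLabels(m)$structure), "target_crown")
})

test_that("phantom masks agree with the generator's analytic voxel classification", {
  spec <- coarse_spec(spacing = 0.5)
  ph <- generatePhantom(spec, GroundTruthMotion())
  cfg <- defaultThresholds(spec)
  crown <- thresholdMask(ph$baseline$volume, cfg@crownRange)
  root <- thresholdMask(ph$baseline$volume, cfg@rootRange)
  bone <- thresholdMask(ph$baseline$volume, cfg@boneRange)
  lab <- ph$baseline$labelVolume
  codes <- structureCodes()
  expect_identical(sum(crown), sum(lab %in% codes[c("target_crown",
                                                    "neighbor_crown")]))
  expect_identical(sum(root), sum(lab == codes[["target_root"]]))
  expect_identical(sum(bone), sum(lab == codes[["bone"]]))
})
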