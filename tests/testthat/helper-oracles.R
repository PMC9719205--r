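# Independent oracles used across the suite. These deliberately re-derive
# the reference quantities with different code paths (direct formulas,
# brute-force searches) so implementation and check never share code.

# Rodrigues rotation, written out long-hand
oracle_rotation <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  c_ <- cos(th); s_ <- sin(th); v <- 1 - c_
  matrix(c(
    c_ + ux * ux * v, ux * uy * v - uz * s_, ux * uz * v + uy * s_,
    uy * ux * v + uz * s_, c_ + uy * uy * v, uy * uz * v - ux * s_,
    uz * ux * v - uy * s_, uz * uy * v + ux * s_, c_ + uz * uz * v),
    3, 3, byrow = TRUE)
}

oracle_rotate_about <- function(points, center, axis, angle_deg) {
  R <- oracle_rotation(axis, angle_deg)
  t(apply(points, 1, function(p) as.vector(R %*% (p - center)) + center))
}

random_rotation <- function() {
  ax <- rnorm(3)
  oracle_rotation(ax, runif(1, 0, 180))
}

# small landmark set in a canonical pose, optionally randomized a little
canonical_landmarks <- function(wiggle = 0) {
  tips <- rbind(MB = c(2.1, -2.7, 0.1), DB = c(-2.2, -2.9, -0.1),
                ML = c(2.0, 2.8, 0.05), DL = c(-2.1, 2.75, 0))
  apexes <- rbind(c(1.5, -1, -15), c(-1.5, -1, -15.2), c(0, 2, -14.8))
  quad <- rbind(tips,
                cbind(9.5 + c(2, -2, 2, -2), c(-2.5, -2.5, 2.5, 2.5), 0),
                cbind(-9.5 + c(2, -2, 2, -2), c(-2.5, -2.5, 2.5, 2.5), 0))
  if (wiggle > 0) {
    tips <- tips + matrix(rnorm(length(tips), 0, wiggle), nrow(tips))
    apexes <- apexes + matrix(rnorm(length(apexes), 0, wiggle), nrow(apexes))
    quad <- quad + matrix(rnorm(length(quad), 0, wiggle), nrow(quad))
  }
  LandmarkSet(tips, apexes, Mm = c(4.2, 0, -1.5), Md = c(-4.2, 0, -1.5),
              quadrantTips = quad)
}

# fast phantom spec for unit tests (coarse voxels keep volumes small)
coarse_spec <- function(spacing = 0.5, ...) {
  PhantomSpec(voxelSpacingMm = spacing, ...)
}

# two-way mixed single-measure consistency ICC straight from the textbook
# mean squares, computed via stats::aov as an independent route
oracle_icc31 <- function(pairs) {
  n <- nrow(pairs)
  y <- c(pairs[, 1], pairs[, 2])
  subj <- factor(rep(seq_len(n), 2))
  occ <- factor(rep(1:2, each = n))
  tab <- anova(aov(y ~ occ + subj))
  msr <- tab["subj", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse)
}
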