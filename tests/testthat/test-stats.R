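test_that("one-sample t works from summaries and matches t.test on raw data", {
  # reference cohort summary row: mean 0.432, sd 0.432, n 68
  r <- oneSampleT(mean = 0.432, sd = 0.432, n = 68)
  expect_equal(r$t, 0.432 / (0.432 / sqrt(68)), tolerance = 1e-12)
  expect_equal(r$t, 8.25, tolerance = 0.01)
  expect_lt(r$p, 0.001)
  expect_identical(r$df, 67)
  # mean at the reference gives t = 0, p = 1
  r0 <- oneSampleT(mean = 5, sd = 2, n = 10, mu0 = 5)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # raw-data route against stats::t.test and the textbook formula
  set.seed(23)
  x <- rnorm(40, 0.3, 1.1)
  mine <- oneSampleT(x)
  ref <- t.test(x, mu = 0)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$t, (mean(x) - 0) / (sd(x) / sqrt(length(x))),
               tolerance = 1e-12)
  expect_error(oneSampleT(mean = 1, sd = 0, n = 5), "variance")
  expect_error(oneSampleT(rep(1, 1)), "n >= 2")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  toy <- data.frame(
    molar_type = rep(c("upper-first", "upper-second", "lower-first",
                       "lower-second"), each = 4),
    OE_mean = c(0.2, 0.3, 0.25, 0.35, 0.5, 0.6, 0.55, 0.45,
                0.1, 0.15, 0.2, 0.05, 0.4, 0.35, 0.3, 0.45))
  r <- oneWayAnova(toy, "OE_mean")
  y <- toy$OE_mean
  g <- toy$molar_type
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  Fhand <- (ssb / 3) / (ssw / 12)
  expect_equal(r$F, Fhand, tolerance = 1e-12)
  expect_identical(c(r$df1, r$df2), c(3L, 12L))
  expect_equal(r$p, pf(Fhand, 3, 12, lower.tail = FALSE), tolerance = 1e-12)
  # degenerate: identical constants in every group
  flat <- data.frame(molar_type = rep(c("a", "b"), each = 3),
                     OE_mean = rep(1, 6))
  expect_error(oneWayAnova(flat, "OE_mean"), "variance")
  # groups with < 2 observations are excluded with a warning
  toy2 <- rbind(toy, data.frame(molar_type = "extra", OE_mean = 1))
  expect_warning(r2 <- oneWayAnova(toy2, "OE_mean"), "excluding")
  expect_identical(r2$df1, 3L)
})

test_that("two equal-mean groups give a small F on average", {
  set.seed(24)
  Fs <- replicate(200, {
    d <- data.frame(molar_type = rep(c("a", "b"), each = 10),
                    OE_mean = rnorm(20))
    oneWayAnova(d, "OE_mean")$F
  })
  expect_equal(mean(Fs), 1, tolerance = 0.35)  # E[F(1, 18)] = 18/16
})

test_that("Dahlberg error reproduces its closed forms", {
  expect_equal(dahlbergError(cbind(1:5, 1:5)), 0)
  expect_equal(dahlbergError(rbind(c(0.2, 0.1), c(0.0, 0.1))),
               sqrt(0.02 / 4), tolerance = 1e-12)
  expect_equal(dahlbergError(rbind(c(1, 0))), sqrt(1 / 2), tolerance = 1e-12)
  expect_error(dahlbergError(matrix(numeric(0), ncol = 2)), "pair")
})

test_that("the two-way mixed consistency ICC matches the independent route", {
  pairs <- cbind(c(10, 12, 9, 14, 11), c(10.2, 11.8, 9.3, 13.9, 11.4))
  expect_equal(iccTwoWayMixed(pairs), oracle_icc31(pairs), tolerance = 1e-9)
  # perfect agreement
  expect_equal(iccTwoWayMixed(cbind(1:6, 1:6)), 1)
  # a constant offset is absorbed by the occasion effect
  expect_equal(iccTwoWayMixed(cbind(1:6, 1:6 + 3)), 1, tolerance = 1e-12)
  set.seed(25)
  p2 <- cbind(rnorm(12, 5, 2), rnorm(12, 5, 2))
  expect_equal(iccTwoWayMixed(p2), oracle_icc31(p2), tolerance = 1e-9)
  expect_error(iccTwoWayMixed(cbind(rep(1, 4), rep(1, 4))), "variance")
})

test_that("Dahlberg shrinks to zero and ICC climbs to one as session noise vanishes", {
  set.seed(26)
  truth <- rnorm(40, 0.5, 0.45)
  noise <- c(0.4, 0.2, 0.1, 0.05, 0.02, 0.005)
  stats_ <- vapply(noise, function(s) {
    p <- cbind(truth + rnorm(40, 0, s), truth + rnorm(40, 0, s))
    c(dahlbergError(p), iccTwoWayMixed(p))
  }, numeric(2))
  expect_true(all(diff(stats_[1, ]) < 0))
  expect_true(all(diff(stats_[2, ]) > 0))
  expect_lt(stats_[1, length(noise)], 0.01)
  expect_gt(stats_[2, length(noise)], 0.999)
})

test_that("null ANOVA F statistics follow the F distribution", {
  set.seed(27)
  Fs <- replicate(500, {
    d <- data.frame(molar_type = rep(c("a", "b", "c", "d"), each = 8),
                    OE_mean = rnorm(32))
    oneWayAnova(d, "OE_mean")$F
  })
  ks <- suppressWarnings(ks.test(Fs, pf, df1 = 3, df2 = 28))
  expect_gt(ks$p.value, 0.01)
})

test_that("descriptive tables reproduce printed-style percentages", {
  cohort <- data.frame(
    sex = rep(c("male", "female"), c(48, 20)),
    arch = rep(c("maxilla", "mandible"), c(47, 21)),
    molar_type = rep(c("upper-first", "upper-second", "lower-first",
                       "lower-second"), c(14, 33, 7, 14)),
    age_years = rep(48.8, 68), t_n_months = rep(9.1, 68))
  d <- descriptiveTable(cohort)
  catg <- d$categorical
  expect_identical(d$n, 68L)
  expect_equal(catg$percent[catg$level == "male"], 70.59)
  expect_equal(catg$percent[catg$level == "maxilla"], 69.12)
  expect_equal(catg$percent[catg$level == "upper-second"], 48.53)
  # per-variable percentages total 100 up to rounding
  for (v in unique(catg$variable)) {
    expect_equal(sum(catg$percent_raw[catg$variable == v]), 100,
                 tolerance = 1e-9)
    expect_equal(sum(catg$percent[catg$variable == v]), 100,
                 tolerance = 0.05)
  }
  one <- descriptiveTable(data.frame(sex = rep("male", 5)))
  expect_equal(one$categorical$percent, 100)
})

test_that("cohort validation enforces the schema and arch consistency", {
  ok <- simulateCohort(nTeeth = 8, seed = 2)
  expect_true(validateCohortTable(ok))
  bad <- ok
  bad$molar_type[1] <- if (bad$arch[1] == "maxilla") "lower-first"
                       else "upper-first"
  expect_error(validateCohortTable(bad), "inconsistent")
  bad2 <- ok
  bad2$t_n_months[2] <- -1
  expect_error(validateCohortTable(bad2), "positive")
})
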