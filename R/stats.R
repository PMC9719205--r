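# Study statistics layer ------------------------------------------------
#
# The cohort analyses (one-sample t against zero, one-way ANOVA across
# molar types, descriptive frequency tables) and the method-error
# protocol (Dahlberg combined error, two-way mixed single-measure
# consistency ICC).

#' One-sample t-test against a reference value
#'
#' Works either from raw values or from summary statistics (mean, SD, n),
#' so printed table rows can be checked directly:
#' t = (mean - mu0) / (sd / sqrt(n)) with df = n - 1 and a two-sided p.
#'
#' @param values numeric vector of raw observations, or NULL when
#'   summaries are given.
#' @param mean,sd,n summary statistics (ignored when \code{values} is
#'   supplied).
#' @param mu0 reference value (zero for a no-movement null).
#' @return A list with \code{t}, \code{df}, \code{p}, \code{mean},
#'   \code{sd}, \code{n}.
#' @export
oneSampleT <- function(values = NULL, mean = NULL, sd = NULL, n = NULL,
                       mu0 = 0) {
  if (!is.null(values)) {
    values <- values[!is.na(values)]
    n <- length(values)
    mean <- base::mean(values)
    sd <- stats::sd(values)
  }
  if (is.null(mean) || is.null(sd) || is.null(n))
    stop("supply either raw values or mean, sd and n")
  if (n < 2L) stop("need n >= 2")
  if (sd <= 0) stop("zero variance; t statistic undefined")
  t <- (mean - mu0) / (sd / sqrt(n))
  df <- n - 1
  list(t = t, df = df, p = 2 * pt(-abs(t), df), mean = mean, sd = sd, n = n)
}

#' One-way ANOVA of an outcome across molar types
#'
#' Standard between/within decomposition via \code{stats::aov}. Groups
#' with fewer than 2 observations are excluded with a warning; a decision
#' flag is reported at alpha = 0.05.
#'
#' @param cohort cohort data.frame.
#' @param outcome name of the outcome column (e.g. "OE_mean").
#' @param group name of the grouping column (default "molar_type").
#' @param alpha significance level for the decision flag.
#' @return A list with \code{F}, \code{df1}, \code{df2}, \code{p},
#'   \code{significant}, \code{groups}.
#' @export
oneWayAnova <- function(cohort, outcome, group = "molar_type",
                        alpha = 0.05) {
  y <- cohort[[outcome]]
  gfull <- as.character(cohort[[group]])
  ok <- !is.na(y) & !is.na(gfull)
  y <- y[ok]
  gfull <- gfull[ok]
  sizes <- table(gfull)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding groups with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(gfull %in% small)
    y <- y[keep]
    gfull <- gfull[keep]
  }
  if (length(unique(gfull)) < 2L)
    stop("need at least 2 groups with >= 2 observations")
  wvar <- tapply(y, gfull, stats::var)
  if (all(wvar <= 1e-12 * max(1, abs(y))^2))
    stop("zero within-group variance; F undefined")
  fit <- aov(y ~ factor(gfull))
  tab <- anova(fit)
  msw <- tab[["Mean Sq"]][2]
  list(F = tab[["F value"]][1], df1 = tab[["Df"]][1], df2 = tab[["Df"]][2],
       p = tab[["Pr(>F)"]][1],
       significant = tab[["Pr(>F)"]][1] < alpha,
       groups = names(table(gfull)))
}

#' Dahlberg combined method error
#'
#' \code{sqrt(sum(d_i^2) / (2 n))} over n duplicate-measurement pairs,
#' in the units of the measurement — the classical combined error of
#' landmark location plus measuring procedure.
#'
#' @param pairs n x 2 matrix or data.frame of duplicate measurements.
#' @return The method error (same units as the input).
#' @export
dahlbergError <- function(pairs) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  if (nrow(pairs) < 1L) stop("need at least one pair")
  d <- pairs[, 1] - pairs[, 2]
  sqrt(sum(d^2) / (2 * nrow(pairs)))
}

#' Two-way mixed, single-measure, consistency ICC
#'
#' ICC(3,1) from the two-way ANOVA decomposition with subjects as random
#' rows and the two measurement occasions as fixed columns:
#' (MS_rows - MS_error) / (MS_rows + (k - 1) MS_error). Consistency form:
#' a constant offset between occasions is absorbed by the occasion effect
#' and does not reduce the coefficient.
#'
#' @param pairs n x 2 matrix or data.frame (n >= 3 subjects, 2 occasions).
#' @return The intraclass correlation coefficient (<= 1).
#' @export
iccTwoWayMixed <- function(pairs) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  n <- nrow(pairs)
  if (n < 3L) stop("need >= 3 subjects")
  k <- 2L
  grand <- mean(pairs)
  rowm <- rowMeans(pairs)
  colm <- colMeans(pairs)
  ssRows <- k * sum((rowm - grand)^2)
  ssCols <- n * sum((colm - grand)^2)
  ssTot <- sum((pairs - grand)^2)
  ssErr <- ssTot - ssRows - ssCols
  msRows <- ssRows / (n - 1)
  msErr <- ssErr / ((n - 1) * (k - 1))
  if (msRows < 1e-300) stop("zero between-subject variance; ICC undefined")
  (msRows - msErr) / (msRows + (k - 1) * msErr)
}

# round-half-up to mirror the printed-table convention (R's round() is
# round-half-even)
.round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Descriptive cohort summary
#'
#' Frequencies and percentages of tooth-level n for the categorical
#' variables (sex, arch, molar type) and mean +/- SD for the continuous
#' ones (age, unopposed time). Percentages are rounded half-up to two
#' decimals; unrounded values are kept alongside.
#'
#' @param cohort cohort data.frame with columns \code{sex}, \code{arch},
#'   \code{molar_type}, \code{age_years}, \code{t_n_months} (missing
#'   columns are skipped).
#' @return A list with \code{n}, \code{categorical} (data.frame:
#'   variable, level, count, percent, percent_raw) and \code{continuous}
#'   (data.frame: variable, mean, sd).
#' @export
descriptiveTable <- function(cohort) {
  stopifnot(nrow(cohort) >= 1L)
  n <- nrow(cohort)
  catRows <- list()
  for (v in intersect(c("sex", "arch", "molar_type"), names(cohort))) {
    tab <- table(cohort[[v]])
    catRows[[v]] <- data.frame(
      variable = v, level = names(tab), count = as.integer(tab),
      percent = .round_half_up(100 * as.integer(tab) / n, 2),
      percent_raw = 100 * as.integer(tab) / n,
      stringsAsFactors = FALSE)
  }
  contRows <- list()
  for (v in intersect(c("age_years", "t_n_months"), names(cohort))) {
    x <- cohort[[v]][!is.na(cohort[[v]])]
    contRows[[v]] <- data.frame(variable = v, mean = mean(x),
                                sd = stats::sd(x), stringsAsFactors = FALSE)
  }
  list(n = n,
       categorical = if (length(catRows)) do.call(rbind, catRows)
                     else data.frame(),
       continuous = if (length(contRows)) do.call(rbind, contRows)
                    else data.frame())
}

#' Validate a cohort table
#'
#' Checks the schema and the consistency constraints: positive unopposed
#' time and molar types consistent with the arch.
#'
#' @param cohort cohort data.frame.
#' @return Invisibly TRUE; errors describe any violation.
#' @export
validateCohortTable <- function(cohort) {
  need <- c("tooth_id", "arch", "molar_type", "t_n_months",
            "OE_mean", "OE_max", "cBLT", "cMDT")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  if (any(cohort$t_n_months <= 0, na.rm = TRUE))
    stop("t_n_months must be positive")
  up <- cohort$arch == "maxilla"
  okType <- ifelse(up, grepl("^upper-", cohort$molar_type),
                   grepl("^lower-", cohort$molar_type))
  if (!all(okType, na.rm = TRUE))
    stop("molar_type inconsistent with arch")
  invisible(TRUE)
}
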