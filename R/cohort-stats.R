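# Group assignment from sex-specific SRS-2 screening cutoffs and the
# descriptive group-comparison statistics of the cohort table.

#' SRS-2 screening cutoff for a given sex
#'
#' Sex-specific screening cutoffs on the SRS-2 T-score scale: 53.5 for
#' boys, 52.5 for girls. Half-point cutoffs make ties impossible for
#' integer scores.
#'
#' @param sex `"M"` or `"F"` (vectorized).
#' @return Numeric cutoff(s).
#' @export
srs2Cutoff <- function(sex) {
  if (!all(sex %in% c("M", "F")))
    stop(sprintf("unknown sex code(s): %s",
                 paste(unique(sex[!sex %in% c("M", "F")]), collapse = ", ")))
  ifelse(sex == "M", 53.5, 52.5)
}

#' Assign the high/low autistic-trait group from sex and SRS-2 score
#'
#' A participant is assigned to the high-trait group iff their SRS-2
#' score strictly exceeds the sex-specific screening cutoff
#' ([srs2Cutoff()]).
#'
#' @param sex `"M"` or `"F"` (vectorized).
#' @param srs2 SRS-2 T-score(s), must be >= 0.
#' @return Character vector of `"high"`/`"low"`.
#' @examples
#' assignGroup("M", 54)  # "high"
#' assignGroup("F", 52)  # "low"
#' @export
assignGroup <- function(sex, srs2) {
  if (any(is.na(srs2)) || any(srs2 < 0)) stop("srs2 scores must be >= 0")
  ifelse(srs2 > srs2Cutoff(sex), "high", "low")
}

#' Welch two-sample t statistic from group summaries
#'
#' Unequal-variance (Welch) t statistic and Welch-Satterthwaite degrees
#' of freedom computed from per-group mean, SD and n:
#' `t = (m1 - m2) / sqrt(sd1^2/n1 + sd2^2/n2)`.
#'
#' @param m1,sd1,n1 summary of group 1.
#' @param m2,sd2,n2 summary of group 2.
#' @return List with `t`, `df` (raw), `df_rounded` (nearest integer) and
#'   the two-sided `p` at the raw df.
#' @examples
#' welchTSummary(68.15, 23.68, 20, 32.06, 11.26, 113)  # t ~ 6.68, df ~ 21
#' @export
welchTSummary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("group SDs must be > 0")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, df_rounded = round(df),
       p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Standard Pearson chi-squared statistic without continuity correction:
#' `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1.
#'
#' @param a,b,c,d cell counts of the 2x2 table (rows = groups, columns =
#'   categories).
#' @return List with `chi2`, `df` (= 1) and two-sided `p`.
#' @examples
#' pearsonChi2(12, 8, 58, 55)   # sex-ratio comparison of the cohort
#' @export
pearsonChi2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be >= 0")
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero row/column margin")
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Descriptive cohort characteristics with group comparisons
#'
#' Per-group n, mean (SD) of age and SRS-2 score, male/female counts,
#' the Welch t statistics for age and SRS-2, and the Pearson chi-squared
#' statistic for the sex ratio.
#'
#' @param cohort data.frame with `sex`, `age_years`, `srs2_score`,
#'   `group`.
#' @return Nested list of group summaries and test statistics.
#' @export
cohortCharacteristics <- function(cohort) {
  stopifnot(all(c("sex", "age_years", "srs2_score", "group") %in%
                  names(cohort)))
  g <- split(cohort, factor(cohort$group, levels = c("high", "low")))
  summ <- lapply(g, function(d) list(
    n = nrow(d),
    age_mean = mean(d$age_years), age_sd = stats::sd(d$age_years),
    srs2_mean = mean(d$srs2_score), srs2_sd = stats::sd(d$srs2_score),
    male = sum(d$sex == "M"), female = sum(d$sex == "F")))
  hi <- summ$high; lo <- summ$low
  list(
    groups = summ,
    age_test = welchTSummary(hi$age_mean, hi$age_sd, hi$n,
                             lo$age_mean, lo$age_sd, lo$n),
    srs2_test = welchTSummary(hi$srs2_mean, hi$srs2_sd, hi$n,
                              lo$srs2_mean, lo$srs2_sd, lo$n),
    sex_test = pearsonChi2(hi$male, hi$female, lo$male, lo$female))
}
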