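#' Welch's two-sample t-test from summaries or raw samples
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, computed either from group summaries (n, mean, sd) or raw
#' samples. Two-sided p-value from the t distribution.
#'
#' @param a,b either numeric vectors of raw observations, or lists/named
#'   vectors with elements `n`, `mean`, `sd` (sample sd).
#' @return list with `t`, `df`, `p`, and the two group summaries.
#' @examples
#' # printed zombie-fraction summaries 20 h vs 28 h post-infection:
#' welch_t(list(n = 3, mean = 25.8, sd = 17.4),
#'         list(n = 3, mean = 30.4, sd = 24.6))
#' @export
welch_t <- function(a, b) {
  a <- as_group_summary(a); b <- as_group_summary(b)
  if (a$sd == 0 && b$sd == 0)
    stop("both group standard deviations are zero; t is degenerate")
  se2a <- a$sd^2 / a$n
  se2b <- b$sd^2 / b$n
  t <- (a$mean - b$mean) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p, a = a, b = b)
}

as_group_summary <- function(x) {
  if (is.list(x) || (!is.null(names(x)) && all(c("n", "mean", "sd") %in%
                                               names(x)))) {
    s <- list(n = as.numeric(x[["n"]]), mean = as.numeric(x[["mean"]]),
              sd = as.numeric(x[["sd"]]))
  } else {
    x <- as.numeric(x)
    if (length(x) < 2) stop("need at least 2 observations per group")
    s <- list(n = length(x), mean = mean(x), sd = sd(x))
  }
  if (s$n < 2) stop("group n must be >= 2")
  if (s$sd < 0) stop("sd must be >= 0")
  s
}

#' One-within-factor repeated-measures ANOVA
#'
#' F test for a condition effect with subject blocking, for designs where
#' the same subjects (here: sampling dates) are measured under every
#' condition (here: zombie counts detected with the SAR11-specific vs the
#' general bacterial 16S probe). `F = MS_condition / MS_(condition x
#' subject)` with `df = (k - 1, (k - 1)(n - 1))` for k conditions and n
#' subjects. Missing cells are an error; no imputation.
#'
#' @param data data.frame with columns `subject`, `condition`, `value`, or
#'   a wide numeric matrix (subjects x conditions).
#' @return list with `F`, `df1`, `df2`, `p` and the sum-of-squares table.
#' @export
rm_anova <- function(data) {
  if (is.matrix(data)) {
    m <- data
  } else {
    need <- c("subject", "condition", "value")
    if (!all(need %in% names(data)))
      stop("data must have columns subject, condition, value")
    tabn <- table(data$subject, data$condition)
    if (any(tabn != 1))
      stop("design must be complete with one value per subject x ",
           "condition cell (no imputation)")
    m <- tapply(data$value, list(data$subject, data$condition), mean)
  }
  if (anyNA(m)) stop("missing cells in the subject x condition table")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions")
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj       # condition x subject
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err == 0) {
    if (ms_cond == 0) 0 else Inf
  } else ms_cond / ms_err
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, df1 = df1, df2 = df2, p = p,
       ss = c(condition = ss_cond, subject = ss_subj, error = ss_err,
              total = ss_tot))
}

#' Shift proportions off zero for beta-distributed modeling
#'
#' The beta distribution is undefined at 0 (and 1); observed relative
#' abundances that can be exactly zero are shifted by a small constant
#' (default 0.001) before beta-regression fitting. The shift is applied
#' uniformly to all values of the response.
#'
#' @param x proportions in `[0, 1 - eps]`.
#' @param eps shift (default 0.001).
#' @return `x + eps`, guaranteed in (0, 1).
#' @export
transform_zero <- function(x, eps = 0.001) {
  if (any(x < 0)) stop("proportions must be >= 0")
  if (any(x + eps >= 1))
    stop("x + eps reaches 1; outside the beta support")
  x + eps
}
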