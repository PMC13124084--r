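#' Bartlett test of equal variances (two groups)
#'
#' Closed-form Bartlett statistic for two samples:
#' \deqn{T = \frac{(N-2)\ln s_p^2 - \sum_i (n_i-1)\ln s_i^2}{1 +
#'   \frac{1}{3}\left(\sum_i \frac{1}{n_i-1} - \frac{1}{N-2}\right)}}
#' with \eqn{s_p^2} the pooled variance, referred to a chi-square
#' distribution with 1 degree of freedom.
#'
#' @param x,y numeric samples, each with at least 2 values and positive
#'   variance.
#' @return list: \code{statistic} (T), \code{df}, \code{p.value}.
#' @export
#' @examples
#' bartlett_test(c(1, 2, 3, 4), c(10, 20, 30, 40))
bartlett_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each sample needs at least 2 values")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 || v2 == 0) {
    stop("degenerate input: a sample has zero variance")
  }
  N <- n1 + n2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (N - 2)
  num <- (N - 2) * log(sp2) - ((n1 - 1) * log(v1) + (n2 - 1) * log(v2))
  corr <- 1 + (1 / (n1 - 1) + 1 / (n2 - 1) - 1 / (N - 2)) / 3
  T <- num / corr
  list(statistic = T, df = 1L,
       p.value = stats::pchisq(T, df = 1L, lower.tail = FALSE))
}

#' Welch's unequal-variance t test
#'
#' \eqn{t = (\bar x - \bar y) / \sqrt{s_x^2/n_x + s_y^2/n_y}} with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from
#' the t reference distribution.
#'
#' @param x,y numeric samples with at least 2 values each; at least one
#'   must have positive variance.
#' @return list: \code{statistic} (t), \code{df}, \code{p.value}.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
welch_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each sample needs at least 2 values")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    stop("degenerate input: both samples have zero variance")
  }
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = t, df = df,
       p.value = 2 * stats::pt(-abs(t), df = df))
}

#' Cohen's d (pooled standard deviation)
#'
#' Standardized mean difference
#' \eqn{d = (\bar x - \bar y) / s_p} with the pooled (n-1 weighted)
#' standard deviation. The pooled-SD form is used even when variances
#' differ; see the methods vignette for the rationale.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return numeric scalar.
#' @export
cohens_d <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each sample needs at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("degenerate input: pooled standard deviation is zero")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Bonferroni adjustment of a significance level
#'
#' @param alpha nominal level, in (0, 1).
#' @param m number of comparisons, >= 1.
#' @return \code{alpha / m}.
#' @export
#' @examples
#' bonferroni_adjust(0.05, 3)
bonferroni_adjust <- function(alpha, m) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 &&
        alpha < 1)) {
    stop("alpha must be a single number in (0, 1)")
  }
  if (!(is.numeric(m) && length(m) == 1L && m >= 1)) {
    stop("m must be a single number >= 1")
  }
  alpha / m
}

#' Compare labelled cohorts of session-level prevalence values
#'
#' Runs, for every pair of cohorts, the Bartlett variance test, the Welch
#' t test, and Cohen's d, with the significance level Bonferroni-adjusted
#' by the number of pairs. The unit of analysis is the within-session (or
#' within-timeline) prevalence value, one per session or individual.
#' Output rows are ordered by sorted cohort label, so the result does not
#' depend on the input order of the samples.
#'
#' @param samples named list of numeric vectors (2 or more cohorts).
#' @param alpha nominal significance level (default 0.05).
#' @return data.frame of class \code{cds_cohort_comparison}: one row per
#'   pair with columns \code{pair}, \code{n1}, \code{n2},
#'   \code{bartlett_T}, \code{bartlett_p}, \code{welch_t},
#'   \code{welch_df}, \code{welch_p}, \code{cohen_d},
#'   \code{alpha_adjusted}, \code{bartlett_significant},
#'   \code{welch_significant}.
#' @export
compare_cohorts <- function(samples, alpha = 0.05) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("need a named list of at least 2 cohorts")
  }
  labs <- names(samples)
  if (is.null(labs) || any(!nzchar(labs)) || anyDuplicated(labs)) {
    stop("cohorts must carry unique non-empty labels")
  }
  labs <- sort(labs)
  pairs <- utils::combn(labs, 2L, simplify = FALSE)
  m <- length(pairs)
  a_adj <- bonferroni_adjust(alpha, m)
  rows <- lapply(pairs, function(pr) {
    x <- samples[[pr[1L]]]; y <- samples[[pr[2L]]]
    b <- bartlett_test(x, y)
    w <- welch_t_test(x, y)
    d <- cohens_d(x, y)
    data.frame(pair = paste(pr[1L], "vs", pr[2L]),
               n1 = length(x), n2 = length(y),
               bartlett_T = b$statistic, bartlett_p = b$p.value,
               welch_t = w$statistic, welch_df = w$df,
               welch_p = w$p.value, cohen_d = d,
               alpha_adjusted = a_adj,
               bartlett_significant = b$p.value < a_adj,
               welch_significant = w$p.value < a_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("cds_cohort_comparison", "data.frame"))
}
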