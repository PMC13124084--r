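# 0/1 indicator for a category set on an annotation table.
# categories = NULL or "overall" -> the whole lexicon (any_cds);
# otherwise the union of the named category flags.
.set_indicator <- function(ann, categories = NULL) {
  if (is.null(categories) || identical(categories, "overall")) {
    return(ann$any_cds)
  }
  codes <- distortion_types()$code
  bad <- setdiff(categories, codes)
  if (length(bad)) stop("unknown category code: ", bad[1L])
  ind <- rep(0L, nrow(ann))
  for (cc in categories) ind <- pmax(ind, ann[[cc]])
  ind
}

.set_label <- function(categories) {
  if (is.null(categories) || identical(categories, "overall")) "overall"
  else paste(categories, collapse = "+")
}

.check_role <- function(r) {
  if (!(length(r) == 1L && r %in% c("h", "o", "b"))) {
    stop("role must be one of 'h', 'o', 'b'")
  }
  r
}

#' Pooled cohort prevalence
#'
#' The fraction of messages of a given role, pooled over all sessions
#' (message-weighted, not session-averaged), that contain at least one
#' marker of the chosen category set.
#'
#' @param ann a \code{cds_annotations} data.frame.
#' @param role \code{"h"}, \code{"o"} or \code{"b"}.
#' @param categories category codes (\code{NULL} = whole lexicon).
#' @return list of class \code{cds_prevalence}: \code{scope}
#'   (\code{"cohort"}), \code{role}, \code{label}, \code{numerator},
#'   \code{denominator}, \code{prevalence}.
#' @export
cohort_prevalence <- function(ann, role, categories = NULL) {
  .check_role(role)
  sel <- ann$role == role
  n <- sum(sel)
  if (n == 0L) stop("no messages with role '", role,
                    "': cohort prevalence undefined (empty denominator)")
  k <- sum(.set_indicator(ann, categories)[sel])
  structure(list(scope = "cohort", role = role,
                 label = .set_label(categories),
                 numerator = k, denominator = n, prevalence = k / n),
            class = "cds_prevalence")
}

#' @export
print.cds_prevalence <- function(x, ...) {
  cat(sprintf("P_%s(%s) = %d/%d = %.4f  [%s scope]\n", x$label, x$role,
              x$numerator, x$denominator, x$prevalence, x$scope))
  invisible(x)
}

#' Within-session prevalence distribution
#'
#' Computes, per session, the fraction of that session's role-\code{r}
#' messages containing a marker, and summarizes the distribution across
#' sessions (mean and sample SD, n-1). Sessions with no message of the
#' role are skipped. This distribution -- one value per session or
#' timeline -- is the unit of analysis for the cohort comparison tests.
#'
#' @inheritParams cohort_prevalence
#' @return list of class \code{cds_within_session}: \code{values} (named
#'   numeric, one per contributing session), \code{weights} (message
#'   counts per session), \code{mean}, \code{sd}, \code{n_sessions}.
#' @export
within_session_prevalence <- function(ann, role, categories = NULL) {
  .check_role(role)
  sel <- ann$role == role
  if (!any(sel)) stop("no messages with role '", role,
                      "': within-session distribution is empty")
  ind <- .set_indicator(ann, categories)[sel]
  sid <- ann$session_id[sel]
  num <- tapply(ind, sid, sum)
  den <- tapply(rep(1L, length(ind)), sid, sum)
  sids <- names(den)
  vals <- as.numeric(num[sids]) / as.numeric(den[sids])
  names(vals) <- sids
  structure(list(values = vals,
                 weights = stats::setNames(as.integer(den[sids]), sids),
                 mean = mean(vals),
                 sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
                 n_sessions = length(vals),
                 role = role, label = .set_label(categories)),
            class = "cds_within_session")
}

#' Monthly prevalence series
#'
#' Bins messages by the calendar month of their session's start date
#' (messages never straddle months even when their elapsed time is
#' large), computes the pooled prevalence per month, and summarizes the
#' series by its mean level and the empirical 2.5/97.5 percentiles across
#' months. Months with no messages are omitted from the series.
#'
#' @param ann a \code{cds_annotations} data.frame.
#' @param sessions either a \code{\link{cds_corpus}} or its
#'   \code{sessions} table (columns \code{session_id},
#'   \code{start_date}).
#' @inheritParams cohort_prevalence
#' @return list of class \code{cds_monthly}: \code{series} (data.frame
#'   month, numerator, denominator, prevalence), \code{level} (mean of
#'   monthly values), \code{interval} (2.5 and 97.5 percentiles).
#' @export
monthly_prevalence <- function(ann, sessions, role, categories = NULL) {
  .check_role(role)
  if (inherits(sessions, "cds_corpus")) sessions <- sessions$sessions
  sel <- ann$role == role
  if (!any(sel)) stop("no messages with role '", role, "'")
  ind <- .set_indicator(ann, categories)[sel]
  sd_ <- sessions$start_date[match(ann$session_id[sel],
                                   sessions$session_id)]
  if (any(is.na(sd_))) stop("sessions without start_date cannot be ",
                            "binned by month")
  month <- format(sd_, "%Y-%m")
  num <- tapply(ind, month, sum)
  den <- tapply(rep(1L, length(ind)), month, sum)
  months <- sort(names(den))
  series <- data.frame(month = months,
                       numerator = as.integer(num[months]),
                       denominator = as.integer(den[months]),
                       stringsAsFactors = FALSE)
  series$prevalence <- series$numerator / series$denominator
  structure(list(series = series,
                 level = mean(series$prevalence),
                 interval = stats::quantile(series$prevalence,
                                            c(0.025, 0.975), names = TRUE),
                 role = role, label = .set_label(categories)),
            class = "cds_monthly")
}

#' Prevalence ratio between two roles
#'
#' The headline effect measure: the ratio of the pooled cohort
#' prevalences of two roles for a given category set,
#' \eqn{R_C(r_1, r_2) = P_C(r_1) / P_C(r_2)}.
#'
#' @param ann a \code{cds_annotations} data.frame.
#' @param r1,r2 roles (numerator and denominator cohorts).
#' @param categories category codes (\code{NULL} = whole lexicon).
#' @return list of class \code{cds_ratio}: \code{label}, \code{roles},
#'   \code{p1}, \code{p2}, \code{ratio}.
#' @export
prevalence_ratio <- function(ann, r1, r2, categories = NULL) {
  p1 <- cohort_prevalence(ann, r1, categories)
  p2 <- cohort_prevalence(ann, r2, categories)
  if (p2$prevalence == 0) {
    stop("denominator prevalence P_", .set_label(categories), "(", r2,
         ") is zero: ratio undefined")
  }
  structure(list(label = .set_label(categories), roles = c(r1, r2),
                 p1 = p1$prevalence, p2 = p2$prevalence,
                 ratio = p1$prevalence / p2$prevalence),
            class = "cds_ratio")
}

#' Per-category prevalence table and ranked ratios for two roles
#'
#' Convenience report: pooled prevalence of each of the 12 categories for
#' both roles, plus the prevalence ratio r1/r2 per category, ranked by
#' descending ratio (ties broken by category code). Categories where the
#' denominator cohort has zero prevalence get an NA ratio and sort last.
#'
#' @param ann a \code{cds_annotations} data.frame.
#' @param r1,r2 roles.
#' @return data.frame with columns \code{code}, \code{name}, \code{p_r1},
#'   \code{p_r2}, \code{ratio}, sorted by descending ratio.
#' @export
prevalence_by_category <- function(ann, r1 = "h", r2 = "o") {
  types <- distortion_types()
  p1 <- vapply(types$code, function(cc)
    cohort_prevalence(ann, r1, cc)$prevalence, numeric(1))
  p2 <- vapply(types$code, function(cc)
    cohort_prevalence(ann, r2, cc)$prevalence, numeric(1))
  ratio <- ifelse(p2 > 0, p1 / p2, NA_real_)
  out <- data.frame(code = types$code, name = types$name,
                    p_r1 = p1, p_r2 = p2, ratio = ratio,
                    stringsAsFactors = FALSE)
  names(out)[3:4] <- paste0("p_", c(r1, r2))
  ord <- order(-ifelse(is.na(out$ratio), -Inf, out$ratio), out$code)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
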