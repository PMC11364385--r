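# Kaplan-Meier estimation, the log-rank test, and mean-signature
# stratification of survival cohorts (overall and within subtypes).

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times, where
#' `d_i` events occur among `n_i` subjects at risk.
#'
#' @param times Non-negative follow-up times.
#' @param events Binary event indicators (1 event, 0 censored).
#' @return `data.frame` (class `km_curve`) with `time` (distinct event
#'   times, sorted), `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  ev_times <- sort(unique(times[events == 1]))
  n_risk <- vapply(ev_times, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ev_times, n_risk = n_risk, n_event = n_event, surv = surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test
#'
#' The standard observed-minus-expected statistic with hypergeometric
#' variance at each distinct event time; for `g` groups the chi-square
#' statistic uses the (g-1)-dimensional quadratic form with `df = g - 1`.
#'
#' @param times,events As in [km_estimate()].
#' @param group_labels Group membership (>= 2 non-empty groups).
#' @return List (class `logrank_result`) with `chi2`, `df`, `p`,
#'   `observed`, `expected` per group.
#' @export
logrank <- function(times, events, group_labels) {
  grp <- factor(group_labels)
  g <- nlevels(grp)
  if (g < 2L) stop("log-rank test needs >= 2 groups", call. = FALSE)
  if (any(table(grp) == 0L)) stop("every group needs >= 1 subject", call. = FALSE)
  ev_times <- sort(unique(times[events == 1]))
  O <- E <- stats::setNames(numeric(g), levels(grp))
  V <- matrix(0, g, g, dimnames = list(levels(grp), levels(grp)))
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events == 1)
    n_j <- vapply(levels(grp), function(l) sum(at_risk & grp == l), numeric(1))
    d_j <- vapply(levels(grp), function(l) sum(times == t & events == 1 & grp == l),
                  numeric(1))
    O <- O + d_j
    E <- E + d * n_j / n
    if (n > 1) {
      scale <- d * (n - d) / (n - 1)
      V <- V + scale * (diag(n_j / n, g) - tcrossprod(n_j / n))
    }
  }
  z <- (O - E)[-g]
  Vsub <- V[-g, -g, drop = FALSE]
  chi2 <- tryCatch(drop(t(z) %*% solve(Vsub, z)), error = function(e) 0)
  chi2 <- max(0, chi2)
  structure(list(chi2 = chi2, df = g - 1L,
                 p = stats::pchisq(chi2, g - 1L, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "logrank_result")
}

#' Stratify a cohort by mean signature expression
#'
#' Scores each patient by the mean expression over the signature genes
#' present in the cohort table, splits at the cohort median (ties assigned to
#' the low group), and compares the two groups with Kaplan-Meier curves and
#' the log-rank test.
#'
#' @param cohort Survival `data.frame` (`time`, `event`, gene columns).
#' @param signature Character vector of gene names (missing genes are dropped
#'   and reported).
#' @param split Only `"median"` is supported.
#' @return List with `labels` (`"high"`/`"low"` per patient), `score`,
#'   `logrank`, `curves` (named list of `km_curve`), `dropped_genes`.
#' @export
stratify_by_signature <- function(cohort, signature, split = "median") {
  split <- match.arg(split, "median")
  cohort <- validate_cohort(cohort)
  present <- intersect(signature, names(cohort))
  dropped <- setdiff(signature, present)
  if (length(present) == 0L) stop("no usable signature gene in the cohort", call. = FALSE)
  score <- rowMeans(as.matrix(cohort[, present, drop = FALSE]))
  med <- stats::median(score)
  labels <- ifelse(score > med, "high", "low")
  if (length(unique(labels)) < 2L) {
    stop("degenerate stratification: all patients fall in one group", call. = FALSE)
  }
  lr <- logrank(cohort$time, cohort$event, labels)
  curves <- lapply(stats::setNames(c("low", "high"), c("low", "high")), function(l) {
    km_estimate(cohort$time[labels == l], cohort$event[labels == l])
  })
  list(labels = labels, score = score, logrank = lr, curves = curves,
       dropped_genes = dropped)
}

#' Signature stratification within each subtype
#'
#' Runs [stratify_by_signature()] independently within every subtype with at
#' least `min_patients` patients; undersized subtypes are skipped and
#' reported.
#'
#' @param cohort Survival `data.frame` with a `subtype` column.
#' @param signature Character vector of gene names.
#' @param subtype_key Column holding the subtype label.
#' @param min_patients Minimum patients per analyzed subtype (default 20).
#' @return Named list of per-subtype stratification results, with skipped
#'   subtypes via attribute `"skipped"`. Errors if no subtype qualifies.
#' @export
subtype_stratified <- function(cohort, signature, subtype_key = "subtype",
                               min_patients = 20L) {
  cohort <- validate_cohort(cohort)
  if (!subtype_key %in% names(cohort)) {
    stop(sprintf("unknown subtype column '%s'", subtype_key), call. = FALSE)
  }
  counts <- table(cohort[[subtype_key]])
  use <- names(counts)[counts >= min_patients]
  skipped <- setdiff(names(counts), use)
  if (length(use) == 0L) stop("no subtype reaches the minimum group size", call. = FALSE)
  out <- lapply(stats::setNames(use, use), function(s) {
    stratify_by_signature(cohort[cohort[[subtype_key]] == s, , drop = FALSE], signature)
  })
  attr(out, "skipped") <- skipped
  out
}
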