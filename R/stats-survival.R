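#' Kaplan-Meier survival estimate for one cluster
#'
#' Product-limit estimator of the survivor function, with the median
#' defined as the earliest time at which the estimate drops to 0.5 or
#' below (undefined when the curve never reaches 0.5).
#'
#' @param table `data.frame(time, event, cluster)` with positive times and
#'   0/1 event indicators.
#' @param cluster Optional cluster label to subset to; default uses all
#'   rows.
#' @return List with `time`, `surv` (step-function values at the event
#'   times), `n_event`, and `median`.
#' @export
km_estimate <- function(table, cluster = NULL) {
  tab <- validate_survival(table)
  if (!is.null(cluster)) tab <- tab[tab$cluster == cluster, , drop = FALSE]
  if (nrow(tab) == 0) stopf("no rows for cluster '%s'", cluster)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = tab)
  # median rule: earliest time at which the estimate reaches 0.5 or below
  # (undefined when the curve never gets there)
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else
    NA_real_
  list(time = fit$time, surv = fit$surv, n_event = sum(tab$event),
       median = med)
}

#' Log-rank (Mantel-Cox) test between two survival clusters
#'
#' Observed-versus-expected event counts across the pooled event times,
#' chi-squared with one degree of freedom.
#'
#' @param table `data.frame(time, event, cluster)` with exactly two cluster
#'   labels, each with at least one event.
#' @return List with `chisq`, `p`, and the per-cluster observed/expected
#'   event counts.
#' @export
logrank_test <- function(table) {
  tab <- validate_survival(table)
  if (length(unique(tab$cluster)) != 2)
    stopf("log-rank test needs exactly two clusters")
  ev <- tapply(tab$event, tab$cluster, sum)
  if (any(ev == 0)) stopf("each cluster needs at least one event")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ cluster, data = tab)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd_$chisq), p = p, observed = sd_$obs,
       expected = sd_$exp)
}

validate_survival <- function(table) {
  for (col in c("time", "event", "cluster"))
    if (!col %in% names(table)) stopf("survival table needs column '%s'", col)
  if (any(table$time <= 0)) stopf("survival times must be positive")
  if (!all(table$event %in% c(0, 1)))
    stopf("event indicator must be 0 (censored) or 1 (event)")
  table
}
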