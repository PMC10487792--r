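# administrative censoring at the follow-up horizon (months)
truncate_followup <- function(time, event, horizon) {
  if (is.null(horizon) || !is.finite(horizon)) return(list(time = time, event = event))
  over <- time > horizon
  list(time = ifelse(over, horizon, time),
       event = ifelse(over, 0L, as.integer(event)))
}

#' Kaplan-Meier product-limit estimator
#'
#' Survival curve with Greenwood standard errors. Observations beyond the
#' follow-up horizon are administratively censored at the horizon (the
#' canonical pipeline compares 5-year overall survival, horizon 60 months).
#'
#' @param times Non-negative follow-up times (months).
#' @param events Event indicators (1 = event, 0 = censored).
#' @param horizon Administrative censoring time; `Inf` disables truncation.
#' @return A tibble of class `km_fit` with one row per distinct observed
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`, `std_err`
#'   (Greenwood SE of the survival probability).
#' @export
km <- function(times, events, horizon = 60) {
  assert_that(length(times) > 0, "empty group")
  assert_that(all(times >= 0), "times must be non-negative")
  assert_that(all(events %in% c(0, 1)), "events must be 0/1")
  tr <- truncate_followup(times, events, horizon)
  ord <- order(tr$time)
  time <- tr$time[ord]; event <- tr$event[ord]
  ut <- unique(time)
  n <- length(time)
  surv <- 1
  gw <- 0  # running Greenwood sum d / (n (n - d))
  rows <- purrr::map_dfr(ut, function(t) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    cns <- sum(time == t & event == 0)
    if (d > 0) {
      surv <<- surv * (1 - d / at_risk)
      # the Greenwood sum diverges when the last subject fails (S = 0)
      gw <<- gw + if (at_risk > d) d / (at_risk * (at_risk - d)) else Inf
    }
    tibble::tibble(time = t, n_risk = at_risk, n_event = d, n_censor = cns,
                   surv = surv, std_err = surv * sqrt(gw))
  })
  class(rows) <- c("km_fit", class(rows))
  attr(rows, "n") <- n
  attr(rows, "horizon") <- horizon
  rows
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square comparing the event
#' hazards of two groups across the pooled distinct event times.
#'
#' @param time_a,event_a Follow-up and event indicator for group A.
#' @param time_b,event_b Same for group B.
#' @param horizon Administrative censoring time (see [km()]).
#' @return A list with `chi2`, `p` (two-sided from the chi-square
#'   reference), `observed` and `expected` events in group A.
#' @export
logrank <- function(time_a, event_a, time_b, event_b, horizon = 60) {
  assert_that(length(time_a) > 0 && length(time_b) > 0, "empty group")
  a <- truncate_followup(time_a, event_a, horizon)
  b <- truncate_followup(time_b, event_b, horizon)
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  grp <- rep(c(1L, 0L), c(length(a$time), length(b$time)))
  if (sum(event) == 0) {
    warn("no events in either group; log-rank p set to 1")
    return(list(chi2 = 0, p = 1, observed = 0, expected = 0))
  }
  ev_times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ev_times) {
    at <- time >= t
    n_t <- sum(at)
    n1 <- sum(at & grp == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1L)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n_t
    if (n_t > 1) v <- v + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
  }
  chi2 <- if (v > 0) (o1 - e1)^2 / v else 0
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = o1, expected = e1)
}

#' Univariable Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation by Newton-Raphson for a single numeric
#' covariate (typically a 0/1 group indicator), with Breslow handling of
#' tied event times and a Wald 95% confidence interval for the hazard
#' ratio.
#'
#' @param times Follow-up times.
#' @param events Event indicators (1 = event).
#' @param x Numeric covariate; for a two-group comparison code group A as 1
#'   and B as 0, so `hr` is the hazard of A relative to B.
#' @param horizon Administrative censoring time (see [km()]).
#' @return A list of class `cox_fit` with `hr`, `ci` (length-2 vector),
#'   `log_hr`, `se`, `p` (Wald), `n`, `n_event`.
#' @export
cox_hr <- function(times, events, x, horizon = 60) {
  tr <- truncate_followup(times, events, horizon)
  time <- tr$time; event <- tr$event; x <- as.numeric(x)
  assert_that(length(unique(x)) >= 2, "covariate is constant")
  if (length(unique(x)) == 2) {
    for (lv in unique(x)) {
      assert_that(sum(event[x == lv]) >= 1,
                  "each group needs at least one event")
    }
  }
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  n <- length(time)
  ev_times <- unique(time[event == 1])
  beta <- 0
  for (iter in 1:50) {
    # risk-set sums via reverse cumulative sums over the time-sorted data
    w <- exp(beta * x)
    s0 <- rev(cumsum(rev(w)))
    s1 <- rev(cumsum(rev(w * x)))
    s2 <- rev(cumsum(rev(w * x^2)))
    first_at <- match(time, time)  # index of first obs with each time
    grad <- 0; info <- 0
    for (t in ev_times) {
      i <- first_at[match(t, time)]
      d_idx <- which(time == t & event == 1)
      d <- length(d_idx)
      mu <- s1[i] / s0[i]
      grad <- grad + sum(x[d_idx]) - d * mu
      info <- info + d * (s2[i] / s0[i] - mu^2)
    }
    if (info <= 0) abort("monotone partial likelihood (complete separation); Firth-style handling is out of scope",
                         class = "sigforge_validation_error")
    step <- grad / info
    beta <- beta + step
    if (abs(beta) > 15) {
      abort("monotone partial likelihood (complete separation); Firth-style handling is out of scope",
            class = "sigforge_validation_error")
    }
    if (abs(step) < 1e-10) break
  }
  w <- exp(beta * x)
  s0 <- rev(cumsum(rev(w)))
  s1 <- rev(cumsum(rev(w * x)))
  s2 <- rev(cumsum(rev(w * x^2)))
  info <- 0
  for (t in ev_times) {
    i <- match(t, time)
    d <- sum(time == t & event == 1)
    mu <- s1[i] / s0[i]
    info <- info + d * (s2[i] / s0[i] - mu^2)
  }
  se <- 1 / sqrt(info)
  z <- qnorm(0.975)
  structure(
    list(hr = exp(beta), ci = exp(c(beta - z * se, beta + z * se)),
         log_hr = beta, se = se,
         p = 2 * pnorm(-abs(beta / se)),
         n = n, n_event = sum(event)),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> HR = %.3f (95%% CI %.3f-%.3f), p = %.4g, %d/%d events\n",
              x$hr, x$ci[1], x$ci[2], x$p, x$n_event, x$n))
  invisible(x)
}

#' @export
#' @rdname cox_hr
#' @param x A `cox_fit`.
#' @param ... Unused.
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(term = "group", estimate = x$log_hr, std.error = x$se,
                 p.value = x$p, hr = x$hr,
                 conf.low = x$ci[1], conf.high = x$ci[2])
}

#' Compare survival across subtypes
#'
#' Joins a subtype assignment to a clinical table and runs, for every pair
#' of clusters, the log-rank test and a univariable Cox fit (first cluster
#' of the pair coded 1). Kaplan-Meier curves are fitted per cluster.
#'
#' @param subtypes A `subtype_result` (columns `sample`, `cluster`).
#' @param clinical A `clinical_table`.
#' @param horizon Administrative censoring time in months (default 60,
#'   i.e. 5-year overall survival).
#' @return A list of class `surv_comparison` with `curves` (long tibble of
#'   per-cluster [km()] output) and `comparisons` (tibble: `cluster_a`,
#'   `cluster_b`, `logrank_chi2`, `logrank_p`, `hr`, `hr_low`, `hr_high`).
#' @export
survival_compare <- function(subtypes, clinical, horizon = 60) {
  joined <- dplyr::inner_join(subtypes, clinical, by = c(sample = "sample_id"))
  assert_that(nrow(joined) > 0, "clinical table covers none of the samples")
  clusters <- sort(unique(joined$cluster))
  curves <- purrr::map_dfr(clusters, function(cl) {
    sub <- joined[joined$cluster == cl, ]
    km(sub$time_months, sub$event, horizon) |>
      dplyr::mutate(cluster = cl, .before = 1)
  })
  if (length(clusters) < 2) {
    return(structure(list(
      curves = curves,
      comparisons = tibble::tibble(cluster_a = integer(0), cluster_b = integer(0),
                                   logrank_chi2 = numeric(0), logrank_p = numeric(0),
                                   hr = numeric(0), hr_low = numeric(0),
                                   hr_high = numeric(0)),
      horizon = horizon), class = "surv_comparison"))
  }
  comparisons <- purrr::map_dfr(utils::combn(clusters, 2, simplify = FALSE),
    function(pr) {
      a <- joined[joined$cluster == pr[1], ]
      b <- joined[joined$cluster == pr[2], ]
      lr <- logrank(a$time_months, a$event, b$time_months, b$event, horizon)
      cx <- tryCatch(
        cox_hr(c(a$time_months, b$time_months), c(a$event, b$event),
               rep(c(1, 0), c(nrow(a), nrow(b))), horizon),
        sigforge_validation_error = function(e) NULL)
      tibble::tibble(
        cluster_a = pr[1], cluster_b = pr[2],
        logrank_chi2 = lr$chi2, logrank_p = lr$p,
        hr = cx$hr %||% NA_real_,
        hr_low = if (is.null(cx)) NA_real_ else cx$ci[1],
        hr_high = if (is.null(cx)) NA_real_ else cx$ci[2])
    })
  structure(list(curves = curves, comparisons = comparisons,
                 horizon = horizon),
            class = "surv_comparison")
}

#' @export
print.surv_comparison <- function(x, ...) {
  cat(sprintf("<surv_comparison> %d clusters, horizon %g months\n",
              dplyr::n_distinct(x$curves$cluster), x$horizon))
  print(x$comparisons)
  invisible(x)
}

#' @export
#' @rdname survival_compare
#' @param x A `surv_comparison`.
#' @param ... Unused.
tidy.surv_comparison <- function(x, ...) x$comparisons

#' @export
#' @rdname survival_compare
glance.surv_comparison <- function(x, ...) {
  tibble::tibble(
    n_clusters = dplyr::n_distinct(x$curves$cluster),
    n_comparisons = nrow(x$comparisons),
    horizon = x$horizon,
    min_logrank_p = min(x$comparisons$logrank_p)
  )
}
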