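#' Compute validated time-to-onset samples
#'
#' Time-to-onset (TTO) is the adverse-event date minus the therapy start
#' date, in whole days. Only day-precision (YYYYMMDD) dates are used: a case
#' whose event or start date is partial (YYYYMM / YYYY) is excluded and
#' counted, as is one with a missing or invalid date, or with an event date
#' before the therapy start (an input error). A case with several therapy
#' rows uses its earliest day-precision start date (alternatively the latest
#' start not after the event, via `start_rule`). Same-day onsets (TTO = 0)
#' are retained. When a grouping table is supplied, a case contributes its
#' TTO to every group it reports, plus the pooled `"all"` group.
#'
#' @param demo Deduplicated DEMO tibble (one row per CASEID, `EVENT_DT`).
#' @param ther THER tibble (`CASEID`, `START_DT`).
#' @param groups Optional tibble with `caseid` and `group` columns (e.g. SOC
#'   mentions); `NULL` gives the single group `"all"` over every case.
#' @param start_rule `"earliest"` (default) or `"latest_before_event"`.
#' @return A `tto_sample` tibble: one row per group with `group`, `n`,
#'   `values` (list of integer days), `n_candidates`, `n_excluded_partial`,
#'   `n_excluded_reversed`, `n_excluded_missing`.
#' @export
compute_tto <- function(demo, ther, groups = NULL,
                        start_rule = c("earliest", "latest_before_event")) {
  start_rule <- match.arg(start_rule)
  stopifnot(all(c("CASEID", "EVENT_DT") %in% names(demo)),
            all(c("CASEID", "START_DT") %in% names(ther)))
  ev <- parse_faers_date(demo$EVENT_DT)
  case_ev <- tibble::tibble(caseid = demo$CASEID,
                            event_date = ev$date,
                            event_precision = ev$precision)
  st <- parse_faers_date(ther$START_DT)
  ther_st <- tibble::tibble(caseid = ther$CASEID,
                            start_date = st$date,
                            start_precision = st$precision)
  # per-case start: day-precision rows win; record whether any partial row
  # existed so the exclusion reason is honest
  per_case_start <- ther_st |>
    dplyr::summarise(
      has_day = any(.data$start_precision == "day"),
      has_partial = any(.data$start_precision %in% c("month", "year")),
      start_min = if (any(.data$start_precision == "day")) {
        min(.data$start_date[.data$start_precision == "day"])
      } else {
        as.Date(NA)
      },
      start_all = list(.data$start_date[.data$start_precision == "day"]),
      .by = "caseid")

  per_case <- dplyr::left_join(case_ev, per_case_start, by = "caseid")
  per_case$has_day[is.na(per_case$has_day)] <- FALSE
  per_case$has_partial[is.na(per_case$has_partial)] <- FALSE

  if (start_rule == "latest_before_event") {
    per_case$start_used <- as.Date(purrr::pmap_dbl(
      list(per_case$start_all, as.numeric(per_case$event_date)),
      function(starts, evn) {
        if (is.null(starts) || !length(starts) || is.na(evn)) return(NA_real_)
        ok <- as.numeric(starts) <= evn
        if (any(ok)) max(as.numeric(starts)[ok]) else min(as.numeric(starts))
      }))
  } else {
    per_case$start_used <- per_case$start_min
  }

  status <- with(per_case, dplyr::case_when(
    event_precision %in% c("missing", "invalid") ~ "missing",
    !has_day & !has_partial ~ "missing",
    event_precision %in% c("month", "year") ~ "partial",
    !has_day & has_partial ~ "partial",
    as.numeric(event_date - start_used) < 0 ~ "reversed",
    TRUE ~ "included"))
  per_case$status <- status
  per_case$tto <- ifelse(status == "included",
                         as.integer(per_case$event_date - per_case$start_used),
                         NA_integer_)

  groups_tbl <- if (is.null(groups)) {
    tibble::tibble(caseid = per_case$caseid, group = "all")
  } else {
    stopifnot(all(c("caseid", "group") %in% names(groups)))
    dplyr::bind_rows(
      dplyr::distinct(tibble::tibble(caseid = groups$caseid, group = groups$group)),
      tibble::tibble(caseid = unique(groups$caseid), group = "all"))
  }
  joined <- dplyr::inner_join(groups_tbl, per_case, by = "caseid")
  out <- joined |>
    dplyr::summarise(
      n = sum(.data$status == "included"),
      values = list(sort(.data$tto[.data$status == "included"])),
      n_candidates = dplyr::n(),
      n_excluded_partial = sum(.data$status == "partial"),
      n_excluded_reversed = sum(.data$status == "reversed"),
      n_excluded_missing = sum(.data$status == "missing"),
      .by = "group") |>
    dplyr::arrange(.data$group != "all", .data$group)
  structure(out, class = c("tto_sample", class(out)))
}

#' Summarise a time-to-onset sample
#'
#' Produces, per group: median and quartiles (linear interpolation between
#' order statistics), minimum and maximum; 30-day (monthly) bin counts with
#' half-up percentages — 0--30, 31--60, ..., 331--360, then a single
#' over-one-year bin — and the cumulative proportion at each distinct onset
#' value. An empty group yields an explicit empty-summary row (`n = 0`, all
#' statistics `NA`) rather than an error.
#'
#' @param s A `tto_sample` from [compute_tto()], or a bare numeric vector of
#'   onset days (treated as one group `"all"`).
#' @return An object of class `tto_summary`: list with tibbles `stats`
#'   (`group`, `n`, `median`, `q1`, `q3`, `min`, `max`), `bins` (`group`,
#'   `bin`, `lower`, `upper`, `count`, `pct`) and `cumulative` (`group`,
#'   `days`, `cum_prop`).
#' @export
#' @examples
#' summarize_tto(c(1, 2, 3, 4, 5))$stats
summarize_tto <- function(s) {
  if (is.numeric(s)) {
    s <- tibble::tibble(group = "all", n = length(s), values = list(sort(s)))
  }
  stopifnot(all(c("group", "values") %in% names(s)))
  breaks_lo <- seq(0, 360, by = 30)
  stats_tbl <- purrr::map2_dfr(s$group, s$values, function(g, v) {
    if (!length(v)) {
      return(tibble::tibble(group = g, n = 0L, median = NA_real_, q1 = NA_real_,
                            q3 = NA_real_, min = NA_real_, max = NA_real_))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(group = g, n = length(v), median = q[2], q1 = q[1],
                   q3 = q[3], min = min(v), max = max(v))
  })
  bins_tbl <- purrr::map2_dfr(s$group, s$values, function(g, v) {
    lower <- c(breaks_lo[-length(breaks_lo)] + c(0, rep(1, length(breaks_lo) - 2)), 361)
    upper <- c(breaks_lo[-1], Inf)
    count <- vapply(seq_along(lower), function(i) {
      sum(v >= lower[i] & v <= upper[i])
    }, numeric(1))
    tibble::tibble(group = g,
                   bin = c(paste0(lower[-length(lower)], "-", upper[-length(upper)], " d"),
                           ">360 d"),
                   lower = lower, upper = upper, count = count,
                   pct = if (length(v)) percent(count, length(v)) else NA_real_)
  })
  cum_tbl <- purrr::map2_dfr(s$group, s$values, function(g, v) {
    if (!length(v)) return(tibble::tibble(group = g, days = numeric(), cum_prop = numeric()))
    vs <- sort(v)
    d <- unique(vs)
    tibble::tibble(group = g, days = d,
                   cum_prop = vapply(d, function(x) mean(vs <= x), numeric(1)))
  })
  structure(list(stats = stats_tbl, bins = bins_tbl, cumulative = cum_tbl),
            class = "tto_summary")
}

#' @export
print.tto_summary <- function(x, ...) {
  cat("Time-to-onset summary\n")
  print(x$stats)
  invisible(x)
}

#' Fit a two-parameter Weibull to onset times
#'
#' Maximum-likelihood fit of the Weibull scale alpha (days) and shape beta,
#' with Wald 95% confidence intervals built from the observed information on
#' (ln alpha, ln beta) and exponentiated. The Weibull density needs t > 0,
#' so same-day onsets (0) are mapped to `zero_adjust` days for the fit only;
#' the raw values are untouched elsewhere. The shape parameter classifies
#' the hazard profile: a CI entirely below 1 is an early failure type
#' (decreasing hazard), entirely above 1 wear-out, and a CI spanning 1 a
#' random failure type.
#'
#' @param values Numeric vector of onset days (>= 0), length >= 10.
#' @param zero_adjust Replacement for zero days during fitting (default 0.5).
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return An object of class `weibull_fit`: `alpha`, `alpha_lo`,
#'   `alpha_hi`, `beta`, `beta_lo`, `beta_hi`, `n`, `n_zero`,
#'   `failure_type`, `loglik`.
#' @export
#' @examples
#' set.seed(1)
#' fit_weibull(round(rweibull(200, shape = 0.5, scale = 20)))
fit_weibull <- function(values, zero_adjust = 0.5, conf_level = 0.95) {
  if (inherits(values, "tto_sample")) {
    abort_bad_arg("pass one group's values, or use fit_tto_weibull() for a tto_sample")
  }
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0)) {
    abort_bad_arg("`values` must be non-negative and non-missing")
  }
  if (length(values) < 10) abort_bad_arg("need at least 10 onset values to fit")
  t <- ifelse(values == 0, zero_adjust, values)
  if (length(unique(t)) == 1) {
    stop("all onset values identical after zero-adjustment; Weibull fit is degenerate",
         call. = FALSE)
  }
  # moment-style start on log scale
  lt <- log(t)
  shape0 <- max(1.2 / stats::sd(lt), 0.05)
  scale0 <- exp(mean(lt) + 0.5772 / shape0)
  nll <- function(par) {
    v <- -sum(suppressWarnings(
      stats::dweibull(t, shape = exp(par[2]), scale = exp(par[1]), log = TRUE)))
    if (!is.finite(v)) return(1e10)
    v
  }
  fit <- stats::optim(c(log(scale0), log(shape0)), nll, method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) {
    stop(sprintf("Weibull fit did not converge (optim code %d, nll %.4f)",
                 fit$convergence, fit$value), call. = FALSE)
  }
  vc <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (is.null(vc) || any(diag(vc) <= 0)) {
    stop("observed information is singular; Weibull CIs unavailable", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(diag(vc))
  est <- fit$par
  alpha <- exp(est[1]); beta <- exp(est[2])
  ci <- rbind(exp(est[1] + c(-1, 1) * z * se[1]),
              exp(est[2] + c(-1, 1) * z * se[2]))
  out <- structure(list(alpha = alpha, alpha_lo = ci[1, 1], alpha_hi = ci[1, 2],
                        beta = beta, beta_lo = ci[2, 1], beta_hi = ci[2, 2],
                        n = length(values), n_zero = sum(values == 0),
                        conf_level = conf_level,
                        loglik = -fit$value),
                   class = "weibull_fit")
  out$failure_type <- classify_failure_type(out)
  out
}

#' Classify the failure type from a Weibull shape CI
#'
#' The hazard of a Weibull decreases over time when the shape beta < 1 and
#' increases when beta > 1. Classification uses the confidence interval:
#' `"early"` when the upper bound is below 1, `"wear-out"` when the lower
#' bound is above 1, `"random"` when the interval spans 1.
#'
#' @param fit A `weibull_fit`, or a numeric lower CI bound of beta.
#' @param beta_hi Upper CI bound (when `fit` is numeric).
#' @return One of `"early"`, `"random"`, `"wear-out"`.
#' @export
#' @examples
#' classify_failure_type(0.27, 0.29)
classify_failure_type <- function(fit, beta_hi = NULL) {
  if (inherits(fit, "weibull_fit")) {
    lo <- fit$beta_lo; hi <- fit$beta_hi
  } else {
    lo <- fit; hi <- beta_hi
  }
  stopifnot(is.numeric(lo), is.numeric(hi), lo <= hi)
  if (hi < 1) "early" else if (lo > 1) "wear-out" else "random"
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit (n = %d, %d zero-day onsets mapped to >0)\n",
              x$n, x$n_zero))
  cat(sprintf("  scale alpha: %.2f (%.2f-%.2f) days\n", x$alpha, x$alpha_lo, x$alpha_hi))
  cat(sprintf("  shape beta : %.2f (%.2f-%.2f)  ->  %s failure type\n",
              x$beta, x$beta_lo, x$beta_hi, x$failure_type))
  invisible(x)
}

#' Fit Weibull onset models for every group of a sample
#'
#' Maps [fit_weibull()] over the groups of a `tto_sample`; groups with
#' fewer than `min_n` onsets are skipped (returned with `NA` fits).
#'
#' @param s A `tto_sample` from [compute_tto()].
#' @param min_n Minimum group size to attempt a fit (default 10).
#' @inheritParams fit_weibull
#' @return Tibble with one row per group: `group`, `n`, `alpha`,
#'   `alpha_lo`, `alpha_hi`, `beta`, `beta_lo`, `beta_hi`, `failure_type`.
#' @export
fit_tto_weibull <- function(s, min_n = 10, zero_adjust = 0.5, conf_level = 0.95) {
  stopifnot(all(c("group", "values") %in% names(s)))
  purrr::map2_dfr(s$group, s$values, function(g, v) {
    if (length(v) < min_n) {
      return(tibble::tibble(group = g, n = length(v), alpha = NA_real_,
                            alpha_lo = NA_real_, alpha_hi = NA_real_,
                            beta = NA_real_, beta_lo = NA_real_,
                            beta_hi = NA_real_, failure_type = NA_character_))
    }
    f <- fit_weibull(v, zero_adjust = zero_adjust, conf_level = conf_level)
    tibble::tibble(group = g, n = f$n, alpha = f$alpha, alpha_lo = f$alpha_lo,
                   alpha_hi = f$alpha_hi, beta = f$beta, beta_lo = f$beta_lo,
                   beta_hi = f$beta_hi, failure_type = f$failure_type)
  })
}
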