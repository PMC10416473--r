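#' Build 2x2 contingency tables for drug--event pairs
#'
#' For each term at the chosen level (preferred term or system organ class),
#' counts unique (case, term) pairs into the standard pharmacovigilance 2x2
#' layout with rows = drug (target / all other) and columns = event (the
#' term / all other terms):
#' \describe{
#'   \item{a}{target-drug pairs mentioning the term}
#'   \item{b}{target-drug pairs mentioning other terms}
#'   \item{c}{other-drug pairs mentioning the term}
#'   \item{d}{all remaining pairs}
#' }
#' `n = a + b + c + d` is the total number of pairs at that level. One case
#' contributes at most one pair per term regardless of duplicate reaction
#' rows.
#'
#' @param events Tibble of mentions with column `caseid` plus `pt` and/or
#'   `soc` (see [collect_events()], [map_pt_to_soc()]).
#' @param target_cases Character vector of CASEIDs exposed to the target
#'   drug (see [extract_target_cases()]).
#' @param level `"pt"` or `"soc"`: which column defines the term.
#' @param terms Optional character vector restricting which terms get a
#'   table; default all terms present in `events`. A requested term absent
#'   from `events` yields a row with `a = c = 0`.
#' @return Tibble with columns `level`, `term`, `a`, `b`, `c`, `d`, `n`.
#' @export
#' @examples
#' events <- tibble::tibble(caseid = c("1", "2", "3"),
#'                          pt = c("X", "X", "Y"))
#' contingency_tables(events, target_cases = c("1", "2"), level = "pt")
contingency_tables <- function(events, target_cases, level = c("pt", "soc"),
                               terms = NULL) {
  level <- match.arg(level)
  col <- level
  if (!col %in% names(events)) {
    abort_bad_arg(sprintf("`events` has no '%s' column for level = '%s'", col, level))
  }
  pairs <- dplyr::distinct(tibble::tibble(caseid = events$caseid,
                                          term = events[[col]]))
  pairs$is_target <- pairs$caseid %in% target_cases
  n_total <- nrow(pairs)
  n_target <- sum(pairs$is_target)
  counts <- pairs |>
    dplyr::summarise(a = sum(.data$is_target), total = dplyr::n(),
                     .by = "term")
  if (!is.null(terms)) {
    counts <- dplyr::left_join(tibble::tibble(term = terms), counts, by = "term")
    counts$a[is.na(counts$a)] <- 0L
    counts$total[is.na(counts$total)] <- 0L
  }
  tibble::tibble(level = level,
                 term = counts$term,
                 a = as.double(counts$a),
                 b = as.double(n_target - counts$a),
                 c = as.double(counts$total - counts$a),
                 d = as.double(n_total - n_target - (counts$total - counts$a)),
                 n = as.double(n_total))
}

#' Build the 2x2 table for a single term
#'
#' Convenience wrapper around [contingency_tables()] for one term.
#'
#' @inheritParams contingency_tables
#' @param term The term label.
#' @return One-row tibble with columns `level`, `term`, `a`, `b`, `c`, `d`, `n`.
#' @export
contingency_table <- function(events, target_cases, term, level = c("pt", "soc")) {
  contingency_tables(events, target_cases, level = level, terms = term)
}

# Internal: return Haldane-Anscombe-corrected cells where a zero cell blocks
# the ratio statistics; `correct` governs behaviour.
corrected_cells <- function(tbl, correct = c("auto", "none")) {
  correct <- match.arg(correct)
  for (col in c("a", "b", "c", "d")) tbl[[col]] <- as.numeric(tbl[[col]])
  zero <- tbl$a == 0 | tbl$b == 0 | tbl$c == 0 | tbl$d == 0
  if (correct == "none" && any(zero)) {
    abort_bad_arg(paste0("zero cell in ", sum(zero), " table(s): ROR/PRR/EBGM ",
                         "are undefined; use correct = 'auto' for the ",
                         "Haldane-Anscombe +0.5 correction"))
  }
  add <- ifelse(zero, 0.5, 0)
  list(a = tbl$a + add, b = tbl$b + add, c = tbl$c + add, d = tbl$d + add,
       corrected = zero)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' Adds `ror`, `ror_lo95`, `ror_hi95` columns:
#' ROR = (a d)/(b c), with the log-normal interval
#' exp(ln ROR +- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). Tables with a zero cell
#' get the Haldane-Anscombe +0.5 correction on all four cells and are marked
#' in the `corrected` column.
#'
#' @param tbl Contingency tibble with columns `a`, `b`, `c`, `d`.
#' @param correct `"auto"` (default: +0.5 correction where a zero cell blocks
#'   the ratio) or `"none"` (error on zero cells).
#' @return `tbl` with `ror`, `ror_lo95`, `ror_hi95`, `corrected` columns.
#' @export
#' @examples
#' ror(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
ror <- function(tbl, correct = c("auto", "none")) {
  cc <- corrected_cells(tbl, correct)
  est <- (cc$a * cc$d) / (cc$b * cc$c)
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  tbl$ror <- est
  tbl$ror_lo95 <- exp(log(est) - 1.96 * se)
  tbl$ror_hi95 <- exp(log(est) + 1.96 * se)
  tbl$corrected <- if ("corrected" %in% names(tbl)) tbl$corrected | cc$corrected else cc$corrected
  tbl
}

#' Proportional reporting ratio with chi-squared statistic
#'
#' Adds `prr` and `chi2` columns: PRR = [a/(a+b)] / [c/(c+d)] and the 2x2
#' chi-squared statistic N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)], without
#' continuity correction by default (Yates available via `yates = TRUE`).
#' The PRR uses corrected cells when a zero cell would make it undefined;
#' the chi-squared is computed on the raw counts.
#'
#' @inheritParams ror
#' @param yates Apply Yates' continuity correction to the chi-squared.
#' @return `tbl` with `prr`, `chi2`, `corrected` columns.
#' @export
#' @examples
#' prr(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
prr <- function(tbl, correct = c("auto", "none"), yates = FALSE) {
  cc <- corrected_cells(tbl, correct)
  tbl$prr <- (cc$a / (cc$a + cc$b)) / (cc$c / (cc$c + cc$d))
  a <- as.numeric(tbl$a); b <- as.numeric(tbl$b)
  c <- as.numeric(tbl$c); d <- as.numeric(tbl$d)
  n <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(dev - n / 2, 0)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  tbl$chi2 <- ifelse(denom > 0, n * dev^2 / denom, NA_real_)
  tbl$corrected <- if ("corrected" %in% names(tbl)) tbl$corrected | cc$corrected else cc$corrected
  tbl
}

#' Credibility lower bound of the information component
#'
#' The 2.5% credibility offset of the shrunken information component as a
#' function of the observed count: IC025 = IC - 3.3 (a + 0.5)^(-1/2) -
#' 2 (a + 0.5)^(-3/2). Exported separately because published screens print
#' (a, IC) pairs from which the bound can be recomputed.
#'
#' @param ic Information component (bits).
#' @param a Observed count of target-drug pairs with the term.
#' @return IC025 in bits.
#' @export
#' @examples
#' ic_credibility_bound(1.40, 3387)
ic_credibility_bound <- function(ic, a) {
  ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
}

#' Information component with credibility lower bound
#'
#' Adds `ic` and `ic025` columns. With E = (a+b)(a+c)/N the expected count
#' under independence, IC = log2((a + 0.5)/(E + 0.5)) — a shrunken
#' observed-to-expected log ratio that is defined for all counts including
#' a = 0 — and IC025 is the credibility bound of
#' [ic_credibility_bound()].
#'
#' @inheritParams ror
#' @return `tbl` with `ic`, `ic025` columns.
#' @export
#' @examples
#' ic(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
ic <- function(tbl) {
  a <- as.numeric(tbl$a); b <- as.numeric(tbl$b)
  c <- as.numeric(tbl$c); d <- as.numeric(tbl$d)
  e <- (a + b) * (a + c) / (a + b + c + d)
  tbl$ic <- log2((a + 0.5) / (e + 0.5))
  tbl$ic025 <- ic_credibility_bound(tbl$ic, a)
  tbl
}

#' Closed-form empirical Bayes geometric mean
#'
#' Adds `ebgm` and `ebgm05` columns using the relative-reporting-ratio
#' closed form EBGM = a N / [(a+b)(a+c)] with a log-normal 90% lower bound
#' EBGM05 = exp(ln EBGM - 1.645 sqrt(1/a + 1/b + 1/c + 1/d)). This is the
#' light-weight default; the full gamma-Poisson shrinker is available via
#' [mgps_fit()] and [ebgm_full()].
#'
#' @inheritParams ror
#' @return `tbl` with `ebgm`, `ebgm05`, `corrected` columns.
#' @export
#' @examples
#' ebgm_simple(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
ebgm_simple <- function(tbl, correct = c("auto", "none")) {
  cc <- corrected_cells(tbl, correct)
  n <- cc$a + cc$b + cc$c + cc$d
  est <- cc$a * n / ((cc$a + cc$b) * (cc$a + cc$c))
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  tbl$ebgm <- est
  tbl$ebgm05 <- exp(log(est) - 1.645 * se)
  tbl$corrected <- if ("corrected" %in% names(tbl)) tbl$corrected | cc$corrected else cc$corrected
  tbl
}

#' Apply the joint four-algorithm signal rule
#'
#' Flags each drug--term pair under the four conventional criteria and marks
#' it a signal only when all four hold simultaneously:
#' \itemize{
#'   \item ROR: lower 95% bound > 1 and a >= `min_count`;
#'   \item PRR: PRR >= 2, chi-squared >= 4 and a >= `min_count`;
#'   \item IC: IC025 > 0;
#'   \item EBGM: EBGM05 > 2.
#' }
#'
#' @param tbl Tibble carrying `a`, `ror_lo95`, `prr`, `chi2`, `ic025`,
#'   `ebgm05` (e.g. from chaining [ror()], [prr()], [ic()],
#'   [ebgm_simple()]).
#' @param min_count Minimum observed count for the ROR/PRR criteria
#'   (default 3).
#' @return `tbl` with logical columns `flag_ror`, `flag_prr`, `flag_ic`,
#'   `flag_ebgm` and `signal`.
#' @export
evaluate_signal <- function(tbl, min_count = 3) {
  need <- c("a", "ror_lo95", "prr", "chi2", "ic025", "ebgm05")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort_bad_arg(paste0("evaluate_signal() needs columns: ",
                         paste(miss, collapse = ", ")))
  }
  tbl$flag_ror <- tbl$ror_lo95 > 1 & tbl$a >= min_count
  tbl$flag_prr <- tbl$prr >= 2 & tbl$chi2 >= 4 & tbl$a >= min_count
  tbl$flag_ic <- tbl$ic025 > 0
  tbl$flag_ebgm <- tbl$ebgm05 > 2
  tbl$signal <- tbl$flag_ror & tbl$flag_prr & tbl$flag_ic & tbl$flag_ebgm
  tbl
}

#' Screen all terms for disproportionality signals
#'
#' End-to-end screen at one level: builds every 2x2 table with at least
#' `min_count` target-drug pairs, computes the four statistics and applies
#' the joint signal rule. At PT level, a dictionary attaches each PT's
#' primary SOC for grouping; results are sorted by SOC, then by descending
#' observed count.
#'
#' @inheritParams contingency_tables
#' @param min_count Minimum observed count `a` for a term to be screened
#'   (default 3).
#' @param ebgm `"simple"` (closed form, default) or `"mgps"` (full
#'   gamma-Poisson shrinker, prior fitted on all screened tables).
#' @param dictionary Optional `pt`/`soc`/`is_primary` tibble for PT-level
#'   grouping.
#' @param yates Passed to [prr()].
#' @return A `signal_screen` tibble: columns `level`, `soc` (if available),
#'   `term`, the 2x2 cells, all statistics, per-criterion flags and
#'   `signal`; attributes `n_signals` and `n_socs_signal`.
#' @export
screen_signals <- function(events, target_cases, level = c("pt", "soc"),
                           min_count = 3, ebgm = c("simple", "mgps"),
                           dictionary = NULL, yates = FALSE) {
  level <- match.arg(level)
  ebgm <- match.arg(ebgm)
  tbl <- contingency_tables(events, target_cases, level = level)
  tbl <- dplyr::filter(tbl, .data$a >= min_count)
  if (nrow(tbl)) {
    tbl <- tbl |> ror() |> prr(yates = yates) |> ic() |> ebgm_simple()
    if (ebgm == "mgps") {
      prior <- mgps_fit(tbl)
      tbl <- ebgm_full(tbl, prior)
    }
    tbl <- evaluate_signal(tbl, min_count = min_count)
  } else {
    for (col in c("ror", "ror_lo95", "ror_hi95", "prr", "chi2", "ic", "ic025",
                  "ebgm", "ebgm05")) {
      tbl[[col]] <- numeric()
    }
    for (col in c("corrected", "flag_ror", "flag_prr", "flag_ic", "flag_ebgm",
                  "signal")) {
      tbl[[col]] <- logical()
    }
  }
  if (level == "pt" && !is.null(dictionary)) {
    prim <- dplyr::filter(dictionary, .data$is_primary)
    tbl <- dplyr::left_join(tbl, dplyr::select(prim, term = "pt", "soc"),
                            by = "term")
    tbl$soc[is.na(tbl$soc)] <- "UNMAPPED"
    tbl <- dplyr::relocate(tbl, "soc", .after = "level")
  } else if (level == "soc") {
    tbl$soc <- tbl$term
    tbl <- dplyr::relocate(tbl, "soc", .after = "level")
  }
  if ("soc" %in% names(tbl)) {
    tbl <- dplyr::arrange(tbl, .data$soc, dplyr::desc(.data$a))
  } else {
    tbl <- dplyr::arrange(tbl, dplyr::desc(.data$a))
  }
  n_signals <- sum(tbl$signal %in% TRUE)
  socs_sig <- if ("soc" %in% names(tbl)) {
    length(unique(tbl$soc[tbl$signal %in% TRUE]))
  } else {
    NA_integer_
  }
  structure(tbl, class = c("signal_screen", class(tbl)),
            n_signals = n_signals, n_socs_signal = socs_sig)
}

#' @export
print.signal_screen <- function(x, ...) {
  cat(sprintf("Disproportionality screen: %d term(s), %d signal(s)%s\n",
              nrow(x), attr(x, "n_signals"),
              if (!is.na(attr(x, "n_socs_signal"))) {
                sprintf(" in %d SOC(s)", attr(x, "n_socs_signal"))
              } else ""))
  NextMethod()
  invisible(x)
}
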