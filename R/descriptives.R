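#' Summarise cohort characteristics
#'
#' Builds a long, Table-1-style summary of a deduplicated cohort: sex, age
#' bands (<18, 18--65, >65 years) with median and IQR, weight bands (<80,
#' 80--100, >100 kg), reporting country (US / non-US), top indications,
#' top combination (non-primary-suspect) drugs, top comorbidities,
#' outcomes (serious / non-serious, and the serious subtypes on the
#' serious-case denominator), reporter class, and reporting year.
#'
#' Each block computes percentages on its own available denominator — the
#' number of cases with the item recorded — not on the cohort size, and the
#' block's available-n is reported alongside. Outcome subtypes keep their
#' multiplicity: a case hospitalised and then deceased counts under both.
#' Comorbidities are the indications recorded for the case's non-suspect
#' drugs.
#'
#' @param cases Case-record tibble from [case_records()].
#' @param drugs Optional DRUG tibble restricted to the cohort, used for the
#'   combination-drug and comorbidity blocks (needs `CASEID`, `drugname`,
#'   `role_cod`; comorbidities additionally use `indi`).
#' @param indi Optional INDI tibble (for comorbidities of non-suspect drugs).
#' @param top_k How many top categories to list for indications,
#'   combination drugs and comorbidities (default 5).
#' @return A `cohort_summary` tibble with columns `block`, `category`, `n`,
#'   `available_n`, `pct`, plus attribute `cohort_n`; medians are reported
#'   as separate `median (IQR)` rows with the value in `n`.
#' @export
summarize_cohort <- function(cases, drugs = NULL, indi = NULL, top_k = 5) {
  cohort_n <- nrow(cases)
  rows <- list()
  add_block <- function(block, categories, counts, available_n) {
    counts <- unname(counts)
    tibble::tibble(block = block, category = categories, n = counts,
                   available_n = available_n,
                   pct = percent(counts, available_n))
  }

  sex_known <- cases$sex[cases$sex != "unknown"]
  rows$sex <- add_block("sex", c("female", "male"),
                        c(sum(sex_known == "female"), sum(sex_known == "male")),
                        length(sex_known))

  age <- cases$age_years[!is.na(cases$age_years)]
  rows$age <- add_block("age (years)", c("<18", "18-65", ">65"),
                        c(sum(age < 18), sum(age >= 18 & age <= 65), sum(age > 65)),
                        length(age))
  med_rows <- function(block, v) {
    q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE) else rep(NA_real_, 3)
    tibble::tibble(block = block, category = c("median", "q1", "q3"),
                   n = q[c(2, 1, 3)], available_n = length(v), pct = NA_real_)
  }
  rows$age_med <- med_rows("age (years)", age)

  wt <- cases$weight_kg[!is.na(cases$weight_kg)]
  rows$wt <- add_block("weight (kg)", c("<80", "80-100", ">100"),
                       c(sum(wt < 80), sum(wt >= 80 & wt <= 100), sum(wt > 100)),
                       length(wt))
  rows$wt_med <- med_rows("weight (kg)", wt)

  country <- cases$country[!is.na(cases$country) & cases$country != ""]
  rows$country <- add_block("country", c("US", "non-US"),
                            c(sum(country == "US"), sum(country != "US")),
                            length(country))

  ind_long <- tibble::tibble(caseid = rep(cases$caseid, lengths(cases$indications)),
                             indication = unlist(cases$indications))
  if (nrow(ind_long)) {
    avail <- length(unique(ind_long$caseid))
    top <- ind_long |>
      dplyr::count(.data$indication, sort = TRUE) |>
      utils::head(top_k)
    rows$indications <- add_block("indications", top$indication, top$n, avail)
  }

  if (!is.null(drugs)) {
    comb <- drugs |>
      dplyr::filter(trimws(.data$role_cod) != "PS",
                    .data$CASEID %in% cases$caseid) |>
      dplyr::distinct(.data$CASEID, drug = toupper(trimws(.data$drugname)))
    if (nrow(comb)) {
      avail <- length(unique(comb$CASEID))
      top <- comb |> dplyr::count(.data$drug, sort = TRUE) |> utils::head(top_k)
      rows$comb <- add_block("combination drugs", top$drug, top$n, avail)
    }
    if (!is.null(indi) && all(c("CASEID", "indi_pt", "indi_drug_seq") %in% names(indi))) {
      nonps_seq <- drugs |>
        dplyr::filter(trimws(.data$role_cod) != "PS") |>
        dplyr::distinct(.data$CASEID, seq = trimws(.data$drug_seq))
      com <- tibble::tibble(CASEID = indi$CASEID,
                            seq = trimws(indi$indi_drug_seq),
                            pt = stringr::str_squish(indi$indi_pt)) |>
        dplyr::semi_join(nonps_seq, by = c("CASEID", "seq")) |>
        dplyr::filter(.data$CASEID %in% cases$caseid) |>
        dplyr::distinct(.data$CASEID, .data$pt)
      if (nrow(com)) {
        avail <- length(unique(com$CASEID))
        top <- com |> dplyr::count(.data$pt, sort = TRUE) |> utils::head(top_k)
        rows$comorb <- add_block("comorbidities", top$pt, top$n, avail)
      }
    }
  }

  n_serious <- sum(cases$serious)
  rows$outcome <- add_block("outcomes", c("non-serious", "serious"),
                            c(cohort_n - n_serious, n_serious), cohort_n)
  out_long <- tibble::tibble(caseid = rep(cases$caseid, lengths(cases$outcomes)),
                             outcome = unlist(cases$outcomes))
  if (nrow(out_long)) {
    lvls <- c("death", "life-threatening", "hospitalization", "disability", "other")
    counts <- vapply(lvls, function(l) {
      length(unique(out_long$caseid[out_long$outcome == l]))
    }, numeric(1))
    rows$serious_sub <- add_block("serious outcomes", lvls, counts, n_serious)
  }

  rep_known <- cases$reporter[cases$reporter != "unknown"]
  rows$reporter <- add_block("reporter", c("health professional", "consumer"),
                             c(sum(rep_known == "health professional"),
                               sum(rep_known == "consumer")),
                             length(rep_known))

  yr <- format(cases$event_date[!is.na(cases$event_date)], "%Y")
  if (length(yr)) {
    tab <- sort(table(yr), decreasing = TRUE)
    rows$year <- add_block("reporting year", names(tab), as.numeric(tab),
                           length(yr))
  }

  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cohort_summary", class(out)), cohort_n = cohort_n)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d cases)\n", attr(x, "cohort_n")))
  NextMethod()
  invisible(x)
}
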