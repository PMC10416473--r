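#' Run the full pharmacovigilance pipeline on a report directory
#'
#' Orchestrates every stage on FAERS-style raw tables: read, deduplicate
#' (latest PRIMARYID per CASEID, minus the deleted-case list), extract
#' target-drug cases by primary-suspect role, map preferred terms to system
#' organ classes, screen both levels with the four disproportionality
#' algorithms under the joint signal rule, summarise the cohort, and run the
#' time-to-onset analysis with per-SOC Weibull fits. Writes one CSV per
#' result plus a run log recording the count retained at every filter step,
#' so the selection funnel is auditable. Outputs are deterministic for fixed
#' inputs; reruns produce byte-identical CSVs.
#'
#' @param input_dir Directory with the raw `$`-delimited tables; a
#'   `deleted_cases.txt` and `pt_to_soc.tsv` are picked up when present.
#' @param drug_synonyms Non-empty character vector of target-drug name
#'   variants (validated before any I/O).
#' @param output_dir Directory for result CSVs and the run log.
#' @param min_count Minimum observed count for screening (default 3).
#' @param ebgm `"simple"` or `"mgps"` EBGM variant.
#' @param policy PT-to-SOC mapping policy, `"primary"` or `"all"`.
#' @param dictionary Optional PT dictionary tibble, overriding
#'   `pt_to_soc.tsv`.
#' @return Invisibly, a list with the in-memory results (`cases`,
#'   `summary`, `screen_pt`, `screen_soc`, `tto`, `tto_summary`,
#'   `weibull`, `log`) and the paths written.
#' @export
run_pipeline <- function(input_dir, drug_synonyms, output_dir,
                         min_count = 3, ebgm = c("simple", "mgps"),
                         policy = c("primary", "all"), dictionary = NULL) {
  ebgm <- match.arg(ebgm)
  policy <- match.arg(policy)
  if (missing(drug_synonyms) || !length(drug_synonyms) ||
      !is.character(drug_synonyms) || all(!nzchar(trimws(drug_synonyms)))) {
    abort_bad_arg("`drug_synonyms` must be a non-empty character vector")
  }
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  note("stage read: loading tables from %s", input_dir)
  raw <- read_faers(input_dir)
  for (nm in names(raw)) note("  %s: %d rows", toupper(nm), nrow(raw[[nm]]))

  del_path <- file.path(input_dir, "deleted_cases.txt")
  deleted <- if (file.exists(del_path)) read_deleted_cases(del_path) else character()
  note("stage dedup: %d deleted-case ids supplied", length(deleted))
  demo <- dedup_reports(raw$demo, deleted)
  note("  removed %d duplicate version row(s), %d deleted case(s); %d cases retained",
       attr(demo, "n_removed_duplicate"), attr(demo, "n_removed_deleted"),
       nrow(demo))

  note("stage extract: primary-suspect match on %s",
       paste(drug_synonyms, collapse = ", "))
  target <- extract_target_cases(raw$drug, drug_synonyms, role = "PS")
  target <- intersect(target, demo$CASEID)
  if (!length(target)) {
    abort_bad_arg("no primary-suspect cases matched the drug synonyms")
  }
  note("  %d target case(s)", length(target))

  if (is.null(dictionary)) {
    dict_path <- file.path(input_dir, "pt_to_soc.tsv")
    dictionary <- if (file.exists(dict_path)) read_pt_dictionary(dict_path) else NULL
  }
  events <- collect_events(raw$reac, caseids = demo$CASEID)
  note("stage map: %d unique case-PT mention(s)", nrow(events))
  if (!is.null(dictionary)) {
    events <- map_pt_to_soc(events, dictionary, policy = policy)
    note("  %d mention(s) unmapped to a SOC", attr(events, "n_unmapped"))
  }

  note("stage screen: min_count = %d, ebgm = %s", min_count, ebgm)
  screen_pt <- screen_signals(events, target, level = "pt",
                              min_count = min_count, ebgm = ebgm,
                              dictionary = dictionary)
  note("  PT level: %d term(s), %d signal(s)", nrow(screen_pt),
       attr(screen_pt, "n_signals"))
  screen_soc <- NULL
  if ("soc" %in% names(events)) {
    screen_soc <- screen_signals(events, target, level = "soc",
                                 min_count = min_count, ebgm = ebgm)
    note("  SOC level: %d term(s), %d signal(s)", nrow(screen_soc),
         attr(screen_soc, "n_signals"))
  }

  demo_target <- dplyr::filter(demo, .data$CASEID %in% target)
  cases <- case_records(demo_target, outc = raw$outc, indi = raw$indi)
  summary_tbl <- summarize_cohort(cases, drugs = raw$drug, indi = raw$indi)

  groups <- if ("soc" %in% names(events)) {
    dplyr::filter(tibble::tibble(caseid = events$caseid, group = events$soc),
                  .data$caseid %in% target)
  } else {
    NULL
  }
  tto <- compute_tto(demo_target, raw$ther, groups = groups)
  tto_sum <- summarize_tto(tto)
  weib <- fit_tto_weibull(tto)
  note("stage tto: %d onset value(s) in pooled group",
       tto$n[tto$group == "all"])

  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  paths <- c(
    cohort_summary = file.path(output_dir, "cohort_summary.csv"),
    screen_pt = file.path(output_dir, "screen_pt.csv"),
    screen_soc = file.path(output_dir, "screen_soc.csv"),
    tto_summary = file.path(output_dir, "tto_summary.csv"),
    tto_weibull = file.path(output_dir, "tto_weibull.csv"),
    log = file.path(output_dir, "run_log.txt"))
  readr::write_csv(tibble::as_tibble(summary_tbl), paths[["cohort_summary"]])
  readr::write_csv(tibble::as_tibble(screen_pt), paths[["screen_pt"]])
  if (!is.null(screen_soc)) {
    readr::write_csv(tibble::as_tibble(screen_soc), paths[["screen_soc"]])
  }
  tto_flat <- dplyr::left_join(tto_sum$stats, weib, by = c("group", "n"))
  readr::write_csv(tto_flat, paths[["tto_weibull"]])
  readr::write_csv(tto_sum$bins, paths[["tto_summary"]])
  writeLines(log_lines, paths[["log"]])

  invisible(list(cases = cases, summary = summary_tbl, screen_pt = screen_pt,
                 screen_soc = screen_soc, tto = tto, tto_summary = tto_sum,
                 weibull = weib, log = log_lines, paths = paths))
}
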