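#' Read FAERS-style quarterly ASCII tables
#'
#' Loads the six `$`-delimited raw tables from a directory, matching files by
#' their FAERS stem (`DEMO*.txt`, `DRUG*.txt`, ...). All columns are read as
#' text: PRIMARYID/CASEID and date fields must never be silently coerced to
#' numbers. Several quarterly files per stem are stacked.
#'
#' @param dir Directory containing the raw files.
#' @param required Stems that must be present; a missing one raises an error
#'   naming the file. Defaults to all six tables.
#' @return A named list of tibbles: `demo`, `drug`, `reac`, `ther`, `outc`,
#'   `indi`.
#' @export
read_faers <- function(dir,
                       required = c("DEMO", "DRUG", "REAC", "THER", "OUTC", "INDI")) {
  if (!dir.exists(dir)) abort_bad_arg(paste0("directory not found: ", dir))
  stems <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
             ther = "THER", outc = "OUTC", indi = "INDI")
  out <- list()
  for (nm in names(stems)) {
    stem <- stems[[nm]]
    files <- list.files(dir, pattern = paste0("^", stem, ".*\\.txt$"),
                        full.names = TRUE)
    if (!length(files)) {
      if (stem %in% required) {
        stop(sprintf("mandatory table %s not found in %s (expected %s*.txt)",
                     stem, dir, stem), call. = FALSE)
      }
      out[[nm]] <- tibble::tibble()
      next
    }
    tbl <- purrr::map_dfr(sort(files), function(f) {
      readr::read_delim(f, delim = "$",
                        col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE,
                        show_col_types = FALSE)
    })
    out[[nm]] <- tbl
  }
  out
}

#' Read a deleted-case list
#'
#' @param path File with one CASEID per line.
#' @return Character vector of CASEIDs.
#' @export
read_deleted_cases <- function(path) {
  if (!file.exists(path)) abort_bad_arg(paste0("file not found: ", path))
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' Read a preferred-term to system-organ-class dictionary
#'
#' @param path Three-column TSV (`pt`, `soc`, `is_primary`).
#' @return Tibble with columns `pt`, `soc`, `is_primary` (logical).
#' @export
read_pt_dictionary <- function(path) {
  if (!file.exists(path)) abort_bad_arg(paste0("file not found: ", path))
  d <- readr::read_tsv(path, col_types = readr::cols(
    pt = readr::col_character(), soc = readr::col_character(),
    is_primary = readr::col_logical()), progress = FALSE)
  d
}

#' Deduplicate versioned reports
#'
#' A case (CASEID) may appear under several report versions (PRIMARYID).
#' Keeps, per CASEID, the row with the numerically highest PRIMARYID — the
#' latest version — then removes any case on the deleted-case list. Ties on
#' identical PRIMARYID keep the first row in file order. The numbers of rows
#' removed by each rule are attached as attributes `n_removed_duplicate` and
#' `n_removed_deleted`.
#'
#' @param demo DEMO tibble with `PRIMARYID` and `CASEID` columns.
#' @param deleted_caseids Character vector of CASEIDs to drop.
#' @return The deduplicated tibble, one row per CASEID.
#' @export
#' @examples
#' demo <- tibble::tibble(PRIMARYID = c("10011", "10012"),
#'                        CASEID = c("1001", "1001"))
#' dedup_reports(demo)
dedup_reports <- function(demo, deleted_caseids = character()) {
  stopifnot(all(c("PRIMARYID", "CASEID") %in% names(demo)))
  pid <- suppressWarnings(as.numeric(demo$PRIMARYID))
  if (anyNA(pid)) {
    abort_bad_arg("non-numeric PRIMARYID values; FAERS report identifiers are numeric text")
  }
  n_in <- nrow(demo)
  kept <- demo |>
    dplyr::mutate(.pid = pid, .row = dplyr::row_number()) |>
    dplyr::group_by(.data$CASEID) |>
    dplyr::filter(.data$.pid == max(.data$.pid)) |>
    dplyr::slice_min(.data$.row, n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".pid", -".row")
  n_dup_removed <- n_in - nrow(kept)
  out <- dplyr::filter(kept, !(.data$CASEID %in% deleted_caseids))
  attr(out, "n_removed_duplicate") <- n_dup_removed
  attr(out, "n_removed_deleted") <- nrow(kept) - nrow(out)
  out
}

#' Extract cases reporting a target drug in a given role
#'
#' Scans the DRUG table for rows whose `drugname` or `prod_ai` matches any
#' synonym and whose `role_cod` equals `role` (by default `"PS"`, primary
#' suspect). Matching is case-insensitive substring matching after trimming,
#' so `" Rubraca "` matches the synonym `"rubraca"`; set `match = "exact"`
#' for whole-field comparison.
#'
#' @param drug DRUG tibble with `CASEID`, `drugname`, `prod_ai`, `role_cod`.
#' @param synonyms Non-empty character vector of drug-name variants.
#' @param role Role code to require (default `"PS"`).
#' @param match `"substring"` (default) or `"exact"`.
#' @return Character vector of unique CASEIDs.
#' @export
extract_target_cases <- function(drug, synonyms, role = "PS",
                                 match = c("substring", "exact")) {
  match <- match.arg(match)
  if (!length(synonyms)) abort_bad_arg("`synonyms` must be non-empty")
  stopifnot(all(c("CASEID", "drugname", "prod_ai", "role_cod") %in% names(drug)))
  syn <- tolower(trimws(synonyms))
  hit_one <- function(x) {
    x <- tolower(trimws(x))
    if (match == "substring") {
      Reduce(`|`, lapply(syn, function(s) stringr::str_detect(x, stringr::fixed(s))),
             accumulate = FALSE)
    } else {
      x %in% syn
    }
  }
  hit <- (hit_one(drug$drugname) | hit_one(drug$prod_ai)) %in% TRUE
  hit <- hit & trimws(drug$role_cod) == role
  unique(drug$CASEID[hit])
}

#' Parse FAERS date text
#'
#' FAERS dates are written as digit strings: `YYYYMMDD` (day precision),
#' `YYYYMM` (month) or `YYYY` (year). Only day-precision dates carry a
#' usable calendar date; month- and year-precision values are partial and
#' are excluded from onset computations. Empty strings are missing; anything
#' else (including out-of-range calendar values such as month 13) is flagged
#' invalid and treated as missing. The number of invalid entries is attached
#' as attribute `n_invalid`.
#'
#' @param x Character vector of raw date fields.
#' @return A tibble with columns `input`, `date` (Date, `NA` unless day
#'   precision) and `precision` (`"day"`, `"month"`, `"year"`, `"missing"`,
#'   `"invalid"`).
#' @export
#' @examples
#' parse_faers_date(c("20200115", "202001", "2020", "", "202013"))
parse_faers_date <- function(x) {
  x <- as.character(x)
  x_trim <- trimws(x)
  n <- length(x_trim)
  date <- rep(as.Date(NA), n)
  precision <- rep("invalid", n)
  precision[is.na(x_trim) | x_trim == ""] <- "missing"
  is8 <- !is.na(x_trim) & grepl("^[0-9]{8}$", x_trim)
  if (any(is8)) {
    d <- as.Date(x_trim[is8], format = "%Y%m%d")
    ok <- !is.na(d)
    idx <- which(is8)
    date[idx[ok]] <- d[ok]
    precision[idx[ok]] <- "day"
    # as.Date() silently rolls some impossible dates on some platforms;
    # re-format to confirm round-trip
    rt <- format(d[ok], "%Y%m%d") == x_trim[idx[ok]]
    bad_rt <- idx[ok][!rt]
    precision[bad_rt] <- "invalid"
    date[bad_rt] <- NA
  }
  is6 <- !is.na(x_trim) & grepl("^[0-9]{6}$", x_trim)
  if (any(is6)) {
    mo <- as.integer(substr(x_trim[is6], 5, 6))
    idx <- which(is6)
    precision[idx[mo >= 1 & mo <= 12]] <- "month"
  }
  is4 <- !is.na(x_trim) & grepl("^[0-9]{4}$", x_trim)
  precision[is4] <- "year"
  out <- tibble::tibble(input = x, date = date, precision = precision)
  attr(out, "n_invalid") <- sum(precision == "invalid")
  out
}

#' Collect unique case--event mentions from the REAC table
#'
#' Normalises reaction rows to one mention per (CASEID, preferred term)
#' pair: term text is trimmed, and duplicate rows arising from report
#' versioning collapse to a single mention. Optionally restricts to a set of
#' retained CASEIDs (e.g. after deduplication).
#'
#' @param reac REAC tibble with `CASEID` and `pt` columns.
#' @param caseids Optional character vector; keep only these cases.
#' @return Tibble with columns `caseid`, `pt`, one row per unique pair.
#' @export
collect_events <- function(reac, caseids = NULL) {
  stopifnot(all(c("CASEID", "pt") %in% names(reac)))
  out <- tibble::tibble(caseid = reac$CASEID,
                        pt = stringr::str_squish(reac$pt))
  if (!is.null(caseids)) out <- dplyr::filter(out, .data$caseid %in% caseids)
  dplyr::distinct(out)
}

#' Map preferred terms to system organ classes
#'
#' Attaches SOC labels to case--event mentions. Under `policy = "primary"`
#' each PT contributes exactly one row (its primary SOC); under
#' `policy = "all"` one row per (PT, SOC) link, since a PT can belong to
#' more than one SOC. PTs absent from the dictionary are kept with
#' `soc = "UNMAPPED"` and counted in a warning rather than dropped silently.
#'
#' @param events Tibble with `caseid`, `pt` (from [collect_events()]).
#' @param dictionary Tibble `pt`, `soc`, `is_primary`; each PT must carry
#'   exactly one primary link.
#' @param policy `"primary"` (default) or `"all"`.
#' @return Tibble with columns `caseid`, `pt`, `soc`, unique rows.
#' @export
map_pt_to_soc <- function(events, dictionary, policy = c("primary", "all")) {
  policy <- match.arg(policy)
  stopifnot(all(c("caseid", "pt") %in% names(events)),
            all(c("pt", "soc", "is_primary") %in% names(dictionary)))
  n_primary <- dictionary |>
    dplyr::group_by(.data$pt) |>
    dplyr::summarise(k = sum(.data$is_primary), .groups = "drop")
  if (any(n_primary$k != 1)) {
    bad <- n_primary$pt[n_primary$k != 1]
    abort_bad_arg(paste0("dictionary must flag exactly one primary SOC per PT; ",
                         "violated for: ", paste(utils::head(bad, 5), collapse = ", ")))
  }
  dict <- if (policy == "primary") {
    dplyr::filter(dictionary, .data$is_primary)
  } else {
    dictionary
  }
  out <- dplyr::left_join(events, dplyr::select(dict, "pt", "soc"),
                          by = "pt", relationship = "many-to-many")
  n_unmapped <- sum(is.na(out$soc))
  if (n_unmapped > 0) {
    warning(sprintf("%d mention(s) with PT absent from the dictionary; kept as soc = 'UNMAPPED'",
                    n_unmapped), call. = FALSE)
    out$soc[is.na(out$soc)] <- "UNMAPPED"
  }
  out <- dplyr::distinct(out)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Build tidy case records from raw deduplicated tables
#'
#' Converts the raw DEMO/OUTC/INDI rows of a deduplicated cohort into one
#' tidy record per case: sex, age in years (units YR/DEC/MON/WK/DY
#' harmonised; unknown codes become missing), weight in kg, country,
#' reporter class (health professional vs consumer from the occupation
#' code), event date with precision, the set of reported outcomes and the
#' serious flag (any outcome code present).
#'
#' @param demo Deduplicated DEMO tibble.
#' @param outc Optional OUTC tibble (`CASEID`, `outc_cod`).
#' @param indi Optional INDI tibble (`CASEID`, `indi_pt`, `indi_drug_seq`).
#' @return Tibble with one row per case: `caseid`, `primaryid`, `sex`,
#'   `age_years`, `weight_kg`, `country`, `reporter`, `event_date`,
#'   `event_precision`, `outcomes` (list of character), `serious`,
#'   `indications` (list of character).
#' @export
case_records <- function(demo, outc = NULL, indi = NULL) {
  stopifnot(all(c("PRIMARYID", "CASEID") %in% names(demo)))
  if (anyDuplicated(demo$CASEID)) {
    abort_bad_arg("`demo` must be deduplicated (one row per CASEID); see dedup_reports()")
  }
  get_col <- function(tbl, nm) if (nm %in% names(tbl)) tbl[[nm]] else rep(NA_character_, nrow(tbl))

  age_num <- suppressWarnings(as.numeric(get_col(demo, "age")))
  age_cod <- toupper(trimws(get_col(demo, "age_cod")))
  age_factor <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.143, DY = 1 / 365.25)
  age_years <- age_num * unname(age_factor[age_cod])
  age_years[!(age_cod %in% names(age_factor))] <- NA_real_

  wt_num <- suppressWarnings(as.numeric(get_col(demo, "wt")))
  wt_cod <- toupper(trimws(get_col(demo, "wt_cod")))
  weight_kg <- dplyr::case_when(wt_cod == "KG" ~ wt_num,
                                wt_cod == "LBS" ~ wt_num * 0.45359237,
                                TRUE ~ NA_real_)

  sex_raw <- toupper(trimws(get_col(demo, "sex")))
  sex <- dplyr::case_when(sex_raw == "F" ~ "female",
                          sex_raw == "M" ~ "male",
                          TRUE ~ "unknown")
  occp <- toupper(trimws(get_col(demo, "occp_cod")))
  reporter <- dplyr::case_when(occp %in% c("MD", "PH", "RN", "OT") ~ "health professional",
                               occp %in% c("CN", "LW") ~ "consumer",
                               TRUE ~ "unknown")
  ev <- parse_faers_date(get_col(demo, "EVENT_DT"))

  out <- tibble::tibble(
    caseid = demo$CASEID, primaryid = demo$PRIMARYID,
    sex = sex, age_years = age_years, weight_kg = weight_kg,
    country = trimws(get_col(demo, "reporter_country")),
    reporter = reporter,
    event_date = ev$date, event_precision = ev$precision)

  outcome_label <- c(DE = "death", LT = "life-threatening", HO = "hospitalization",
                     DS = "disability", CA = "other", RI = "other", OT = "other")
  if (!is.null(outc) && nrow(outc)) {
    oc <- tibble::tibble(caseid = outc$CASEID,
                         code = toupper(trimws(outc$outc_cod))) |>
      dplyr::mutate(outcome = dplyr::coalesce(outcome_label[.data$code], "other")) |>
      dplyr::distinct(.data$caseid, .data$outcome) |>
      dplyr::summarise(outcomes = list(.data$outcome), .by = "caseid")
    out <- dplyr::left_join(out, oc, by = "caseid")
  } else {
    out$outcomes <- vector("list", nrow(out))
  }
  out$outcomes <- purrr::map(out$outcomes, function(v) if (is.null(v)) character() else v)
  out$serious <- lengths(out$outcomes) > 0

  if (!is.null(indi) && nrow(indi)) {
    primary_seq <- if ("indi_drug_seq" %in% names(indi)) {
      trimws(indi$indi_drug_seq) %in% c("1", "")
    } else {
      rep(TRUE, nrow(indi))
    }
    ind <- tibble::tibble(caseid = indi$CASEID[primary_seq],
                          indication = stringr::str_squish(indi$indi_pt[primary_seq])) |>
      dplyr::distinct() |>
      dplyr::summarise(indications = list(.data$indication), .by = "caseid")
    out <- dplyr::left_join(out, ind, by = "caseid")
  } else {
    out$indications <- vector("list", nrow(out))
  }
  out$indications <- purrr::map(out$indications, function(v) if (is.null(v)) character() else v)
  out
}
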