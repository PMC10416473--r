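#' Default preferred-term catalogue for simulated cohorts
#'
#' A small catalogue of MedDRA-style preferred terms with their primary
#' system organ class and a baseline per-report reporting probability. The
#' baselines are of the order seen for common terms in spontaneous-report
#' databases (0.5--5% of reports mention a given common term).
#'
#' @return A tibble with columns `pt`, `soc`, `baseline`.
#' @export
default_pt_catalog <- function() {
  tibble::tribble(
    ~pt,                         ~soc,                                          ~baseline,
    "Nausea",                    "Gastrointestinal disorders",                  0.040,
    "Vomiting",                  "Gastrointestinal disorders",                  0.025,
    "Diarrhoea",                 "Gastrointestinal disorders",                  0.025,
    "Constipation",              "Gastrointestinal disorders",                  0.012,
    "Abdominal pain",            "Gastrointestinal disorders",                  0.015,
    "Fatigue",                   "General disorders",                           0.045,
    "Asthenia",                  "General disorders",                           0.018,
    "Pyrexia",                   "General disorders",                           0.015,
    "Anaemia",                   "Blood and lymphatic system disorders",        0.010,
    "Thrombocytopenia",          "Blood and lymphatic system disorders",        0.006,
    "Neutropenia",               "Blood and lymphatic system disorders",        0.005,
    "Dysgeusia",                 "Nervous system disorders",                    0.005,
    "Headache",                  "Nervous system disorders",                    0.030,
    "Dizziness",                 "Nervous system disorders",                    0.022,
    "Decreased appetite",        "Metabolism and nutrition disorders",          0.012,
    "Dehydration",               "Metabolism and nutrition disorders",          0.006,
    "Rash",                      "Skin and subcutaneous tissue disorders",      0.020,
    "Photosensitivity reaction", "Skin and subcutaneous tissue disorders",      0.003,
    "Pruritus",                  "Skin and subcutaneous tissue disorders",      0.012,
    "Dyspnoea",                  "Respiratory disorders",                       0.020,
    "Cough",                     "Respiratory disorders",                       0.015,
    "Insomnia",                  "Psychiatric disorders",                       0.014,
    "Anxiety",                   "Psychiatric disorders",                       0.012,
    "Arthralgia",                "Musculoskeletal and connective tissue disorders", 0.016
  )
}

#' Configuration for the synthetic spontaneous-report generator
#'
#' Bundles and validates every knob of [simulate_reports()]. The defaults
#' describe a cohort in which the target drug is a PARP-inhibitor-like
#' oncology drug: three planted adverse-event associations (reporting-rate
#' ratios 8, 5 and 2), onset times that cluster early after the start of
#' therapy (Weibull shape well below 1), and the usual data pathologies of a
#' public spontaneous-report corpus (versioned duplicate reports, a
#' deleted-case list, partial and reversed dates).
#'
#' @param n_cases Number of distinct cases to simulate.
#' @param target_drug_share Fraction of cases whose primary-suspect drug is
#'   the target drug.
#' @param pt_catalog Tibble with columns `pt`, `soc`, `baseline` (baseline
#'   per-case reporting probability in (0, 1]).
#' @param effect_map Named numeric vector mapping a preferred term to its true
#'   reporting-rate ratio for target-drug cases (values >= 0). Terms absent
#'   from the map have ratio 1.
#' @param onset_map Named list mapping a preferred term (or SOC) to
#'   `c(scale, shape)` of its true onset-time Weibull in days. Terms without
#'   an entry use `default_onset`.
#' @param default_onset Length-2 numeric `c(scale, shape)` for onset times of
#'   unmapped terms; defaults to scale 16.57 days, shape 0.28 (an early
#'   failure profile).
#' @param duplicate_rate Fraction of cases that receive a second, higher
#'   PRIMARYID row with the same CASEID.
#' @param deleted_rate Fraction of cases whose CASEID is placed on the
#'   deleted-case list.
#' @param partial_date_rate Fraction of cases whose therapy start date is
#'   written with month or year precision only (YYYYMM / YYYY).
#' @param reversed_date_rate Fraction of cases whose event date is written
#'   earlier than the therapy start date (an input error).
#' @param missing_event_rate Fraction of cases with an empty event date.
#' @param target_drug Character vector of name variants used when writing the
#'   target drug into the DRUG table (exercises case-insensitive matching).
#' @param seed Integer seed; the generator is deterministic given the full
#'   configuration.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 500, seed = 42)
#' cfg$n_cases
sim_config <- function(n_cases = 5000,
                       target_drug_share = 0.10,
                       pt_catalog = default_pt_catalog(),
                       effect_map = c("Nausea" = 8, "Anaemia" = 5, "Fatigue" = 2),
                       onset_map = list(),
                       default_onset = c(scale = 16.57, shape = 0.28),
                       duplicate_rate = 0.05,
                       deleted_rate = 0.01,
                       partial_date_rate = 0.10,
                       reversed_date_rate = 0.02,
                       missing_event_rate = 0.10,
                       target_drug = c("RUCAPARIB", "Rubraca"),
                       seed = 1L) {
  if (!is.numeric(n_cases) || length(n_cases) != 1 || n_cases < 1 ||
      n_cases != floor(n_cases)) {
    abort_bad_arg("`n_cases` must be a positive whole number")
  }
  check_fraction(target_drug_share, "target_drug_share", closed_hi = TRUE)
  check_fraction(duplicate_rate, "duplicate_rate")
  check_fraction(deleted_rate, "deleted_rate")
  check_fraction(partial_date_rate, "partial_date_rate")
  check_fraction(reversed_date_rate, "reversed_date_rate")
  check_fraction(missing_event_rate, "missing_event_rate")
  stopifnot(is.data.frame(pt_catalog),
            all(c("pt", "soc", "baseline") %in% names(pt_catalog)))
  if (anyDuplicated(pt_catalog$pt)) {
    abort_bad_arg("`pt_catalog` must have one row per preferred term")
  }
  if (any(pt_catalog$baseline <= 0 | pt_catalog$baseline > 1)) {
    abort_bad_arg("`pt_catalog$baseline` values must lie in (0, 1]")
  }
  if (length(effect_map)) {
    if (is.null(names(effect_map)) || any(names(effect_map) == "")) {
      abort_bad_arg("`effect_map` must be a named numeric vector")
    }
    missing_pt <- setdiff(names(effect_map), pt_catalog$pt)
    if (length(missing_pt)) {
      abort_bad_arg(paste0("`effect_map` names absent from `pt_catalog`: ",
                           paste(missing_pt, collapse = ", ")))
    }
    if (any(effect_map < 0)) abort_bad_arg("`effect_map` ratios must be >= 0")
  }
  if (length(onset_map)) {
    known <- c(pt_catalog$pt, unique(pt_catalog$soc))
    missing_term <- setdiff(names(onset_map), known)
    if (length(missing_term)) {
      abort_bad_arg(paste0("`onset_map` names absent from `pt_catalog`: ",
                           paste(missing_term, collapse = ", ")))
    }
    bad <- !vapply(onset_map, function(p) length(p) == 2 && all(p > 0), TRUE)
    if (any(bad)) abort_bad_arg("`onset_map` entries must be positive c(scale, shape)")
  }
  stopifnot(length(default_onset) == 2, all(default_onset > 0))
  stopifnot(is.character(target_drug), length(target_drug) >= 1)
  structure(
    list(n_cases = as.integer(n_cases),
         target_drug_share = target_drug_share,
         pt_catalog = tibble::as_tibble(pt_catalog[c("pt", "soc", "baseline")]),
         effect_map = effect_map,
         onset_map = onset_map,
         default_onset = stats::setNames(as.numeric(default_onset),
                                         c("scale", "shape")),
         duplicate_rate = duplicate_rate,
         deleted_rate = deleted_rate,
         partial_date_rate = partial_date_rate,
         reversed_date_rate = reversed_date_rate,
         missing_event_rate = missing_event_rate,
         target_drug = target_drug,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a preferred-term to system-organ-class dictionary
#'
#' Builds a synthetic MedDRA-style mapping in which every preferred term (PT)
#' links to at least one system organ class (SOC), exactly one link per PT is
#' flagged primary, and a chosen fraction of PTs carry a second, non-primary
#' SOC link (a PT can belong to several SOCs in the real dictionary).
#'
#' @param n_pts Number of preferred terms (>= `n_socs`).
#' @param n_socs Number of system organ classes (>= 1).
#' @param multi_soc_fraction Fraction of PTs given a second SOC link.
#' @param seed Integer seed.
#' @return A tibble with columns `pt`, `soc`, `is_primary`.
#' @export
#' @examples
#' simulate_dictionary(10, 3, multi_soc_fraction = 0.5, seed = 1)
simulate_dictionary <- function(n_pts, n_socs, multi_soc_fraction = 0,
                                seed = 1L) {
  if (!is.numeric(n_socs) || n_socs < 1) abort_bad_arg("`n_socs` must be >= 1")
  if (!is.numeric(n_pts) || n_pts < n_socs) {
    abort_bad_arg("`n_pts` must be >= `n_socs`")
  }
  check_fraction(multi_soc_fraction, "multi_soc_fraction", closed_hi = TRUE)
  set.seed(as.integer(seed))
  pts <- sprintf("PT_%03d", seq_len(n_pts))
  socs <- sprintf("SOC_%02d", seq_len(n_socs))
  # Round-robin primary assignment so every SOC is used at least once.
  primary <- tibble::tibble(
    pt = pts,
    soc = socs[((seq_len(n_pts) - 1L) %% n_socs) + 1L],
    is_primary = TRUE)
  n_multi <- round(multi_soc_fraction * n_pts)
  if (n_multi > 0 && n_socs > 1) {
    multi_pts <- sort(sample(pts, n_multi))
    extra <- purrr::map_dfr(multi_pts, function(p) {
      prim <- primary$soc[primary$pt == p]
      tibble::tibble(pt = p,
                     soc = sample(setdiff(socs, prim), 1),
                     is_primary = FALSE)
    })
    out <- dplyr::arrange(dplyr::bind_rows(primary, extra), pt,
                          dplyr::desc(is_primary))
  } else {
    out <- primary
  }
  out
}

# Internal: format a Date vector as FAERS YYYYMMDD text.
format_faers_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(d)] <- ""
  out
}

#' Simulate a FAERS-shaped spontaneous-report cohort with known ground truth
#'
#' Generates the six raw quarterly tables (DEMO, DRUG, REAC, THER, OUTC,
#' INDI) plus a deleted-case list and a PT-to-SOC dictionary for a cohort in
#' which the true drug--event reporting-rate ratios and the true onset-time
#' Weibull parameters are known. For each case, every catalogue term is
#' drawn as an independent Bernoulli with probability `baseline * RR`
#' (target-drug cases) or `baseline` (all others), truncated to 1; a case
#' that draws no term receives the filler reaction `"Drug ineffective"` —
#' assigned by the same rule in both arms, so it cannot distort a planted
#' rate ratio — and every report carries at least one reaction. Onset days
#' are drawn from the term's Weibull and written as a START_DT / EVENT_DT
#' pair (`EVENT_DT = START_DT + round(onset)`, so same-day onsets occur
#' naturally). A chosen fraction of cases receive a versioned duplicate row
#' (same CASEID, higher PRIMARYID), appear on the deleted-case list, get a
#' right-truncated partial start date, or get a reversed (event before
#' start) date pair; the generator audits exactly what it injected.
#'
#' All randomness flows from `config$seed` through one generator consumed in
#' a fixed documented order (target assignment, per-term draws, fallback
#' terms, onset draws, start dates, demographics, concomitant drugs,
#' outcomes, pathology injection), so two calls with the same configuration
#' give byte-identical written tables.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_cohort` with elements `tables` (named list of
#'   tibbles: demo, drug, reac, ther, outc, indi), `deleted_caseids`
#'   (character), `dictionary` (pt, soc, is_primary), `ground_truth` (list
#'   with `effects`, `onset`, `audit` tibbles) and `config`.
#' @export
#' @examples
#' sim <- simulate_reports(sim_config(n_cases = 200, seed = 7))
#' names(sim$tables)
#' sim$ground_truth$audit
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases
  cat_tbl <- config$pt_catalog
  n_pt <- nrow(cat_tbl)
  rr <- stats::setNames(rep(1, n_pt), cat_tbl$pt)
  rr[names(config$effect_map)] <- config$effect_map

  caseid <- sprintf("%07d", 1000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")  # version suffix 1

  # 1. target-drug assignment
  is_target <- stats::runif(n) < config$target_drug_share

  # 2. per-term Bernoulli draws, catalogue order
  draw <- matrix(FALSE, n, n_pt)
  for (j in seq_len(n_pt)) {
    p <- cat_tbl$baseline[j] * ifelse(is_target, rr[j], 1)
    draw[, j] <- stats::runif(n) < pmin(p, 1)
  }

  # 3. cases that drew nothing get the filler reaction, the same way in both
  # arms, so every report has >= 1 PT without touching planted rate ratios
  filler_pt <- "Drug ineffective"
  filler_soc <- "General disorders"
  none <- rowSums(draw) == 0L

  # 4. onset draw per case, from the first (catalogue-order) drawn term;
  # filler-only cases use the default onset distribution
  first_pt <- apply(draw, 1, which.max)
  onset_par <- t(vapply(seq_len(n_pt), function(j) {
    pt <- cat_tbl$pt[j]; soc <- cat_tbl$soc[j]
    p <- config$onset_map[[pt]]
    if (is.null(p)) p <- config$onset_map[[soc]]
    if (is.null(p)) p <- config$default_onset
    as.numeric(p)
  }, numeric(2)))
  colnames(onset_par) <- c("scale", "shape")
  case_scale <- ifelse(none, config$default_onset[["scale"]],
                       onset_par[first_pt, "scale"])
  case_shape <- ifelse(none, config$default_onset[["shape"]],
                       onset_par[first_pt, "shape"])
  onset_days <- round(stats::rweibull(n, shape = case_shape, scale = case_scale))

  # 5. therapy start dates, uniform over the study window
  window <- as.integer(as.Date("2022-06-30") - as.Date("2017-01-01"))
  start_date <- as.Date("2017-01-01") + sample.int(window + 1L, n, replace = TRUE) - 1L
  event_date <- start_date + onset_days

  # 6. demographics
  sex <- sample(c("F", "M", "UNK"), n, replace = TRUE, prob = c(0.70, 0.25, 0.05))
  age_val <- pmin(pmax(stats::rnorm(n, 64, 12), 18), 95)
  age_missing <- stats::runif(n) < 0.30
  age_cod <- sample(c("YR", "YR", "YR", "YR", "DEC", "MON"), n, replace = TRUE)
  age_out <- dplyr::case_when(
    age_cod == "YR" ~ round(age_val),
    age_cod == "DEC" ~ round(age_val / 10),
    age_cod == "MON" ~ round(age_val * 12))
  age_txt <- ifelse(age_missing, "", as.character(age_out))
  age_cod_txt <- ifelse(age_missing, "", age_cod)
  wt_val <- round(pmax(stats::rnorm(n, 72, 15), 35), 1)
  wt_missing <- stats::runif(n) < 0.60
  wt_txt <- ifelse(wt_missing, "", as.character(wt_val))
  wt_cod_txt <- ifelse(wt_missing, "", "KG")
  country <- sample(c("US", "GB", "JP", "FR", "CA"), n, replace = TRUE,
                    prob = c(0.90, 0.03, 0.03, 0.02, 0.02))
  occp <- sample(c("MD", "PH", "OT", "CN", ""), n, replace = TRUE,
                 prob = c(0.30, 0.15, 0.20, 0.30, 0.05))

  # 7. drug rows: PS row per case; concomitants for some
  background <- c("TAMOXIFEN", "CARBOPLATIN", "ONDANSETRON", "GABAPENTIN",
                  "LORAZEPAM", "METFORMIN", "LISINOPRIL", "ATORVASTATIN",
                  "OMEPRAZOLE", "SERTRALINE")
  target_name <- sample(config$target_drug, n, replace = TRUE)
  ps_name <- ifelse(is_target, target_name,
                    sample(background, n, replace = TRUE))
  drug <- tibble::tibble(PRIMARYID = primaryid, CASEID = caseid,
                         drug_seq = "1", role_cod = "PS",
                         drugname = ps_name,
                         prod_ai = toupper(ps_name))
  conc_n <- ifelse(stats::runif(n) < 0.35, sample(1:2, n, replace = TRUE), 0L)
  conc_idx <- rep.int(seq_len(n), conc_n)
  conc_nm <- sample(background, length(conc_idx), replace = TRUE)
  conc_rows <- tibble::tibble(
    PRIMARYID = primaryid[conc_idx], CASEID = caseid[conc_idx],
    drug_seq = as.character(1L + unlist(lapply(conc_n[conc_n > 0], seq_len))),
    role_cod = "C", drugname = conc_nm, prod_ai = conc_nm)
  # a few non-target cases mention the target drug as concomitant only,
  # to exercise the primary-suspect role filter
  conc_target <- which(!is_target & stats::runif(n) < 0.02)
  if (length(conc_target)) {
    conc_rows <- dplyr::bind_rows(conc_rows, tibble::tibble(
      PRIMARYID = primaryid[conc_target], CASEID = caseid[conc_target],
      drug_seq = "9", role_cod = "C",
      drugname = sample(config$target_drug, length(conc_target), replace = TRUE),
      prod_ai = toupper(config$target_drug[1])))
  }
  drug <- dplyr::arrange(dplyr::bind_rows(drug, conc_rows), CASEID, drug_seq)

  # 8. outcomes: ~40% serious with one or two outcome codes
  serious <- stats::runif(n) < 0.40
  ser_idx <- which(serious)
  ser_k <- ifelse(stats::runif(length(ser_idx)) < 0.25, 2L, 1L)
  out_idx <- rep.int(ser_idx, ser_k)
  outc_rows <- tibble::tibble(
    PRIMARYID = primaryid[out_idx], CASEID = caseid[out_idx],
    outc_cod = sample(c("HO", "DE", "LT", "DS", "OT"), length(out_idx),
                      replace = TRUE, prob = c(0.40, 0.15, 0.05, 0.05, 0.35)))

  # indications: target cases get oncology indications, others generic
  onc_ind <- c("Ovarian cancer", "Fallopian tube cancer",
               "Malignant peritoneal neoplasm", "Breast cancer")
  gen_ind <- c("Hypertension", "Depression", "Pain", "Diabetes mellitus",
               "Product used for unknown indication")
  indi_pt <- ifelse(is_target,
                    sample(onc_ind, n, replace = TRUE, prob = c(0.8, .08, .06, .06)),
                    sample(gen_ind, n, replace = TRUE))
  indi <- tibble::tibble(PRIMARYID = primaryid, CASEID = caseid,
                         indi_drug_seq = "1", indi_pt = indi_pt)
  # concomitant-drug indications double as comorbidity records
  if (nrow(conc_rows)) {
    indi <- dplyr::bind_rows(indi, tibble::tibble(
      PRIMARYID = conc_rows$PRIMARYID, CASEID = conc_rows$CASEID,
      indi_drug_seq = conc_rows$drug_seq,
      indi_pt = sample(gen_ind, nrow(conc_rows), replace = TRUE)))
  }
  indi <- dplyr::arrange(indi, CASEID, indi_drug_seq)

  # 9. pathology injection: disjoint partial / reversed / missing-event sets
  n_partial <- floor(config$partial_date_rate * n)
  n_reversed <- floor(config$reversed_date_rate * n)
  n_missing <- floor(config$missing_event_rate * n)
  shuffled <- sample.int(n)
  idx_partial <- shuffled[seq_len(n_partial)]
  idx_reversed <- shuffled[n_partial + seq_len(n_reversed)]
  idx_missing <- shuffled[n_partial + n_reversed + seq_len(n_missing)]
  if (n_reversed > 0) {
    event_date[idx_reversed] <- start_date[idx_reversed] -
      sample(1:30, n_reversed, replace = TRUE)
  }
  start_txt <- format_faers_date(start_date)
  if (n_partial > 0) {
    trunc_to <- sample(c(6L, 4L), n_partial, replace = TRUE)
    start_txt[idx_partial] <- substr(start_txt[idx_partial], 1, trunc_to)
  }
  event_txt <- format_faers_date(event_date)
  if (n_missing > 0) event_txt[idx_missing] <- ""

  demo <- tibble::tibble(
    PRIMARYID = primaryid, CASEID = caseid, EVENT_DT = event_txt,
    age = age_txt, age_cod = age_cod_txt, sex = sex,
    wt = wt_txt, wt_cod = wt_cod_txt,
    reporter_country = country, occp_cod = occp)
  ther <- tibble::tibble(PRIMARYID = primaryid, CASEID = caseid,
                         dsg_drug_seq = "1", START_DT = start_txt)
  reac_idx <- which(draw, arr.ind = TRUE)
  reac <- tibble::tibble(PRIMARYID = primaryid[reac_idx[, 1]],
                         CASEID = caseid[reac_idx[, 1]],
                         pt = cat_tbl$pt[reac_idx[, 2]])
  if (any(none)) {
    reac <- dplyr::bind_rows(reac, tibble::tibble(
      PRIMARYID = primaryid[none], CASEID = caseid[none], pt = filler_pt))
  }
  reac <- dplyr::arrange(reac, CASEID, pt)

  # duplicate versions: extra DEMO row with higher PRIMARYID, same CASEID
  n_dup <- floor(config$duplicate_rate * n)
  if (n_dup > 0) {
    idx_dup <- sort(sample.int(n, n_dup))
    dup_rows <- demo[idx_dup, ]
    dup_rows$PRIMARYID <- paste0(caseid[idx_dup], "2")
    demo <- dplyr::bind_rows(demo, dup_rows)
  }
  demo <- dplyr::arrange(demo, CASEID, PRIMARYID)

  n_del <- floor(config$deleted_rate * n)
  deleted <- if (n_del > 0) sort(sample(caseid, n_del)) else character()

  dictionary <- dplyr::distinct(tibble::tibble(
    pt = c(cat_tbl$pt, filler_pt),
    soc = c(cat_tbl$soc, filler_soc),
    is_primary = TRUE))
  ground_truth <- list(
    effects = tibble::tibble(pt = cat_tbl$pt, soc = cat_tbl$soc,
                             baseline = cat_tbl$baseline,
                             rr_true = unname(rr)),
    onset = tibble::tibble(pt = cat_tbl$pt,
                           scale = onset_par[, "scale"],
                           shape = onset_par[, "shape"]),
    audit = tibble::tibble(n_cases = n,
                           n_target = sum(is_target),
                           n_duplicates = n_dup,
                           n_deleted = n_del,
                           n_partial_dates = n_partial,
                           n_reversed_dates = n_reversed,
                           n_missing_event = n_missing))
  structure(list(tables = list(demo = demo, drug = drug, reac = reac,
                               ther = ther, outc = outc_rows, indi = indi),
                 deleted_caseids = deleted,
                 dictionary = dictionary,
                 ground_truth = ground_truth,
                 config = config),
            class = "sim_cohort")
}

#' Write a simulated cohort as FAERS-style quarterly ASCII files
#'
#' Emits the six `$`-delimited tables under quarterly-file names
#' (`DEMO22Q2.txt`, ...), the deleted-case list (`deleted_cases.txt`, one
#' CASEID per line), the PT-to-SOC dictionary (`pt_to_soc.tsv`) and the
#' generator's ground truth (`ground_truth.tsv`).
#'
#' @param sim A `sim_cohort` from [simulate_reports()].
#' @param dir Output directory (created if absent).
#' @param quarter Quarter tag used in file names, e.g. `"22Q2"`.
#' @return Invisibly, the paths written.
#' @export
write_faers <- function(sim, dir, quarter = "22Q2") {
  stopifnot(inherits(sim, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stems <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
             ther = "THER", outc = "OUTC", indi = "INDI")
  paths <- character()
  for (nm in names(stems)) {
    p <- file.path(dir, paste0(stems[[nm]], quarter, ".txt"))
    readr::write_delim(sim$tables[[nm]], p, delim = "$", na = "")
    paths <- c(paths, p)
  }
  p_del <- file.path(dir, "deleted_cases.txt")
  writeLines(sim$deleted_caseids, p_del)
  p_dict <- file.path(dir, "pt_to_soc.tsv")
  readr::write_tsv(sim$dictionary, p_dict)
  p_gt <- file.path(dir, "ground_truth.tsv")
  readr::write_tsv(sim$ground_truth$effects, p_gt)
  invisible(c(paths, p_del, p_dict, p_gt))
}
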