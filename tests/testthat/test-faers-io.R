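test_that("written tables round-trip with identical record counts", {
  s <- tiny_sim()
  d <- withr::local_tempdir()
  write_faers(s, d)
  raw <- read_faers(d)
  for (nm in names(s$tables)) {
    expect_equal(nrow(raw[[nm]]), nrow(s$tables[[nm]]), label = nm)
  }
  # identifiers survive as text
  expect_type(raw$demo$PRIMARYID, "character")
  expect_identical(sort(raw$demo$CASEID), sort(s$tables$demo$CASEID))
})

test_that("missing and empty tables are handled explicitly", {
  s <- tiny_sim(n_cases = 50)
  d <- withr::local_tempdir()
  write_faers(s, d)
  file.remove(list.files(d, pattern = "^REAC", full.names = TRUE))
  expect_error(read_faers(d), "REAC")

  d2 <- withr::local_tempdir()
  write_faers(s, d2)
  drug_file <- list.files(d2, pattern = "^DRUG", full.names = TRUE)
  writeLines("PRIMARYID$CASEID$drug_seq$role_cod$drugname$prod_ai", drug_file)
  raw <- read_faers(d2)
  expect_equal(nrow(raw$drug), 0)
})

test_that("deduplication keeps the highest PRIMARYID and honours the deleted list", {
  demo <- tibble::tibble(PRIMARYID = c("1001", "1002", "2001"),
                         CASEID = c("100", "100", "200"))
  out <- dedup_reports(demo)
  expect_equal(out$PRIMARYID[out$CASEID == "100"], "1002")
  expect_equal(attr(out, "n_removed_duplicate"), 1)

  out2 <- dedup_reports(demo, deleted_caseids = "100")
  expect_false("100" %in% out2$CASEID)
  expect_equal(attr(out2, "n_removed_deleted"), 1)

  # idempotence on already-unique input
  out3 <- dedup_reports(out)
  expect_equal(out3$PRIMARYID, out$PRIMARYID)
  expect_equal(out3$CASEID, out$CASEID)
  expect_equal(attr(out3, "n_removed_duplicate"), 0)

  expect_error(dedup_reports(tibble::tibble(PRIMARYID = "x1", CASEID = "1")),
               "numeric")
})

test_that("deduplication never grows the table and keeps a CASEID subset", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    demo <- tibble::tibble(
      PRIMARYID = as.character(sample(1e5, n)),
      CASEID = as.character(sample(10:30, n, replace = TRUE)))
    out <- dedup_reports(demo)
    expect_lte(nrow(out), nrow(demo))
    expect_true(all(out$CASEID %in% demo$CASEID))
    expect_equal(anyDuplicated(out$CASEID), 0)
  }
})

test_that("target-case extraction matches both name columns, case-insensitively", {
  drug <- tibble::tibble(
    CASEID = c("1", "2", "3", "4"),
    drugname = c("RUBRACA", "  rucaparib  ", "rucaparib", "UNRELATED"),
    prod_ai = c("", "", "", "RUCAPARIB CAMSYLATE"),
    role_cod = c("PS", "PS", "C", "PS"))
  got <- extract_target_cases(drug, c("rucaparib", "rubraca"), role = "PS")
  expect_setequal(got, c("1", "2", "4"))  # case 3 fails the role filter
  # whitespace/case invariance of the synonyms themselves
  got2 <- extract_target_cases(drug, c(" RUCAPARIB ", "RuBrAcA"), role = "PS")
  expect_setequal(got2, got)
  expect_error(extract_target_cases(drug, character()), "non-empty")

  # exact matching does not hit the salt-form substring
  got3 <- extract_target_cases(drug, c("rucaparib", "rubraca"), match = "exact")
  expect_setequal(got3, c("1", "2"))
})

test_that("extraction on a generated cohort finds exactly the PS cases", {
  drug <- tibble::tibble(
    CASEID = c("10", "10", "20", "30"),
    drugname = c("Rubraca", "ONDANSETRON", "RUCAPARIB", "rucaparib"),
    prod_ai = c("RUCAPARIB", "", "RUCAPARIB", "RUCAPARIB"),
    role_cod = c("PS", "C", "PS", "C"))
  expect_setequal(extract_target_cases(drug, c("rucaparib", "rubraca")),
                  c("10", "20"))
})

test_that("date parsing distinguishes day, month, year, missing and invalid", {
  p <- parse_faers_date(c("20200115", "202001", "2020", "", "202013",
                          "2020-1-5", "20200230"))
  expect_equal(p$precision,
               c("day", "month", "year", "missing", "invalid", "invalid", "invalid"))
  expect_equal(p$date[1], as.Date("2020-01-15"))
  expect_true(all(is.na(p$date[-1])))
  expect_equal(attr(p, "n_invalid"), 3)
})

test_that("PT-to-SOC mapping follows the policy and flags unmapped terms", {
  dict <- tibble::tibble(pt = c("A", "B", "B"),
                         soc = c("S1", "S1", "S2"),
                         is_primary = c(TRUE, TRUE, FALSE))
  ev <- tibble::tibble(caseid = c("1", "1", "2"), pt = c("A", "B", "B"))
  prim <- map_pt_to_soc(ev, dict, policy = "primary")
  expect_equal(nrow(prim), 3)
  expect_true(all(prim$soc[prim$pt == "B"] == "S1"))
  all_links <- map_pt_to_soc(ev, dict, policy = "all")
  # oracle: naive join row count = sum over mentions of per-PT link counts
  links_per_pt <- table(dict$pt)
  expect_equal(nrow(all_links), sum(links_per_pt[ev$pt]))

  expect_warning(out <- map_pt_to_soc(tibble::tibble(caseid = "9", pt = "ZZZ"),
                                      dict), "UNMAPPED")
  expect_equal(out$soc, "UNMAPPED")

  bad <- dict; bad$is_primary <- c(TRUE, TRUE, TRUE)
  expect_error(map_pt_to_soc(ev, bad), "primary")
})

test_that("case records harmonise ages, outcomes and seriousness", {
  demo <- tibble::tibble(
    PRIMARYID = c("11", "21", "31", "41", "51"),
    CASEID = c("1", "2", "3", "4", "5"),
    EVENT_DT = c("20210510", "2021", "", "20200101", "20190315"),
    age = c("65", "7", "24", "", "520"),
    age_cod = c("YR", "DEC", "MON", "", "WK"),
    sex = c("F", "M", "", "F", "F"),
    wt = c("70", "", "154", "", ""),
    wt_cod = c("KG", "", "LBS", "", ""),
    reporter_country = c("US", "US", "GB", "US", "JP"),
    occp_cod = c("MD", "CN", "", "PH", "OT"))
  outc <- tibble::tibble(CASEID = c("1", "1", "2"),
                         outc_cod = c("HO", "DE", "OT"))
  cr <- case_records(demo, outc = outc)
  expect_equal(cr$age_years, c(65, 70, 2, NA, 520 / 52.143), tolerance = 1e-6)
  expect_equal(cr$sex, c("female", "male", "unknown", "female", "female"))
  expect_equal(cr$weight_kg[3], 154 * 0.45359237)
  expect_equal(cr$reporter,
               c("health professional", "consumer", "unknown",
                 "health professional", "health professional"))
  # outcome multiplicity preserved; serious iff any outcome
  expect_setequal(cr$outcomes[[1]], c("hospitalization", "death"))
  expect_equal(cr$serious, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(cr$event_precision, c("day", "year", "missing", "day", "day"))
  expect_error(case_records(dplyr::bind_rows(demo, demo[1, ])), "deduplicated")
})
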