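make_pair <- function(event, start, caseid = "1") {
  list(demo = tibble::tibble(PRIMARYID = paste0(caseid, "1"), CASEID = caseid,
                             EVENT_DT = event),
       ther = tibble::tibble(PRIMARYID = paste0(caseid, "1"), CASEID = caseid,
                             START_DT = start))
}

test_that("onset is event minus start in whole days, with same-day retained", {
  p <- make_pair("20200115", "20200103")
  s <- compute_tto(p$demo, p$ther)
  expect_equal(s$values[[1]], 12L)

  same <- make_pair("20200103", "20200103")
  s0 <- compute_tto(same$demo, same$ther)
  expect_equal(s0$values[[1]], 0L)
  expect_equal(s0$n, 1)
})

test_that("partial, reversed and missing dates are excluded and counted", {
  demo <- tibble::tibble(
    PRIMARYID = paste0(1:5, "1"), CASEID = as.character(1:5),
    EVENT_DT = c("20200110", "20200101", "202001", "20200110", ""))
  ther <- tibble::tibble(
    PRIMARYID = paste0(1:5, "1"), CASEID = as.character(1:5),
    START_DT = c("20200101", "20200103", "20200101", "2020", "20200101"))
  s <- compute_tto(demo, ther)
  expect_equal(s$n, 1)           # only case 1 usable
  expect_equal(s$values[[1]], 9L)
  expect_equal(s$n_excluded_reversed, 1)  # case 2: event before start
  expect_equal(s$n_excluded_partial, 2)   # cases 3 (event) and 4 (start)
  expect_equal(s$n_excluded_missing, 1)   # case 5
  # conservation: candidates = included + all exclusions
  expect_equal(s$n_candidates,
               s$n + s$n_excluded_partial + s$n_excluded_reversed +
                 s$n_excluded_missing)
})

test_that("multiple therapy rows use the earliest day-precision start", {
  demo <- tibble::tibble(PRIMARYID = "11", CASEID = "1", EVENT_DT = "20200301")
  ther <- tibble::tibble(PRIMARYID = rep("11", 3), CASEID = rep("1", 3),
                         START_DT = c("202002", "20200210", "20200201"))
  s <- compute_tto(demo, ther)
  expect_equal(s$values[[1]], 29L)  # from 2020-02-01
  s2 <- compute_tto(demo, ther, start_rule = "latest_before_event")
  expect_equal(s2$values[[1]], 20L)  # from 2020-02-10
})

test_that("group assignment contributes a case to every group it reports", {
  demo <- tibble::tibble(PRIMARYID = c("11", "21"), CASEID = c("1", "2"),
                         EVENT_DT = c("20200110", "20200120"))
  ther <- tibble::tibble(PRIMARYID = c("11", "21"), CASEID = c("1", "2"),
                         START_DT = c("20200101", "20200101"))
  groups <- tibble::tibble(caseid = c("1", "1", "2"),
                           group = c("SOC A", "SOC B", "SOC A"))
  s <- compute_tto(demo, ther, groups = groups)
  expect_setequal(s$group, c("all", "SOC A", "SOC B"))
  expect_equal(s$values[[which(s$group == "SOC A")]], c(9L, 19L))
  expect_equal(s$values[[which(s$group == "SOC B")]], 9L)
  expect_equal(s$values[[which(s$group == "all")]], c(9L, 19L))
})

test_that("summaries use linear-interpolation quartiles and 30-day bins", {
  sm <- summarize_tto(c(1, 2, 3, 4, 5))
  expect_equal(sm$stats$median, 3)
  expect_equal(sm$stats$q1, 2)
  expect_equal(sm$stats$q3, 4)

  one <- summarize_tto(7)
  expect_equal(c(one$stats$median, one$stats$q1, one$stats$q3), c(7, 7, 7))

  v <- c(0, 10, 30, 31, 45, 200, 400, 800)
  sm2 <- summarize_tto(v)
  bins <- sm2$bins
  expect_equal(sum(bins$count), length(v))
  expect_equal(bins$count[bins$bin == "0-30 d"], 3)
  expect_equal(bins$count[bins$bin == "31-60 d"], 2)
  expect_equal(bins$count[bins$bin == ">360 d"], 2)
  expect_equal(bins$pct[bins$bin == "0-30 d"], 37.5)
  # cumulative curve nondecreasing, ends at 1
  cum <- sm2$cumulative
  expect_true(all(diff(cum$cum_prop) >= 0))
  expect_equal(cum$cum_prop[nrow(cum)], 1)

  empty <- summarize_tto(tibble::tibble(group = "g", n = 0L,
                                        values = list(integer())))
  expect_equal(empty$stats$n, 0L)
  expect_true(is.na(empty$stats$median))
})

test_that("Weibull fit recovers known parameters and matches an independent MLE", {
  set.seed(2024)
  x <- rweibull(2000, shape = 0.28, scale = 16.57)
  f <- fit_weibull(x)
  expect_gte(0.28, f$beta_lo)
  expect_lte(0.28, f$beta_hi)
  expect_lt(abs(f$beta - 0.28) / 0.28, 0.15)
  expect_equal(f$failure_type, "early")

  # exponential data: shape 1 inside the CI
  y <- rexp(5000, rate = 1 / 30)
  fe <- fit_weibull(y)
  expect_gte(1, fe$beta_lo)
  expect_lte(1, fe$beta_hi)

  # independent MLE oracle on a small sample
  z <- rweibull(50, shape = 0.7, scale = 25)
  fz <- fit_weibull(z)
  alt <- fitdistrplus::fitdist(z, "weibull",
                               start = list(shape = 0.5, scale = 20),
                               control = list(reltol = 1e-12))
  expect_equal(fz$beta, unname(alt$estimate["shape"]), tolerance = 1e-4)
  expect_equal(fz$alpha, unname(alt$estimate["scale"]), tolerance = 1e-4)

  expect_error(fit_weibull(rep(5, 20)), "identical")
  expect_error(fit_weibull(c(1, 2, 3)), "at least 10")
  expect_error(fit_weibull(c(-1, rep(2, 10))), "non-negative")
})

test_that("zero-day onsets are adjusted for fitting only", {
  set.seed(9)
  v <- c(rep(0, 40), round(rweibull(200, 0.5, 20)))
  f <- fit_weibull(v)
  expect_equal(f$n_zero, sum(v == 0))
  expect_equal(f$n, length(v))
  # a different zero adjustment changes the fit, proving zeros enter it
  f2 <- fit_weibull(v, zero_adjust = 0.1)
  expect_false(isTRUE(all.equal(f$beta, f2$beta)))
})

test_that("failure types follow the shape-parameter CI rule", {
  expect_equal(classify_failure_type(0.27, 0.29), "early")
  expect_equal(classify_failure_type(0.43, 0.62), "early")
  expect_equal(classify_failure_type(0.90, 1.10), "random")
  expect_equal(classify_failure_type(1.05, 1.80), "wear-out")
})

test_that("shape recovery sweep: coverage and classification across regimes", {
  regimes <- expand.grid(beta = c(0.3, 1.0, 2.5), alpha = c(10, 50))
  for (r in seq_len(nrow(regimes))) {
    bt <- regimes$beta[r]; at <- regimes$alpha[r]
    covered <- 0L; classed <- 0L
    truth <- if (bt < 1) "early" else if (bt > 1) "wear-out" else "random"
    for (seed in 1:20) {
      set.seed(seed * 100 + r)
      f <- fit_weibull(rweibull(1000, shape = bt, scale = at))
      if (f$beta_lo <= bt && bt <= f$beta_hi) covered <- covered + 1L
      if (f$failure_type == truth) classed <- classed + 1L
    }
    expect_gte(covered, 17)  # ~85% nominal coverage over 20 runs
    if (bt != 1) expect_gte(classed, 18)
  }
})

test_that("tidy and glance expose the fit in broom style", {
  set.seed(4)
  f <- fit_weibull(rweibull(300, 0.4, 12))
  td <- tidy(f)
  expect_equal(td$term, c("alpha", "beta"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  g <- glance(f)
  expect_equal(g$n, 300)
  expect_equal(g$failure_type, "early")
})
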