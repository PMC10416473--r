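test_that("contingency tables count unique case-term pairs", {
  ev <- tibble::tibble(caseid = c("1", "2", "3", "3"),
                       pt = c("X", "X", "Y", "Y"))  # duplicate mention collapses
  t_x <- contingency_table(ev, target_cases = c("1", "2"), term = "X", level = "pt")
  expect_equal(t_x[, c("a", "b", "c", "d")],
               tibble::tibble(a = 2, b = 0, c = 0, d = 1))
  expect_equal(t_x$n, 3)

  # empty target set
  t0 <- contingency_table(ev, character(), term = "X", level = "pt")
  expect_equal(c(t0$a, t0$b), c(0, 0))

  # absent term allowed, a = c = 0
  t_z <- contingency_table(ev, c("1"), term = "Z", level = "pt")
  expect_equal(c(t_z$a, t_z$c), c(0, 0))
})

test_that("closed-form statistics reproduce hand-checked values", {
  t1 <- tibble::tibble(a = 10, b = 90, c = 100, d = 9900)
  r <- t1 |> ror() |> prr() |> ic() |> ebgm_simple()
  expect_equal(round_half_up(r$ror, 2), 11.00)
  expect_equal(round_half_up(r$ror_lo95, 2), 5.56)
  expect_equal(round_half_up(r$ror_hi95, 2), 21.76, tolerance = 0.011)
  expect_equal(round_half_up(r$prr, 2), 10.00)
  expect_equal(round_half_up(r$chi2, 2), 74.45)
  expect_equal(round_half_up(r$ic, 2), 2.72)
  expect_equal(round_half_up(r$ic025, 2), 1.65)
  expect_equal(round_half_up(r$ebgm, 2), 9.18)
  expect_equal(round_half_up(r$ebgm05, 2), 5.18)

  # independence table: every ratio 1, chi2 0
  ti <- tibble::tibble(a = 5, b = 5, c = 5, d = 5) |>
    ror() |> prr() |> ic() |> ebgm_simple()
  expect_equal(ti$ror, 1)
  expect_equal(ti$prr, 1)
  expect_equal(ti$chi2, 0)
  expect_equal(ti$ebgm, 1)
})

test_that("statistics obey their exchange symmetries", {
  t1 <- tibble::tibble(a = 7, b = 41, c = 23, d = 901)
  swapped <- tibble::tibble(a = t1$b, b = t1$a, c = t1$d, d = t1$c)
  expect_equal(ror(swapped)$ror, 1 / ror(t1)$ror)
  # chi-squared invariant under transposing the 2x2
  transposed <- tibble::tibble(a = t1$a, b = t1$c, c = t1$b, d = t1$d)
  expect_equal(prr(transposed)$chi2, prr(t1)$chi2)
})

test_that("every closed form matches its independent oracle to 1e-10", {
  tbls <- random_tables(1000, seed = 42)
  got <- tbls |> ror() |> prr() |> ic() |> ebgm_simple()
  for (i in seq_len(nrow(tbls))) {
    a <- tbls$a[i]; b <- tbls$b[i]; c <- tbls$c[i]; d <- tbls$d[i]
    o_ror <- oracle_ror(a, b, c, d)
    o_ic <- oracle_ic(a, b, c, d)
    o_eb <- oracle_ebgm_simple(a, b, c, d)
    rel <- function(x, y) abs(x - y) / abs(y)
    expect_lt(rel(got$ror[i], o_ror$est), 1e-10)
    expect_lt(rel(got$ror_lo95[i], o_ror$lo), 1e-10)
    expect_lt(rel(got$ror_hi95[i], o_ror$hi), 1e-10)
    expect_lt(rel(got$prr[i], oracle_prr(a, b, c, d)), 1e-10)
    expect_lt(rel(got$chi2[i], oracle_chi2(a, b, c, d)), 1e-10)
    expect_lt(abs(got$ic[i] - o_ic$ic), 1e-10)
    expect_lt(abs(got$ic025[i] - o_ic$ic025), 1e-10)
    expect_lt(rel(got$ebgm[i], o_eb$est), 1e-10)
    expect_lt(rel(got$ebgm05[i], o_eb$lo05), 1e-10)
  }
})

test_that("pre-shrinkage estimators agree in direction and IC025 < IC", {
  tbls <- random_tables(300, seed = 13)
  got <- tbls |> ror() |> prr() |> ic() |> ebgm_simple()
  e <- (got$a + got$b) * (got$a + got$c) / (got$a + got$b + got$c + got$d)
  s <- sign(got$a - e)
  nonzero <- s != 0
  expect_true(all(sign(got$ror - 1)[nonzero] == s[nonzero]))
  expect_true(all(sign(got$prr - 1)[nonzero] == s[nonzero]))
  expect_true(all(sign(got$ebgm - 1)[nonzero] == s[nonzero]))
  # credibility bound strictly below the point estimate, down to a = 0
  a_grid <- tibble::tibble(a = c(0, 1, 2, 5, 50, 5000), b = 10, c = 10, d = 1000)
  g <- ic(a_grid)
  expect_true(all(g$ic025 < g$ic))
})

test_that("zero cells engage the continuity correction exactly when needed", {
  tz <- tibble::tibble(a = 4, b = 20, c = 0, d = 500)
  r <- tz |> ror() |> prr() |> ebgm_simple()
  expect_true(r$corrected)
  expect_true(is.finite(r$ror) && is.finite(r$prr) && is.finite(r$ebgm))
  expect_error(ror(tz, correct = "none"), "correction|corrected|zero")
  # no correction for strictly positive tables
  tp <- tibble::tibble(a = 4, b = 20, c = 3, d = 500)
  expect_false(ror(tp)$corrected)
})

test_that("the joint four-criterion rule needs all four flags", {
  base <- tibble::tibble(a = 100, ror_lo95 = 2, prr = 3, chi2 = 50,
                         ic025 = 0.5, ebgm05 = 3)
  expect_true(evaluate_signal(base)$signal)
  # knocking out any single criterion kills the signal
  knock <- list(c(ror_lo95 = 0.9), c(prr = 1.5), c(chi2 = 3),
                c(ic025 = -0.1), c(ebgm05 = 1.9), c(a = 2))
  for (k in knock) {
    m <- base
    m[[names(k)]] <- unname(k)
    expect_false(evaluate_signal(m)$signal, label = names(k))
  }
  expect_error(evaluate_signal(tibble::tibble(a = 1)), "needs columns")
})

test_that("screening a cohort with a strongly planted term flags it", {
  cat1 <- tibble::tibble(
    pt = c("Nausea", "Fatigue", "Headache", "Rash", "Dizziness"),
    soc = c("GI", "General", "Nervous", "Skin", "Nervous"),
    baseline = c(0.01, 0.05, 0.04, 0.03, 0.03))
  cfg <- sim_config(n_cases = 6000, target_drug_share = 0.2, pt_catalog = cat1,
                    effect_map = c("Nausea" = 8), duplicate_rate = 0,
                    deleted_rate = 0, seed = 21)
  s <- simulate_reports(cfg)
  target <- extract_target_cases(s$tables$drug, c("rucaparib", "rubraca"))
  ev <- collect_events(s$tables$reac)
  sc <- screen_signals(ev, target, level = "pt", dictionary = s$dictionary)
  expect_s3_class(sc, "signal_screen")
  expect_true(sc$signal[sc$term == "Nausea"])
  expect_false(any(sc$signal[sc$term != "Nausea"]))
  g <- glance(sc)
  expect_equal(g$n_signals, 1)
  # min_count larger than any a empties the screen
  sc0 <- screen_signals(ev, target, level = "pt", min_count = 1e6)
  expect_equal(nrow(sc0), 0)
})

test_that("gamma-Poisson prior fit concentrates near 1 on null tables", {
  set.seed(101)
  e_true <- runif(200, 5, 400)
  n <- 2e5
  # null: a ~ Poisson(E); embed in tables with matching margins
  a <- rpois(200, e_true)
  row1 <- pmax(round(runif(200, 500, 4000)), a + 1)
  col1 <- pmax(round(e_true * n / row1), a + 1)
  tbl <- tibble::tibble(a = a, b = row1 - a, c = col1 - a,
                        d = n - row1 - col1 + a)
  prior <- mgps_fit(tbl)
  post <- ebgm_full(tbl, prior)
  expect_true(all(post$ebgm > 0.7 & post$ebgm < 1.35))
  expect_true(mean(post$ebgm > 0.8 & post$ebgm < 1.25) > 0.95)
  expect_error(mgps_fit(tbl[1:5, ]), "20 tables")
})

test_that("full-shrinkage EBGM shrinks toward the null and vanishes asymptotically", {
  tbls <- random_tables(150, seed = 77)
  prior <- mgps_fit(tbls)
  full <- ebgm_full(tbls, prior)
  e <- (tbls$a + tbls$b) * (tbls$a + tbls$c) / (tbls$a + tbls$b + tbls$c + tbls$d)
  rr <- tbls$a / e
  # shrinkage moves the estimate toward the prior mass, never past the MLE
  expect_true(all(abs(log(full$ebgm)) <= abs(log(rr)) + 0.3))
  # for one huge count the shrinkage is negligible
  big <- tibble::tibble(a = 60000, b = 40000, c = 100000, d = 1.2e6)
  e_big <- (big$a + big$b) * (big$a + big$c) / (big$a + big$b + big$c + big$d)
  got <- ebgm_full(big, prior)
  expect_equal(got$ebgm, big$a / e_big, tolerance = 0.01)
})

test_that("posterior 5th percentile matches numeric integration of the mixture", {
  tbls <- random_tables(60, seed = 3)
  prior <- mgps_fit(tbls)
  full <- ebgm_full(tbls, prior)
  th <- prior$theta
  for (i in c(1, 7, 20, 44, 60)) {
    a <- tbls$a[i]
    e <- (tbls$a[i] + tbls$b[i]) * (tbls$a[i] + tbls$c[i]) /
      (tbls$a[i] + tbls$b[i] + tbls$c[i] + tbls$d[i])
    f1 <- dnbinom(a, size = th["alpha1"], prob = th["beta1"] / (th["beta1"] + e))
    f2 <- dnbinom(a, size = th["alpha2"], prob = th["beta2"] / (th["beta2"] + e))
    q <- unname(th["w"] * f1 / (th["w"] * f1 + (1 - th["w"]) * f2))
    dens <- function(l) {
      q * dgamma(l, th["alpha1"] + a, rate = th["beta1"] + e) +
        (1 - q) * dgamma(l, th["alpha2"] + a, rate = th["beta2"] + e)
    }
    mass_below <- integrate(dens, 0, full$ebgm05[i], rel.tol = 1e-9)$value
    expect_equal(mass_below, 0.05, tolerance = 1e-5)
  }
})
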