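test_that("estimator matches the direct-summation oracle on tiny cohorts", {
  ## constant per-sex expected hazards so S_P has a closed form the oracle
  ## can use independently of the life-table machinery
  df <- const_lt_df(0)
  df$rate <- ifelse(df$sex == "male", 0.1, 0.05)
  lt <- life_table(df)
  cohorts <- list(
    data.frame(sex = c("male", "male", "male"), time = c(1, 2, 3),
               status = c(1, 0, 1)),
    data.frame(sex = c("male", "female", "male", "female"),
               time = c(0.4, 1.7, 2.2, 3.1), status = c(1, 1, 0, 1)),
    data.frame(sex = c("female", "male", "female", "male", "female"),
               time = c(0.9, 1.1, 1.3, 2.8, 4.6), status = c(0, 1, 1, 1, 1))
  )
  for (co in cohorts) {
    co$id <- seq_len(nrow(co)); co$age_dx <- 60.3; co$year_dx <- 2007.2
    co$region <- "R1"
    fit <- pohar_perme(co, lt, eval_times = c(1, 2, 3))
    lamP <- ifelse(co$sex == "male", 0.1, 0.05)
    orc <- pp_oracle_const(co$time, co$status, lamP, eval_times = c(1, 2, 3))
    expect_equal(fit$cumhaz, orc$cumhaz, tolerance = 1e-10)
    expect_equal(fit$cumhaz_var, orc$var, tolerance = 1e-10)
  }
})

test_that("three-patient worked example is stable", {
  lt <- make_const_lt(0.1)
  co <- data.frame(id = 1:3, sex = "male", age_dx = 60.3, year_dx = 2007.2,
                   region = "R1", time = c(1, 2, 3), status = c(1, 0, 1))
  fit <- pohar_perme(co, lt, eval_times = 3)
  orc <- pp_oracle_const(co$time, co$status, rep(0.1, 3), eval_times = 3)
  expect_equal(fit$cumhaz, orc$cumhaz, tolerance = 1e-12)
  ## hand-computed: discrete term 1/3 (u=1, three at risk, equal weights)
  ## + 1 (u=3, one at risk); population term 0.1 * 3
  expect_equal(fit$cumhaz, 1 / 3 + 1 - 0.3, tolerance = 1e-12)
})

test_that("with zero expected hazard the estimator is exp(-Nelson-Aalen)", {
  skip_if_not_installed("survival")
  lt0 <- make_const_lt(0)
  for (seed in 1:3) {
    co <- random_cohort(200, seed)
    fit <- pohar_perme(co, lt0, eval_times = c(0, 0.5, 1, 2, 3))
    sf <- survival::survfit(survival::Surv(time, status) ~ 1, data = co,
                            ctype = 1)
    na <- stats::stepfun(sf$time, c(0, cumsum(sf$n.event / sf$n.risk)))
    nav <- stats::stepfun(sf$time, c(0, cumsum(sf$n.event / sf$n.risk^2)))
    expect_equal(fit$cumhaz, na(fit$time), tolerance = 1e-12)
    expect_equal(fit$cumhaz_var, nav(fit$time), tolerance = 1e-12)
    expect_equal(fit$ns, exp(-na(fit$time)), tolerance = 1e-12)
  }
})

test_that("analyses are deterministic and NS starts at 1", {
  lt <- make_const_lt(0.03)
  co <- random_cohort(150, 11)
  f1 <- pohar_perme(co, lt, eval_times = c(0, 1, 2))
  f2 <- pohar_perme(co, lt, eval_times = c(0, 1, 2))
  expect_identical(f1$cumhaz, f2$cumhaz)
  expect_identical(f1$cumhaz_var, f2$cumhaz_var)
  expect_equal(f1$ns[1], 1)
  expect_true(all(diff(f1$cumhaz_var) >= 0))
})

test_that("curves are truncated with a warning once the risk set empties", {
  lt <- make_const_lt(0.02)
  co <- random_cohort(30, 2)
  co$time <- pmin(co$time, 2)
  w <- testthat::capture_warnings(fit <- pohar_perme(co, lt,
                                                     eval_times = c(1, 4)))
  expect_true(any(grepl("truncated|risk set", w)))
  expect_true(max(fit$time) <= 2)
  co$time[1] <- -1
  expect_error(pohar_perme(co, lt, eval_times = 1), "negative")
})

test_that("age standardization recomposes group-specific estimates", {
  lt <- make_const_lt(0.04)
  co <- random_cohort(400, 13)
  ## single group with weight one degenerates to plain Pohar-Perme
  f_all <- age_standardized_ns(co, lt, eval_times = c(1, 2),
                               age_breaks = c(15, Inf), weights = 1)
  f_pp <- pohar_perme(co, lt, eval_times = c(1, 2))
  expect_equal(f_all$ns, f_pp$ns, tolerance = 1e-12)
  ## ICSS groups: weighted recomposition oracle
  br <- c(15, 45, 55, 65, 75, Inf)
  w <- c(0.07, 0.12, 0.23, 0.29, 0.29)
  f_std <- age_standardized_ns(co, lt, eval_times = c(1, 2),
                               age_breaks = br, weights = w)
  g <- findInterval(co$age_dx, br)
  ns_or <- v_or <- 0
  for (k in 1:5) {
    fk <- pohar_perme(co[g == k, ], lt, eval_times = c(1, 2))
    ns_or <- ns_or + w[k] * fk$ns
    v_or <- v_or + w[k]^2 * fk$ns_var
  }
  expect_equal(f_std$ns, ns_or, tolerance = 1e-12)
  expect_equal(f_std$ns_var, v_or, tolerance = 1e-12)
  ## empty groups renormalize with a warning
  co_old <- co[co$age_dx >= 55, ]
  expect_warning(f_r <- age_standardized_ns(co_old, lt, eval_times = 1,
                                            age_breaks = br, weights = w),
                 "renormalized")
  expect_equal(sum(f_r$weights), 1)
})

test_that("exchangeable quintiles give a null gap with covering CI", {
  lt <- make_const_lt(0.03)
  base <- random_cohort(300, 17)
  base$quintile <- NULL
  co <- rbind(transform(base, quintile = 1), transform(base, quintile = 5))
  g <- deprivation_gap(co, lt, horizon = 2)
  expect_equal(g$gap, 0, tolerance = 1e-12)
  expect_true(g$ci[1] <= 0 && g$ci[2] >= 0)
  expect_equal(g$ci[2] - g$gap, 1.96 * g$se, tolerance = 1e-12)
  ## determinism bit-for-bit
  g2 <- deprivation_gap(co, lt, horizon = 2)
  expect_identical(g$gap, g2$gap)
  expect_error(suppressWarnings(deprivation_gap(co, lt, horizon = 50)),
               "support|truncated")
})
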