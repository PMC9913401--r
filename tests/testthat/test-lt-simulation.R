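test_that("vingtile aggregation averages fifths of the 20-quantile scale", {
  src <- external_rate_source(vingtile_src_df(1:20 / 1000))
  agg <- aggregate_vingtiles(src)
  expect_equal(attr(agg, "L"), 5)
  expect_equal(agg$rate, c(2.5, 6.5, 10.5, 14.5, 18.5) / 1000)
  ## constant rates stay constant
  srcc <- external_rate_source(vingtile_src_df(rep(0.007, 20)))
  expect_equal(aggregate_vingtiles(srcc)$rate, rep(0.007, 5))
  ## randomized rates against a brute-force mean oracle
  set.seed(9)
  r <- runif(20, 1e-4, 0.1)
  agg2 <- aggregate_vingtiles(external_rate_source(vingtile_src_df(r)))
  oracle <- vapply(1:5, function(k) mean(r[(4 * k - 3):(4 * k)]), numeric(1))
  expect_equal(agg2$rate, oracle, tolerance = 1e-12)
  ## refuses non-vingtile sources
  expect_error(aggregate_vingtiles(agg), "20-level")
})

test_that("rate ratios divide level rates by the overall rate", {
  df <- data.frame(sex = "male", age = 50, level = c(1:5, 0),
                   rate = c(8, 9, 10, 11, 12, 10))
  rrt <- compute_rate_ratios(external_rate_source(df, unit = "per1000"))
  expect_equal(rrt$rr, c(0.8, 0.9, 1.0, 1.1, 1.2))
  ## all levels equal to overall give unit ratios
  dfe <- df; dfe$rate <- 10
  expect_equal(compute_rate_ratios(external_rate_source(dfe, "per1000"))$rr,
               rep(1, 5))
  ## absent overall: derived as the weighted mean of levels, and the
  ## weighted mean of the ratios is then 1
  dfw <- data.frame(sex = "male", age = 50, level = 1:5,
                    rate = c(8, 9, 10, 11, 12), weight = 0.2)
  rrw <- compute_rate_ratios(external_rate_source(dfw, "per1000"))
  expect_equal(sum(0.2 * rrw$rr), 1, tolerance = 1e-12)
  expect_equal(rrw$rr, c(8, 9, 10, 11, 12) / 10)
  ## all-zero strata yield unit ratios; zero overall with signal errors
  dfz <- df; dfz$rate <- 0
  expect_equal(compute_rate_ratios(external_rate_source(dfz))$rr, rep(1, 5))
  dfb <- df; dfb$rate[6] <- 0
  expect_error(compute_rate_ratios(external_rate_source(dfb, "per1000")),
               "overall rate is zero")
})

test_that("year extension carries the last covered year forward", {
  df <- expand.grid(sex = "male", age = 50, year = 2006:2011, level = 1:5,
                    stringsAsFactors = FALSE)
  df$rate <- (1 + 0.1 * df$level) * (1 + 0.01 * (df$year - 2006)) / 100
  ov <- expand.grid(sex = "male", age = 50, year = 2006:2011, level = 0,
                    stringsAsFactors = FALSE)
  ov$rate <- 0.013
  rrt <- compute_rate_ratios(external_rate_source(rbind(df, ov)))
  ext <- extend_years(rrt, 2006:2013)
  for (y in 2012:2013)
    expect_equal(ext$rr[ext$year == y],
                 ext$rr[ext$year == 2011])
  ## identity when targets already covered
  ext2 <- extend_years(rrt, 2007:2010)
  expect_equal(ext2$rr[ext2$year == 2008], rrt$rr[rrt$year == 2008])
  ## year-free table is replicated across target years
  dfy <- data.frame(sex = "male", age = 50, level = c(1:5, 0),
                    rate = c(8, 9, 10, 11, 12, 10))
  rr_yf <- compute_rate_ratios(external_rate_source(dfy, "per1000"))
  ext3 <- extend_years(rr_yf, 2006:2008)
  expect_equal(ext3$rr[ext3$year == 2006], ext3$rr[ext3$year == 2008])
  expect_error(extend_years(rrt, integer(0)), "non-empty")
})

test_that("rate-ratio transfer multiplies base rates per stratum", {
  base_df <- const_lt_df(ages = 60:64, years = 2006:2008)
  set.seed(4)
  base_df$rate <- runif(nrow(base_df), 0.005, 0.05)
  base <- life_table(base_df)
  ## unit ratios reproduce the base exactly at every quintile
  rr1 <- structure(expand.grid(sex = c("male", "female"), age = 60:64,
                               quintile = 1:5, stringsAsFactors = FALSE),
                   class = c("rate_ratio_table", "data.frame"))
  rr1$rr <- 1
  attr(rr1, "has_year") <- FALSE
  sim1 <- apply_rate_ratios(base, rr1)
  for (q in 1:5) expect_equal(sim1$rates[, , , , q], base$rates[, , , , 1])

  ## randomized ratios against an exhaustive product oracle
  rrr <- rr1
  rrr$rr <- runif(nrow(rrr), 0.5, 1.8)
  simr <- apply_rate_ratios(base, rrr)
  simdf <- as.data.frame(simr)
  key <- paste(simdf$sex, simdf$age, simdf$quintile)
  rkey <- paste(rrr$sex, rrr$age, rrr$quintile)
  bdf <- as.data.frame(base)
  bkey <- paste(bdf$sex, bdf$age, bdf$year, bdf$region)
  skey <- paste(simdf$sex, simdf$age, simdf$year, simdf$region)
  expect_equal(simdf$rate,
               bdf$rate[match(skey, bkey)] * rrr$rr[match(key, rkey)],
               tolerance = 1e-15)
  ## single-cell arithmetic: 0.010 x 1.35 = 0.0135
  b1 <- life_table(data.frame(sex = "male", age = 60, year = 2006,
                              region = "R1", rate = 0.010))
  rr5 <- structure(data.frame(sex = "male", age = 60, quintile = 1:5,
                              rr = c(1, 1, 1, 1, 1.35)),
                   has_year = FALSE,
                   class = c("rate_ratio_table", "data.frame"))
  s1 <- apply_rate_ratios(b1, rr5)
  expect_equal(unname(s1$rates[1, 1, 1, 1, 5]), 0.0135)

  ## gradient transfer: output Q5/Q1 ratio equals rr5/rr1 exactly
  q5q1_out <- simr$rates[, , , , 5] / simr$rates[, , , , 1]
  q5q1_in <- rrr$rr[rrr$quintile == 5] / rrr$rr[rrr$quintile == 1]
  lookup <- paste(rrr$sex[rrr$quintile == 5], rrr$age[rrr$quintile == 5])
  grid <- expand.grid(age = 60:64, year = 2006:2008,
                      sex = c("female", "male"), stringsAsFactors = FALSE)
  expect_equal(as.vector(q5q1_out),
               q5q1_in[match(paste(grid$sex, grid$age), lookup)],
               tolerance = 1e-12)
})

test_that("weighted-mean-one ratios conserve the population-average rate", {
  base_df <- const_lt_df(ages = 60:62, years = 2006:2007)
  set.seed(5)
  base_df$rate <- runif(nrow(base_df), 0.01, 0.04)
  base <- life_table(base_df)
  w <- c(0.15, 0.2, 0.25, 0.2, 0.2)
  raw <- c(0.7, 0.9, 1.0, 1.2, 1.5)
  rr <- raw / sum(w * raw)             # level-weighted mean exactly 1
  rrt <- structure(expand.grid(sex = c("male", "female"), age = 60:62,
                               quintile = 1:5, stringsAsFactors = FALSE),
                   has_year = FALSE,
                   class = c("rate_ratio_table", "data.frame"))
  rrt$rr <- rr[rrt$quintile]
  sim <- apply_rate_ratios(base, rrt)
  mixed <- Reduce(`+`, lapply(1:5, function(q) w[q] * sim$rates[, , , , q]))
  expect_equal(mixed, base$rates[, , , , 1], tolerance = 1e-12)
})

test_that("optional age smoothing averages within sex-level series", {
  df <- expand.grid(sex = "male", age = 50:56, level = c(1:5, 0),
                    stringsAsFactors = FALSE)
  set.seed(12)
  df$rate <- runif(nrow(df), 0.01, 0.05)
  src <- external_rate_source(df)
  sm <- smooth_source_rates(src, window = 5)
  ## interior point: plain 5-term mean of the same level's series
  r3 <- df$rate[df$level == 3]
  ages <- df$age[df$level == 3]
  expect_equal(sm$rate[sm$level == 3 & sm$age == 53],
               mean(r3[ages %in% 51:55]), tolerance = 1e-12)
  ## edge point: window shrinks
  expect_equal(sm$rate[sm$level == 3 & sm$age == 50],
               mean(r3[ages %in% 50:52]), tolerance = 1e-12)
  ## constant series is a fixed point
  dfc <- df; dfc$rate <- 0.02
  smc <- smooth_source_rates(external_rate_source(dfc))
  expect_equal(smc$rate, rep(0.02, nrow(smc)))
})

test_that("the aggregate-compute-extend-apply pipeline is deterministic", {
  set.seed(6)
  r20 <- runif(20, 0.002, 0.03)
  run <- function() {
    src <- external_rate_source(vingtile_src_df(r20, ages = 60:64,
                                                sexes = c("male", "female")))
    rrt <- extend_years(compute_rate_ratios(aggregate_vingtiles(src)),
                        2006:2008)
    base_df <- const_lt_df(ages = 60:64, years = 2006:2008)
    base_df$rate <- 0.01 + 1e-4 * base_df$age
    sim <- apply_rate_ratios(life_table(base_df), rrt)
    path <- tempfile(fileext = ".csv")
    write_life_table(sim, path)
    on.exit(unlink(path))
    readLines(path)
  }
  expect_identical(run(), run())
})
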