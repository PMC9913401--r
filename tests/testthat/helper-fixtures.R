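## Shared fixtures and independent oracles.  The oracles deliberately share
## no code with the package internals: direct per-subject summation loops
## and brute-force integration.

const_lt_df <- function(rate = 0.02, ages = 15:99, years = 2006:2013,
                        sexes = c("male", "female"), region = "R1",
                        stratified = FALSE) {
  g <- expand.grid(age = ages, year = years, sex = sexes,
                   stringsAsFactors = FALSE)
  g$region <- region
  g$rate <- rate
  if (stratified) {
    g <- do.call(rbind, lapply(1:5, function(d) {
      gd <- g; gd$quintile <- d; gd
    }))
  }
  g
}

make_const_lt <- function(rate = 0.02, ...) life_table(const_lt_df(rate, ...))

## small random cohort on the fixture life-table world
random_cohort <- function(n, seed, rate_scale = 0.3, p_event = NULL) {
  set.seed(seed)
  data.frame(id = seq_len(n),
             sex = sample(c("male", "female"), n, TRUE),
             age_dx = runif(n, 30, 85),
             year_dx = runif(n, 2006, 2010),
             region = "R1",
             edi = rnorm(n, 0, 5),
             quintile = sample(1:5, n, TRUE),
             time = rexp(n, rate_scale),
             status = if (is.null(p_event)) rbinom(n, 1, 0.7)
                      else rbinom(n, 1, p_event))
}

## midpoint Riemann integration of lookup_rate along the diagonal
riemann_cumhaz <- function(lt, sex, region, age_dx, year_dx, t,
                           quintile = NULL, h = 1e-4) {
  if (t == 0) return(0)
  n <- ceiling(t / h)
  w <- t / n
  mids <- (seq_len(n) - 0.5) * w
  sum(w * lookup_rate(lt, sex, region, age_dx + mids, year_dx + mids,
                      quintile = quintile))
}

## Direct-summation Pohar-Perme oracle for constant per-subject expected
## hazards lamP (so S_Pi(u) = exp(-lamP_i * u) in closed form).  Implements
## the estimator exactly as defined: discrete term over event times,
## population term by trapezoid on the <= `step` refinement of the
## inter-observation grid.
pp_oracle_const <- function(time, status, lamP, eval_times, step = 1 / 52) {
  tmax <- max(eval_times)
  knots <- sort(unique(c(0, time[time <= tmax], eval_times, tmax)))
  nodes <- 0
  for (j in seq_len(length(knots) - 1)) {
    a <- knots[j]; b <- knots[j + 1]
    k <- ceiling((b - a) / step)
    nodes <- c(nodes, seq(a, b, length.out = k + 1)[-1])
  }
  K <- length(nodes)
  disc <- dvar <- integrand <- numeric(K)
  for (k in seq_len(K)) {
    u <- nodes[k]
    den <- 0; num2 <- 0
    for (i in seq_along(time)) {
      if (time[i] >= u) {
        w <- exp(lamP[i] * u)
        den <- den + w
        num2 <- num2 + lamP[i] * w
      }
    }
    if (den > 0) {
      integrand[k] <- num2 / den
      for (i in seq_along(time)) {
        if (status[i] == 1 && time[i] == u) {
          disc[k] <- disc[k] + exp(lamP[i] * u) / den
          dvar[k] <- dvar[k] + exp(2 * lamP[i] * u) / den^2
        }
      }
    }
  }
  h <- diff(nodes)
  cumint <- c(0, cumsum(h * (integrand[-1] + integrand[-K]) / 2))
  idx <- match(eval_times, nodes)
  list(time = eval_times,
       cumhaz = (cumsum(disc) - cumint)[idx],
       var = cumsum(dvar)[idx])
}

## 20-level external source data.frame
vingtile_src_df <- function(rates_by_level, sexes = "male", ages = 50,
                            weight = 1 / 20) {
  g <- expand.grid(sex = sexes, age = ages, level = 1:20,
                   stringsAsFactors = FALSE)
  g$rate <- rates_by_level[g$level]
  g$weight <- weight
  g
}
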