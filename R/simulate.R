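#' Simulation configuration for registry-like cohorts
#'
#' Bundles the parameters of the synthetic registry world: demographics,
#' diagnosis window and administrative censoring, the EDI (ecological
#' deprivation score) marginal, the deprivation-graded background mortality
#' (Gompertz life table times quintile rate ratios), and the cancer excess
#' hazard (Weibull baseline with a configurable deprivation effect).
#'
#' The defaults emulate a French registry cohort: diagnoses uniform over
#' 2006-2009, follow-up administratively censored mid-2013, ages at
#' diagnosis from a truncated normal on [15, 99], an EDI marginal with
#' median -0.75 on a range of about (-17, 51), and a background gradient
#' rising from 0.80 (least deprived fifth) to 1.35 (most deprived) times the
#' population rate.
#'
#' @param n number of patients.
#' @param p_male probability of male sex.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age-at-diagnosis
#'   parameters (years).
#' @param dx_years diagnosis-year window `c(first, last_exclusive)`.
#' @param censor_date administrative censoring date (decimal year).
#' @param edi_meanlog,edi_sdlog,edi_shift shifted-lognormal EDI marginal:
#'   `EDI = exp(N(meanlog, sdlog)) - shift`, truncated to
#'   `[-shift, edi_upper]`.
#' @param edi_upper upper truncation of the EDI score.
#' @param gomp_a,gomp_b,gomp_drift Gompertz background hazard
#'   `a * exp(b * age) * exp(drift * (year - year_ref))`.
#' @param year_ref calendar reference year of the background hazard.
#' @param background_rr length-5 quintile rate ratios of background
#'   mortality (least to most deprived).
#' @param weib_shape,weib_scale Weibull excess hazard
#'   `(shape/scale) * (t/scale)^(shape-1)`.
#' @param edi_form deprivation effect on the excess hazard: 1 none,
#'   2 proportional, 3 time-dependent (exponentially decaying log-effect).
#' @param log_ehr_p90_p10 effect size: log excess-hazard ratio between EDI
#'   4.4 and -3.9 (at t = 0 for form 3).
#' @param decay_time e-folding time (years) of the form-3 effect decay.
#' @param ages_lt,years_lt age and year coverage of the generated life
#'   tables.
#' @param region single region label of the synthetic world.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 20000, p_male = 0.5,
                       age_mean = 65, age_sd = 12, age_min = 15, age_max = 99,
                       dx_years = c(2006, 2010), censor_date = 2013.5,
                       edi_meanlog = log(16.25), edi_sdlog = 0.41,
                       edi_shift = 17, edi_upper = 51,
                       gomp_a = 3.7e-5, gomp_b = 0.09, gomp_drift = -0.01,
                       year_ref = 2006,
                       background_rr = c(0.80, 0.90, 1.00, 1.15, 1.35),
                       weib_shape = 0.8, weib_scale = 8,
                       edi_form = 1, log_ehr_p90_p10 = 0, decay_time = 1.5,
                       ages_lt = 15:99, years_lt = 2006:2013,
                       region = "R1") {
  stopifnot(n >= 1, gomp_a > 0, gomp_b > 0, weib_shape > 0, weib_scale > 0,
            length(background_rr) == 5, all(background_rr > 0),
            edi_form %in% 1:3, decay_time > 0,
            dx_years[2] > dx_years[1], age_min >= 15)
  if (censor_date <= dx_years[2] - 1)
    stop("censoring date must allow follow-up for every diagnosis year")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

## theoretical quantile of the configured EDI marginal (ignoring the upper
## truncation, which removes < 0.05% of mass at the defaults)
edi_quantile <- function(cfg, p) {
  exp(stats::qnorm(p, cfg$edi_meanlog, cfg$edi_sdlog)) - cfg$edi_shift
}

#' National quintile cut points of the configured EDI marginal
#'
#' @param cfg a [sim_config()].
#' @return Numeric vector of 4 interior cut points (20/40/60/80 percentiles).
#' @export
edi_cutpoints <- function(cfg) {
  edi_quantile(cfg, c(0.2, 0.4, 0.6, 0.8))
}

#' Assign deprivation quintiles from EDI scores
#'
#' Lower-closed intervals; scores tied with a cut point fall in the lower
#' quintile.
#'
#' @param edi numeric EDI scores.
#' @param cuts 4 interior cut points (ascending).
#' @return Integer quintiles 1..5.
#' @export
edi_to_quintile <- function(edi, cuts) {
  stopifnot(length(cuts) == 4, !is.unsorted(cuts))
  findInterval(edi, cuts, left.open = TRUE) + 1L
}

## log excess-hazard multiplier at (t, edi) under the configured effect
excess_log_effect <- function(cfg, t, edi) {
  if (cfg$edi_form == 1 || cfg$log_ehr_p90_p10 == 0) return(rep(0, max(length(t), length(edi))))
  beta <- cfg$log_ehr_p90_p10 / (4.4 - (-3.9))
  eff <- beta * (edi - (-3.9))
  if (cfg$edi_form == 3) eff * exp(-t / cfg$decay_time)
  else rep_len(eff, max(length(t), length(edi)))
}

## true excess hazard and cumulative excess hazard at (t, edi)
true_excess_hazard <- function(cfg, t, edi) {
  base <- (cfg$weib_shape / cfg$weib_scale) *
    (pmax(t, 1e-12) / cfg$weib_scale)^(cfg$weib_shape - 1)
  base * exp(excess_log_effect(cfg, t, edi))
}

true_cum_excess_hazard <- function(cfg, t, edi) {
  if (cfg$edi_form %in% c(1, 2) || cfg$log_ehr_p90_p10 == 0) {
    (t / cfg$weib_scale)^cfg$weib_shape *
      exp(excess_log_effect(cfg, 0, edi))
  } else {
    ## time-dependent effect: numeric integral on a fine grid
    vapply(seq_along(t), function(i) {
      tt <- t[i]
      if (tt <= 0) return(0)
      g <- seq(0, tt, length.out = 512)
      h <- true_excess_hazard(cfg, g, edi[min(i, length(edi))])
      ## Weibull shape < 1 diverges at 0: integrate the closed-form baseline
      ## increment per panel scaled by the mid-panel effect multiplier
      inc <- diff((g / cfg$weib_scale)^cfg$weib_shape)
      mid <- (g[-1] + g[-length(g)]) / 2
      sum(inc * exp(excess_log_effect(cfg, mid, edi[min(i, length(edi))])))
    }, numeric(1))
  }
}

#' Generate the ground-truth life tables and external gradient source
#'
#' Builds (i) an unstratified base life table from the configured Gompertz
#' hazard with calendar drift, (ii) the true deprivation-stratified table
#' (base times the quintile rate ratios), and (iii) an external rate source
#' exposing the same gradient (level rates = overall Gompertz rate times
#' rate ratio, equal level weights), so that the rate-ratio transfer
#' pipeline can reconstruct the stratified table exactly.
#'
#' @param cfg a [sim_config()].
#' @return List with elements `base` (`life_table`), `stratified`
#'   (`life_table`), `source` (`external_rate_source`).
#' @export
gen_truth_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- expand.grid(age = cfg$ages_lt, year = cfg$years_lt,
                   sex = c("female", "male"), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  ## mild sex contrast: male background 1.25x female
  sexmul <- ifelse(g$sex == "male", 1.25, 1 / 1.25)
  g$rate <- cfg$gomp_a * exp(cfg$gomp_b * g$age) *
    exp(cfg$gomp_drift * (g$year - cfg$year_ref)) * sexmul
  g$region <- cfg$region
  base <- life_table(g)

  strat <- do.call(rbind, lapply(1:5, function(d) {
    s <- g
    s$quintile <- d
    s$rate <- s$rate * cfg$background_rr[d]
    s
  }))
  stratified <- life_table(strat)

  src_lev <- do.call(rbind, lapply(1:5, function(d) {
    s <- g[, c("sex", "age", "year")]
    s$level <- d
    s$rate <- g$rate * cfg$background_rr[d]
    s$weight <- 0.2
    s
  }))
  src_ov <- g[, c("sex", "age", "year")]
  src_ov$level <- 0
  src_ov$rate <- g$rate
  src_ov$weight <- NA
  source <- external_rate_source(rbind(src_lev, src_ov))
  list(base = base, stratified = stratified, source = source)
}

#' Invert a piecewise-linear cumulative hazard
#'
#' Given segment end times and the cumulative hazard at those ends (a
#' non-decreasing, piecewise-linear function starting at 0), returns
#' `inf{t : cumhaz(t) >= -log(u)}` for standard-uniform draws `u`, exactly
#' within each linear segment.  Draws whose target exceeds the final
#' cumulative hazard return `Inf` (survival beyond the tabulated horizon).
#'
#' @param ends segment end times: vector (shared) or matrix (one row per
#'   draw).
#' @param cumhaz cumulative hazard at the segment ends, same shape.
#' @param u standard-uniform draws in (0, 1].
#' @return Event times (possibly `Inf`).
#' @export
invert_piecewise_hazard <- function(ends, cumhaz, u) {
  if (any(u <= 0 | u > 1)) stop("u must lie in (0, 1]")
  target <- -log(u)
  if (is.matrix(ends)) {
    stopifnot(nrow(ends) == length(u), all(dim(ends) == dim(cumhaz)))
    m <- ncol(ends)
    j <- rowSums(cumhaz < target) + 1L
    out <- rep(Inf, length(u))
    ok <- j <= m
    jj <- cbind(which(ok), j[ok])
    h0 <- ifelse(j[ok] > 1, cumhaz[cbind(jj[, 1], pmax(j[ok] - 1L, 1L))], 0)
    t0 <- ifelse(j[ok] > 1, ends[cbind(jj[, 1], pmax(j[ok] - 1L, 1L))], 0)
    slope <- (cumhaz[jj] - h0) / (ends[jj] - t0)
    out[ok] <- t0 + (target[ok] - h0) / slope
    ## zero-slope segments cannot reach the target inside themselves; the
    ## construction above only lands there when target == h0 exactly
    out[ok][slope == 0] <- t0[slope == 0]
    out
  } else {
    stopifnot(length(ends) == length(cumhaz))
    vapply(target, function(tg) {
      j <- findInterval(tg, cumhaz, left.open = TRUE) + 1L
      if (j > length(ends)) return(Inf)
      h0 <- if (j > 1) cumhaz[j - 1] else 0
      t0 <- if (j > 1) ends[j - 1] else 0
      sl <- (cumhaz[j] - h0) / (ends[j] - t0)
      if (sl == 0) t0 else t0 + (tg - h0) / sl
    }, numeric(1))
  }
}

#' Generate a registry-like cohort with known ground truth
#'
#' Per patient: demographics and EDI are drawn from the configured
#' marginals; a background death time is drawn by inverting the cumulative
#' hazard along the patient's diagonal through the supplied stratified life
#' table; an excess (cancer) death time is drawn from the configured Weibull
#' excess hazard modified by the deprivation effect; the observed time is
#' the minimum of the two latent times and the administrative censoring
#' time, with the vital status and latent cause recorded.
#'
#' @param cfg a [sim_config()].
#' @param stratified_lt the true deprivation-stratified `life_table`
#'   (typically `gen_truth_tables(cfg)$stratified`).
#' @param seed integer seed; the generator is deterministic given
#'   `(cfg, seed)`.
#' @return List with `cohort` (data.frame: id, sex, age_dx, year_dx, region,
#'   edi, quintile, time, status) and `truth` (list: config, cut points,
#'   latent times, cause of death, and the true net-survival /
#'   excess-hazard functions).
#' @export
gen_cohort <- function(cfg, stratified_lt, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"), inherits(stratified_lt, "life_table"),
            stratified_lt$stratified)
  if (cfg$censor_date <= cfg$dx_years[1])
    stop("censoring date precedes the diagnosis window")
  set.seed(seed)
  n <- cfg$n
  sex <- ifelse(stats::runif(n) < cfg$p_male, "male", "female")
  ## truncated normal age at diagnosis
  plo <- stats::pnorm(cfg$age_min, cfg$age_mean, cfg$age_sd)
  phi <- stats::pnorm(cfg$age_max, cfg$age_mean, cfg$age_sd)
  age_dx <- stats::qnorm(stats::runif(n, plo, phi), cfg$age_mean, cfg$age_sd)
  year_dx <- stats::runif(n, cfg$dx_years[1], cfg$dx_years[2])
  ## shifted-lognormal EDI, upper-truncated
  pup <- stats::pnorm((log(cfg$edi_upper + cfg$edi_shift) - cfg$edi_meanlog) /
                      cfg$edi_sdlog)
  edi <- exp(stats::qnorm(stats::runif(n, 0, pup),
                          cfg$edi_meanlog, cfg$edi_sdlog)) - cfg$edi_shift
  cuts <- edi_cutpoints(cfg)
  quintile <- edi_to_quintile(edi, cuts)

  censor <- cfg$censor_date - year_dx
  horizon <- max(censor) + 1e-9

  path <- lt_hazard_path(stratified_lt, sex, age_dx, year_dx,
                         rep(cfg$region, n), quintile, horizon = horizon)
  u_bg <- stats::runif(n)
  t_bg <- invert_piecewise_hazard(path$ends, path$cumhaz, u_bg)

  u_ex <- stats::runif(n)
  if (cfg$edi_form %in% c(1, 2) || cfg$log_ehr_p90_p10 == 0) {
    mult <- exp(excess_log_effect(cfg, 0, edi))
    t_ex <- cfg$weib_scale * (-log(u_ex) / mult)^(1 / cfg$weib_shape)
  } else {
    ## time-dependent effect: per-patient piecewise-linear cumulative hazard
    ## on a fine grid, then exact linear inversion
    grid <- seq(0, horizon, by = 1 / 104)[-1]
    inc_base <- diff(c(0, (grid / cfg$weib_scale)^cfg$weib_shape))
    midg <- grid - 1 / 208
    beta <- cfg$log_ehr_p90_p10 / 8.3
    ## cumhaz_i(g) = sum inc_base * exp(beta*(edi_i+3.9)*exp(-mid/tau))
    decay <- exp(-midg / cfg$decay_time)
    t_ex <- numeric(n)
    for (b in split(seq_len(n), ceiling(seq_len(n) / 2000))) {
      E <- exp(outer(beta * (edi[b] + 3.9), decay))      # |b| x G
      CH <- E * matrix(inc_base, nrow(E), length(inc_base), byrow = TRUE)
      CH <- t(apply(CH, 1, cumsum))
      t_ex[b] <- invert_piecewise_hazard(
        matrix(grid, nrow = length(b), ncol = length(grid), byrow = TRUE),
        CH, u_ex[b])
    }
  }

  time <- pmin(t_bg, t_ex, censor)
  status <- as.integer(time < censor)
  cause <- ifelse(status == 0, "censored",
                  ifelse(t_ex <= t_bg, "excess", "background"))

  cohort <- data.frame(id = seq_len(n), sex = sex, age_dx = age_dx,
                       year_dx = year_dx, region = cfg$region, edi = edi,
                       quintile = quintile, time = time, status = status,
                       stringsAsFactors = FALSE)
  truth <- list(
    config = cfg, cutpoints = cuts,
    t_background = t_bg, t_excess = t_ex, censor = censor, cause = cause,
    net_survival = function(t, edi) exp(-true_cum_excess_hazard(cfg, t, edi)),
    excess_hazard = function(t, edi) true_excess_hazard(cfg, t, edi),
    ehr_p90_p10 = function(t) exp(excess_log_effect(cfg, t, 4.4) -
                                  excess_log_effect(cfg, t, -3.9)),
    form = cfg$edi_form
  )
  list(cohort = cohort, truth = truth)
}

#' Validate a cohort data.frame
#'
#' @param cohort data.frame with columns `sex`, `age_dx`, `year_dx`,
#'   `region`, `time`, `status`, and (for deprivation analyses) `edi` and/or
#'   `quintile`.
#' @return The cohort, invisibly, after validation.
#' @export
validate_cohort <- function(cohort) {
  req <- c("sex", "age_dx", "year_dx", "region", "time", "status")
  miss <- setdiff(req, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  if (any(cohort$time < 0)) stop("negative follow-up time(s)")
  if (!all(cohort$status %in% 0:1)) stop("status must be 0 (censored) or 1 (dead)")
  if (any(cohort$age_dx < 15)) stop("ages at diagnosis must be >= 15")
  invisible(cohort)
}
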