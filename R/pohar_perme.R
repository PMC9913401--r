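#' Pohar-Perme non-parametric net survival
#'
#' Estimates net survival in the relative-survival setting: each subject's
#' counting process and at-risk indicator are weighted by the inverse of the
#' subject's expected survival `S_P(u) = exp(-Lambda_P(u))`, read from the
#' supplied life table along the diagonal (age at diagnosis + u, year of
#' diagnosis + u).  The cumulative excess hazard is
#' \deqn{\hat\Lambda_E(t) = \sum_{u \le t} \frac{\sum_i dN_i(u)/S_{Pi}(u)}
#'   {\sum_i Y_i(u)/S_{Pi}(u)} - \int_0^t \frac{\sum_i Y_i(u)\,
#'   \lambda_{Pi}(u)/S_{Pi}(u)}{\sum_i Y_i(u)/S_{Pi}(u)}\, du,}
#' the first sum running over event times, the integral computed by the
#' trapezoid rule on a grid that refines every interval between consecutive
#' observed times to steps of at most `step` years.  The variance of
#' `Lambda_E` is the sum over event times of
#' `(sum dN_i/S_Pi^2) / (sum Y_i/S_Pi)^2`, and `NS(t) = exp(-Lambda_E(t))`
#' (unconstrained: it may exceed 1).
#'
#' @param cohort data.frame with columns `sex`, `age_dx`, `year_dx`,
#'   `region`, `time`, `status`, and `quintile` when `lt` is
#'   deprivation-stratified.
#' @param lt a [life_table()].
#' @param eval_times times (years since diagnosis) at which to report the
#'   estimate.
#' @param step maximum integration step for the population term (years).
#' @param conf_type `"plain"` for symmetric delta-method intervals on the
#'   survival scale, `"loglog"` for log-cumulative-hazard intervals.
#' @return Object of class `net_survival`: data.frame-like list with
#'   `time`, `ns`, `cumhaz`, `cumhaz_var`, `ns_var`, `lower`, `upper`,
#'   `at_risk`, `events`, plus `n`, `n_events`.
#' @export
pohar_perme <- function(cohort, lt, eval_times = seq(0, 5, by = 0.25),
                        step = 1 / 52, conf_type = c("plain", "loglog")) {
  conf_type <- match.arg(conf_type)
  validate_cohort(cohort)
  stopifnot(inherits(lt, "life_table"))
  if (lt$stratified && !"quintile" %in% names(cohort))
    stop("life table is deprivation-stratified: cohort needs a quintile column")
  eval_times <- sort(unique(eval_times))
  if (any(eval_times < 0)) stop("eval_times must be >= 0")
  tmax <- max(eval_times)
  n <- nrow(cohort)
  T_i <- cohort$time
  d_i <- cohort$status

  tmax_data <- max(T_i)
  if (tmax > tmax_data) {
    warning("risk set empty beyond t = ", format(tmax_data, digits = 4),
            "; curve truncated")
  }

  ## integration/reporting node set
  knots <- sort(unique(c(0, T_i[T_i <= tmax], eval_times, tmax)))
  nodes <- unlist(lapply(seq_len(length(knots) - 1), function(j) {
    a <- knots[j]; b <- knots[j + 1]
    k <- ceiling((b - a) / step)
    seq(a, b, length.out = k + 1)[-1]
  }))
  tt <- c(0, nodes)
  K <- length(tt)

  ## per-subject expected survival at own exit time
  horizon <- max(tmax, tmax_data, 1e-6) + 1e-9
  quint <- if (lt$stratified) cohort$quintile else NULL

  R1 <- numeric(K); R2 <- numeric(K); atrisk <- numeric(K)
  ev_idx <- match(T_i, tt)           # node index of each subject's exit time
  dw <- numeric(K); dw2 <- numeric(K); dcount <- numeric(K)

  blocks <- split(seq_len(n), ceiling(seq_len(n) / 5000))
  for (b in blocks) {
    path <- lt_hazard_path(lt, cohort$sex[b], cohort$age_dx[b],
                           cohort$year_dx[b], cohort$region[b],
                           if (is.null(quint)) NULL else quint[b],
                           horizon = horizon)
    Tb <- T_i[b]
    m <- ncol(path$ends)
    cumhaz0 <- cbind(0, path$cumhaz[, -m, drop = FALSE])
    for (r in seq_along(b)) {
      kT <- findInterval(Tb[r], tt)       # nodes with u <= T_i (Y_i = 1)
      if (kT < 1) next
      u <- tt[seq_len(kT)]
      j <- findInterval(u, path$ends[r, ]) + 1L   # right-continuous cell
      j[j > m] <- m
      lam <- path$rate[r, j]
      w <- exp(cumhaz0[r, j] + lam * (u - path$starts[r, j]))
      R1[seq_len(kT)] <- R1[seq_len(kT)] + w
      R2[seq_len(kT)] <- R2[seq_len(kT)] + lam * w
      atrisk[seq_len(kT)] <- atrisk[seq_len(kT)] + 1
      if (d_i[b[r]] == 1 && Tb[r] <= tmax) {
        ## T_i is itself a node, so its weight is the last one computed
        wT <- w[kT]
        ix <- ev_idx[b[r]]
        dw[ix] <- dw[ix] + wT
        dw2[ix] <- dw2[ix] + wT^2
        dcount[ix] <- dcount[ix] + 1
      }
    }
  }

  ok <- R1 > 0
  dLam <- ifelse(ok, dw / R1, 0)
  dVar <- ifelse(ok, dw2 / R1^2, 0)
  integrand <- ifelse(ok, R2 / R1, 0)
  wtrap <- diff(tt)
  cumint <- c(0, cumsum(wtrap * (integrand[-1] + integrand[-K]) / 2))
  Lam <- cumsum(dLam) - cumint
  Var <- cumsum(dVar)

  ## support: last node with a non-empty risk set
  last_ok <- max(which(ok))
  support <- tt[last_ok]
  keep <- eval_times <= support + 1e-12
  if (!all(keep))
    warning("estimate truncated at t = ", format(support, digits = 4))
  et <- eval_times[keep]
  ki <- match(et, tt)
  ns <- exp(-Lam[ki])
  chv <- Var[ki]
  nsv <- ns^2 * chv
  se <- sqrt(nsv)
  if (conf_type == "plain") {
    lower <- ns - 1.96 * se
    upper <- ns + 1.96 * se
  } else {
    lse <- sqrt(chv) / pmax(Lam[ki], 1e-12)
    lower <- ns^exp(1.96 * lse)
    upper <- ns^exp(-1.96 * lse)
  }
  structure(list(time = et, ns = ns, cumhaz = Lam[ki], cumhaz_var = chv,
                 ns_var = nsv, lower = lower, upper = upper,
                 at_risk = atrisk[ki],
                 events = cumsum(dcount)[ki],
                 n = n, n_events = sum(d_i == 1 & T_i <= tmax),
                 conf_type = conf_type, support = support),
            class = "net_survival")
}

#' @export
print.net_survival <- function(x, ...) {
  cat("Net survival (Pohar-Perme", if (!is.null(x$weights)) ", age-standardized",
      "), n = ", x$n, ", events = ", x$n_events, "\n", sep = "")
  sel <- unique(round(seq(1, length(x$time), length.out = 6)))
  df <- data.frame(time = x$time[sel], ns = x$ns[sel],
                   se = sqrt(x$ns_var[sel]),
                   lower = x$lower[sel], upper = x$upper[sel])
  print(format(df, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
summary.net_survival <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$time
  ki <- match(times, object$time)
  if (anyNA(ki)) stop("requested times not on the estimate's grid")
  data.frame(time = object$time[ki], ns = object$ns[ki],
             se = sqrt(object$ns_var[ki]),
             lower = object$lower[ki], upper = object$upper[ki],
             at_risk = object$at_risk[ki], events = object$events[ki])
}

#' @export
plot.net_survival <- function(x, ylim = NULL, xlab = "Years since diagnosis",
                              ylab = "Net survival", ci = TRUE, ...) {
  if (is.null(ylim)) ylim <- range(0, 1, x$lower, x$upper, finite = TRUE)
  graphics::plot(x$time, x$ns, type = "s", ylim = ylim, xlab = xlab,
                 ylab = ylab, ...)
  if (ci) {
    graphics::lines(x$time, x$lower, type = "s", lty = 3)
    graphics::lines(x$time, x$upper, type = "s", lty = 3)
  }
  invisible(x)
}

#' Age-standardized net survival
#'
#' Weighted sum of Pohar-Perme estimates over age-at-diagnosis groups.  The
#' default groups and weights follow the International Cancer Survival
#' Standard convention: \[15,45), \[45,55), \[55,65), \[65,75), 75+ with
#' weights 0.07, 0.12, 0.23, 0.29, 0.29.  Groups with no patients are
#' dropped and the remaining weights renormalized (with a warning).
#'
#' @inheritParams pohar_perme
#' @param age_breaks ascending breaks partitioning `[15, Inf)`; the last
#'   break may be `Inf`.
#' @param weights standardization weights, one per age group, summing to 1.
#' @return A `net_survival` object (variance combined on the survival scale:
#'   `Var = sum w_g^2 NS_g^2 V_g`).
#' @export
age_standardized_ns <- function(cohort, lt, eval_times = seq(0, 5, by = 0.25),
                                age_breaks = c(15, 45, 55, 65, 75, Inf),
                                weights = c(0.07, 0.12, 0.23, 0.29, 0.29),
                                step = 1 / 52,
                                conf_type = c("plain", "loglog")) {
  conf_type <- match.arg(conf_type)
  stopifnot(length(weights) == length(age_breaks) - 1)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  g <- findInterval(cohort$age_dx, age_breaks, rightmost.closed = FALSE)
  if (any(g < 1 | g > length(weights)))
    stop("ages outside the standardization groups")
  nonempty <- sort(unique(g))
  if (length(nonempty) == 0) stop("all age groups empty")
  if (length(nonempty) < length(weights)) {
    warning("empty age group(s): weights renormalized over non-empty groups")
    weights <- weights[nonempty] / sum(weights[nonempty])
  } else {
    weights <- weights[nonempty]
  }
  fits <- lapply(nonempty, function(gg)
    pohar_perme(cohort[g == gg, , drop = FALSE], lt, eval_times, step = step))
  et <- Reduce(intersect, lapply(fits, `[[`, "time"))
  if (length(et) == 0) stop("no common support across age groups")
  nsm <- vapply(fits, function(f) f$ns[match(et, f$time)], numeric(length(et)))
  vm <- vapply(fits, function(f) f$ns_var[match(et, f$time)], numeric(length(et)))
  nsm <- matrix(nsm, nrow = length(et))
  vm <- matrix(vm, nrow = length(et))
  ns <- drop(nsm %*% weights)
  nsv <- drop(vm %*% weights^2)
  se <- sqrt(nsv)
  if (conf_type == "plain") {
    lower <- ns - 1.96 * se
    upper <- ns + 1.96 * se
  } else {
    lam <- -log(pmax(ns, 1e-12))
    lse <- se / pmax(ns * lam, 1e-12)
    lower <- ns^exp(1.96 * lse)
    upper <- ns^exp(-1.96 * lse)
  }
  structure(list(time = et, ns = ns, cumhaz = -log(pmax(ns, 1e-300)),
                 cumhaz_var = nsv / pmax(ns, 1e-300)^2, ns_var = nsv,
                 lower = lower, upper = upper,
                 at_risk = Reduce(`+`, lapply(fits, function(f)
                   f$at_risk[match(et, f$time)])),
                 events = Reduce(`+`, lapply(fits, function(f)
                   f$events[match(et, f$time)])),
                 n = nrow(cohort), n_events = sum(vapply(fits, `[[`,
                   numeric(1), "n_events")),
                 weights = weights, groups = nonempty,
                 conf_type = conf_type,
                 support = min(vapply(fits, `[[`, numeric(1), "support"))),
            class = "net_survival")
}

#' Quintile deprivation gap in age-standardized net survival
#'
#' Difference, in percentage points, between the age-standardized net
#' survival of the least-deprived (Q1) and most-deprived (Q5) patients at a
#' horizon (default 5 years), with a delta-method standard error
#' (`SE = 100 * sqrt(SE_Q1^2 + SE_Q5^2)`) and a symmetric 95% CI.
#'
#' @inheritParams age_standardized_ns
#' @param horizon evaluation time in years.
#' @param quintiles the two quintiles compared, default `c(1, 5)`.
#' @return Object of class `deprivation_gap`.
#' @export
deprivation_gap <- function(cohort, lt, horizon = 5,
                            age_breaks = c(15, 45, 55, 65, 75, Inf),
                            weights = c(0.07, 0.12, 0.23, 0.29, 0.29),
                            quintiles = c(1, 5), step = 1 / 52) {
  if (!"quintile" %in% names(cohort))
    stop("cohort needs a quintile column")
  sub1 <- cohort[cohort$quintile == quintiles[1], , drop = FALSE]
  sub5 <- cohort[cohort$quintile == quintiles[2], , drop = FALSE]
  if (nrow(sub1) == 0 || nrow(sub5) == 0)
    stop("cohort lacks members of quintile ", quintiles[1], " or ",
         quintiles[2])
  et <- sort(unique(c(horizon, pretty(c(0, horizon)))))
  et <- et[et >= 0 & et <= horizon]
  f1 <- age_standardized_ns(sub1, lt, eval_times = et, age_breaks = age_breaks,
                            weights = weights, step = step)
  f5 <- age_standardized_ns(sub5, lt, eval_times = et, age_breaks = age_breaks,
                            weights = weights, step = step)
  if (!(horizon %in% f1$time) || !(horizon %in% f5$time))
    stop("horizon beyond the support of the quintile curves")
  i1 <- match(horizon, f1$time); i5 <- match(horizon, f5$time)
  gap <- 100 * (f1$ns[i1] - f5$ns[i5])
  se <- 100 * sqrt(f1$ns_var[i1] + f5$ns_var[i5])
  structure(list(gap = gap, se = se, ci = gap + c(-1.96, 1.96) * se,
                 horizon = horizon, quintiles = quintiles,
                 asns = c(f1$ns[i1], f5$ns[i5]),
                 n = c(nrow(sub1), nrow(sub5)),
                 fits = list(f1, f5)),
            class = "deprivation_gap")
}

#' @export
print.deprivation_gap <- function(x, ...) {
  cat(sprintf("%g-year deprivation gap (Q%d - Q%d): %.2f pp (95%% CI %.2f; %.2f)\n",
              x$horizon, x$quintiles[1], x$quintiles[2], x$gap,
              x$ci[1], x$ci[2]))
  cat(sprintf("  ASNS Q%d = %.3f (n = %d), ASNS Q%d = %.3f (n = %d)\n",
              x$quintiles[1], x$asns[1], x$n[1],
              x$quintiles[2], x$asns[2], x$n[2]))
  invisible(x)
}
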