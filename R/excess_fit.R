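#' Penalized-spline excess mortality hazard regression
#'
#' Fits the relative-survival decomposition `lambda = lambda_E(t, age, EDI)
#' + lambda_P(age + t, year + t, z)` by maximizing the penalized
#' log-likelihood
#' \deqn{\ell_{pen}(\beta) = \sum_i [\delta_i \log(\lambda_E(T_i) +
#'   \lambda_{Pi}(T_i)) - \Lambda_E(T_i)] - \tfrac12 \sum_m s_m \beta' P_m
#'   \beta,}
#' with `log lambda_E` a tensor-product B-spline in follow-up time and age
#' (form 1), plus a smooth (or linear) EDI term (form 2), plus a
#' time-by-EDI tensor (form 3), or a full three-way tensor (form 4).  The
#' expected hazard `lambda_P` is a fixed offset read from the life table at
#' each subject's exit time.  `Lambda_E` is computed by fixed-order
#' Gauss-Legendre quadrature per subject; smoothing multipliers are chosen
#' by corrected-AIC minimization over a log-scale grid (coordinate-wise,
#' coarse-then-refine); the coefficient covariance is the inverse penalized
#' observed information and the effective degrees of freedom (EDF) is
#' `trace(H_pen^-1 H_unpen)`.
#'
#' @param cohort data.frame with `sex`, `age_dx`, `year_dx`, `region`,
#'   `edi`, `time`, `status` (+ `quintile` if `lt` is stratified).
#' @param lt a [life_table()] supplying the expected hazard.
#' @param form deprivation-effect form: 1 none, 2 proportional,
#'   3 time-dependent, 4 time- and/or age-dependent (three-way tensor).
#' @param config an [excess_basis_config()].
#' @param lambda optional fixed smoothing multipliers (one per smoothing
#'   group, natural scale); skips the AICc search.  `lambda = 0` gives the
#'   unpenalized fit.
#' @param smooth_init optional log10 multipliers warm-starting the leading
#'   smoothing groups (those groups are then only refined locally, not
#'   scanned coarsely) -- used by [select_model()] to share the baseline
#'   smoothing across nested forms.
#' @return Object of class `excess_fit`.
#' @export
fit_excess_hazard <- function(cohort, lt, form = 1,
                              config = excess_basis_config(),
                              lambda = NULL, smooth_init = NULL) {
  validate_cohort(cohort)
  stopifnot(inherits(lt, "life_table"), form %in% 1:4)
  if (form >= 2 && !"edi" %in% names(cohort))
    stop("forms 2-4 need an edi column in the cohort")
  if (lt$stratified && !"quintile" %in% names(cohort))
    stop("life table is deprivation-stratified: cohort needs a quintile column")
  n <- nrow(cohort)
  if (n == 0) stop("empty cohort")

  ## truncate modelling follow-up
  tcap <- config$t_trunc
  T_i <- pmin(cohort$time, tcap)
  d_i <- ifelse(cohort$time <= tcap, cohort$status, 0L)
  edi <- if ("edi" %in% names(cohort)) cohort$edi else rep(0, n)
  age <- cohort$age_dx

  ## expected hazard at exit (offset) for events
  quint <- if (lt$stratified) cohort$quintile else NULL
  lamP_T <- lookup_rate(lt, cohort$sex, cohort$region,
                        current_age = age + T_i,
                        current_year = cohort$year_dx + T_i,
                        quintile = quint)

  spec <- build_spec(form, t = T_i[d_i == 1], age = age, edi = edi,
                     config = config)
  pen <- build_penalties(spec, tie_margins = config$tie_margins)
  n_events <- sum(d_i == 1)
  if (n_events < 5) stop("too few events (", n_events, ") to fit")
  dat <- excess_fit_data(T_i, d_i, age, edi, lamP_T, spec, config)

  ## crude excess-rate initialisation on the first block's constant direction
  expd <- sum(cumulative_expected_hazard(lt, cohort$sex, cohort$region,
                                         age, cohort$year_dx, T_i,
                                         quintile = quint))
  crude <- max(n_events - expd, 0.05 * n_events + 1e-3) / max(sum(T_i), 1e-9)
  beta0 <- numeric(pen$p)
  beta0[(pen$offsets[1] + 1):(pen$offsets[1] + pen$block_cols[1])] <- log(crude)

  search <- is.null(lambda)
  if (!search) {
    lambda <- rep_len(lambda, max(pen$groups))
    P <- assemble_penalty(pen, lambda)
    fit <- newton_fit(beta0, dat, P)
    if (!fit$converged) stop("excess-hazard fit did not converge: ",
                             fit$message)
  } else {
    ng <- max(pen$groups)
    logs_init <- NULL; coarse <- NULL
    if (!is.null(smooth_init)) {
      k <- min(length(smooth_init), ng)
      logs_init <- rep(1, ng); logs_init[seq_len(k)] <- smooth_init[seq_len(k)]
      coarse <- rep(TRUE, ng); coarse[seq_len(k)] <- FALSE
    }
    sel <- aicc_search(beta0, dat, pen, config, logs_init = logs_init,
                       coarse_groups = coarse)
    lambda <- sel$lambda
    fit <- sel$fit
    P <- assemble_penalty(pen, lambda)
  }

  ## information matrices at the optimum
  info <- excess_loglik(fit$beta, dat, P, what = "all")
  Hu <- -info$hess_unpen
  Hp <- Hu + P
  V <- chol2inv(safe_chol(Hp))
  edf <- sum(diag(V %*% Hu))
  ll <- info$ll
  structure(list(coefficients = fit$beta, V = V, edf = edf,
                 loglik = ll, loglik_pen = info$ll - 0.5 * sum(fit$beta * (P %*% fit$beta)),
                 aicc = aicc_value(ll, edf, n_events),
                 form = form, spec = spec, pen = pen, lambda = lambda,
                 n = n, n_events = n_events, config = config,
                 converged = fit$converged, iterations = fit$iter,
                 edi_range = range(edi), age_range = range(age),
                 call = match.call()),
            class = "excess_fit")
}

## Event-time and quadrature design matrices for the likelihood.  The
## log-hazard spline is only C^2 at its interior time knots, so the
## cumulative hazard is integrated by Gauss-Legendre per inter-knot piece
## (the integrand is analytic within each piece).
excess_fit_data <- function(T_i, d_i, age, edi, lamP_T, spec, config) {
  n <- length(T_i)
  ev <- which(d_i == 1)
  X_ev <- build_design(spec, T_i[ev], age[ev], edi[ev], warn = FALSE)
  gl <- gauss_legendre(config$gl_nodes)
  kts <- sort(config$time_knots[config$time_knots > 0 &
                                config$time_knots < config$t_trunc])
  lo_p <- c(0, kts); up_p <- c(kts, Inf)
  qt_list <- list(); qw_list <- list(); subj_list <- list()
  for (pp in seq_along(lo_p)) {
    a <- pmin(lo_p[pp], T_i); b <- pmin(up_p[pp], T_i)
    half <- (b - a) / 2; mid <- (a + b) / 2
    qt_list[[pp]] <- as.vector(outer(gl$nodes, half) +
                               rep(mid, each = config$gl_nodes))
    qw_list[[pp]] <- as.vector(outer(gl$weights, half))
    subj_list[[pp]] <- rep(seq_len(n), each = config$gl_nodes)
  }
  tq <- unlist(qt_list); wq <- unlist(qw_list); subj <- unlist(subj_list)
  keep <- wq > 0
  tq <- tq[keep]; wq <- wq[keep]; subj <- subj[keep]
  X_q <- build_design(spec, tq, age[subj], edi[subj], warn = FALSE)
  list(X_ev = X_ev, lamP_ev = lamP_T[ev], X_q = X_q, wq = wq,
       n_events = length(ev), n = n)
}

## reconstruct the likelihood data of an existing fit (for diagnostics and
## tests probing the score/Hessian)
rebuild_fit_data <- function(cohort, lt, fit) {
  config <- fit$config
  T_i <- pmin(cohort$time, config$t_trunc)
  d_i <- ifelse(cohort$time <= config$t_trunc, cohort$status, 0L)
  edi <- if ("edi" %in% names(cohort)) cohort$edi else rep(0, nrow(cohort))
  quint <- if (lt$stratified) cohort$quintile else NULL
  lamP_T <- lookup_rate(lt, cohort$sex, cohort$region,
                        current_age = cohort$age_dx + T_i,
                        current_year = cohort$year_dx + T_i,
                        quintile = quint)
  excess_fit_data(T_i, d_i, cohort$age_dx, edi, lamP_T, fit$spec, config)
}

assemble_penalty <- function(pen, lambda) {
  P <- matrix(0, pen$p, pen$p)
  for (j in seq_along(pen$pens))
    P <- P + lambda[pen$groups[j]] * pen$pens[[j]]
  P
}

safe_chol <- function(M) {
  for (r in c(0, 10^seq(-10, -2))) {
    R <- tryCatch(chol(M + r * mean(diag(M)) * diag(nrow(M))),
                  error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stop("information matrix is not positive definite")
}

## penalized log-likelihood, score and Hessian
excess_loglik <- function(beta, dat, P, what = "all") {
  eta_ev <- drop(dat$X_ev %*% beta)
  eta_q <- drop(dat$X_q %*% beta)
  eta_ev <- pmin(eta_ev, 30); eta_q <- pmin(eta_q, 30)
  lamE_ev <- exp(eta_ev)
  h <- lamE_ev + dat$lamP_ev
  cumq <- dat$wq * exp(eta_q)
  ll <- sum(log(h)) - sum(cumq)
  if (what == "ll") return(list(ll = ll))
  mu <- lamE_ev / h
  grad <- drop(crossprod(dat$X_ev, mu)) - drop(crossprod(dat$X_q, cumq))
  w1 <- mu * (1 - mu)
  H <- crossprod(dat$X_ev * sqrt(w1)) - crossprod(dat$X_q * sqrt(cumq))
  list(ll = ll, grad = grad, hess_unpen = H,
       ll_pen = ll - 0.5 * sum(beta * (P %*% beta)),
       grad_pen = grad - drop(P %*% beta),
       hess_pen = H - P)
}

## damped Newton maximization of the penalized log-likelihood
newton_fit <- function(beta0, dat, P, maxit = 100, tol = 1e-6,
                       restarts = 5) {
  try_one <- function(beta) {
    st <- excess_loglik(beta, dat, P)
    for (it in seq_len(maxit)) {
      g <- st$grad_pen
      if (max(abs(g)) < tol * max(1, abs(st$ll_pen)))
        return(list(beta = beta, converged = TRUE, iter = it,
                    ll_pen = st$ll_pen))
      H <- -st$hess_pen
      step <- NULL
      for (r in c(0, 10^seq(-8, 2))) {
        R <- tryCatch(chol(H + r * (1 + mean(abs(diag(H)))) * diag(nrow(H))),
                      error = function(e) NULL)
        if (!is.null(R)) { step <- backsolve(R, forwardsolve(t(R), g)); break }
      }
      if (is.null(step))
        return(list(beta = beta, converged = FALSE, iter = it,
                    message = "singular Hessian"))
      alpha <- 1; improved <- FALSE
      for (ls in 1:30) {
        cand <- beta + alpha * step
        stc <- excess_loglik(cand, dat, P)
        if (is.finite(stc$ll_pen) && stc$ll_pen > st$ll_pen - 1e-12) {
          beta <- cand; st <- stc; improved <- TRUE; break
        }
        alpha <- alpha / 2
      }
      if (!improved)
        return(list(beta = beta, converged = max(abs(st$grad_pen)) <
                      1e-4 * max(1, abs(st$ll_pen)),
                    iter = it, ll_pen = st$ll_pen,
                    message = "line search stalled"))
    }
    list(beta = beta, converged = FALSE, iter = maxit,
         message = "iteration limit reached", ll_pen = st$ll_pen)
  }
  fit <- try_one(beta0)
  k <- 0
  while (!fit$converged && k < restarts) {
    k <- k + 1
    jitter <- 0.05 * k * rep_len(c(1, -1), length(beta0)) *
      seq_along(beta0) / length(beta0)
    fit <- try_one(beta0 + jitter)
  }
  fit
}

#' Corrected Akaike information criterion of an excess-hazard fit
#'
#' `AICc = -2 l + 2 EDF + 2 EDF (EDF + 1) / (n_events - EDF - 1)`, with `l`
#' the unpenalized log-likelihood at the penalized optimum and EDF the
#' effective degrees of freedom.
#'
#' @param fit an `excess_fit`.
#' @return Numeric AICc.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "excess_fit"))
  aicc_value(fit$loglik, fit$edf, fit$n_events)
}

aicc_value <- function(ll, edf, n_events) {
  if (n_events <= edf + 1)
    stop("AICc undefined: n_events (", n_events, ") <= EDF + 1 (",
         format(edf + 1), ")")
  -2 * ll + 2 * edf + 2 * edf * (edf + 1) / (n_events - edf - 1)
}

## coordinate-wise AICc minimization over log10 smoothing multipliers:
## coarse grid first, then local refinement to 0.5 resolution, warm-started.
aicc_search <- function(beta0, dat, pen, config, logs_init = NULL,
                        coarse_groups = NULL) {
  ng <- max(pen$groups)
  logs <- if (is.null(logs_init)) rep(1, ng) else rep_len(logs_init, ng)
  if (is.null(coarse_groups)) coarse_groups <- rep(TRUE, ng)
  beta <- beta0
  eval_at <- function(logs, beta_start) {
    P <- assemble_penalty(pen, 10^logs)
    fit <- newton_fit(beta_start, dat, P, restarts = 2)
    if (!fit$converged) return(list(aicc = Inf, fit = fit))
    info <- excess_loglik(fit$beta, dat, P, what = "all")
    Hu <- -info$hess_unpen
    Vp <- tryCatch(chol2inv(safe_chol(Hu + P)), error = function(e) NULL)
    if (is.null(Vp)) return(list(aicc = Inf, fit = fit))
    edf <- sum(diag(Vp %*% Hu))
    a <- tryCatch(aicc_value(info$ll, edf, dat$n_events),
                  error = function(e) Inf)
    list(aicc = a, fit = fit)
  }
  best <- eval_at(logs, beta)
  if (is.finite(best$aicc)) beta <- best$fit$beta
  passes <- if (ng > 1) 2 else 1
  for (pass in seq_len(passes)) {
    changed <- FALSE
    for (gidx in seq_len(ng)) {
      ## full coarse scan on the first pass only (and only for groups not
      ## already warm-started from a simpler form); later passes refine
      cand_coarse <- if (pass == 1 && coarse_groups[gidx])
        setdiff(config$grid_log10, logs[gidx]) else numeric(0)
      for (v in cand_coarse) {
        trial <- logs; trial[gidx] <- v
        res <- eval_at(trial, beta)
        if (res$aicc < best$aicc - 1e-9) {
          best <- res; logs <- trial; beta <- res$fit$beta; changed <- TRUE
        }
      }
      for (v in logs[gidx] + c(-1, 1, -0.5, 0.5)) {
        v <- max(min(v, max(config$grid_log10)), min(config$grid_log10))
        if (abs(v - logs[gidx]) < 1e-9) next
        trial <- logs; trial[gidx] <- v
        res <- eval_at(trial, beta)
        if (res$aicc < best$aicc - 1e-9) {
          best <- res; logs <- trial; beta <- res$fit$beta; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  if (!is.finite(best$aicc))
    stop("smoothing search failed: no converged fit with finite AICc")
  list(lambda = 10^logs, fit = best$fit, aicc = best$aicc)
}

#' Fit all four deprivation-effect forms and select by corrected AIC
#'
#' Fits forms 1 (no EDI effect), 2 (proportional), 3 (time-dependent) and
#' 4 (time- and/or age-dependent) and returns the minimum-AICc fit.  Ties
#' within 1e-6 go to the lower (more parsimonious) form.  Forms that fail
#' to fit are recorded and excluded with a warning.
#'
#' @inheritParams fit_excess_hazard
#' @param forms subset of 1:4 to consider.
#' @return Object of class `excess_selection`: list with `best` (the
#'   selected `excess_fit`), `form` (its code), `aicc` (named vector over
#'   forms, `NA` for failures), `fits` (all successful fits), `errors`.
#' @export
select_model <- function(cohort, lt, config = excess_basis_config(),
                         forms = 1:4) {
  fits <- list(); errs <- list()
  av <- rep(NA_real_, length(forms)); names(av) <- paste0("form", forms)
  base_logs <- NULL
  for (i in seq_along(forms)) {
    f <- forms[i]
    ## forms 2-3 extend form 1's baseline tensor: reuse its selected
    ## baseline smoothing as a warm start
    hint <- if (f %in% 2:3 && !is.null(base_logs)) base_logs else NULL
    res <- tryCatch(fit_excess_hazard(cohort, lt, form = f, config = config,
                                      smooth_init = hint),
                    error = function(e) e)
    if (!inherits(res, "error") && f == 1 && length(res$lambda) >= 1)
      base_logs <- log10(res$lambda[1])
    if (inherits(res, "error")) {
      errs[[paste0("form", f)]] <- conditionMessage(res)
      warning("form ", f, " failed: ", conditionMessage(res))
    } else {
      fits[[paste0("form", f)]] <- res
      av[i] <- res$aicc
    }
  }
  if (all(is.na(av))) stop("all candidate forms failed to fit")
  ok <- which(!is.na(av))
  best_i <- ok[which(av[ok] <= min(av[ok]) + 1e-6)][1]
  structure(list(best = fits[[names(av)[best_i]]], form = forms[best_i],
                 aicc = av, fits = fits, errors = errs),
            class = "excess_selection")
}

#' @export
print.excess_selection <- function(x, ...) {
  cat("Excess-hazard model selection (corrected AIC)\n")
  tab <- data.frame(form = names(x$aicc), aicc = x$aicc,
                    selected = ifelse(seq_along(x$aicc) == which(
                      names(x$aicc) == paste0("form", x$form)), "*", ""))
  print(format(tab, digits = 6), row.names = FALSE)
  invisible(x)
}
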