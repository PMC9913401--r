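## small shared fixture: proportional-effect world, moderate n
fix_env <- new.env()
fixture_fit <- function() {
  if (is.null(fix_env$gc)) {
    fix_env$cfg <- sim_config(n = 2500, edi_form = 2,
                              log_ehr_p90_p10 = log(1.5))
    fix_env$tt <- gen_truth_tables(fix_env$cfg)
    fix_env$gc <- gen_cohort(fix_env$cfg, fix_env$tt$stratified, seed = 31)
  }
  fix_env
}

test_that("corrected AIC follows its closed form", {
  expect_equal(depnetsurv:::aicc_value(-100, 4, 50), 208 + 40 / 45,
               tolerance = 1e-12)
  expect_equal(depnetsurv:::aicc_value(-100, 0, 50), 200, tolerance = 1e-12)
  expect_error(depnetsurv:::aicc_value(-100, 49, 50), "undefined")
  f <- fixture_fit()
  fit <- suppressMessages(fit_excess_hazard(f$gc$cohort, f$tt$stratified,
                                            form = 1, lambda = 10))
  ## formula recomputed independently from the stored components
  expect_equal(aicc(fit),
               -2 * fit$loglik + 2 * fit$edf +
                 2 * fit$edf * (fit$edf + 1) / (fit$n_events - fit$edf - 1),
               tolerance = 1e-10)
})

test_that("analytic score matches central finite differences", {
  f <- fixture_fit()
  co <- f$gc$cohort[1:400, ]
  fit <- suppressMessages(fit_excess_hazard(co, f$tt$stratified, form = 2,
                                            lambda = 5))
  ## rebuild the internal data and probe the score at a random point
  set.seed(77)
  p <- length(fit$coefficients)
  beta <- fit$coefficients + rnorm(p, 0, 0.3)
  P <- depnetsurv:::assemble_penalty(fit$pen, rep(5, max(fit$pen$groups)))
  dat <- depnetsurv:::rebuild_fit_data(co, f$tt$stratified, fit)
  st <- depnetsurv:::excess_loglik(beta, dat, P)
  eps <- 1e-5
  for (j in sample(p, 6)) {
    b1 <- beta; b1[j] <- b1[j] + eps
    b2 <- beta; b2[j] <- b2[j] - eps
    fd <- (depnetsurv:::excess_loglik(b1, dat, P, "ll")$ll -
           depnetsurv:::excess_loglik(b2, dat, P, "ll")$ll) / (2 * eps)
    expect_equal(st$grad[j], fd, tolerance = 1e-5 * max(1, abs(fd)))
  }
})

test_that("nested unpenalized forms have ordered likelihoods", {
  f <- fixture_fit()
  co <- f$gc$cohort[1:1200, ]
  cfgb <- excess_basis_config(time_knots = numeric(0), age_df = 0, edi_df = 0,
                              form4_interior = c(0, 0, 0))
  ll <- vapply(1:4, function(fm)
    suppressMessages(fit_excess_hazard(co, f$tt$stratified, form = fm,
                                       config = cfgb, lambda = 0))$loglik,
    numeric(1))
  expect_true(all(diff(ll) > -1e-3))
})

test_that("doubling quadrature nodes leaves the likelihood unchanged", {
  f <- fixture_fit()
  co <- f$gc$cohort[1:1500, ]
  f1 <- suppressMessages(fit_excess_hazard(co, f$tt$stratified, form = 2,
         config = excess_basis_config(gl_nodes = 6), lambda = c(10, 10)))
  f2 <- suppressMessages(fit_excess_hazard(co, f$tt$stratified, form = 2,
         config = excess_basis_config(gl_nodes = 12), lambda = c(10, 10)))
  expect_lt(abs(f2$loglik - f1$loglik) / abs(f1$loglik), 1e-6)
})

test_that("EHR algebra: reference point, form-1 flatness, linear slope", {
  f <- fixture_fit()
  fit1 <- suppressMessages(fit_excess_hazard(f$gc$cohort, f$tt$stratified,
                                             form = 1, lambda = 10))
  cv1 <- ehr_vs_edi(fit1, t_fixed = 1, age_fixed = 65,
                    edi_grid = seq(-5, 5, by = 1))
  expect_equal(cv1$ehr, rep(1, nrow(cv1)), tolerance = 1e-10)

  cfg_lin <- excess_basis_config(edi_linear = TRUE)
  fit2 <- suppressMessages(fit_excess_hazard(f$gc$cohort, f$tt$stratified,
                                             form = 2, config = cfg_lin,
                                             lambda = 10))
  ## the EDI column is the single last coefficient; log EHR is linear with
  ## that slope
  slope <- fit2$coefficients[length(fit2$coefficients)]
  cv2 <- ehr_vs_edi(fit2, t_fixed = 1, age_fixed = 65, ref_edi = -3.9,
                    edi_grid = c(-3.9, 0, 4.4))
  expect_equal(log(cv2$ehr), slope * (c(-3.9, 0, 4.4) + 3.9),
               tolerance = 1e-10)
  ## EHR = 1 with a zero-width CI at the reference
  expect_equal(cv2$ehr[1], 1, tolerance = 1e-12)
  expect_equal(cv2$hi[1] - cv2$lo[1], 0, tolerance = 1e-12)
  ## time-profile of a proportional fit is flat
  tp <- ehr_p90_p10_over_time(fit2, time_grid = c(0.5, 2, 4), ages = 65)
  expect_equal(tp$ehr, rep(tp$ehr[1], 3), tolerance = 1e-10)
  ## recovered effect is near the simulated EHR p90/p10 = 1.5
  expect_equal(tp$ehr[1], 1.5, tolerance = 0.12)
})

test_that("duplicating every record leaves the unpenalized optimum fixed", {
  f <- fixture_fit()
  co <- f$gc$cohort[1:800, ]
  cfgs <- excess_basis_config(time_knots = numeric(0), age_df = 0, edi_df = 0)
  fa <- suppressMessages(fit_excess_hazard(co, f$tt$stratified, form = 2,
                                           config = cfgs, lambda = 0))
  fb <- suppressMessages(fit_excess_hazard(rbind(co, co), f$tt$stratified,
                                           form = 2, config = cfgs,
                                           lambda = 0))
  expect_equal(fb$coefficients, fa$coefficients, tolerance = 1e-4)
  expect_equal(fb$loglik, 2 * fa$loglik, tolerance = 1e-4)
  expect_false(isTRUE(all.equal(fb$aicc, 2 * fa$aicc)))
})

test_that("EHR is invariant to affine rescaling of the EDI covariate", {
  f <- fixture_fit()
  co <- f$gc$cohort[1:1200, ]
  cfgs <- excess_basis_config(time_knots = numeric(0), age_df = 0, edi_df = 0)
  fa <- suppressMessages(fit_excess_hazard(co, f$tt$stratified, form = 2,
                                           config = cfgs, lambda = 0))
  co2 <- co; co2$edi <- 2 * co$edi + 10
  fb <- suppressMessages(fit_excess_hazard(co2, f$tt$stratified, form = 2,
                                           config = cfgs, lambda = 0))
  g1 <- ehr_vs_edi(fa, 1, 65, ref_edi = -3.9, edi_grid = c(0, 4.4))
  g2 <- ehr_vs_edi(fb, 1, 65, ref_edi = 2 * (-3.9) + 10,
                   edi_grid = 2 * c(0, 4.4) + 10)
  expect_equal(g2$ehr, g1$ehr, tolerance = 1e-5)
})

test_that("model selection separates argmin and breaks ties to parsimony", {
  ## argmin logic probed through the selection object structure
  f <- fixture_fit()
  co <- f$gc$cohort[1:1500, ]
  sel <- suppressMessages(suppressWarnings(
    select_model(co, f$tt$stratified,
                 config = excess_basis_config(grid_log10 = c(0, 3)))))
  expect_s3_class(sel$best, "excess_fit")
  expect_equal(sel$form, as.integer(sub("form", "", names(
    which.min(sel$aicc)))))
  expect_true(all(is.finite(sel$aicc[!is.na(sel$aicc)])))
})

test_that("extrapolation beyond the basis support warns and clamps", {
  f <- fixture_fit()
  fit <- suppressMessages(fit_excess_hazard(f$gc$cohort[1:600, ],
                                            f$tt$stratified, form = 2,
                                            lambda = 10))
  expect_warning(predict(fit, data.frame(time = 1, age = 64, edi = 500)),
                 "outside the basis support")
})
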