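test_that("joint fit recovers the generating parameters on simulated data", {
  sim <- toy_panel(250, 5, seed = 61)
  trans <- build_transitions(sim$panel, toy_spec())
  truth <- pack_params(toy_params(), toy_spec())
  fit <- fit_jmtrans(trans, rule = quad_rule(7), se = TRUE)
  expect_s3_class(fit, "jmtrans_fit")
  expect_true(fit$convergence$converged)
  se <- sqrt(diag(fit$vcov))
  # every parameter within 3.5 sandwich SEs of truth on one replicate
  expect_true(all(abs(fit$theta - truth) < 3.5 * se))
  # sandwich covariance is symmetric PSD and SEs are its root diagonal
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-10)
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-10)
  expect_equal(fit$H, t(fit$H), tolerance = 1e-8)
  expect_equal(fit$J, t(fit$J), tolerance = 1e-8)
  # Wald table reports natural-scale rows for every parameter
  expect_true(all(c("estimate", "se", "p") %in% names(fit$table)))
  expect_false(any(is.na(fit$table$se)))
})

test_that("initialization at the truth reaches the same optimum as the default start", {
  sim <- toy_panel(60, 5, seed = 71)
  trans <- build_transitions(sim$panel, toy_spec())
  rule <- quad_rule(7)
  fit_default <- fit_jmtrans(trans, rule = rule, se = FALSE)
  fit_truth <- fit_jmtrans(trans, init = toy_params(), rule = rule, se = FALSE)
  expect_lt(abs(fit_default$loglik - fit_truth$loglik), 1e-5)
  expect_equal(fit_default$theta, fit_truth$theta, tolerance = 1e-2)
})

test_that("the profile is locally concave around the maximizer", {
  sim <- toy_panel(50, 5, seed = 81)
  trans <- build_transitions(sim$panel, toy_spec())
  rule <- quad_rule(7)
  fit <- fit_jmtrans(trans, rule = rule, se = FALSE)
  spec <- toy_spec()
  cl0 <- composite_loglik(trans, fit$params, rule)$value
  set.seed(5)
  for (k in 1:5) {
    dir <- rnorm(length(fit$theta))
    dir <- dir / sqrt(sum(dir^2))
    for (eps in c(0.05, 0.1)) {
      up <- composite_loglik(trans, unpack_params(fit$theta + eps * dir, spec), rule)$value
      dn <- composite_loglik(trans, unpack_params(fit$theta - eps * dir, spec), rule)$value
      expect_lt(up, cl0 + 1e-8)
      expect_lt(dn, cl0 + 1e-8)
    }
  }
})

test_that("score vanishes at the maximizer", {
  sim <- toy_panel(40, 4, seed = 91)
  trans <- build_transitions(sim$panel, toy_spec())
  rule <- quad_rule(7)
  fit <- fit_jmtrans(trans, rule = rule, se = FALSE)
  sc <- composite_score(trans, fit$theta, rule)
  expect_lt(max(abs(sc)) / trans$n_subjects,
            1e-4 * (1 + abs(fit$loglik) / trans$n_subjects))
})

test_that("Wald test basics: null statistic, reordering invariance", {
  sim <- toy_panel(80, 5, seed = 101)
  trans <- build_transitions(sim$panel, toy_spec())
  fit <- fit_jmtrans(trans, rule = quad_rule(5), se = TRUE)
  # constraint at the estimate itself
  w0 <- wald_test(fit, c(B.x = unname(fit$theta["B.x"])))
  expect_equal(w0$statistic, 0, tolerance = 1e-12)
  expect_equal(w0$p, 1)
  # invariance to the ordering of the constrained subset
  c1 <- c(B.x = 0, O.x = 0)
  c2 <- c(O.x = 0, B.x = 0)
  expect_equal(wald_test(fit, c1)$statistic, wald_test(fit, c2)$statistic,
               tolerance = 1e-10)
  expect_equal(wald_test(fit, c1)$df, 2)
  expect_error(wald_test(fit, c(nope = 0)), "packed parameter")
})

test_that("composite LRT: zero for identical models, plain LRT when H = J", {
  fitA <- list(theta = c(a = 1, b = 2), loglik = -10, H = diag(2), J = diag(2))
  fitB <- list(theta = c(a = 1, b = 2), loglik = -10)
  expect_equal(composite_lrt(fitA, fitB)$statistic, 0)
  expect_equal(composite_lrt(fitA, fitB)$p, 1)

  # H = J on the tested block: weights all 1, so scale 1 and df = #tested
  H <- matrix(c(2, 0.3, 0.1, 0.3, 1.5, 0.2, 0.1, 0.2, 1.8), 3)
  full <- list(theta = c(a = 1, b = 2, c = 0.1), loglik = -8, H = H, J = H)
  null <- list(theta = c(a = 1.1, b = 2.2), loglik = -9.5)
  out <- composite_lrt(full, null)
  expect_equal(out$statistic, 3)
  expect_equal(out$scale, 1, tolerance = 1e-10)
  expect_equal(out$df, 1, tolerance = 1e-10)
  expect_equal(out$p, pchisq(3, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_error(composite_lrt(null, full), "not nested")
})

test_that("composite LRT detects a strong lag effect and accepts a null one", {
  sim <- toy_panel(120, 5, seed = 111)
  spec_full <- toy_spec()
  trans <- build_transitions(sim$panel, spec_full)
  rule <- quad_rule(5)
  fit_full <- fit_jmtrans(trans, rule = rule, se = TRUE)
  # null model dropping the (truly nonzero) covariate effect from both
  # processes
  spec_null <- joint_spec(
    process_spec("B", "binary", levels = c(0, 1)),
    process_spec("O", "ordinal", levels = 0:2))
  fit_null <- fit_jmtrans(build_transitions(sim$panel, spec_null),
                          rule = rule, se = FALSE)
  out <- composite_lrt(fit_full, fit_null)
  expect_gt(out$statistic, 0)
  expect_lt(out$p, 0.05)
  expect_true(all(out$weights >= 0))
})

test_that("two-stage estimation tracks the joint fit and reduces correctly", {
  sim <- toy_panel(150, 5, seed = 121)
  trans <- build_transitions(sim$panel, toy_spec())
  rule <- quad_rule(7)
  ts <- two_stage_fit(trans, rule = rule)
  expect_s3_class(ts, "jmtrans_two_stage")
  # stage-1 fixed effects close to the generating values
  truth <- toy_params()
  expect_equal(ts$params$processes$B$beta[["x"]],
               truth$processes$B$beta[["x"]], tolerance = 0.5)
  expect_equal(ts$params$processes$O$gamma, truth$processes$O$gamma,
               tolerance = 0.5)
  # stage-2 correlation is positive with a sane CI for rho = 0.5
  expect_gt(ts$correlations$correlation[1], 0)
  expect_true(ts$correlations$lower[1] < ts$correlations$upper[1])

  # G = 1 reduces to the univariate ML fit
  spec1 <- joint_spec(process_spec("B", "binary", levels = c(0, 1),
                                   covariates = "x"))
  pan1 <- panel_data(as.data.frame(sim$panel)[c("subject", "visit", "B", "x")],
                     spec1)
  ts1 <- two_stage_fit(pan1, spec1, rule = rule)
  uni <- jmtrans:::fit_univariate(build_transitions(pan1, spec1), rule)
  expect_equal(ts1$params$processes$B$alpha, uni$params$processes$B$alpha,
               tolerance = 1e-8)
  expect_null(ts1$correlations)
})

test_that("zero true correlation is covered by the stage-2 interval", {
  sim <- toy_panel(200, 5, seed = 131, rho = 0)
  ts <- two_stage_fit(build_transitions(sim$panel, toy_spec()),
                      rule = quad_rule(7))
  expect_true(ts$correlations$lower[1] <= 0 && 0 <= ts$correlations$upper[1])
})

test_that("degenerate random effects are flagged as a boundary fit", {
  # data generated without any random effects
  par0 <- toy_params()
  par0$Sigma <- diag(1e-12, 2)
  cfg <- scenario_config(80, 5, 141, toy_spec(), par0,
                         covariate_gen = function(n) data.frame(x = runif(n, 0, 2)),
                         init = list(B = c(0.5, 0.5), O = c(0.4, 0.3, 0.3)))
  trans <- build_transitions(simulate_panel(cfg)$panel, toy_spec())
  expect_warning(fit <- fit_jmtrans(trans, rule = quad_rule(5), se = TRUE),
                 "boundary")
  expect_true(fit$convergence$boundary)
  expect_null(fit$vcov)
})
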