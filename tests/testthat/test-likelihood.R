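test_that("pair likelihood matches dense-grid trapezoid integration", {
  sim <- toy_panel(5, 3, seed = 21)
  trans <- build_transitions(sim$panel, toy_spec())
  par <- toy_params()
  oracle <- trapezoid_pair_loglik(trans, "B", "O", par, npts = 400)
  agq <- pair_conditional_loglik(trans, "B", "O", par, quad_rule(15))
  expect_equal(agq, oracle, tolerance = 1e-6)
})

test_that("adaptive and prior-centered quadrature agree", {
  sim <- toy_panel(30, 5, seed = 8)
  trans <- build_transitions(sim$panel, toy_spec())
  par <- toy_params()
  a <- pair_conditional_loglik(trans, "B", "O", par, quad_rule(15))
  b <- pair_conditional_loglik(trans, "B", "O", par, quad_rule(25, adaptive = FALSE))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("near-degenerate random effects recover the fixed-effects likelihood", {
  sim <- toy_panel(8, 4, seed = 13)
  spec <- toy_spec()
  trans <- build_transitions(sim$panel, spec)
  par <- toy_params()
  par$Sigma <- diag(1e-10, 2)
  ll <- pair_conditional_loglik(trans, "B", "O", par, quad_rule(15))
  # independent sum of conditional log-densities at b = 0
  ll0 <- 0
  for (g in c("B", "O")) {
    pd <- trans$processes[[g]]
    prep <- jmtrans:::prepare_eval(trans, par)
    ld <- jmtrans:::logdens_eta(spec$processes[[g]], prep[[g]]$parts,
                                pd, matrix(prep[[g]]$ef))
    ll0 <- ll0 + sum(ld)
  }
  expect_equal(ll, ll0, tolerance = 1e-5)
})

test_that("zero correlation factorizes into univariate integrated likelihoods", {
  sim <- toy_panel(12, 4, seed = 17, rho = 0)
  trans <- build_transitions(sim$panel, toy_spec())
  par <- toy_params(rho = 0)
  rule <- quad_rule(15)
  pair <- pair_conditional_loglik(trans, "B", "O", par, rule)
  uni <- sum(vapply(c("B", "O"), function(g) {
    sub <- jmtrans:::subset_trans(trans, g)
    parg <- param_template(sub$spec)
    parg$processes[[g]] <- par$processes[[g]]
    parg$Sigma <- par$Sigma[match(g, c("B", "O")), match(g, c("B", "O")), drop = FALSE]
    full_conditional_loglik(sub, parg, rule)
  }, 0))
  expect_equal(pair, uni, tolerance = 1e-8)
})

test_that("pairwise composite equals the full likelihood for two processes", {
  sim <- toy_panel(20, 5, seed = 31)
  trans <- build_transitions(sim$panel, toy_spec())
  par <- toy_params()
  rule <- quad_rule(15)
  expect_equal(composite_loglik(trans, par, rule)$value,
               full_conditional_loglik(trans, par, rule),
               tolerance = 1e-10)
})

test_that("composite likelihood sums pairs and is additive over subjects", {
  # four processes: composite = sum over the six pairs
  spec4 <- joint_spec(lapply(1:4, function(i)
    process_spec(paste0("P", i), "binary", levels = c(0, 1))))
  par4 <- param_template(spec4)
  par4$processes$P1$gamma <- 0.5
  par4$processes$P3$gamma <- -0.5
  par4$Sigma <- diag(4) * 0.6 + 0.2
  set.seed(9)
  cfg <- scenario_config(10, 4, 99, spec4, par4,
                         covariate_gen = function(n) data.frame(z = rep(0, n)),
                         init = lapply(1:4, function(i) c(0.5, 0.5)) |>
                           setNames(paste0("P", 1:4)))
  trans <- build_transitions(simulate_panel(cfg)$panel, spec4)
  rule <- quad_rule(9)
  cl <- composite_loglik(trans, par4, rule)
  nms <- paste0("P", 1:4)
  manual <- 0
  for (i in 1:3) for (j in (i + 1):4)
    manual <- manual + pair_conditional_loglik(trans, nms[i], nms[j], par4, rule)
  expect_equal(cl$value, manual, tolerance = 1e-9)
  expect_equal(sum(cl$by_subject), cl$value, tolerance = 1e-9)

  # duplicating every subject doubles the composite log-likelihood
  pan <- as.data.frame(simulate_panel(cfg)$panel)
  pan2 <- rbind(pan, transform(pan, subject = paste0(subject, "_copy")))
  trans2 <- build_transitions(panel_data(pan2, spec4), spec4)
  expect_equal(composite_loglik(trans2, par4, rule)$value, 2 * cl$value,
               tolerance = 1e-8)
})

test_that("full conditional likelihood factorizes under a diagonal covariance", {
  spec3 <- joint_spec(
    process_spec("P1", "binary", levels = c(0, 1)),
    process_spec("P2", "binary", levels = c(0, 1)),
    process_spec("P3", "ordinal", levels = 0:2))
  par3 <- param_template(spec3)
  par3$processes$P1$gamma <- 0.6
  par3$processes$P3$gamma <- -0.4
  par3$Sigma <- diag(c(0.8, 1.2, 0.5))
  cfg <- scenario_config(8, 4, 55, spec3, par3,
                         covariate_gen = function(n) data.frame(z = rep(0, n)),
                         init = list(P1 = c(0.5, 0.5), P2 = c(0.5, 0.5),
                                     P3 = c(0.4, 0.3, 0.3)))
  trans <- build_transitions(simulate_panel(cfg)$panel, spec3)
  rule <- quad_rule(11)
  full <- full_conditional_loglik(trans, par3, rule)
  uni <- sum(vapply(c("P1", "P2", "P3"), function(g) {
    sub <- jmtrans:::subset_trans(trans, g)
    parg <- param_template(sub$spec)
    parg$processes[[g]] <- par3$processes[[g]]
    k <- match(g, names(spec3$processes))
    parg$Sigma <- par3$Sigma[k, k, drop = FALSE]
    full_conditional_loglik(sub, parg, rule)
  }, 0))
  expect_equal(full, uni, tolerance = 1e-8)
})

test_that("full conditional likelihood refuses high-dimensional integrals", {
  spec5 <- joint_spec(lapply(1:5, function(i)
    process_spec(paste0("P", i), "binary", levels = c(0, 1))))
  par5 <- param_template(spec5)
  cfg <- scenario_config(4, 3, 77, spec5, par5,
                         covariate_gen = function(n) data.frame(z = rep(0, n)),
                         init = lapply(1:5, function(i) c(0.5, 0.5)) |>
                           setNames(paste0("P", 1:5)))
  trans <- build_transitions(simulate_panel(cfg)$panel, spec5)
  expect_error(full_conditional_loglik(trans, par5), "<= 4")
})

test_that("quadrature refinement leaves the composite likelihood unchanged", {
  sim <- toy_panel(40, 5, seed = 23)
  trans <- build_transitions(sim$panel, toy_spec())
  par <- toy_params()
  v9 <- composite_loglik(trans, par, quad_rule(9))$value
  v15 <- composite_loglik(trans, par, quad_rule(15))$value
  v21 <- composite_loglik(trans, par, quad_rule(21))$value
  expect_lt(abs(v15 - v9), 1e-6 * abs(v15))
  expect_lt(abs(v21 - v15), 1e-6 * abs(v21))
})

test_that("composite score matches higher-order differentiation", {
  sim <- toy_panel(10, 4, seed = 41)
  trans <- build_transitions(sim$panel, toy_spec())
  spec <- toy_spec()
  par <- toy_params()
  theta <- pack_params(par, spec)
  rule <- quad_rule(9)
  sc <- composite_score(trans, theta, rule)
  # Richardson extrapolation of central differences (independent higher-order
  # oracle for the same derivative)
  rich <- vapply(seq_along(theta), function(j) {
    f <- function(t) {
      th <- theta; th[j] <- t
      composite_loglik(trans, unpack_params(th, spec), rule)$value
    }
    h <- 1e-3 * (1 + abs(theta[j]))
    d1 <- (f(theta[j] + h) - f(theta[j] - h)) / (2 * h)
    d2 <- (f(theta[j] + h / 2) - f(theta[j] - h / 2)) / h
    (4 * d2 - d1) / 3
  }, 0)
  expect_equal(sc, setNames(rich, names(sc)), tolerance = 1e-5)
})

test_that("finite differences are calibrated on an exact quadratic", {
  # same step policy as composite_score, applied to a known gradient
  f <- function(x) sum(c(2, -1, 0.5) * x^2) + sum(x)
  x0 <- c(0.3, -1.2, 4)
  g <- vapply(1:3, function(j) {
    h <- 1e-5 * (1 + abs(x0[j]))
    xp <- xm <- x0
    xp[j] <- x0[j] + h
    xm[j] <- x0[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
  expect_equal(g, 2 * c(2, -1, 0.5) * x0 + 1, tolerance = 1e-6)
})

test_that("count and continuous processes run through both integration routes", {
  spec <- joint_spec(
    process_spec("N", "poisson", covariates = "x", lag_form = "zeger_qaqish"),
    process_spec("Yc", "gaussian", covariates = "x"))
  par <- param_template(spec)
  par$processes$N$alpha <- 0.4
  par$processes$N$beta[] <- 0.3
  par$processes$N$gamma <- 0.5
  par$processes$Yc$alpha <- 1
  par$processes$Yc$beta[] <- -0.5
  par$processes$Yc$gamma <- 0.6
  par$processes$Yc$sigma <- 0.8
  par$Sigma <- matrix(c(0.4, 0.1, 0.1, 0.5), 2)
  cfg <- scenario_config(25, 4, 202, spec, par,
                         covariate_gen = function(n) data.frame(x = runif(n)),
                         init = list(N = function(n) rpois(n, 2),
                                     Yc = function(n) rnorm(n, 1, 1)))
  sim <- simulate_panel(cfg)
  expect_true(all(sim$panel$N >= 0 & sim$panel$N == round(sim$panel$N)))
  trans <- build_transitions(sim$panel, spec)
  a <- pair_conditional_loglik(trans, "N", "Yc", par, quad_rule(15))
  # dense-grid oracle: the prior-centered rule needs far more nodes for the
  # concentrated Poisson/Gaussian integrand, so the trapezoid is the referee
  oracle <- trapezoid_pair_loglik(trans, "N", "Yc", par, npts = 600, span = 10)
  expect_equal(a, oracle, tolerance = 1e-6)
  # per-subject scores sum to the total composite score
  th <- pack_params(par, spec)
  sc <- composite_score(trans, th, quad_rule(9))
  scs <- composite_score(trans, th, quad_rule(9), per_subject = TRUE)
  expect_equal(colSums(scs), sc, tolerance = 1e-6)
  # a short fit runs and improves the criterion
  fit <- fit_jmtrans(trans, init = par, rule = quad_rule(5), se = FALSE,
                     control = list(maxit = 40, restarts = 0))
  expect_gte(fit$loglik, composite_loglik(trans, par, quad_rule(5))$value - 1e-6)
})
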