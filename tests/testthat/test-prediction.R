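# the transition-table fixtures below rebuild the published dementia-cohort
# models from their printed coefficients (intercepts, increments, lag and
# education effects) plus slopes recovered by logit inversion of single
# printed cells; test-acceptance.R carries the cell-by-cell reproductions

cdr_model <- function() {
  spec <- joint_spec(process_spec("CDRGLOB", "ordinal", levels = c(0, 0.5, 1, 2, 3),
                                  covariates = c("age", "apoe1", "apoe2")))
  par <- param_template(spec)
  beta_age <- (qlogis(0.9740) - 5.565) / 55
  gamma <- (qlogis(0.3084) - qlogis(0.9740)) / 0.5
  par$processes$CDRGLOB$alpha <- cumsum(c(5.565, 3.933, 4.737, 8.539))
  par$processes$CDRGLOB$beta[] <- c(beta_age, 0, 0)
  par$processes$CDRGLOB$gamma <- gamma
  list(spec = spec, params = par)
}

test_that("transition rows are probability vectors and collapse when the lag is off", {
  m <- cdr_model()
  tt <- transition_matrix(m$spec, m$params, "CDRGLOB",
                          list(age = 70, apoe1 = 0, apoe2 = 0))
  expect_equal(unname(rowSums(tt$matrix)), rep(1, 5), tolerance = 1e-10)
  expect_true(all(tt$matrix >= 0 & tt$matrix <= 1))

  par0 <- m$params
  par0$processes$CDRGLOB$gamma <- 0
  tt0 <- transition_matrix(m$spec, par0, "CDRGLOB",
                           list(age = 70, apoe1 = 0, apoe2 = 0))
  for (r in 2:5) expect_equal(tt0$matrix[r, ], tt0$matrix[1, ], tolerance = 1e-12)

  expect_error(transition_matrix(m$spec, m$params, "CDRGLOB", list(age = 70)),
               "missing")
})

test_that("dementia-rating matrix reproduces printed cells at both ages", {
  m <- cdr_model()
  t55 <- transition_matrix(m$spec, m$params, "CDRGLOB",
                           list(age = 55, apoe1 = 0, apoe2 = 0))
  t85 <- transition_matrix(m$spec, m$params, "CDRGLOB",
                           list(age = 85, apoe1 = 0, apoe2 = 0))
  expect_lt(abs(t55$matrix["0", "0"] - 0.9740), 2e-4)
  expect_lt(abs(t85$matrix["0", "0"] - 0.9287), 2e-3)
  expect_lt(abs(t55$matrix["0.5", "0"] - 0.3084), 2e-4)
  expect_lt(abs(t55$matrix["1", "0"] - 0.0053), 5e-4)
  expect_lt(abs(t55$matrix["3", "3"] - 0.9969), 1e-3)
})

test_that("a nonzero random-effect value shifts the whole matrix coherently", {
  m <- cdr_model()
  tt_pos <- transition_matrix(m$spec, m$params, "CDRGLOB",
                              list(age = 70, apoe1 = 0, apoe2 = 0), b = 2)
  tt_zero <- transition_matrix(m$spec, m$params, "CDRGLOB",
                               list(age = 70, apoe1 = 0, apoe2 = 0), b = 0)
  # positive b raises every cumulative probability of being in a better state
  expect_true(all(tt_pos$matrix[, 1] >= tt_zero$matrix[, 1]))
  expect_equal(unname(rowSums(tt_pos$matrix)), rep(1, 5), tolerance = 1e-10)
})

test_that("transition tables round-trip through their text format", {
  m <- cdr_model()
  tt <- transition_matrix(m$spec, m$params, "CDRGLOB",
                          list(age = 55, apoe1 = 0, apoe2 = 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_transition_table(tt, path)
  lines <- readLines(path)
  expect_match(lines[1], "process: CDRGLOB")
  expect_match(lines[2], "age=55")
  M <- as.matrix(read.table(path, skip = 3, header = TRUE, row.names = 1,
                            check.names = FALSE))
  expect_equal(unname(M), unname(tt$matrix), tolerance = 1e-9)
})

test_that("empirical Bayes mode shrinks to zero under a tight prior and matches a grid search", {
  sim <- toy_panel(10, 5, seed = 151)
  spec <- toy_spec()
  trans <- build_transitions(sim$panel, spec)
  par <- toy_params()

  tight <- par
  tight$Sigma <- diag(1e-8, 2)
  eb0 <- empirical_bayes(trans, params = tight)
  expect_lt(max(abs(eb0$mode)), 1e-4)

  # 1-D grid oracle: single-process posterior mode
  spec1 <- joint_spec(process_spec("B", "binary", levels = c(0, 1),
                                   covariates = "x"))
  pan1 <- panel_data(as.data.frame(sim$panel)[c("subject", "visit", "B", "x")],
                     spec1)
  trans1 <- build_transitions(pan1, spec1)
  par1 <- param_template(spec1)
  par1$processes$B <- par$processes$B
  par1$Sigma <- matrix(1.3, 1, 1)
  eb1 <- empirical_bayes(trans1, params = par1)
  prep <- jmtrans:::prepare_eval(trans1, par1)
  for (i in c(1, 4, 7)) {
    pd <- trans1$processes$B
    sel <- pd$subject == i
    grid <- seq(-6, 6, by = 1e-4)
    post <- dnorm(grid, 0, sqrt(1.3), log = TRUE)
    pdi <- list(y = pd$y[sel], yidx = pd$yidx[sel])
    ETA <- outer(prep$B$ef[sel], grid, `+`)
    post <- post + colSums(jmtrans:::logdens_eta(spec1$processes$B,
                                                 prep$B$parts, pdi, ETA))
    expect_equal(eb1$mode[i, 1], grid[which.max(post)], tolerance = 1e-3)
  }
  # posterior curvature is a positive variance
  expect_true(all(eb1$vcov[1, 1, ] > 0))
})

test_that("EB recovery: subjects with large true effects get large predictions", {
  sim <- toy_panel(300, 5, seed = 161)
  trans <- build_transitions(sim$panel, toy_spec())
  eb <- empirical_bayes(trans, params = toy_params())
  # EB predictions correlate with the simulated truth for both processes
  expect_gt(cor(eb$mode[, 1], sim$b[, 1]), 0.25)
  expect_gt(cor(eb$mode[, 2], sim$b[, 2]), 0.35)
})

test_that("subject forecasts chain the EB transition matrix", {
  sim <- toy_panel(15, 5, seed = 171)
  spec <- toy_spec()
  trans <- build_transitions(sim$panel, spec)
  par <- toy_params()
  subj <- trans$subjects[3]
  fc1 <- subject_forecast(trans, params = par, subject = subj, horizon = 1)
  # horizon 1 equals the relevant row of the EB transition matrix
  eb <- empirical_bayes(trans, params = par, subject = subj)
  pd <- trans$processes$O
  i <- match(subj, trans$subjects)
  sel <- which(pd$subject == i)
  last <- sel[length(sel)]
  tm <- transition_matrix(spec, par, "O",
                          list(x = pd$X[last, "x"]), b = eb$mode[1, 2])
  expect_equal(unname(fc1$O[1, ]),
               unname(tm$matrix[as.character(pd$y[last]), ]), tolerance = 1e-10)

  # long horizons approach the stationary distribution of the frozen chain
  fc <- subject_forecast(trans, params = par, subject = subj, horizon = 400)
  expect_lt(max(abs(fc$O[400, ] - fc$O[399, ])), 1e-8)
  # direct chain-multiplication oracle at an intermediate horizon
  v <- as.numeric(rownames(tm$matrix) == as.character(pd$y[last]))
  for (k in 1:7) v <- drop(v %*% tm$matrix)
  expect_equal(unname(fc$O[7, ]), unname(v), tolerance = 1e-9)
})

test_that("a near-absorbing top state monotonically accumulates mass", {
  m <- cdr_model()
  # forecast chain at fixed covariates starting from the mildly-impaired state
  tt <- transition_matrix(m$spec, m$params, "CDRGLOB",
                          list(age = 85, apoe1 = 0, apoe2 = 1))
  v <- c(0, 0, 1, 0, 0)
  mass_top <- numeric(30)
  for (k in 1:30) {
    v <- drop(v %*% tt$matrix)
    mass_top[k] <- v[5]
  }
  expect_true(all(diff(mass_top) > -1e-12))
  expect_gt(tt$matrix["3", "3"], 0.99)
})
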