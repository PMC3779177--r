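#' Simulation scenario for joint transition models
#'
#' Bundles everything needed to generate a multivariate transition panel
#' with known truth: sample size, number of visits, the model specification
#' and true parameters, a covariate generator, and the initial-state
#' distributions (the first \eqn{q} visits are drawn from these and then
#' conditioned on — matching the conditional likelihood, which never models
#' them).
#'
#' @param n number of subjects.
#' @param T_visits visits per subject.
#' @param seed RNG seed (mandatory; generation is fully reproducible).
#' @param spec a [joint_spec()].
#' @param params true `jmtrans_params`.
#' @param covariate_gen `function(n)` returning a data frame of per-subject
#'   covariates (repeated across visits). Default: [ad_covariates()].
#' @param init named list, one entry per process: a probability vector over
#'   the level set (ordinal/binary), or a `function(n)` returning initial
#'   values (gaussian/poisson).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(n, T_visits, seed, spec, params,
                            covariate_gen = NULL, init) {
  stopifnot(inherits(spec, "joint_spec"), inherits(params, "jmtrans_params"))
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  implied_covariance(params)   # validates SPD
  if (is.null(covariate_gen)) covariate_gen <- ad_covariates
  for (g in names(spec$processes)) {
    p <- spec$processes[[g]]
    ini <- init[[g]]
    if (is.null(ini)) stop("no initial-state distribution for ", g)
    if (is.numeric(ini)) {
      if (is.null(p$levels) || length(ini) != length(p$levels) ||
          any(ini < 0) || abs(sum(ini) - 1) > 1e-8)
        stop("invalid initial-state probabilities for ", g)
    } else if (!is.function(ini)) stop("init entries must be probabilities or functions")
  }
  structure(list(n = as.integer(n), T_visits = as.integer(T_visits),
                 seed = as.integer(seed), spec = spec, params = params,
                 covariate_gen = covariate_gen, init = init),
            class = "scenario_config")
}

#' Default per-subject covariate generator
#'
#' Age at initial visit uniform on 55-85 years, education integer-uniform on
#' 8-20 years, and APOE-e4 allele copies categorical with probabilities
#' (0.6, 0.3, 0.1) for 0/1/2 copies, coded as two dummies `apoe1`, `apoe2`.
#'
#' @param n number of subjects.
#' @return data frame with columns `age`, `educ`, `apoe1`, `apoe2`.
#' @export
ad_covariates <- function(n) {
  copies <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  data.frame(age = stats::runif(n, 55, 85),
             educ = sample(8:20, n, replace = TRUE),
             apoe1 = as.numeric(copies == 1L),
             apoe2 = as.numeric(copies == 2L))
}

# one visit's draw for every subject of one process
draw_states <- function(p, parts, X, lagmat, zb) {
  pd <- list(X = X, lags = lagmat)
  eta <- eta_fixed(p, parts, pd) + zb
  n <- length(eta)
  switch(p$family,
    ordinal = {
      pr <- ordinal_category_probs(parts$alpha, eta)
      if (is.null(dim(pr))) pr <- matrix(pr, 1)
      cum <- t(apply(pr, 1L, cumsum))
      ix <- rowSums(stats::runif(n) > cum) + 1L
      p$levels[pmin(ix, length(p$levels))]
    },
    binary = {
      plow <- stats::plogis(parts$alpha[1L] + eta)
      ifelse(stats::runif(n) < plow, p$levels[1L], p$levels[2L])
    },
    gaussian = stats::rnorm(n, parts$alpha[1L] + eta, parts$sigma),
    poisson = stats::rpois(n, exp(parts$alpha[1L] + eta)))
}

#' Simulate a multivariate transition panel
#'
#' Draws, for each subject, random effects \eqn{b_i \sim N(0, \Sigma)},
#' covariates, initial states from the scenario's initial distributions, and
#' then iterates the per-process conditional transition distributions
#' forward through the visits. Identical seeds give identical panels.
#'
#' @param cfg a [scenario_config()].
#' @return list of class `sim_panel` with `panel` (a [panel_data()]) and
#'   `b` (n x d matrix of true random effects).
#' @export
simulate_panel <- function(cfg) {
  spec <- cfg$spec
  params <- cfg$params
  n <- cfg$n; TT <- cfg$T_visits
  set.seed(cfg$seed)
  covs <- cfg$covariate_gen(n)
  Cl <- t(chol(params$Sigma))
  b <- matrix(stats::rnorm(n * spec$dim_b), n) %*% t(Cl)
  blocks <- b_blocks(spec)

  qmax <- max(vapply(spec$processes, `[[`, 0L, "lag_order"))
  states <- lapply(spec$processes, function(p) matrix(NA_real_, n, TT))
  for (g in names(spec$processes)) {
    p <- spec$processes[[g]]
    ini <- cfg$init[[g]]
    for (j in seq_len(p$lag_order))
      states[[g]][, j] <- if (is.function(ini)) ini(n)
        else sample(p$levels, n, replace = TRUE, prob = ini)
  }
  for (j in seq.int(qmax + 1L, TT)) {
    for (g in names(spec$processes)) {
      p <- spec$processes[[g]]
      if (j <= p$lag_order) next
      q <- p$lag_order
      lagmat <- states[[g]][, j - seq_len(q), drop = FALSE]
      X <- if (length(p$covariates))
        as.matrix(covs[p$covariates]) else matrix(0, n, 0)
      Z <- matrix(0, n, length(p$random))
      for (r in seq_along(p$random)) {
        term <- p$random[r]
        Z[, r] <- if (term == "intercept") 1
          else if (grepl("^lag[0-9]+$", term))
            lagmat[, as.integer(sub("lag", "", term))]
          else X[, term]
      }
      zb <- rowSums(Z * b[, blocks[[g]], drop = FALSE])
      states[[g]][, j] <- draw_states(p, params$processes[[g]], X, lagmat, zb)
    }
  }

  df <- data.frame(subject = rep(sprintf("S%04d", seq_len(n)), each = TT),
                   visit = rep(seq_len(TT), n))
  for (g in names(spec$processes))
    df[[g]] <- as.vector(t(states[[g]]))
  for (cn in names(covs))
    df[[cn]] <- rep(covs[[cn]], each = TT)
  structure(list(panel = panel_data(df, spec), b = b, config = cfg),
            class = "sim_panel")
}

#' Packaged Alzheimer's-disease-like simulation scenario
#'
#' A four-process scenario emulating the structure of the motivating
#' dementia cohort: two 5-level ordinal processes (a global dementia rating
#' on codes 0, 0.5, 1, 2, 3 and a functional-disability grade on 0-4), two
#' binary processes (a dichotomized cognitive screen and a clinician rating
#' of normal-for-age cognition), all first-order with random intercepts.
#' True coefficients sit at the magnitudes estimated from that cohort
#' (ordinal lag coefficients around -4 to -9, age slopes around -0.04 to
#' -0.08, large increasing cutpoints), and the random-intercept correlations
#' follow the high / high / near-zero pattern: the two ordinal processes and
#' the cognitive screen are strongly correlated (0.51-0.75) while the
#' fourth process is uncorrelated with the rest.
#'
#' @param scale `"full"` (n = 746 subjects, the motivating cohort's size) or
#'   `"ci"` (n = 200, the scaled-down size used for repeated-fit calibration
#'   studies); both have 5 annual visits.
#' @param seed seed stored in the scenario (default 20130920).
#' @return a [scenario_config()].
#' @export
ad_fixture <- function(scale = c("full", "ci"), seed = 20130920L) {
  scale <- match.arg(scale)
  n <- if (scale == "full") 746L else 200L
  spec <- joint_spec(
    process_spec("CDRGLOB", "ordinal", levels = c(0, 0.5, 1, 2, 3),
                 covariates = c("age", "apoe1", "apoe2")),
    process_spec("FAQ", "ordinal", levels = 0:4,
                 covariates = c("age", "apoe1", "apoe2")),
    process_spec("MMSE", "binary", levels = c(0, 1),
                 covariates = c("age", "apoe1", "apoe2")),
    process_spec("COGSTAT", "binary", levels = c(0, 1),
                 covariates = c("age", "educ", "apoe1", "apoe2")))
  params <- param_template(spec)
  params$processes$CDRGLOB$alpha <- cumsum(c(5.565, 3.933, 4.737, 8.539))
  params$processes$CDRGLOB$beta[] <- c(-0.0353, -0.736, -1.248)
  params$processes$CDRGLOB$gamma <- -8.862
  params$processes$FAQ$alpha <- cumsum(c(7.063, 1.645, 2.141, 4.112))
  params$processes$FAQ$beta[] <- c(-0.0456, -0.930, -1.466)
  params$processes$FAQ$gamma <- -3.732
  params$processes$MMSE$alpha <- 10.045
  params$processes$MMSE$beta[] <- c(-0.0752, -1.713, -2.678)
  params$processes$MMSE$gamma <- -7.452
  params$processes$COGSTAT$alpha <- 5.128
  params$processes$COGSTAT$beta[] <- c(-0.0529, 0.055, -0.633, -0.719)
  params$processes$COGSTAT$gamma <- -3.148
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.508
  R[1, 3] <- R[3, 1] <- 0.576
  R[2, 3] <- R[3, 2] <- 0.754
  sd <- sqrt(c(2.264, 0.960, 8.946, 1.021))
  params$Sigma <- diag(sd) %*% R %*% diag(sd)
  init <- list(CDRGLOB = c(0.30, 0.25, 0.20, 0.15, 0.10),
               FAQ = c(0.30, 0.25, 0.20, 0.15, 0.10),
               MMSE = c(0.5, 0.5),
               COGSTAT = c(0.5, 0.5))
  scenario_config(n, 5L, seed, spec, params, init = init)
}
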