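# ---- vectorized internals -------------------------------------------------

# fixed part of the linear predictor for all records of one process:
# x'beta + f(lags; gamma), excluding cutpoint/intercept and random effects
eta_fixed <- function(p, parts, pd) {
  xb <- if (ncol(pd$X)) drop(pd$X %*% parts$beta) else numeric(nrow(pd$lags))
  f <- switch(p$lag_form,
    linear = drop(pd$lags %*% parts$gamma),
    zeger_qaqish = parts$gamma[1L] *
      (log(pmax(pd$lags[, 1L], p$poisson_floor)) - xb),
    log_linear = drop(log(pd$lags + 1) %*% parts$gamma))
  xb + f
}

# fast inverse-logit and log inverse-logit (hot path; stable for |x| large)
expit <- function(x) 1 / (1 + exp(-x))
log_expit <- function(x) pmin(x, 0) - log1p(exp(-abs(x)))

# stable log of expit(u) - expit(l) for u > l (category probability)
log_expit_diff <- function(l, u) {
  log1p(-exp(l - u)) + log_expit(u) + log_expit(-l)
}

# log conditional density for every record at every random-effect value:
# ETA is an n x K matrix of (fixed + random) linear predictors (no intercept);
# returns an n x K matrix of log densities
logdens_eta <- function(p, parts, pd, ETA) {
  ETA <- as.matrix(ETA)
  switch(p$family,
    ordinal = {
      K <- length(p$levels)
      a <- parts$alpha
      up <- c(a, Inf)[pd$yidx]
      lo <- c(-Inf, a)[pd$yidx]
      out <- ETA
      top <- pd$yidx == K
      bot <- pd$yidx == 1L
      mid <- !top & !bot
      if (any(bot)) out[bot, ] <- log_expit(a[1L] + ETA[bot, , drop = FALSE])
      if (any(top)) out[top, ] <- log_expit(-(a[K - 1L] + ETA[top, , drop = FALSE]))
      if (any(mid)) out[mid, ] <- log_expit_diff(lo[mid] + ETA[mid, , drop = FALSE],
                                                 up[mid] + ETA[mid, , drop = FALSE])
      out
    },
    binary = {
      eta <- parts$alpha[1L] + ETA
      s <- ifelse(pd$yidx == 1L, 1, -1)   # level 1 = "low" state modeled
      log_expit(s * eta)
    },
    gaussian = {
      stats::dnorm(pd$y, mean = parts$alpha[1L] + ETA, sd = parts$sigma, log = TRUE)
    },
    poisson = {
      mu <- exp(parts$alpha[1L] + ETA)
      stats::dpois(pd$y, mu, log = TRUE)
    })
}

# first and second derivatives of the record log-density w.r.t. eta,
# at a single eta vector (used for posterior-mode Newton steps)
logdens_deriv <- function(p, parts, pd, eta) {
  switch(p$family,
    ordinal = {
      K <- length(p$levels)
      a <- parts$alpha
      up <- c(a, Inf)[pd$yidx] + eta
      lo <- c(-Inf, a)[pd$yidx] + eta
      Fu <- expit(up); Fl <- expit(lo)
      fu <- Fu * (1 - Fu); fl <- Fl * (1 - Fl)
      pr <- pmax(Fu - Fl, 1e-300)
      d1 <- (fu - fl) / pr
      # f'(x) = f(x)(1-2F(x))
      d2 <- (fu * (1 - 2 * Fu) - fl * (1 - 2 * Fl)) / pr - d1^2
      list(d1 = d1, d2 = d2)
    },
    binary = {
      e <- parts$alpha[1L] + eta
      Fp <- expit(e)
      s <- ifelse(pd$yidx == 1L, 1, -1)
      list(d1 = s * (1 - expit(s * e)),
           d2 = -Fp * (1 - Fp))
    },
    gaussian = {
      mu <- parts$alpha[1L] + eta
      list(d1 = (pd$y - mu) / parts$sigma^2,
           d2 = rep(-1 / parts$sigma^2, length(eta)))
    },
    poisson = {
      mu <- exp(parts$alpha[1L] + eta)
      list(d1 = pd$y - mu, d2 = -mu)
    })
}

# ---- per-record exported surface ------------------------------------------

# random-effects design row for a single record
z_row <- function(p, rec) {
  vapply(p$random, function(term) {
    if (term == "intercept") 1
    else if (grepl("^lag[0-9]+$", term)) rec$lags[as.integer(sub("lag", "", term))]
    else rec$x[[term]]
  }, 0)
}

#' Linear predictor of a transition submodel at one record
#'
#' Evaluates \eqn{x'\beta + f_g(\mathrm{history}; \gamma) + z'b} for a single
#' transition record — everything except the cutpoint/intercept. Under the
#' default `"linear"` lag form with \eqn{q = 1} the history term is
#' \eqn{\gamma_1} times the numeric code of the previous state.
#'
#' @param p a [process_spec()].
#' @param parts the process's parameter parts (`alpha`, `beta`, `gamma`, ...).
#' @param rec a record: list with `x` (named covariates), `lags` (numeric
#'   previous states, most recent first), `y` (target, optional here).
#' @param b random-effect vector matching the process's random design
#'   (default zero).
#' @return a single numeric value.
#' @export
linear_predictor <- function(p, parts, rec, b = rep(0, length(p$random))) {
  if (length(b) != length(p$random))
    stop("random-effect vector has length ", length(b),
         ", expected ", length(p$random))
  X <- if (length(p$covariates))
    matrix(unlist(rec$x[p$covariates]), 1, dimnames = list(NULL, p$covariates))
  else matrix(0, 1, 0)
  pd <- list(X = X, lags = matrix(rec$lags[seq_len(p$lag_order)], 1))
  eta_fixed(p, parts, pd) + sum(z_row(p, rec) * b)
}

#' Category probabilities of the cumulative-logit transition model
#'
#' With increasing cutpoints \eqn{\alpha_1 < \dots < \alpha_{K-1}} and linear
#' predictor \eqn{\eta}, the model sets \eqn{P(Y \le k) =
#' \mathrm{expit}(\alpha_k + \eta)}; category probabilities are the
#' successive differences, the last being \eqn{1 -
#' \mathrm{expit}(\alpha_{K-1} + \eta)}. Higher levels encode worse states,
#' so negative covariate effects shift mass toward worse outcomes.
#'
#' @param cutpoints strictly increasing numeric vector (length K-1).
#' @param eta linear predictor (scalar or vector).
#' @return a vector (or matrix, one row per `eta`) of K probabilities
#'   summing to 1.
#' @export
ordinal_category_probs <- function(cutpoints, eta) {
  if (length(cutpoints) >= 2L && any(diff(cutpoints) <= 0))
    stop("cutpoints must be strictly increasing")
  cum <- stats::plogis(outer(eta, cutpoints, `+`))
  pr <- cbind(cum, 1)[, c(1L, seq_len(ncol(cum)) + 1L), drop = FALSE] -
    cbind(0, cum)
  colnames(pr) <- NULL
  if (length(eta) == 1L) drop(pr) else pr
}

#' Conditional log-density of one transition record
#'
#' The exponential-family log-density of the target state given history,
#' covariates and random effects: Gaussian with mean equal to the predictor
#' and SD `sigma`; Bernoulli with logit \eqn{\alpha + \eta} for the lower
#' state; Poisson with log-mean \eqn{\alpha + \eta} (with the
#' Zeger-Qaqish floored-log history feature if declared); ordinal as the log
#' category probability from [ordinal_category_probs()].
#'
#' @inheritParams linear_predictor
#' @return log density (numeric scalar).
#' @export
conditional_logdensity <- function(p, parts, rec, b = rep(0, length(p$random))) {
  eta <- linear_predictor(p, parts, rec, b)
  if (p$family == "poisson" && rec$y < 0) stop("count outcome must be non-negative")
  pd <- list(y = rec$y,
             yidx = if (!is.null(p$levels)) match(rec$y, p$levels) else NA_integer_)
  if (!is.null(p$levels) && is.na(pd$yidx))
    stop("outcome ", rec$y, " not in the level set of ", p$name)
  drop(logdens_eta(p, parts, pd, matrix(eta, 1, 1)))
}
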