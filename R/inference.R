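# ---- composite objective with pair-level bookkeeping ----------------------

# estimation units: all unordered process pairs (or the single process when
# G = 1, where the "composite" likelihood is the ordinary integrated one).
# Each unit records which packed parameters can change its value, so
# finite-difference loops only re-evaluate affected units.
make_units <- function(spec) {
  nms <- names(spec$processes)
  G <- length(nms)
  pn <- packed_names(spec)
  # packed index ranges per process, and covariance-parameter dims
  proc_idx <- lapply(nms, function(g) grep(paste0("^", g, "\\."), pn))
  names(proc_idx) <- nms
  d <- spec$dim_b
  logsd_idx <- match(paste0("cov.logsd", seq_len(d)), pn)
  w_ij <- if (d > 1) which(lower.tri(diag(d)), arr.ind = TRUE)
  w_idx <- if (d > 1) grep("^cov\\.w", pn)
  bl <- b_blocks(spec)

  gsets <- if (G >= 2L) {
    out <- list()
    for (i in seq_len(G - 1L)) for (j in seq.int(i + 1L, G))
      out[[length(out) + 1L]] <- c(nms[i], nms[j])
    out
  } else list(nms)

  units <- lapply(gsets, function(gs) {
    U <- unique(unlist(bl[gs]))
    local <- c(unlist(proc_idx[gs]),
               logsd_idx[U],
               if (d > 1) w_idx[w_ij[, 1] %in% U])
    list(gset = gs, local = sort(unname(local)))
  })
  affected <- lapply(seq_along(pn), function(j)
    which(vapply(units, function(u) j %in% u$local, TRUE)))
  list(units = units, affected = affected, p = length(pn), names = pn)
}

unit_value <- function(trans, theta, gset, rule, cache = NULL) {
  spec <- trans$spec
  params <- unpack_params(theta, spec)
  prep <- prepare_eval(trans, params, gset)
  sum(integrated_loglik(trans, prep, params, gset, rule, cache))
}

unit_value_subjects <- function(trans, theta, gset, rule) {
  spec <- trans$spec
  params <- unpack_params(theta, spec)
  prep <- prepare_eval(trans, params, gset)
  integrated_loglik(trans, prep, params, gset, rule)
}

# total composite log-likelihood as sum over units
units_total <- function(trans, theta, ub, rule, cache = NULL) {
  sum(vapply(ub$units, function(u) unit_value(trans, theta, u$gset, rule, cache), 0))
}

# finite-difference gradient re-evaluating only affected units; central
# differences by default, forward differences (half the evaluations) for
# heavy simulation loops
units_gradient <- function(trans, theta, ub, rule, rel_step = 1e-5,
                           cache = NULL, forward = FALSE) {
  g <- numeric(ub$p)
  base <- if (forward)
    vapply(ub$units, function(u) unit_value(trans, theta, u$gset, rule, cache), 0)
  for (j in seq_len(ub$p)) {
    aff <- ub$affected[[j]]
    if (!length(aff)) next
    hj <- rel_step * (1 + abs(theta[j]))
    tp <- theta
    tp[j] <- theta[j] + hj
    vp <- sum(vapply(aff, function(k) unit_value(trans, tp, ub$units[[k]]$gset, rule, cache), 0))
    if (forward) {
      g[j] <- (vp - sum(base[aff])) / hj
    } else {
      tm <- theta
      tm[j] <- theta[j] - hj
      vm <- sum(vapply(aff, function(k) unit_value(trans, tm, ub$units[[k]]$gset, rule, cache), 0))
      g[j] <- (vp - vm) / (2 * hj)
    }
  }
  g
}

# ---- fitting ---------------------------------------------------------------

# search bounds per packed-parameter kind (wide enough to be inert for any
# identified model: correlations can still reach +/-0.9995)
param_bounds <- function(pnames) {
  lower <- rep(-50, length(pnames))
  upper <- rep(50, length(pnames))
  lw <- grep("^cov\\.logsd", pnames)
  lower[lw] <- -8; upper[lw] <- 8
  ww <- grep("^cov\\.w", pnames)
  lower[ww] <- -30; upper[ww] <- 30
  list(lower = lower, upper = upper)
}

#' Fit a joint transition model by maximum composite conditional likelihood
#'
#' Maximizes the pairwise composite conditional log-likelihood over the
#' unconstrained parameter packing with BFGS, using central
#' finite-difference gradients that only re-evaluate the process pairs a
#' parameter touches. Unless starting values are supplied, each process is
#' first fitted as a univariate random-effects transition model (its ML fit
#' via the same quadrature) and the joint fit is warm-started from those
#' estimates with cross-process correlations at zero. For a single-process
#' specification the criterion reduces to the ordinary integrated
#' log-likelihood.
#'
#' @param data a [panel_data()] or a [build_transitions()] object.
#' @param spec a [joint_spec()] (ignored if `data` is already a
#'   `transition_set`).
#' @param init optional `jmtrans_params` starting values.
#' @param rule a [quad_rule()].
#' @param se compute the Godambe sandwich covariance and the Wald table
#'   (default `TRUE`; skip for pure point estimation in simulation loops).
#' @param control list: `maxit` (BFGS iteration cap, default 300),
#'   `reltol` (relative log-likelihood change declaring convergence, default
#'   1e-8 on the per-subject scale), `restarts` (extra BFGS runs if the
#'   score has not converged, default 2), `grad_tol` (max-norm tolerance for
#'   the per-subject-scaled score, default 1e-5), `forward_diff` (use
#'   forward instead of central differences in the optimizer gradient;
#'   halves the cost in long simulation loops).
#' @return an object of class `jmtrans_fit`.
#' @export
fit_jmtrans <- function(data, spec = NULL, init = NULL, rule = quad_rule(),
                        se = TRUE, control = list()) {
  trans <- if (inherits(data, "transition_set")) data
    else build_transitions(data, spec)
  spec <- trans$spec
  ctl <- utils::modifyList(list(maxit = 300L, reltol = 1e-8,
                                restarts = 2L, grad_tol = 1e-5,
                                forward_diff = FALSE), control)
  ub <- make_units(spec)
  n <- trans$n_subjects

  theta0 <- if (!is.null(init)) pack_params(init, spec)
    else warm_start(trans, rule)

  cache <- new.env(parent = emptyenv())
  negfn <- function(th) -units_total(trans, th, ub, rule, cache) / n
  neggr <- function(th) -units_gradient(trans, th, ub, rule, cache = cache,
                                        forward = ctl$forward_diff) / n

  opt <- stats::optim(theta0, negfn, neggr, method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  tries <- 0L
  grad <- units_gradient(trans, opt$par, ub, rule, cache = cache) / n
  while (max(abs(grad)) > ctl$grad_tol * (1 + abs(opt$value)) &&
         tries < ctl$restarts) {
    # polish with a tighter function tolerance so the score norm can converge
    opt <- stats::optim(opt$par, negfn, neggr, method = "BFGS",
                        control = list(maxit = ctl$maxit,
                                       reltol = ctl$reltol * 1e-6))
    grad <- units_gradient(trans, opt$par, ub, rule, cache = cache) / n
    tries <- tries + 1L
  }
  theta <- opt$par
  names(theta) <- ub$names
  params <- unpack_params(theta, spec)
  loglik <- -opt$value * n
  converged <- opt$convergence == 0 &&
    max(abs(grad)) <= ctl$grad_tol * (1 + abs(opt$value))
  d <- spec$dim_b
  boundary <- any(theta[grep("^cov\\.logsd", ub$names)] < -6)

  fit <- structure(
    list(spec = spec, trans = trans, rule = rule,
         theta = theta, params = params, loglik = loglik,
         n = n, units = ub,
         convergence = list(converged = converged, boundary = boundary,
                            iterations = opt$iterations,
                            restarts = tries,
                            grad_norm = max(abs(grad)),
                            status = opt$convergence)),
    class = "jmtrans_fit")
  if (boundary)
    warning("variance parameter at the boundary (log-SD < -6); sandwich inference skipped")
  if (se && !boundary) {
    gd <- godambe(trans, theta, rule)
    fit$H <- gd$H; fit$J <- gd$J; fit$G <- gd$G; fit$vcov <- gd$vcov
    fit$table <- wald_table(fit)
  }
  fit
}

# univariate warm start: fit each process alone, assemble block covariance
warm_start <- function(trans, rule) {
  spec <- trans$spec
  full <- param_template(spec)
  Sigma <- diag(spec$dim_b)
  bl <- b_blocks(spec)
  for (g in names(spec$processes)) {
    sub <- subset_trans(trans, g)
    subfit <- fit_univariate(sub, rule)
    full$processes[[g]] <- subfit$params$processes[[g]]
    if (spec$covariance == "unstructured")
      Sigma[bl[[g]], bl[[g]]] <- subfit$params$Sigma
  }
  if (spec$covariance == "shared") {
    blocks <- lapply(names(spec$processes), function(g) {
      sub <- subset_trans(trans, g)
      fit_univariate(sub, rule)$params$Sigma
    })
    Sigma <- Reduce(`+`, blocks) / length(blocks)
  }
  full$Sigma <- Sigma
  pack_params(full, spec)
}

# single-process view of a transition set
subset_trans <- function(trans, g) {
  sp <- joint_spec(trans$spec$processes[g])
  structure(list(subjects = trans$subjects, n_subjects = trans$n_subjects,
                 processes = trans$processes[g], spec = sp),
            class = "transition_set")
}

# ML fit of one univariate random-effects transition model
fit_univariate <- function(trans1, rule, maxit = 300L) {
  spec1 <- trans1$spec
  ub <- make_units(spec1)
  n <- trans1$n_subjects
  theta0 <- pack_params(param_template(spec1), spec1)
  cache <- new.env(parent = emptyenv())
  negfn <- function(th) -units_total(trans1, th, ub, rule, cache) / n
  neggr <- function(th) -units_gradient(trans1, th, ub, rule, cache = cache) / n
  bb <- param_bounds(ub$names)
  opt <- stats::nlminb(theta0, negfn, neggr,
                       lower = bb$lower, upper = bb$upper,
                       control = list(iter.max = maxit, eval.max = 2L * maxit,
                                      rel.tol = 1e-10))
  theta <- stats::setNames(opt$par, ub$names)
  list(theta = theta, params = unpack_params(theta, spec1),
       loglik = -opt$objective * n, spec = spec1, trans = trans1,
       converged = opt$convergence == 0)
}

# ---- Godambe sandwich ------------------------------------------------------

#' Sensitivity, variability and Godambe information at an estimate
#'
#' \eqn{H = -(1/n)\sum_i \nabla^2 c\ell_i(\hat\theta)} (second
#' finite differences, evaluated pair by pair on the parameters each pair
#' involves), \eqn{J = (1/n)\sum_i s_i s_i'} with \eqn{s_i} the centered
#' per-subject composite score, Godambe information \eqn{G = H J^{-1} H},
#' and the sandwich covariance of the estimator \eqn{\widehat{\mathrm{cov}}
#' (\hat\theta) = H^{-1} J H^{-1} / n = (nG)^{-1}}.
#'
#' @param trans a [build_transitions()] object.
#' @param theta packed parameter estimate.
#' @param rule a [quad_rule()].
#' @param hess_step relative step for the second differences.
#' @return list with `H`, `J`, `G`, `vcov`.
#' @export
godambe <- function(trans, theta, rule = quad_rule(), hess_step = 1e-3) {
  spec <- trans$spec
  ub <- make_units(spec)
  n <- trans$n_subjects
  p <- ub$p

  # variability: per-subject centered scores, central differences per unit
  Sc <- matrix(0, n, p)
  for (j in seq_len(p)) {
    aff <- ub$affected[[j]]
    hj <- 1e-5 * (1 + abs(theta[j]))
    tp <- tm <- theta
    tp[j] <- theta[j] + hj
    tm[j] <- theta[j] - hj
    vp <- vm <- numeric(n)
    for (k in aff) {
      vp <- vp + unit_value_subjects(trans, tp, ub$units[[k]]$gset, rule)
      vm <- vm + unit_value_subjects(trans, tm, ub$units[[k]]$gset, rule)
    }
    Sc[, j] <- (vp - vm) / (2 * hj)
  }
  Sc <- sweep(Sc, 2L, colMeans(Sc))
  J <- crossprod(Sc) / n

  # sensitivity: second differences, unit by unit on its local parameters
  H <- matrix(0, p, p)
  hstep <- hess_step * (1 + abs(theta))
  for (u in ub$units) {
    L <- u$local
    f0 <- unit_value(trans, theta, u$gset, rule)
    uv <- function(th) unit_value(trans, th, u$gset, rule)
    fp <- fm <- numeric(length(L))
    for (a in seq_along(L)) {
      tp <- tm <- theta
      tp[L[a]] <- theta[L[a]] + hstep[L[a]]
      tm[L[a]] <- theta[L[a]] - hstep[L[a]]
      fp[a] <- uv(tp); fm[a] <- uv(tm)
      H[L[a], L[a]] <- H[L[a], L[a]] + (fp[a] - 2 * f0 + fm[a]) / hstep[L[a]]^2
    }
    if (length(L) > 1L) for (a in seq_len(length(L) - 1L)) for (b in seq.int(a + 1L, length(L))) {
      ja <- L[a]; jb <- L[b]
      tpp <- tpm <- tmp <- tmm <- theta
      tpp[ja] <- theta[ja] + hstep[ja]; tpp[jb] <- theta[jb] + hstep[jb]
      tpm[ja] <- theta[ja] + hstep[ja]; tpm[jb] <- theta[jb] - hstep[jb]
      tmp[ja] <- theta[ja] - hstep[ja]; tmp[jb] <- theta[jb] + hstep[jb]
      tmm[ja] <- theta[ja] - hstep[ja]; tmm[jb] <- theta[jb] - hstep[jb]
      v <- (uv(tpp) - uv(tpm) - uv(tmp) + uv(tmm)) / (4 * hstep[ja] * hstep[jb])
      H[ja, jb] <- H[ja, jb] + v
      H[jb, ja] <- H[jb, ja] + v
    }
  }
  H <- -(H + t(H)) / (2 * n)

  Jinv <- tryCatch(solve(J), error = function(e) {
    warning("ill-conditioned variability matrix; ridged by 1e-8")
    solve(J + diag(1e-8, p))
  })
  Hinv <- tryCatch(solve(H), error = function(e) {
    warning("singular sensitivity matrix; pseudo-inverse used")
    ev <- eigen(H, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-10
    ev$vectors[, pos] %*% (t(ev$vectors[, pos]) / ev$values[pos])
  })
  G <- H %*% Jinv %*% H
  V <- Hinv %*% J %*% Hinv / n
  V <- (V + t(V)) / 2
  dimnames(H) <- dimnames(J) <- dimnames(G) <- dimnames(V) <-
    list(names(theta), names(theta))
  list(H = H, J = J, G = G, vcov = V)
}

# ---- reporting -------------------------------------------------------------

# natural-scale parameter vector (what the fit table reports)
natural_fn <- function(theta, spec) {
  params <- unpack_params(theta, spec)
  out <- c()
  for (g in names(spec$processes)) {
    p <- spec$processes[[g]]
    pp <- params$processes[[g]]
    a <- if (p$family == "ordinal")
      stats::setNames(c(pp$alpha[1L], diff(pp$alpha)),
                      c("Intercept", paste0("Increment", seq_len(length(pp$alpha) - 1L))))
    else c(Intercept = pp$alpha[1L])
    v <- c(a, pp$beta, stats::setNames(pp$gamma, paste0("Lag", seq_along(pp$gamma))))
    if (p$family == "gaussian") v <- c(v, sigma = pp$sigma)
    names(v) <- paste0(g, ".", names(v))
    out <- c(out, v)
  }
  s <- implied_covariance(params)
  vn <- stats::setNames(s$variances,
                        paste0("Variance.", var_corr_names(spec)$var))
  cn <- if (length(s$correlations))
    stats::setNames(s$correlations, paste0("Correlation.", var_corr_names(spec)$corr))
  c(out, vn, cn)
}

var_corr_names <- function(spec) {
  bl <- b_blocks(spec)
  dim_names <- character(spec$dim_b)
  if (spec$covariance == "shared") {
    dim_names <- paste0("shared", seq_len(spec$dim_b))
  } else {
    for (g in names(spec$processes)) {
      terms <- spec$processes[[g]]$random
      dim_names[bl[[g]]] <- if (length(terms) == 1L && terms == "intercept") g
        else paste0(g, ":", terms)
    }
  }
  ij <- which(lower.tri(diag(spec$dim_b)), arr.ind = TRUE)
  list(var = dim_names,
       corr = if (spec$dim_b > 1)
         paste0(dim_names[ij[, 2]], ",", dim_names[ij[, 1]]))
}

# Wald table on the natural scale via finite-difference delta method
wald_table <- function(fit) {
  theta <- fit$theta
  spec <- fit$spec
  est <- natural_fn(theta, spec)
  Jc <- matrix(0, length(est), length(theta))
  for (j in seq_along(theta)) {
    hj <- 1e-6 * (1 + abs(theta[j]))
    tp <- tm <- theta
    tp[j] <- theta[j] + hj
    tm[j] <- theta[j] - hj
    Jc[, j] <- (natural_fn(tp, spec) - natural_fn(tm, spec)) / (2 * hj)
  }
  Vn <- Jc %*% fit$vcov %*% t(Jc)
  se <- sqrt(pmax(diag(Vn), 0))
  z <- est / se
  data.frame(parameter = names(est), estimate = unname(est), se = se,
             z = unname(z), p = 2 * stats::pnorm(-abs(z)),
             row.names = NULL)
}

#' @export
print.jmtrans_fit <- function(x, digits = 4, ...) {
  cat("Joint random-effects transition model",
      sprintf("(%d processes, %d subjects)\n", n_proc(x$spec), x$n))
  cat(sprintf("Composite conditional log-likelihood: %.4f\n", x$loglik))
  cv <- x$convergence
  cat(sprintf("Convergence: %s (%d evaluations%s)%s\n",
              if (cv$converged) "yes" else "NOT CONVERGED",
              cv$iterations,
              if (cv$restarts) paste0(", ", cv$restarts, " restart(s)") else "",
              if (cv$boundary) " [variance boundary]" else ""))
  if (!is.null(x$table)) {
    cat("\nEstimates (Godambe sandwich SEs):\n")
    tb <- x$table
    tb$estimate <- round(tb$estimate, digits)
    tb$se <- round(tb$se, digits)
    tb$z <- round(tb$z, 2)
    tb$p <- signif(tb$p, 2)
    print(tb, row.names = FALSE)
  }
  invisible(x)
}

#' Write a fit report table
#'
#' Tab-separated table with columns Measurement, Parameter, Estimate, SE,
#' p-value — regression rows per process followed by the random-effects
#' variance and correlation block.
#'
#' @param fit a [fit_jmtrans()] result (fitted with `se = TRUE`).
#' @param path output path.
#' @export
write_fit_report <- function(fit, path) {
  tb <- fit$table
  if (is.null(tb)) {
    # boundary or se = FALSE fits: report estimates without sandwich SEs
    est <- natural_fn(fit$theta, fit$spec)
    tb <- data.frame(parameter = names(est), estimate = unname(est),
                     se = NA_real_, z = NA_real_, p = NA_real_)
  }
  parts <- strsplit(tb$parameter, ".", fixed = TRUE)
  out <- data.frame(Measurement = vapply(parts, `[[`, "", 1L),
                    Parameter = vapply(parts, function(z) paste(z[-1L], collapse = "."), ""),
                    Estimate = sprintf("%.6g", tb$estimate),
                    SE = sprintf("%.6g", tb$se),
                    p.value = sprintf("%.4g", tb$p))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- tests -----------------------------------------------------------------

#' Wald test of a parameter constraint
#'
#' Quadratic-form Wald statistic \eqn{(\hat\theta_s - v)' V_{ss}^{-1}
#' (\hat\theta_s - v)} using the sandwich covariance, referred to a
#' chi-square with as many degrees of freedom as constrained parameters.
#'
#' @param fit a [fit_jmtrans()] result with `se = TRUE`.
#' @param constraint named numeric vector: packed-parameter names mapped to
#'   their hypothesized values.
#' @return list with `statistic`, `df`, `p`.
#' @export
wald_test <- function(fit, constraint) {
  if (is.null(fit$vcov)) stop("fit has no sandwich covariance")
  nm <- names(constraint)
  if (is.null(nm) || !all(nm %in% names(fit$theta)))
    stop("constraint names must be packed parameter names")
  d <- fit$theta[nm] - constraint
  Vss <- fit$vcov[nm, nm, drop = FALSE]
  cn <- tryCatch(solve(Vss, d), error = function(e)
    stop("singular sub-covariance for the constrained subset"))
  stat <- drop(d %*% cn)
  list(statistic = stat, df = length(d),
       p = stats::pchisq(stat, length(d), lower.tail = FALSE))
}

#' Adjusted composite likelihood-ratio test
#'
#' For nested models fitted by composite likelihood, \eqn{2(c\ell_1 -
#' c\ell_0)} is asymptotically a weighted sum of chi-squares; the weights
#' are the eigenvalues of \eqn{[(H^{-1})_{\eta\eta}]^{-1} (H^{-1} J
#' H^{-1})_{\eta\eta}} on the tested block \eqn{\eta}, and the statistic is
#' referred to a Satterthwaite-matched scaled chi-square. When \eqn{H = J}
#' (a full likelihood) every weight is 1 and the test reduces to the
#' ordinary LRT.
#'
#' @param fit_full,fit_null nested [fit_jmtrans()] results: every packed
#'   parameter of the null model must also appear in the full model (the
#'   tested block is the complement). The full fit must carry `H` and `J`.
#' @return list with `statistic` (unscaled), `scale`, `df` (effective),
#'   `p`, `weights`.
#' @export
composite_lrt <- function(fit_full, fit_null) {
  nf <- names(fit_full$theta)
  nn <- names(fit_null$theta)
  if (!all(nn %in% nf))
    stop("models are not nested: null parameters ",
         paste(setdiff(nn, nf), collapse = ", "), " absent from the full model")
  eta <- setdiff(nf, nn)
  stat <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  if (!length(eta))
    return(list(statistic = stat, scale = 1, df = 0, p = 1, weights = numeric()))
  if (is.null(fit_full$H)) stop("full fit has no H/J; refit with se = TRUE")
  Hinv <- solve(fit_full$H)
  Vfull <- Hinv %*% fit_full$J %*% Hinv
  dimnames(Hinv) <- dimnames(Vfull) <- list(nf, nf)
  lam <- Re(eigen(solve(Hinv[eta, eta, drop = FALSE]) %*%
                  Vfull[eta, eta, drop = FALSE], only.values = TRUE)$values)
  lam <- pmax(lam, 0)
  scale <- sum(lam^2) / sum(lam)
  df <- sum(lam)^2 / sum(lam^2)
  list(statistic = stat, scale = scale, df = df,
       p = stats::pchisq(stat / scale, df, lower.tail = FALSE),
       weights = lam)
}

# ---- two-stage comparison estimator ---------------------------------------

#' Two-stage maximum likelihood comparison estimator
#'
#' Stage 1 fits each process's univariate random-intercept transition model
#' by maximum likelihood (adaptive quadrature). Stage 2 estimates the
#' cross-process random-effect correlations as Pearson correlations of the
#' paired empirical-Bayes intercept predictions, with Fisher-z 95%
#' confidence intervals. Returned for comparison with the joint composite
#' fit; no sandwich inference is attached.
#'
#' @param data a [panel_data()] or `transition_set`.
#' @param spec a [joint_spec()]; every process must have a scalar random
#'   intercept.
#' @param rule a [quad_rule()].
#' @return an object of class `jmtrans_two_stage`: per-process stage-1
#'   fits, assembled `params`, and a correlation table.
#' @export
two_stage_fit <- function(data, spec = NULL, rule = quad_rule()) {
  trans <- if (inherits(data, "transition_set")) data
    else build_transitions(data, spec)
  spec <- trans$spec
  if (any(spec$d_g != 1L))
    stop("two-stage estimation requires a scalar random effect per process")
  G <- n_proc(spec)
  nms <- names(spec$processes)
  stage1 <- lapply(nms, function(g) fit_univariate(subset_trans(trans, g), rule))
  names(stage1) <- nms
  if (G == 1L) {
    f <- stage1[[1L]]
    return(structure(list(stage1 = stage1, params = f$params,
                          correlations = NULL, spec = spec),
                     class = "jmtrans_two_stage"))
  }
  eb <- vapply(nms, function(g) {
    f <- stage1[[g]]
    sub <- subset_trans(trans, g)
    prep <- prepare_eval(sub, f$params)
    pm <- posterior_modes(sub, prep, g, solve(f$params$Sigma))
    pm$mu[, 1L]
  }, numeric(trans$n_subjects))

  params <- param_template(spec)
  for (g in nms) params$processes[[g]] <- stage1[[g]]$params$processes[[g]]
  sds <- vapply(nms, function(g) sqrt(stage1[[g]]$params$Sigma[1, 1]), 0)
  R <- stats::cor(eb)
  # shrink if the EB correlation matrix is not positive definite
  while (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
    R <- 0.95 * R + 0.05 * diag(G)
  params$Sigma <- diag(sds) %*% R %*% diag(sds)

  ij <- which(lower.tri(diag(G)), arr.ind = TRUE)
  r <- stats::cor(eb)[lower.tri(diag(G))]
  zf <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  sez <- 1 / sqrt(trans$n_subjects - 3)
  tab <- data.frame(pair = paste0(nms[ij[, 2]], ",", nms[ij[, 1]]),
                    correlation = r,
                    lower = tanh(zf - 1.96 * sez),
                    upper = tanh(zf + 1.96 * sez))
  structure(list(stage1 = stage1, params = params, correlations = tab,
                 spec = spec),
            class = "jmtrans_two_stage")
}

#' @export
print.jmtrans_two_stage <- function(x, ...) {
  cat("Two-stage ML estimates (stage-1 univariate fits + EB correlations)\n")
  if (!is.null(x$correlations)) {
    cat("Stage-2 random-intercept correlations (Fisher-z 95% CI):\n")
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}
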