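# ---- evaluation plumbing ---------------------------------------------------

# per-process parameter parts and precomputed fixed linear predictors
prepare_eval <- function(trans, params, gset = names(trans$spec$processes)) {
  spec <- trans$spec
  lapply(gset, function(g) {
    p <- spec$processes[[g]]
    parts <- params$processes[[g]]
    list(parts = parts, ef = eta_fixed(p, parts, trans$processes[[g]]))
  }) |> stats::setNames(gset)
}

family_code <- c(ordinal = 1L, binary = 2L, gaussian = 3L, poisson = 4L)

# per-subject sums of record log-densities over a grid of linear predictors
subject_logdens <- function(p, parts, pd, ETA, S) {
  yi <- pd$yidx
  yi[is.na(yi)] <- 0L
  if (!is.matrix(ETA)) ETA <- as.matrix(ETA)
  cpp_subject_logdens(ETA, family_code[[p$family]],
                      as.numeric(pd$y), yi, as.numeric(parts$alpha),
                      if (p$family == "gaussian") parts$sigma else 1.0,
                      pd$subject, S)
}

# union of the random-effect blocks of a set of processes, plus the mapping
# from each process's random design columns into that union
block_info <- function(spec, gset) {
  bl <- b_blocks(spec)
  bidx <- unique(unlist(bl[gset]))
  list(bidx = bidx, map = lapply(bl[gset], function(ix) match(ix, bidx)))
}

# Laplace machinery: per-subject posterior modes of the random effects for
# the processes in gset, with the Cholesky factor of the inverse curvature.
# Newton iterations are vectorized across subjects (the conditional
# log-densities are concave in the linear predictor for every family, so the
# per-subject problems are strictly concave).
posterior_modes <- function(trans, prep, gset, Omega, max_iter = 100L, tol = 1e-10,
                            start = NULL) {
  spec <- trans$spec
  S <- trans$n_subjects
  bi <- block_info(spec, gset)
  d <- length(bi$bidx)
  mu <- if (!is.null(start) && identical(dim(start), c(S, d))) start
    else matrix(0, S, d)

  newton_pieces <- function(mu) {
    Gr <- -(mu %*% Omega)
    Harr <- array(rep(-Omega, each = S), c(S, d, d))
    for (k in seq_along(gset)) {
      g <- gset[[k]]
      p <- spec$processes[[g]]
      pd <- trans$processes[[g]]
      cols <- bi$map[[k]]
      if (!length(pd$y)) next
      eta <- prep[[g]]$ef +
        rowSums(pd$Z * mu[pd$subject, cols, drop = FALSE])
      yi <- pd$yidx
      yi[is.na(yi)] <- 0L
      parts <- prep[[g]]$parts
      dv <- cpp_deriv_accum(eta, family_code[[p$family]], as.numeric(pd$y),
                            yi, as.numeric(parts$alpha),
                            if (p$family == "gaussian") parts$sigma else 1.0,
                            pd$Z, pd$subject, S)
      Gr[, cols] <- Gr[, cols] + dv$G
      dg <- length(cols)
      for (a in seq_len(dg)) for (b in seq_len(dg))
        Harr[, cols[a], cols[b]] <- Harr[, cols[a], cols[b]] +
          dv$H[, (a - 1L) * dg + b]
    }
    list(Gr = Gr, Hpos = -Harr)
  }

  solve_step <- function(Hpos, Gr) {
    if (d == 1L) {
      cbind(Gr[, 1L] / Hpos[, 1L, 1L])
    } else if (d == 2L) {
      det <- Hpos[, 1, 1] * Hpos[, 2, 2] - Hpos[, 1, 2]^2
      cbind((Hpos[, 2, 2] * Gr[, 1] - Hpos[, 1, 2] * Gr[, 2]) / det,
            (Hpos[, 1, 1] * Gr[, 2] - Hpos[, 1, 2] * Gr[, 1]) / det)
    } else {
      t(vapply(seq_len(S), function(i) solve(Hpos[i, , ], Gr[i, ]),
               numeric(d)))
    }
  }

  for (it in seq_len(max_iter)) {
    np <- newton_pieces(mu)
    step <- solve_step(np$Hpos, np$Gr)
    nrm <- sqrt(rowSums(step^2))
    step <- step * pmin(1, 4 / pmax(nrm, 1e-300))   # damp very long steps
    mu <- mu + step
    if (max(abs(step)) < tol) break
  }
  np <- newton_pieces(mu)
  Hpos <- np$Hpos

  # lower Cholesky of Hpos^{-1} and its log-determinant, per subject
  Larr <- array(0, c(S, d, d))
  if (d == 1L) {
    Larr[, 1, 1] <- 1 / sqrt(Hpos[, 1, 1])
    logdetL <- -0.5 * log(Hpos[, 1, 1])
  } else if (d == 2L) {
    det <- Hpos[, 1, 1] * Hpos[, 2, 2] - Hpos[, 1, 2]^2
    v11 <- Hpos[, 2, 2] / det
    v21 <- -Hpos[, 1, 2] / det
    v22 <- Hpos[, 1, 1] / det
    Larr[, 1, 1] <- sqrt(v11)
    Larr[, 2, 1] <- v21 / Larr[, 1, 1]
    Larr[, 2, 2] <- sqrt(v22 - Larr[, 2, 1]^2)
    logdetL <- -0.5 * log(det)
  } else {
    logdetL <- numeric(S)
    for (i in seq_len(S)) {
      L <- t(chol(solve(Hpos[i, , ])))
      Larr[i, , ] <- L
      logdetL[i] <- sum(log(diag(L)))
    }
  }
  list(mu = mu, Larr = Larr, logdetL = logdetL)
}

# per-subject integrated conditional log-likelihood for the processes in
# gset (a character vector of process names): the log of the integral over
# the joint normal random effects of the product of all transition densities
integrated_loglik <- function(trans, prep, params, gset, rule, cache = NULL) {
  spec <- trans$spec
  S <- trans$n_subjects
  bi <- block_info(spec, gset)
  d <- length(bi$bidx)
  Sigma_P <- params$Sigma[bi$bidx, bi$bidx, drop = FALSE]
  grid <- gh_grid(rule, d)

  if (!rule$adaptive) {
    Cl <- t(chol(Sigma_P))
    B <- grid$z %*% t(Cl)                    # K x d node values of b
    A <- matrix(0, S, grid$K)
    for (k in seq_along(gset)) {
      g <- gset[[k]]
      pd <- trans$processes[[g]]
      if (!length(pd$y)) next
      ETA <- prep[[g]]$ef +
        pd$Z %*% t(B[, bi$map[[k]], drop = FALSE])
      A <- A + subject_logdens(spec$processes[[g]], prep[[g]]$parts, pd, ETA, S)
    }
    lw <- grid$lw - d / 2 * log(pi)          # normalized Gaussian weights
    return(logsumexp_rows(A + rep(lw, each = S)))
  }

  ckey <- if (!is.null(cache)) paste(gset, collapse = "|")

  if (d <= 2L) {
    # fused C++ fast path: Newton mode search + node evaluation in one pass
    procs <- lapply(seq_along(gset), function(k) {
      g <- gset[[k]]
      p <- spec$processes[[g]]
      pd <- trans$processes[[g]]
      parts <- prep[[g]]$parts
      yi <- pd$yidx
      yi[is.na(yi)] <- 0L
      list(ef = prep[[g]]$ef, Z = pd$Z, y = as.numeric(pd$y), yidx = yi,
           subj = pd$subject, alpha = as.numeric(parts$alpha),
           family = family_code[[p$family]],
           sigma = if (p$family == "gaussian") parts$sigma else 1.0,
           cols = bi$map[[k]] - 1L)
    })
    mu0 <- if (!is.null(cache)) cache[[ckey]]
    if (is.null(mu0) || !identical(dim(mu0), c(S, d))) mu0 <- matrix(0, S, d)
    res <- cpp_agq_loglik(procs, Sigma_P, S, grid$z, grid$lw, grid$zz2,
                          mu0, 100L, 1e-10)
    if (!is.null(cache)) cache[[ckey]] <- res$mu
    return(as.numeric(res$ll))
  }

  Omega <- solve(Sigma_P)
  pm <- posterior_modes(trans, prep, gset, Omega,
                        start = if (!is.null(cache)) cache[[ckey]])
  if (!is.null(cache)) cache[[ckey]] <- pm$mu
  # node values per union dimension: S x K matrices
  Bd <- lapply(seq_len(d), function(a) {
    acc <- matrix(pm$mu[, a], S, grid$K)
    for (cc in seq_len(d)) acc <- acc + outer(pm$Larr[, a, cc], grid$z[, cc])
    acc
  })
  A <- matrix(0, S, grid$K)
  for (k in seq_along(gset)) {
    g <- gset[[k]]
    pd <- trans$processes[[g]]
    if (!length(pd$y)) next
    cols <- bi$map[[k]]
    ETA <- matrix(prep[[g]]$ef, length(pd$y), grid$K)
    for (a in seq_along(cols))
      ETA <- ETA + pd$Z[, a] * Bd[[cols[a]]][pd$subject, , drop = FALSE]
    A <- A + subject_logdens(spec$processes[[g]], prep[[g]]$parts, pd, ETA, S)
  }
  # multivariate normal prior density at the nodes
  q <- matrix(0, S, grid$K)
  for (a in seq_len(d)) for (b in seq_len(d))
    q <- q + Omega[a, b] * Bd[[a]] * Bd[[b]]
  logphi <- -d / 2 * log(2 * pi) - 0.5 * determinant(Sigma_P)$modulus[1] - 0.5 * q
  tot <- A + logphi + rep(grid$lw + grid$zz2, each = S)
  logsumexp_rows(tot) + pm$logdetL + d / 2 * log(2)
}

# ---- exported likelihood surface ------------------------------------------

#' Pairwise conditional log-likelihood of two processes
#'
#' The log of the double integral, over the two processes' correlated random
#' effects, of the product of all transition densities of the pair,
#' conditioning on each process's first \eqn{q} states. One such term per
#' subject and unordered pair is what the composite conditional likelihood
#' sums.
#'
#' @param trans a [build_transitions()] object.
#' @param g,h process names (distinct).
#' @param params a `jmtrans_params`.
#' @param rule a [quad_rule()].
#' @param per_subject return the per-subject vector instead of the sum.
#' @return log-likelihood value (or per-subject vector).
#' @export
pair_conditional_loglik <- function(trans, g, h, params, rule = quad_rule(),
                                    per_subject = FALSE) {
  if (identical(g, h)) stop("g and h must be distinct processes")
  prep <- prepare_eval(trans, params)
  ll <- integrated_loglik(trans, prep, params, c(g, h), rule)
  if (any(!is.finite(ll)))
    stop("non-finite pair log-likelihood for pair (", g, ", ", h, ")")
  if (per_subject) ll else sum(ll)
}

#' Composite conditional log-likelihood
#'
#' Sum of [pair_conditional_loglik()] over all unordered process pairs and
#' subjects, with equal pair weights. This is the estimation criterion: it
#' replaces one \eqn{d}-dimensional integral per subject by
#' \eqn{\binom{G}{2}} two-block integrals, and by conditioning on the first
#' \eqn{q} states it never needs an initial-state model.
#'
#' @inheritParams pair_conditional_loglik
#' @return list with `value` (total) and `by_subject` (vector of per-subject
#'   contributions summed over pairs, used for the variability matrix).
#' @export
composite_loglik <- function(trans, params, rule = quad_rule()) {
  spec <- trans$spec
  G <- n_proc(spec)
  if (G < 2L) stop("composite likelihood needs at least two processes")
  prep <- prepare_eval(trans, params)
  nms <- names(spec$processes)
  by_subject <- numeric(trans$n_subjects)
  for (i in seq_len(G - 1L)) for (j in seq.int(i + 1L, G))
    by_subject <- by_subject +
      integrated_loglik(trans, prep, params, c(nms[i], nms[j]), rule)
  if (any(!is.finite(by_subject))) stop("non-finite composite log-likelihood")
  list(value = sum(by_subject), by_subject = by_subject)
}

#' Full conditional log-likelihood (small-dimension oracle)
#'
#' The exact conditional likelihood integrates all \eqn{G} processes'
#' densities against the joint random-effects distribution in one
#' \eqn{d}-dimensional integral. It is tractable only for small \eqn{d} and
#' is provided as a reference: for \eqn{G = 2} it coincides with the
#' pairwise composite likelihood (same integral, same quadrature), and for a
#' single process it is the ordinary integrated likelihood of a univariate
#' random-effects transition model.
#'
#' @inheritParams pair_conditional_loglik
#' @return log-likelihood (or per-subject vector).
#' @export
full_conditional_loglik <- function(trans, params, rule = quad_rule(),
                                    per_subject = FALSE) {
  spec <- trans$spec
  bi <- block_info(spec, names(spec$processes))
  if (length(bi$bidx) > 4L)
    stop("full conditional likelihood is only evaluated for total random-effect dimension <= 4")
  prep <- prepare_eval(trans, params)
  ll <- integrated_loglik(trans, prep, params, names(spec$processes), rule)
  if (per_subject) ll else sum(ll)
}

#' Composite score (finite-difference gradient)
#'
#' Central finite-difference gradient of the composite conditional
#' log-likelihood with respect to the packed (unconstrained) parameter
#' vector, with per-parameter step scaling. With `per_subject = TRUE`
#' returns the matrix of per-subject score contributions used to estimate
#' the variability matrix.
#'
#' @inheritParams pair_conditional_loglik
#' @param theta packed parameter vector (see [pack_params()]).
#' @param rel_step relative step size for the central differences.
#' @param per_subject return the n-by-p matrix of per-subject scores.
#' @export
composite_score <- function(trans, theta, rule = quad_rule(),
                            rel_step = 1e-5, per_subject = FALSE) {
  spec <- trans$spec
  p <- length(theta)
  eval_at <- function(th) {
    cl <- composite_loglik(trans, unpack_params(th, spec), rule)
    if (per_subject) cl$by_subject else cl$value
  }
  out <- if (per_subject)
    matrix(0, trans$n_subjects, p, dimnames = list(NULL, names(theta)))
  else stats::setNames(numeric(p), names(theta))
  for (j in seq_len(p)) {
    hj <- rel_step * (1 + abs(theta[j]))
    tp <- tm <- theta
    tp[j] <- theta[j] + hj
    tm[j] <- theta[j] - hj
    gj <- (eval_at(tp) - eval_at(tm)) / (2 * hj)
    if (per_subject) out[, j] <- gj else out[j] <- gj
  }
  if (any(!is.finite(out))) stop("non-finite composite score")
  out
}
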