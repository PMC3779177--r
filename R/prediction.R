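#' Transition-probability matrix at fixed covariates and random effects
#'
#' For a categorical (ordinal or binary) process, tabulates the conditional
#' distribution of the next state for every prior state: row \eqn{\ell},
#' column \eqn{k} holds \eqn{P(Y_{j} = k \mid Y_{j-1} = \ell, x, b)}. The
#' prior state enters the linear predictor as its numeric level code times
#' the lag coefficient; `b = 0` gives the matrix of the median subject (the
#' link is nonlinear, so this is not the population-averaged matrix).
#'
#' @param spec a [joint_spec()].
#' @param params a `jmtrans_params`.
#' @param process process name.
#' @param covariates named list/vector with every covariate the process uses.
#' @param b random-effect value (scalar or vector matching the process's
#'   random design; default 0).
#' @return an object of class `transition_table`: the K x K matrix plus the
#'   setting it was evaluated at. Rows sum to 1.
#' @export
transition_matrix <- function(spec, params, process, covariates = list(), b = 0) {
  p <- spec$processes[[process]]
  if (is.null(p)) stop("unknown process: ", process)
  if (!p$family %in% c("ordinal", "binary"))
    stop("transition matrices are defined for categorical processes")
  parts <- params$processes[[process]]
  miss <- setdiff(p$covariates, names(covariates))
  if (length(miss))
    stop("covariate value(s) missing: ", paste(miss, collapse = ", "))
  if (length(b) == 1L && length(p$random) > 1L) b <- rep(b, length(p$random))
  K <- length(p$levels)
  M <- matrix(NA_real_, K, K,
              dimnames = list(prior = p$levels, next_state = p$levels))
  x <- lapply(covariates, as.numeric)
  for (l in seq_len(K)) {
    rec <- list(x = x, lags = rep(p$levels[l], p$lag_order))
    eta <- linear_predictor(p, parts, rec, b)
    M[l, ] <- if (p$family == "ordinal")
      ordinal_category_probs(parts$alpha, eta)
    else {
      pl <- stats::plogis(parts$alpha[1L] + eta)
      c(pl, 1 - pl)
    }
  }
  structure(list(process = process, covariates = covariates, b = b,
                 matrix = M),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, digits = 4, ...) {
  cat("Transition probabilities for ", x$process, " at ",
      paste(names(x$covariates), unlist(x$covariates), sep = "=", collapse = ", "),
      ", b = ", paste(format(x$b), collapse = ", "), "\n", sep = "")
  print(round(x$matrix, digits))
  invisible(x)
}

#' Write a transition table with its setting header
#'
#' Tab-delimited matrix preceded by `#`-comment lines recording the process,
#' covariate setting and random-effect value.
#'
#' @param x a [transition_matrix()] result.
#' @param path output file.
#' @export
write_transition_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# process: ", x$process),
               paste0("# covariates: ",
                      paste(names(x$covariates), unlist(x$covariates),
                            sep = "=", collapse = " ")),
               paste0("# b: ", paste(format(x$b), collapse = " "))), con)
  utils::write.table(format(x$matrix, digits = 10), con, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Empirical-Bayes prediction of subject random effects
#'
#' Posterior mode of \eqn{b_i} given the subject's observed transitions
#' under all processes jointly — the maximizer of \eqn{\sum_g \log f_g +
#' \log\phi(b; \Sigma)} — together with the inverse negative Hessian as a
#' posterior curvature (covariance) estimate. Subjects without transition
#' records fall back to the prior mode 0.
#'
#' @param data a [panel_data()] or `transition_set`.
#' @param spec a [joint_spec()] (ignored for a `transition_set`).
#' @param params a `jmtrans_params`.
#' @param subject optional subject id (default: all subjects).
#' @return list with `subjects`, `mode` (n x d matrix) and `vcov`
#'   (d x d x n array).
#' @export
empirical_bayes <- function(data, spec = NULL, params, subject = NULL) {
  trans <- if (inherits(data, "transition_set")) data
    else build_transitions(data, spec)
  spec <- trans$spec
  prep <- prepare_eval(trans, params)
  pm <- posterior_modes(trans, prep, names(spec$processes), solve(params$Sigma))
  d <- spec$dim_b
  S <- trans$n_subjects
  V <- array(0, c(d, d, S))
  for (i in seq_len(S)) {
    L <- matrix(pm$Larr[i, , ], d, d)
    V[, , i] <- tcrossprod(L)
  }
  out <- list(subjects = trans$subjects, mode = pm$mu, vcov = V)
  if (!is.null(subject)) {
    i <- match(as.character(subject), trans$subjects)
    if (is.na(i)) stop("unknown subject: ", subject)
    out <- list(subjects = subject, mode = pm$mu[i, , drop = FALSE],
                vcov = V[, , i, drop = FALSE])
  }
  out
}

#' Forecast a subject's future state distributions
#'
#' Chains the subject's empirical-Bayes transition matrix forward from the
#' last observed state: the fitted first-order model is treated as a
#' homogeneous Markov chain with the subject's covariates (and random
#' effects) frozen. The horizon-1 row is exactly the relevant row of
#' [transition_matrix()] at the EB mode.
#'
#' @param data a [panel_data()] or `transition_set`.
#' @param spec a [joint_spec()].
#' @param params a `jmtrans_params`.
#' @param subject subject id.
#' @param horizon number of future visits (>= 1).
#' @param processes processes to forecast (default: all categorical ones
#'   with first-order lags).
#' @return named list, one `horizon x K` probability matrix per process.
#' @export
subject_forecast <- function(data, spec = NULL, params, subject, horizon = 1L,
                             processes = NULL) {
  if (horizon < 1L) stop("horizon must be >= 1")
  trans <- if (inherits(data, "transition_set")) data
    else build_transitions(data, spec)
  spec <- trans$spec
  panel_row <- NULL
  eb <- empirical_bayes(trans, params = params, subject = subject)
  bmode <- drop(eb$mode)
  bl <- b_blocks(spec)
  if (is.null(processes))
    processes <- names(spec$processes)[vapply(spec$processes, function(p)
      p$family %in% c("ordinal", "binary") && p$lag_order == 1L, TRUE)]
  i <- match(as.character(subject), trans$subjects)
  out <- list()
  for (g in processes) {
    p <- spec$processes[[g]]
    pd <- trans$processes[[g]]
    sel <- which(pd$subject == i)
    if (!length(sel)) stop("subject ", subject, " has no transitions for ", g)
    last <- sel[length(sel)]
    covs <- as.list(pd$X[last, ])
    names(covs) <- colnames(pd$X)
    tm <- transition_matrix(spec, params, g, covs, b = bmode[bl[[g]]])
    K <- length(p$levels)
    dist <- matrix(0, horizon, K, dimnames = list(NULL, p$levels))
    v <- as.numeric(p$levels == pd$y[last])
    for (hstep in seq_len(horizon)) {
      v <- drop(v %*% tm$matrix)
      dist[hstep, ] <- v
    }
    out[[g]] <- dist
  }
  out
}
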