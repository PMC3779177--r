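# softplus and inverse, stable for large arguments
softplus <- function(u) ifelse(u > 30, u, log1p(exp(u)))
inv_softplus <- function(d) {
  if (any(d <= 0)) stop("increments must be strictly positive")
  ifelse(d > 30, d, log(expm1(d)))
}

#' Parameter set for a joint transition model
#'
#' Builds a template parameter list for a [joint_spec()]: per process the
#' ordinal cutpoints (or single intercept), fixed-effect coefficients `beta`,
#' lag coefficients `gamma`, and a Gaussian residual SD `sigma` where
#' relevant; plus the random-effects covariance matrix `Sigma`. All effects
#' start at zero, cutpoints at unit spacing, `Sigma` at the identity.
#'
#' @param spec a [joint_spec()].
#' @return an object of class `jmtrans_params`.
#' @export
param_template <- function(spec) {
  procs <- lapply(spec$processes, function(p) {
    K <- length(p$levels)
    alpha <- switch(p$family,
                    ordinal = seq(0, K - 2),
                    0)                       # single intercept otherwise
    out <- list(alpha = alpha,
                beta = stats::setNames(rep(0, length(p$covariates)), p$covariates),
                gamma = rep(0, p$lag_order))
    if (p$family == "gaussian") out$sigma <- 1
    out
  })
  names(procs) <- names(spec$processes)
  structure(list(processes = procs,
                 Sigma = diag(spec$dim_b)),
            class = "jmtrans_params")
}

# names of the packed vector, in packing order
packed_names <- function(spec) {
  nm <- unlist(lapply(spec$processes, function(p) {
    K <- length(p$levels)
    a <- if (p$family == "ordinal")
      c("alpha1", paste0("incr", seq_len(K - 2))) else "alpha1"
    c(paste0(p$name, ".", a),
      if (length(p$covariates)) paste0(p$name, ".", p$covariates),
      paste0(p$name, ".lag", seq_len(p$lag_order)),
      if (p$family == "gaussian") paste0(p$name, ".logsigma"))
  }), use.names = FALSE)
  d <- spec$dim_b
  w <- if (d > 1) {
    ij <- which(lower.tri(diag(d)), arr.ind = TRUE)
    sprintf("cov.w%d.%d", ij[, 1], ij[, 2])
  }
  c(nm, paste0("cov.logsd", seq_len(d)), w)
}

#' Pack parameters to an unconstrained real vector (and back)
#'
#' The optimizer works on an unconstrained vector: ordinal cutpoints are
#' stored as the first cutpoint plus inverse-softplus increments (so the
#' increasing-cutpoint constraint can never be violated), Gaussian SDs as
#' logs, and the random-effects covariance as log-SDs plus the strictly
#' lower-triangular entries of a row-normalized Cholesky factor of the
#' correlation matrix (so every packing maps to a symmetric positive-definite
#' matrix). `unpack_params(pack_params(p))` recovers `p` to machine
#' precision.
#'
#' @param params a `jmtrans_params` list.
#' @param spec a [joint_spec()].
#' @return `pack_params()`: a named numeric vector; `unpack_params()`: a
#'   `jmtrans_params`.
#' @export
pack_params <- function(params, spec) {
  out <- unlist(lapply(names(spec$processes), function(g) {
    p <- spec$processes[[g]]
    pp <- params$processes[[g]]
    a <- pp$alpha
    apacked <- if (p$family == "ordinal") c(a[1L], inv_softplus(diff(a))) else a
    c(apacked, pp$beta, pp$gamma,
      if (p$family == "gaussian") log(pp$sigma))
  }), use.names = FALSE)
  S <- params$Sigma
  d <- spec$dim_b
  stopifnot(nrow(S) == d)
  sds <- sqrt(diag(S))
  w <- if (d > 1) {
    R <- stats::cov2cor(S)
    L <- t(chol(R))
    (L / diag(L))[lower.tri(L)]
  }
  stats::setNames(c(out, log(sds), w), packed_names(spec))
}

#' @param theta packed numeric vector.
#' @rdname pack_params
#' @export
unpack_params <- function(theta, spec) {
  pos <- 0L
  take <- function(k) {
    v <- theta[pos + seq_len(k)]
    pos <<- pos + k
    v
  }
  procs <- lapply(spec$processes, function(p) {
    K <- length(p$levels)
    alpha <- if (p$family == "ordinal") {
      a1 <- take(1L)
      cumsum(c(a1, softplus(take(K - 2L))))
    } else take(1L)
    out <- list(alpha = unname(alpha),
                beta = stats::setNames(unname(take(length(p$covariates))), p$covariates),
                gamma = unname(take(p$lag_order)))
    if (p$family == "gaussian") out$sigma <- exp(unname(take(1L)))
    out
  })
  d <- spec$dim_b
  sds <- exp(take(d))
  Sigma <- if (d > 1) {
    L <- diag(d)
    L[lower.tri(L)] <- take(d * (d - 1L) / 2L)
    L <- L / sqrt(rowSums(L^2))         # rows to unit norm -> corr Cholesky
    R <- tcrossprod(L)
    diag(sds, d) %*% R %*% diag(sds, d)
  } else matrix(sds^2, 1, 1)
  structure(list(processes = procs, Sigma = (Sigma + t(Sigma)) / 2),
            class = "jmtrans_params")
}

#' Random-effects covariance implied by a parameter set
#'
#' Returns the covariance matrix together with the per-dimension variances
#' and the pairwise correlations — the quantities reported in the fit table,
#' where their sandwich standard errors are obtained by the delta method.
#'
#' @param params a `jmtrans_params`.
#' @return list with `Sigma`, `variances`, `correlations` (named lower-tri
#'   entries).
#' @export
implied_covariance <- function(params) {
  S <- params$Sigma
  d <- nrow(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (!all(is.finite(S)) || min(ev) <= 0)
    stop("implied covariance is not positive definite")
  R <- stats::cov2cor(S)
  ij <- which(lower.tri(S), arr.ind = TRUE)
  corr <- if (d > 1)
    stats::setNames(R[lower.tri(R)], sprintf("corr.%d.%d", ij[, 1], ij[, 2]))
  else numeric()
  list(Sigma = S, variances = diag(S), correlations = corr)
}

#' Serialize fitted parameters to a flat key=value text file
#'
#' @param params a `jmtrans_params`.
#' @param spec a [joint_spec()].
#' @param path output file.
#' @return the path, invisibly; `read_params()` returns the `jmtrans_params`.
#' @export
write_params <- function(params, spec, path) {
  th <- pack_params(params, spec)
  writeLines(sprintf("%s=%.17g", names(th), th), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path, spec) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  th <- stats::setNames(vapply(kv, function(x) as.numeric(x[2L]), 0),
                        vapply(kv, `[[`, "", 1L))
  want <- packed_names(spec)
  if (!all(want %in% names(th)))
    stop("parameter file is missing entries: ",
         paste(setdiff(want, names(th)), collapse = ", "))
  unpack_params(unname(th[want]), spec)
}
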