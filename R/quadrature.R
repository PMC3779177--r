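#' Gauss-Hermite quadrature rule for random-effects integration
#'
#' The integrals over the random-effects distribution are evaluated by
#' Gauss-Hermite quadrature, by default *adaptive*: the node grid is
#' recentered at each subject's posterior mode of the random effects and
#' rescaled by the posterior curvature, which makes a modest number of nodes
#' per dimension accurate for the near-Gaussian integrands that
#' random-intercept logistic/ordinal transition models produce. With
#' `adaptive = FALSE` the grid is centered at the prior mode (zero) and
#' scaled by the prior covariance.
#'
#' @param nodes nodes per random-effect dimension (>= 3; default 15).
#' @param adaptive recenter/rescale per subject (default `TRUE`).
#' @return an object of class `quad_rule`.
#' @export
quad_rule <- function(nodes = 15L, adaptive = TRUE) {
  nodes <- as.integer(nodes)
  if (nodes < 3L) stop("at least 3 quadrature nodes per dimension")
  gh <- pracma::gaussHermite(nodes)
  structure(list(m = nodes, x = gh$x, w = gh$w, adaptive = isTRUE(adaptive)),
            class = "quad_rule")
}

#' @export
print.quad_rule <- function(x, ...) {
  cat("<quad_rule> ", x$m, " Gauss-Hermite nodes/dimension, ",
      if (x$adaptive) "adaptive" else "prior-centered", "\n", sep = "")
  invisible(x)
}

# tensor grid over d dimensions: list(z = K x d matrix of sqrt(2)*x nodes,
# lw = log product weights, zz2 = |z|^2/2 correction); memoized per (m, d)
.grid_memo <- new.env(parent = emptyenv())
gh_grid <- function(rule, d) {
  key <- paste0(rule$m, ".", d)
  g <- .grid_memo[[key]]
  if (!is.null(g)) return(g)
  m <- rule$m
  idx <- as.matrix(expand.grid(rep(list(seq_len(m)), d)))
  z <- matrix(sqrt(2) * rule$x[idx], ncol = d)
  lw <- rowSums(matrix(log(rule$w)[idx], ncol = d))
  g <- list(z = z, lw = lw, zz2 = rowSums(z^2) / 2, K = m^d)
  .grid_memo[[key]] <- g
  g
}

# row-wise log-sum-exp, guarding all -Inf rows
logsumexp_rows <- function(a) {
  m <- a[cbind(seq_len(nrow(a)), max.col(a, ties.method = "first"))]
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(a - m)))
}
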