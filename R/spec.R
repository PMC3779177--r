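#' Declare a single transition-model process
#'
#' A process is one longitudinal outcome (e.g. a dementia rating, a
#' dichotomized cognitive screen, a count) together with the regression
#' structure of its Markov transition submodel: the exponential family, the
#' level set for categorical outcomes, the lag order \eqn{q}, the fixed-effect
#' covariates, the random-effects design, and the form in which past states
#' enter the linear predictor.
#'
#' The linear predictor of the submodel for process \eqn{g} at visit \eqn{j} is
#' \deqn{\eta_{gij} = x_{gij}'\beta_g + f_g(H_{gij}; \gamma_g) + z_{gij}' b_{gi},}
#' where \eqn{H_{gij}} is the history of the previous \eqn{q} states. For the
#' ordinal family the cumulative logit of lower (better) states is modeled,
#' \eqn{\mathrm{logit}\, P(Y_{gij} \le k) = \alpha_{gk} + \eta_{gij}} with
#' increasing cutpoints \eqn{\alpha_{g1} < \dots < \alpha_{g,K-1}}; the binary
#' family is the two-level special case \eqn{\mathrm{logit}\, P(Y = y_{low}) =
#' \alpha_g + \eta_{gij}}.
#'
#' @param name process name; must match the outcome column in the panel.
#' @param family one of `"ordinal"`, `"binary"`, `"gaussian"`, `"poisson"`.
#' @param levels ordered numeric level codes (ordinal/binary only), best to
#'   worst. Lagged states enter the predictor as these numeric codes.
#' @param lag_order Markov order \eqn{q \ge 1}.
#' @param covariates character vector of fixed-effect covariate columns.
#' @param random random-effects design: a subset of `"intercept"`, the
#'   covariate names, and `"lag1"`, ..., `"lagq"`. Default random intercept.
#' @param lag_form how past states enter: `"linear"` (numeric lag codes times
#'   coefficients; all families), `"zeger_qaqish"` (Poisson only,
#'   \eqn{\gamma[\log\max(y_{prev}, c) - x'\beta]}), or `"log_linear"`
#'   (Poisson, \eqn{\gamma \log(y_{prev} + 1)}).
#' @param poisson_floor floor constant \eqn{c \in (0,1)} preventing an
#'   absorbing zero state under `"zeger_qaqish"`.
#' @return an object of class `process_spec`.
#' @seealso [joint_spec()]
#' @export
process_spec <- function(name, family = c("ordinal", "binary", "gaussian", "poisson"),
                         levels = NULL, lag_order = 1L,
                         covariates = character(), random = "intercept",
                         lag_form = c("linear", "zeger_qaqish", "log_linear"),
                         poisson_floor = 0.5) {
  family <- match.arg(family)
  lag_form <- match.arg(lag_form)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  lag_order <- as.integer(lag_order)
  if (lag_order < 1L) stop("lag_order must be a positive integer")
  if (family %in% c("ordinal", "binary")) {
    if (is.null(levels)) {
      if (family == "binary") levels <- c(0, 1)
      else stop("ordinal process '", name, "' needs a declared level set")
    }
    levels <- as.numeric(levels)
    if (anyDuplicated(levels) || is.unsorted(levels))
      stop("levels must be strictly increasing numeric codes")
    if (family == "ordinal" && length(levels) < 2L)
      stop("ordinal process needs at least 2 levels")
    if (family == "binary" && length(levels) != 2L)
      stop("binary process needs exactly 2 levels")
  } else {
    levels <- NULL
  }
  if (lag_form != "linear" && family != "poisson")
    stop("lag_form '", lag_form, "' is only available for the poisson family")
  if (!(poisson_floor > 0 && poisson_floor < 1))
    stop("poisson_floor must lie in (0, 1)")
  lag_names <- paste0("lag", seq_len(lag_order))
  allowed <- c("intercept", covariates, lag_names)
  random <- as.character(random)
  if (length(random) && !all(random %in% allowed))
    stop("random design terms must be among: ", paste(allowed, collapse = ", "))
  structure(
    list(name = name, family = family, levels = levels,
         lag_order = lag_order, covariates = as.character(covariates),
         random = random, lag_form = lag_form, poisson_floor = poisson_floor),
    class = "process_spec")
}

#' Assemble a joint model from process declarations
#'
#' The joint model links the per-process transition submodels through a
#' mean-zero multivariate normal distribution over the stacked random-effect
#' vectors \eqn{b_i = (b_{1i}', \dots, b_{Gi}')'} with covariance
#' \eqn{\Sigma}. `covariance = "unstructured"` leaves \eqn{\Sigma} a free
#' symmetric positive-definite matrix; `"shared"` constrains the processes'
#' random effects to be a single common vector (\eqn{b_{gi} \equiv b_i},
#' loading fixed to 1 for every process), which requires all processes to have
#' the same random-design dimension.
#'
#' @param ... `process_spec` objects (or a single list of them).
#' @param covariance `"unstructured"` or `"shared"`.
#' @return an object of class `joint_spec` with elements `processes`,
#'   `covariance`, and the total random-effect dimension `dim_b`.
#' @export
joint_spec <- function(..., covariance = c("unstructured", "shared")) {
  covariance <- match.arg(covariance)
  procs <- list(...)
  if (length(procs) == 1L && !inherits(procs[[1L]], "process_spec"))
    procs <- procs[[1L]]
  if (!length(procs) || !all(vapply(procs, inherits, TRUE, "process_spec")))
    stop("joint_spec() takes one or more process_spec objects")
  nms <- vapply(procs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("process names must be unique")
  names(procs) <- nms
  d_g <- vapply(procs, function(p) length(p$random), 0L)
  if (covariance == "shared" && length(unique(d_g)) != 1L)
    stop("shared covariance requires equal random-design dimension across processes")
  dim_b <- if (covariance == "shared") d_g[[1L]] else sum(d_g)
  structure(list(processes = procs, covariance = covariance,
                 d_g = d_g, dim_b = dim_b),
            class = "joint_spec")
}

#' @export
print.process_spec <- function(x, ...) {
  cat("<process_spec> ", x$name, ": ", x$family, sep = "")
  if (!is.null(x$levels)) cat(" {", paste(x$levels, collapse = ", "), "}", sep = "")
  cat(", q = ", x$lag_order, sep = "")
  if (length(x$covariates)) cat(", covariates: ", paste(x$covariates, collapse = " + "), sep = "")
  cat(", random: ", paste(x$random, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' @export
print.joint_spec <- function(x, ...) {
  cat("<joint_spec> ", length(x$processes), " processes, ",
      x$covariance, " random-effects covariance (dim ", x$dim_b, ")\n", sep = "")
  for (p in x$processes) print(p)
  invisible(x)
}

# number of processes
n_proc <- function(spec) length(spec$processes)

# indices of each process's random-effect block within the stacked b vector
b_blocks <- function(spec) {
  if (spec$covariance == "shared") {
    idx <- seq_len(spec$dim_b)
    return(lapply(spec$processes, function(p) idx))
  }
  ends <- cumsum(spec$d_g)
  starts <- ends - spec$d_g + 1L
  Map(function(s, e) seq.int(s, e), starts, ends)
}
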