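#' Long-format multivariate longitudinal panel
#'
#' `panel_data()` validates a long-format data frame — one row per
#' subject-visit — against a [joint_spec()]: required columns present, visits
#' consecutive within subject, ordinal/binary outcomes inside their declared
#' level sets, counts non-negative. Subjects whose visit sequence has a gap
#' are truncated to their longest initial consecutive run (with a warning);
#' the transition models assume no intermittent missingness.
#'
#' @param df data frame with columns `subject`, `visit`, one column per
#'   process outcome, and all covariate columns named in the spec.
#' @param spec a [joint_spec()].
#' @return the validated, (subject, visit)-sorted data frame with class
#'   `panel_data`.
#' @export
panel_data <- function(df, spec) {
  df <- as.data.frame(df)
  need <- c("subject", "visit", names(spec$processes),
            unique(unlist(lapply(spec$processes, `[[`, "covariates"))))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  df$subject <- as.character(df$subject)
  df$visit <- as.integer(df$visit)
  df <- df[order(df$subject, df$visit), , drop = FALSE]
  if (anyDuplicated(df[c("subject", "visit")]))
    stop("duplicated (subject, visit) rows")

  # truncate each subject to the longest initial consecutive visit run
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$subject), function(ix) {
    v <- df$visit[ix]
    run <- which(v != v[1L] + seq_along(v) - 1L)
    if (length(run)) ix[seq_len(run[1L] - 1L)] else ix
  }), use.names = FALSE)
  if (length(keep) < nrow(df)) {
    dropped <- nrow(df) - length(keep)
    warning(sprintf(
      "%d row(s) dropped: non-consecutive visits truncated to the longest initial run",
      dropped))
    df <- df[sort(keep), , drop = FALSE]
  }

  for (p in spec$processes) {
    y <- df[[p$name]]
    if (anyNA(y)) stop("missing values in outcome '", p$name, "'")
    if (p$family %in% c("ordinal", "binary")) {
      bad <- which(!(y %in% p$levels))
      if (length(bad))
        stop("outcome '", p$name, "' has value ", y[bad[1L]],
             " outside its level set at row ", bad[1L])
    } else if (p$family == "poisson") {
      if (any(y < 0) || any(y != round(y)))
        stop("count outcome '", p$name, "' must be non-negative integers")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("panel_data", "data.frame")
  df
}

#' Read / write a long-format panel file
#'
#' Delimited text with a header row (comma by default, tab accepted and
#' auto-detected on read). Columns: `subject`, `visit`, one per process
#' outcome, plus covariates. Reading validates through [panel_data()].
#'
#' @param path file path.
#' @param spec a [joint_spec()].
#' @param sep field separator for writing; reading auto-detects `,` vs tab.
#' @return `read_panel()` returns a `panel_data`; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path, spec, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  panel_data(df, spec)
}

#' @param x a `panel_data`.
#' @rdname read_panel
#' @export
write_panel <- function(x, path, sep = ",") {
  df <- as.data.frame(x)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dichotomize a 0-30 cognitive screening score at the 23/24 cutoff
#'
#' Scores of 23 or below are classified impaired (1), 24-30 unimpaired (0) —
#' the conventional cutoff used to detect cognitive impairment on the 0-30
#' Mini-Mental State Examination scale.
#'
#' @param score integer vector in 0..30.
#' @return integer vector of 0 (unimpaired) / 1 (impaired).
#' @export
dichotomize_mmse <- function(score) {
  if (any(score < 0 | score > 30 | score != round(score), na.rm = TRUE))
    stop("score must be an integer in 0..30")
  as.integer(score <= 23)
}

#' Categorize a 0-30 functional-disability score into five ordinal levels
#'
#' Returns the number of `breaks` that are less than or equal to the score,
#' giving levels 0..4 (normal through complete disability) under a half-open
#' convention: a score equal to a break falls in the higher level. The default
#' breaks isolate 0 as "normal" and split the rest into equal-width bins:
#' 0 / 1-8 / 9-16 / 17-24 / 25-30.
#'
#' @param score integer vector in 0..30.
#' @param breaks four strictly increasing thresholds within 0..30.
#' @return integer vector of levels 0..4.
#' @export
categorize_faq <- function(score, breaks = c(1, 9, 17, 25)) {
  if (length(breaks) != 4L || is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be 4 strictly increasing thresholds")
  if (any(score < 0 | score > 30, na.rm = TRUE))
    stop("score must lie in 0..30")
  rowSums(outer(score, breaks, `>=`))
}

#' Build per-process transition records
#'
#' Expands a panel into the records the conditional likelihood is built from:
#' for each process \eqn{g} and each visit \eqn{j > q}, the target value
#' \eqn{y_{gij}}, its \eqn{q} lagged values, the covariate row, and the
#' random-effects design row. The first \eqn{q} visits of every subject are
#' conditioned on, never modeled; subjects with \eqn{T_i \le q} contribute
#' nothing.
#'
#' @param data a [panel_data()].
#' @param spec a [joint_spec()].
#' @return an object of class `transition_set`: a list with `subjects` (ids)
#'   and per-process components holding `y`, `yidx` (1-based category index
#'   for ordinal/binary), `lags` (n x q matrix of numeric lag codes), `X`
#'   (covariate matrix), `Z` (random-design matrix) and `subject` (integer
#'   index into `subjects`).
#' @export
build_transitions <- function(data, spec) {
  stopifnot(inherits(data, "panel_data"))
  subjects <- unique(data$subject)
  si <- match(data$subject, subjects)
  ord <- order(si, data$visit)
  data <- data[ord, , drop = FALSE]
  si <- si[ord]
  first <- !duplicated(si)
  Tlen <- tabulate(si, nbins = length(subjects))

  procs <- lapply(spec$processes, function(p) {
    q <- p$lag_order
    yfull <- as.numeric(data[[p$name]])
    # within-subject row offsets
    off <- sequence(Tlen)            # 1..T_i within each subject
    keep <- off > q
    n <- sum(keep)
    lags <- matrix(0, n, q)
    idx <- which(keep)
    for (l in seq_len(q)) lags[, l] <- yfull[idx - l]
    X <- if (length(p$covariates))
      as.matrix(data[idx, p$covariates, drop = FALSE]) else
      matrix(0, n, 0)
    storage.mode(X) <- "double"
    Z <- matrix(0, n, length(p$random),
                dimnames = list(NULL, p$random))
    for (r in seq_along(p$random)) {
      term <- p$random[r]
      Z[, r] <- if (term == "intercept") 1
        else if (grepl("^lag[0-9]+$", term)) lags[, as.integer(sub("lag", "", term))]
        else X[, term]
    }
    yidx <- if (p$family %in% c("ordinal", "binary"))
      match(yfull[idx], p$levels) else rep(NA_integer_, n)
    list(y = yfull[idx], yidx = yidx, lags = lags, X = X, Z = Z,
         subject = si[idx])
  })
  names(procs) <- names(spec$processes)
  structure(list(subjects = subjects, n_subjects = length(subjects),
                 processes = procs, spec = spec),
            class = "transition_set")
}

#' @export
print.transition_set <- function(x, ...) {
  cat("<transition_set> ", x$n_subjects, " subjects\n", sep = "")
  for (g in names(x$processes))
    cat("  ", g, ": ", length(x$processes[[g]]$y), " transition records\n", sep = "")
  invisible(x)
}
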