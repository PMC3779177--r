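# shared fixtures: small simulation scenarios used across test files

# two processes (binary + 3-level ordinal), one covariate, random intercepts
toy_spec <- function() {
  joint_spec(
    process_spec("B", "binary", levels = c(0, 1), covariates = "x"),
    process_spec("O", "ordinal", levels = 0:2, covariates = "x"))
}

toy_params <- function(rho = 0.5, v1 = 1, v2 = 1) {
  spec <- toy_spec()
  par <- param_template(spec)
  par$processes$B$alpha <- 0.5
  par$processes$B$beta[] <- 0.8
  par$processes$B$gamma <- -1
  par$processes$O$alpha <- c(-0.5, 1.5)
  par$processes$O$beta[] <- 0.5
  par$processes$O$gamma <- -0.8
  par$Sigma <- matrix(c(v1, rho * sqrt(v1 * v2), rho * sqrt(v1 * v2), v2), 2)
  par
}

toy_scenario <- function(n, T_visits = 5, seed = 1, rho = 0.5) {
  scenario_config(n, T_visits, seed, toy_spec(), toy_params(rho),
                  covariate_gen = function(n) data.frame(x = stats::runif(n, 0, 2)),
                  init = list(B = c(0.5, 0.5), O = c(0.4, 0.3, 0.3)))
}

toy_panel <- function(n, T_visits = 5, seed = 1, rho = 0.5) {
  simulate_panel(toy_scenario(n, T_visits, seed, rho))
}

# two binary processes (cheapest families) for repeated-fit studies
bin2_spec <- function() {
  joint_spec(
    process_spec("P1", "binary", levels = c(0, 1), covariates = "x"),
    process_spec("P2", "binary", levels = c(0, 1), covariates = "x"))
}

bin2_params <- function(rho = 0.5) {
  spec <- bin2_spec()
  par <- param_template(spec)
  par$processes$P1$alpha <- 0.5
  par$processes$P1$beta[] <- 0.8
  par$processes$P1$gamma <- -1
  par$processes$P2$alpha <- -0.3
  par$processes$P2$beta[] <- 0.6
  par$processes$P2$gamma <- 0.9
  par$Sigma <- matrix(c(1, rho, rho, 1), 2)
  par
}

bin2_scenario <- function(n, T_visits = 5, seed = 1, rho = 0.5) {
  scenario_config(n, T_visits, seed, bin2_spec(), bin2_params(rho),
                  covariate_gen = function(n) data.frame(x = stats::runif(n, 0, 2)),
                  init = list(P1 = c(0.5, 0.5), P2 = c(0.5, 0.5)))
}

# dense 2-D trapezoid integration of the pair likelihood (independent oracle)
trapezoid_pair_loglik <- function(trans, g, h, params, npts = 400, span = 8) {
  spec <- trans$spec
  prep <- jmtrans:::prepare_eval(trans, params)
  sd1 <- sqrt(params$Sigma[1, 1])
  sd2 <- sqrt(params$Sigma[2, 2])
  g1 <- seq(-span * sd1, span * sd1, length.out = npts)
  g2 <- seq(-span * sd2, span * sd2, length.out = npts)
  Om <- solve(params$Sigma)
  ldet <- determinant(params$Sigma)$modulus[1]
  BB <- as.matrix(expand.grid(g1, g2))
  lphi <- -log(2 * pi) - 0.5 * ldet - 0.5 * rowSums((BB %*% Om) * BB)
  h1 <- g1[2] - g1[1]
  h2 <- g2[2] - g2[1]
  w <- rep(1, npts); w[c(1, npts)] <- 0.5
  W <- outer(w, w)
  tot <- 0
  for (i in seq_len(trans$n_subjects)) {
    M <- matrix(lphi, npts, npts)
    for (k in c(1, 2)) {
      gnm <- c(g, h)[k]
      pd <- trans$processes[[gnm]]
      sel <- pd$subject == i
      if (!any(sel)) next
      pdi <- list(y = pd$y[sel], yidx = pd$yidx[sel])
      gv <- if (k == 1) g1 else g2
      ETA <- outer(prep[[gnm]]$ef[sel], gv, `+`)
      ld <- colSums(jmtrans:::logdens_eta(spec$processes[[gnm]],
                                          prep[[gnm]]$parts, pdi, ETA))
      M <- M + if (k == 1) matrix(ld, npts, npts)
        else matrix(ld, npts, npts, byrow = TRUE)
    }
    tot <- tot + log(sum(exp(M) * W) * h1 * h2)
  }
  tot
}
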