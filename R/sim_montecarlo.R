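#' Configuration for the Monte Carlo estimator study
#'
#' Each iteration simulates k two-arm studies with per-arm sizes drawn
#' from `round(N(n_mean, n_sd^2))` (floored at 2), control observations
#' `N(0, sigma2)` and case observations `N(mu_i, sigma2)` with the true
#' study effect `mu_i ~ N(0, tau2)`.  Effect sizes are computed with the
#' chosen measure and all six between-study variance estimators are
#' applied.
#'
#' @param k_list Numbers of studies to sweep.
#' @param tau2_list True between-study variances to sweep.
#' @param n_mean,n_sd Mean and standard deviation of the per-arm sample
#'   size distribution.
#' @param sigma2 Common within-arm observation variance.
#' @param n_iter Iterations (independent meta-analyses) per setting.
#' @param measure `"SMD"` or `"MD"`.
#' @param seed Integer seed.
#' @return A list of class `"mc_config"`.
#' @export
mc_config <- function(k_list = c(5, 10, 20, 40, 80),
                      tau2_list = c(0, 1), n_mean = 40, n_sd = 40 / 3,
                      sigma2 = 10, n_iter = 1000,
                      measure = c("SMD", "MD"), seed = 1L) {
  measure <- match.arg(measure)
  stopifnot(all(k_list >= 2), all(tau2_list >= 0), n_mean > 0, n_sd > 0,
            sigma2 > 0, n_iter >= 1)
  structure(list(k_list = k_list, tau2_list = tau2_list, n_mean = n_mean,
                 n_sd = n_sd, sigma2 = sigma2, n_iter = n_iter,
                 measure = measure, seed = as.integer(seed)),
            class = "mc_config")
}

mc_estimators <- function() c("DSL", "DSLR2", "PM", "RML", "SJ", "DSLD2")

#' One Monte Carlo iteration
#'
#' Simulates one meta-analysis of `k` studies under the model described in
#' [mc_config()] and returns every estimator's between-study variance
#' estimate together with its I-squared.
#'
#' @param k Number of studies.
#' @param tau2 True between-study variance on the raw-mean scale.
#' @param measure `"SMD"` or `"MD"`.
#' @param n_mean,n_sd,sigma2 As in [mc_config()].
#' @param fixed_n Optional fixed per-arm size overriding the random draw
#'   (used by reduction checks).
#' @return A list with numeric vectors `tau2_hat` and `i2`, named by
#'   estimator, and the per-study `y`, `s2`.
#' @export
mc_iteration <- function(k, tau2, measure = c("SMD", "MD"), n_mean = 40,
                         n_sd = 40 / 3, sigma2 = 10, fixed_n = NULL) {
  measure <- match.arg(measure)
  n <- if (is.null(fixed_n)) pmax(2L, as.integer(round(stats::rnorm(
    k, n_mean, n_sd)))) else rep(as.integer(fixed_n), k)
  mu_case <- if (tau2 > 0) stats::rnorm(k, 0, sqrt(tau2)) else numeric(k)
  y <- s2 <- numeric(k)
  for (i in seq_len(k)) {
    ctrl <- stats::rnorm(n[i], 0, sqrt(sigma2))
    case <- stats::rnorm(n[i], mu_case[i], sqrt(sigma2))
    sm <- two_group_summary(n[i], n[i], mean(ctrl), mean(case),
                            stats::sd(ctrl), stats::sd(case))
    eff <- if (measure == "MD") md_effect(sm) else smd_effect(sm)
    y[i] <- eff$y; s2[i] <- eff$s2
  }
  ests <- mc_estimators()
  t2 <- i2 <- stats::setNames(numeric(length(ests)), ests)
  for (m in ests) {
    t2[m] <- tau2_fun(m)(y, s2)$tau2
    i2[m] <- i_squared(t2[m], s2)
  }
  list(tau2_hat = t2, i2 = i2, y = y, s2 = s2)
}

#' Run the Monte Carlo estimator study
#'
#' Sweeps the configured numbers of studies and true between-study
#' variances, and reports each estimator's bias, root mean square error
#' and mean I-squared over the iterations, with Monte Carlo standard
#' errors.  On the standardized-mean-difference scale the generating
#' between-study variance of the raw means corresponds to `tau2 / sigma2`,
#' and the bias/RMSE are scored against that value.
#'
#' @param cfg An [mc_config()].
#' @return Long data frame with columns `method`, `k`, `tau2`, `measure`,
#'   `tau2_true_scored`, `bias`, `rmse`, `mean_i2`, `mc_se`, `n_iter`.
#'   The matrix of raw estimates per setting is attached as attribute
#'   `"draws"` (a named list).
#' @export
run_mc <- function(cfg = mc_config()) {
  stopifnot(inherits(cfg, "mc_config"))
  set.seed(cfg$seed)
  ests <- mc_estimators()
  rows <- list()
  draws <- list()
  for (k in cfg$k_list) {
    for (t2 in cfg$tau2_list) {
      est_mat <- matrix(NA_real_, cfg$n_iter, length(ests),
                        dimnames = list(NULL, ests))
      i2_mat <- est_mat
      for (it in seq_len(cfg$n_iter)) {
        r <- mc_iteration(k, t2, cfg$measure, cfg$n_mean, cfg$n_sd,
                          cfg$sigma2)
        est_mat[it, ] <- r$tau2_hat
        i2_mat[it, ] <- r$i2
      }
      scored <- if (cfg$measure == "SMD") t2 / cfg$sigma2 else t2
      err <- est_mat - scored
      rows[[length(rows) + 1]] <- data.frame(
        method = ests, k = k, tau2 = t2, measure = cfg$measure,
        tau2_true_scored = scored,
        bias = colMeans(err),
        rmse = sqrt(colMeans(err^2)),
        mean_i2 = colMeans(i2_mat),
        mc_se = apply(est_mat, 2, stats::sd) / sqrt(cfg$n_iter),
        n_iter = cfg$n_iter, stringsAsFactors = FALSE)
      draws[[sprintf("k%d_tau%g", k, t2)]] <- est_mat
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "draws") <- draws
  out
}
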