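## Between-study variance estimators.
##
## All estimators take a vector of observed effect sizes y (one per study)
## and strictly positive within-study variances s2, and return a
## "tau2_estimate": the heterogeneity estimate plus diagnostics (Cochran's
## Q at fixed-effects weights, truncation flag, iteration count,
## convergence flag).

new_tau2 <- function(method, tau2, Q, truncated = FALSE, iterations = 0L,
                     converged = TRUE) {
  structure(list(method = method, tau2 = tau2, Q = Q,
                 truncated = truncated, iterations = as.integer(iterations),
                 converged = converged),
            class = "tau2_estimate")
}

#' @export
print.tau2_estimate <- function(x, ...) {
  cat(sprintf("tau^2 (%s) = %.6g  [Q = %.4g%s]\n", x$method, x$tau2, x$Q,
              if (x$truncated) ", truncated at 0" else ""))
  invisible(x)
}

check_ys2 <- function(y, s2) {
  if (length(y) != length(s2))
    stop("y and s2 must have the same length", call. = FALSE)
  if (length(y) < 2)
    stop("at least 2 studies are required", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(s2)) || any(s2 <= 0))
    stop("all s2 must be finite and strictly positive", call. = FALSE)
}

## denominator of the DerSimonian-Laird moment equation
dsl_denom <- function(w) sum(w) - sum(w^2) / sum(w)

#' Cochran's Q statistic
#'
#' Q at fixed-effects (inverse within-study variance) weights, together
#' with the fixed-effects pooled mean it is measured around.
#'
#' @param y Observed effect sizes, one per study (k >= 2).
#' @param s2 Within-study variances, strictly positive.
#' @return List with elements `Q` and `M_fem`.
#' @export
#' @examples
#' cochran_q(c(0, 2, 4), c(1, 1, 1))  # Q = 8, M = 2
cochran_q <- function(y, s2) {
  check_ys2(y, s2)
  w <- 1 / s2
  M <- sum(w * y) / sum(w)
  list(Q = sum(w * (y - M)^2), M_fem = M)
}

#' DerSimonian-Laird estimator
#'
#' The moment estimator `max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))`
#' with `w = 1/s2`.
#'
#' @inheritParams cochran_q
#' @return A `tau2_estimate`.
#' @export
#' @examples
#' tau2_dsl(c(0, 2, 4), c(1, 1, 1))  # tau2 = 3
tau2_dsl <- function(y, s2) {
  check_ys2(y, s2)
  w <- 1 / s2
  den <- dsl_denom(w)
  if (den <= 0 || !is.finite(den))
    stop("degenerate weights: all weight concentrated in one study",
         call. = FALSE)
  Q <- cochran_q(y, s2)$Q
  raw <- (Q - (length(y) - 1)) / den
  new_tau2("DSL", max(0, raw), Q, truncated = raw < 0)
}

#' Paule-Mandel estimator
#'
#' Solves the generalized-Q estimating equation
#' `sum((y - M*(tau2))^2 / (s2 + tau2)) = k - 1` for `tau2` by bracketed
#' root-finding; the left-hand side is continuous and non-increasing in
#' `tau2`, so the root is unique.  If the equation is already below
#' `k - 1` at `tau2 = 0` the estimate is truncated at 0.
#'
#' @inheritParams cochran_q
#' @param tol Root-finding tolerance on tau2.
#' @return A `tau2_estimate`.
#' @export
tau2_pm <- function(y, s2, tol = 1e-10) {
  check_ys2(y, s2)
  k <- length(y)
  Q <- cochran_q(y, s2)$Q
  Ffun <- function(t2) {
    w <- 1 / (s2 + t2)
    M <- sum(w * y) / sum(w)
    sum(w * (y - M)^2) - (k - 1)
  }
  if (Ffun(0) <= 0)
    return(new_tau2("PM", 0, Q, truncated = TRUE))
  upper <- max(s2, stats::var(y))
  it <- 0L
  while (Ffun(upper) > 0) {
    upper <- upper * 2
    it <- it + 1L
    if (upper > 1e6 * max(s2))
      stop("Paule-Mandel bracket expansion failed to converge",
           call. = FALSE)
  }
  root <- stats::uniroot(Ffun, c(0, upper), tol = tol)
  new_tau2("PM", root$root, Q, iterations = it + root$iter,
           converged = TRUE)
}

#' Restricted maximum likelihood estimator
#'
#' Maximizes the restricted log-likelihood of the random-effects model
#' (the profile form with the `-0.5 * log(sum(1/(s2 + tau2)))` adjustment)
#' by scoring iterations started at the DerSimonian-Laird estimate; the
#' overall mean is profiled out as the inverse-variance weighted mean at
#' each step.  Negative estimates are truncated to 0.
#'
#' @inheritParams cochran_q
#' @param tol Convergence tolerance on successive tau2 values.
#' @param max_iter Maximum number of scoring iterations.
#' @return A `tau2_estimate`; `converged = FALSE` (with a warning) if the
#'   iteration limit is reached.
#' @export
tau2_rml <- function(y, s2, tol = 1e-8, max_iter = 100L) {
  check_ys2(y, s2)
  Q <- cochran_q(y, s2)$Q
  t2 <- tau2_dsl(y, s2)$tau2
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    w <- 1 / (s2 + t2)
    mu <- sum(w * y) / sum(w)
    e2 <- (y - mu)^2
    ## scoring update: solves the REML score equation at convergence
    t2_new <- sum(w^2 * (e2 - s2)) / sum(w^2) + 1 / sum(w)
    t2_new <- max(0, t2_new)
    if (abs(t2_new - t2) < tol) {
      t2 <- t2_new
      converged <- TRUE
      break
    }
    t2 <- t2_new
    if (it >= max_iter) break
  }
  if (!converged) {
    ## scoring can oscillate on awkward instances; fall back to bracketed
    ## root-finding on the REML score, which shares the same zero
    score <- function(t2) {
      v <- s2 + t2
      w <- 1 / v
      mu <- sum(w * y) / sum(w)
      sum((y - mu)^2 / v^2) + sum(w^2) / sum(w) - sum(w)
    }
    if (score(0) <= 0) {
      t2 <- 0
      converged <- TRUE
    } else {
      upper <- max(s2, stats::var(y))
      while (score(upper) > 0 && upper < 1e6 * max(s2)) upper <- upper * 2
      if (score(upper) <= 0) {
        t2 <- stats::uniroot(score, c(0, upper), tol = tol)$root
        converged <- TRUE
      }
    }
  }
  if (!converged)
    warning("REML estimation did not converge", call. = FALSE)
  new_tau2("RML", t2, Q, truncated = t2 == 0, iterations = it,
           converged = converged)
}

#' Restricted log-likelihood of the random-effects model
#'
#' The profile restricted log-likelihood evaluated at `tau2` with the mean
#' profiled out; used by the scoring iterations' oracle checks and
#' exported for diagnostics.
#'
#' @inheritParams cochran_q
#' @param tau2 Between-study variance value (>= 0).
#' @return The restricted log-likelihood value.
#' @export
reml_loglik <- function(tau2, y, s2) {
  v <- s2 + tau2
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  -0.5 * sum(log(v)) - 0.5 * sum((y - mu)^2 / v) - 0.5 * log(sum(w))
}

#' Sidik-Jonkman estimator
#'
#' Two-step estimator: an initial crude estimate
#' `tau0^2 = max(0.01, var_raw)` with
#' `var_raw = sum((y - mean(y))^2) / (k - 1) - mean(s2)`, then one
#' reweighting step `tau^2 = sum(w* (y - M*)^2) / (k - 1)` with
#' `w* = 1 / (1 + s2 / tau0^2)`.
#'
#' @inheritParams cochran_q
#' @return A `tau2_estimate`.
#' @export
#' @examples
#' tau2_sj(c(0, 2, 4), c(1, 1, 1))  # tau2 = 3
tau2_sj <- function(y, s2) {
  check_ys2(y, s2)
  k <- length(y)
  Q <- cochran_q(y, s2)$Q
  t0 <- max(0.01, sum((y - mean(y))^2) / (k - 1) - mean(s2))
  ws <- 1 / (1 + s2 / t0)
  M <- sum(ws * y) / sum(ws)
  new_tau2("SJ", sum(ws * (y - M)^2) / (k - 1), Q)
}

#' Two-step R-squared heterogeneity statistic
#'
#' After a DerSimonian-Laird fit, the relative drop in the weighted sum of
#' squared deviations when moving from fixed-effects to random-effects
#' weights and means:
#' `R^2 = 1 - sum(w* (y - M*)^2) / Q`.  The statistic (truncated below at
#' 0) is then used in place of a between-study variance in the pooling
#' weights, mirroring the two-step structure of the D-squared method.
#' `Q = 0` (no dispersion at all) returns 0.
#'
#' @inheritParams cochran_q
#' @return A `tau2_estimate`.
#' @export
tau2_dslr2 <- function(y, s2) {
  check_ys2(y, s2)
  cq <- cochran_q(y, s2)
  if (cq$Q <= 0)
    return(new_tau2("DSLR2", 0, cq$Q, truncated = TRUE))
  t2 <- tau2_dsl(y, s2)$tau2
  ws <- 1 / (s2 + t2)
  Ms <- sum(ws * y) / sum(ws)
  r2 <- 1 - sum(ws * (y - Ms)^2) / cq$Q
  new_tau2("DSLR2", max(0, r2), cq$Q, truncated = r2 < 0)
}

#' D-squared moments estimator
#'
#' The two-step moments estimator of the between-study variance:
#' after a first-pass DerSimonian-Laird fit,
#' `D^2 = (Q - S_MM) / (sum(w) - sum(w^2) / sum(w))`, where `Q` is
#' Cochran's statistic at fixed-effects weights and
#' `S_MM = sum((y - M*)^2 / (s2 + tau2_DSL))` is the generalized Q at
#' random-effects weights around the random-effects pooled mean `M*`.
#' Because random-effects weighting can only reduce the weighted sum of
#' squares, `D^2 >= 0`; tiny negative values from floating-point roundoff
#' are clamped to 0.
#'
#' @inheritParams cochran_q
#' @return A `tau2_estimate`.
#' @export
#' @examples
#' tau2_dsld2(c(0, 2, 4), c(1, 1, 1))  # D^2 = 3 (equal-variance identity)
tau2_dsld2 <- function(y, s2) {
  check_ys2(y, s2)
  w <- 1 / s2
  den <- dsl_denom(w)
  if (den <= 0 || !is.finite(den))
    stop("degenerate weights: all weight concentrated in one study",
         call. = FALSE)
  dsl <- tau2_dsl(y, s2)
  ws <- 1 / (s2 + dsl$tau2)
  Ms <- sum(ws * y) / sum(ws)
  S_MM <- sum((y - Ms)^2 * ws)
  d2 <- (dsl$Q - S_MM) / den
  new_tau2("DSLD2", max(0, d2), dsl$Q, truncated = d2 < 0)
}

#' I-squared heterogeneity fraction
#'
#' Fraction of total variability attributable to between-study
#' heterogeneity, `I^2 = tau2 / (tau2 + s2_typ)`, where the typical
#' within-study variance is the moment form
#' `s2_typ = (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))` with `w = 1/s2`.
#' With equal within-study variances `s2_typ` reduces to that common
#' variance.
#'
#' @param tau2 Between-study variance estimate (>= 0).
#' @param s2 Within-study variances.
#' @return I-squared in `[0, 1]`.
#' @export
i_squared <- function(tau2, s2) {
  stopifnot(tau2 >= 0, all(s2 > 0))
  w <- 1 / s2
  s2_typ <- (length(s2) - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  tau2 / (tau2 + s2_typ)
}
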