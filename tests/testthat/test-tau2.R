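# Worked example used throughout: y = (0, 2, 4), s2 = (1, 1, 1).  Under
# equal within-study variances every estimator has a closed form.
y3 <- c(0, 2, 4); s3 <- c(1, 1, 1)

test_that("Cochran's Q matches hand computations", {
  q <- cochran_q(c(1, 1, 1), s3)
  expect_equal(q$Q, 0)
  expect_equal(q$M_fem, 1)

  q2 <- cochran_q(y3, s3)
  expect_equal(q2$Q, 8)
  expect_equal(q2$M_fem, 2)

  q3 <- cochran_q(c(0, 1), c(1, 4))
  expect_equal(q3$M_fem, 0.2)
  expect_equal(q3$Q, 0.2^2 * 1 + 0.8^2 * 0.25)

  expect_error(cochran_q(1, 1), "at least 2")
})

test_that("DSL estimator truncates at zero and matches hand values", {
  expect_equal(tau2_dsl(c(0, 1, 2), s3)$tau2, 0)   # Q = 2 = k - 1
  expect_false(tau2_dsl(c(0, 1, 2), s3)$truncated)

  e <- tau2_dsl(y3, s3)
  expect_equal(e$tau2, 3)
  expect_equal(e$Q, 8)

  t <- tau2_dsl(c(1, 1, 1), c(0.5, 2, 1))
  expect_equal(t$tau2, 0)
  expect_true(t$truncated)
})

test_that("equal-variance closed forms hold for PM, RML, SJ, DSLR2, DSLD2", {
  expect_equal(tau2_pm(y3, s3)$tau2, 3, tolerance = 1e-8)
  expect_equal(tau2_rml(y3, s3)$tau2, 3, tolerance = 1e-6)
  expect_equal(tau2_sj(y3, s3)$tau2, 3)
  expect_equal(tau2_dslr2(y3, s3)$tau2, 0.75)
  expect_equal(tau2_dsld2(y3, s3)$tau2, 3)

  # no dispersion: everything collapses to 0 (SJ floors tau0 at 0.01)
  const <- c(2, 2, 2)
  expect_equal(tau2_pm(const, s3)$tau2, 0)
  expect_equal(tau2_rml(const, s3)$tau2, 0)
  expect_equal(tau2_sj(const, s3)$tau2, 0)
  expect_equal(tau2_dslr2(const, s3)$tau2, 0)
  expect_equal(tau2_dsld2(const, s3)$tau2, 0)
})

test_that("DSL, REML and PM agree with metafor on random instances", {
  library(metafor)
  set.seed(7)
  for (i in 1:25) {
    inst <- random_instance()
    expect_equal(tau2_dsl(inst$y, inst$s2)$tau2,
                 rma(yi = inst$y, vi = inst$s2, method = "DL")$tau2,
                 tolerance = 1e-8)
    ref <- try(rma(yi = inst$y, vi = inst$s2, method = "REML",
                   control = list(maxiter = 500, stepadj = 0.5)),
               silent = TRUE)
    if (!inherits(ref, "try-error"))  # metafor itself can fail to converge
      expect_equal(tau2_rml(inst$y, inst$s2)$tau2, ref$tau2,
                   tolerance = 1e-4)
    expect_equal(tau2_pm(inst$y, inst$s2)$tau2,
                 rma(yi = inst$y, vi = inst$s2, method = "PM")$tau2,
                 tolerance = 1e-4)
  }
})

test_that("PM root satisfies its estimating equation", {
  set.seed(11)
  for (i in 1:30) {
    inst <- random_instance()
    t2 <- tau2_pm(inst$y, inst$s2)$tau2
    if (t2 > 0) {
      w <- 1 / (inst$s2 + t2)
      M <- sum(w * inst$y) / sum(w)
      expect_lt(abs(sum(w * (inst$y - M)^2) - (length(inst$y) - 1)), 1e-8)
    }
  }
})

test_that("SJ reweighting step matches its defining two-step formula", {
  set.seed(3)
  for (i in 1:20) {
    inst <- random_instance()
    k <- length(inst$y)
    t0 <- max(0.01, sum((inst$y - mean(inst$y))^2) / (k - 1) -
                mean(inst$s2))
    ws <- 1 / (1 + inst$s2 / t0)
    M <- sum(ws * inst$y) / sum(ws)
    expect_equal(tau2_sj(inst$y, inst$s2)$tau2,
                 sum(ws * (inst$y - M)^2) / (k - 1))
    # strictly positive whenever y disperses at all
    expect_gt(tau2_sj(inst$y, inst$s2)$tau2, 0)
  }
})

test_that("DSLR2 statistic never exceeds 1 and is 0 when DSL is 0", {
  set.seed(5)
  for (i in 1:50) {
    inst <- random_instance(tau2 = runif(1, 0, 5))
    r2 <- tau2_dslr2(inst$y, inst$s2)
    expect_lte(r2$tau2, 1)
    expect_gte(r2$tau2, 0)
    if (tau2_dsl(inst$y, inst$s2)$tau2 == 0 && r2$Q > 0)
      expect_equal(r2$tau2, 0)
  }
})

test_that("D-squared direct formula agrees with the step-by-step path", {
  y <- c(0, 1, 5); s2 <- c(0.5, 1, 2)
  w <- 1 / s2
  dsl <- tau2_dsl(y, s2)
  Ms <- pool(y, s2, dsl$tau2)$mean
  S_MM <- sum((y - Ms)^2 / (s2 + dsl$tau2))
  direct <- (dsl$Q - S_MM) / (sum(w) - sum(w^2) / sum(w))
  expect_equal(tau2_dsld2(y, s2)$tau2, direct, tolerance = 1e-12)
})

test_that("all estimators are non-negative on many random instances", {
  set.seed(2024)
  fns <- list(tau2_dsl, tau2_dslr2, tau2_pm, tau2_rml, tau2_sj, tau2_dsld2)
  for (i in 1:400) {
    inst <- random_instance(tau2 = rexp(1))
    for (f in fns) expect_gte(f(inst$y, inst$s2)$tau2, 0)
  }
})

test_that("D-squared is non-decreasing in the plugged-in tau2", {
  # D^2 as a function of the tau2 used for the random-effects weights and
  # mean in S_MM, evaluated over a grid
  d2_at <- function(y, s2, t2) {
    w <- 1 / s2
    Q <- cochran_q(y, s2)$Q
    Ms <- pool(y, s2, t2)$mean
    (Q - sum((y - Ms)^2 / (s2 + t2))) / (sum(w) - sum(w^2) / sum(w))
  }
  set.seed(9)
  grid <- seq(0, 10, by = 0.25)
  for (i in 1:25) {
    inst <- random_instance()
    vals <- vapply(grid, function(t) d2_at(inst$y, inst$s2, t), 0)
    expect_true(all(diff(vals) > -1e-10))
    expect_true(all(vals > -1e-12))
  }
})

test_that("I-squared has its closed form under equal weights", {
  expect_equal(i_squared(0, c(1, 2, 3)), 0)
  s2 <- rep(0.7, 6)
  expect_equal(i_squared(0.7, s2), 0.5)  # typical within-variance = 0.7
  i2s <- vapply(seq(0, 5, by = 0.5), i_squared, 0, s2 = c(0.5, 1, 2))
  expect_true(all(diff(i2s) > 0))
  expect_true(all(i2s >= 0 & i2s <= 1))
})
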