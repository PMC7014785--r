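test_that("BH adjustment matches hand computation and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(1)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # monotone in p
  o <- order(p)
  expect_true(all(diff(q[o]) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("confusion metrics match hand computation and edge rules", {
  perfect <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$fdr, 0)

  # tp=9 fp=1 tn=89 fn=1
  calls <- c(rep(1, 10), rep(0, 90))
  truth <- c(rep(1, 9), 0, 1, rep(0, 89))
  cm <- confusion(calls, truth)
  expect_equal(cm$precision, 0.9)
  expect_equal(cm$fdr, 0.1)
  expect_equal(cm$fpr, 1 / 90)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$accuracy, 98 / 100)
  expect_equal(cm$mcc, (9 * 89 - 1 * 1) / sqrt(10 * 10 * 90 * 90))

  # zero-denominator metrics come back as flagged zeros, not NaN
  none <- confusion(c(0, 0), c(1, 0))
  expect_equal(none$precision, 0)
  expect_true("precision" %in% none$undefined)

  # random calls are uncorrelated with truth
  set.seed(2)
  mccs <- replicate(200, {
    confusion(rbinom(100, 1, 0.3), rbinom(100, 1, 0.5))$mcc
  })
  expect_lt(abs(mean(mccs)), 0.03)
})

test_that("ROC area matches the hand example, pROC and Mann-Whitney", {
  r <- roc_pr(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_pr(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_pr(c(0, 0, 1, 1), c(1, 1, 0, 0))$auc, 0)

  suppressMessages(library(pROC))
  set.seed(3)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, 0.4)
    if (length(unique(truth)) < 2) next
    scores <- rnorm(n, truth)          # continuous
    ties <- round(rnorm(n, truth), 1)  # heavy ties
    for (s in list(scores, ties)) {
      mine <- roc_pr(s, truth)$auc
      expect_equal(mine, mw_auc_oracle(s, truth))
      expect_equal(mine,
                   as.numeric(auc(roc(truth, s, quiet = TRUE,
                                      direction = "<"))))
    }
  }
  expect_error(roc_pr(c(1, 2), c(1, 1)), "both classes")
})

test_that("precision-recall curve starts at full precision for a good ranker", {
  set.seed(4)
  truth <- rep(c(1, 0), c(30, 70))
  scores <- truth + rnorm(100, sd = 0.3)
  r <- roc_pr(scores, truth)
  expect_gt(r$pr_auc, 0.8)
  expect_true(all(r$pr$precision >= 0 & r$pr$precision <= 1))
  expect_equal(max(r$pr$recall), 1)
  # random scores give pr_auc near the prevalence
  r0 <- roc_pr(rnorm(2000), rbinom(2000, 1, 0.3))
  expect_lt(abs(r0$pr_auc - 0.3), 0.1)
})

test_that("BH calls control the empirical FDR on null-heavy data", {
  set.seed(6)
  fdrs <- replicate(30, {
    truth <- rep(c(1, 0), c(100, 900))
    z <- rnorm(1000, mean = truth * 3)
    p <- 2 * pnorm(-abs(z))
    calls <- bh_adjust(p) < 0.05
    confusion(calls, truth)$fdr
  })
  expect_lt(mean(fdrs), 0.05 + 2 * sd(fdrs) / sqrt(30))
})

test_that("group histogram tallies calls per DE group", {
  group_id <- rep(c(0, 1, 2, 3, 4, 5), c(1000, 200, 200, 200, 200, 200))
  perfect_h1 <- as.integer(group_id == 5)
  expect_equal(unname(group_histogram(perfect_h1, group_id)),
               c(0, 0, 0, 0, 0, 200))
  expect_equal(unname(group_histogram(rep(1, 2000), group_id)),
               c(1000, 200, 200, 200, 200, 200))
})

test_that("benchmark metrics assemble the per-method summary", {
  bm <- run_benchmark(small_expr_config(seed = 55, n_per_arm = 20),
                      methods = c("FEM", "DSLD2"))
  expect_equal(nrow(bm$metrics), 2)
  expect_true(all(c("de1", "de2", "fdr1", "fdr2", "auc") %in%
                    names(bm$metrics)))
  expect_true(all(bm$metrics$de2 <= bm$metrics$de1))
  expect_true(all(bm$metrics$fdr1 >= 0 & bm$metrics$fdr1 <= 1))
  expect_true(all(bm$metrics$auc > 0.5))
  # per-gene results cover both methods for every gene
  expect_equal(nrow(bm$results), 2 * 400)
})
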