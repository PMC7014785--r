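#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment via [stats::p.adjust()], with
#' input validation.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, `>= p`, `<= 1`).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Confusion counts and derived metrics
#'
#' Compares binary calls with binary truth and returns the four confusion
#' counts plus the standard derived metrics: precision, empirical false
#' discovery rate `fp / (tp + fp)`, accuracy, false positive rate,
#' sensitivity and the Matthews correlation coefficient.  Metrics with a
#' zero denominator are reported as 0 and listed in the `undefined`
#' element rather than returned as NaN, so sweep tables stay numeric.
#'
#' @param calls 0/1 (or logical) vector of positive calls.
#' @param truth 0/1 (or logical) vector of true positives, same length.
#' @return A list of class `"confusion"` with elements `tp`, `fp`, `tn`,
#'   `fn`, `precision`, `fdr`, `accuracy`, `fpr`, `sensitivity`, `mcc`,
#'   `undefined` (character vector of zero-denominator metrics).
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion <- function(calls, truth) {
  if (length(calls) != length(truth))
    stop("calls and truth must have the same length", call. = FALSE)
  calls <- as.integer(as.logical(calls))
  truth <- as.integer(as.logical(truth))
  tp <- sum(calls == 1 & truth == 1)
  fp <- sum(calls == 1 & truth == 0)
  tn <- sum(calls == 0 & truth == 0)
  fn <- sum(calls == 0 & truth == 1)
  undefined <- character()
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              precision = safe(tp, tp + fp, "precision"),
              fdr = safe(fp, tp + fp, "fdr"),
              accuracy = (tp + tn) / length(calls),
              fpr = safe(fp, fp + tn, "fpr"),
              sensitivity = safe(tp, tp + fn, "sensitivity"),
              mcc = safe(tp * tn - fp * fn, mcc_den, "mcc"))
  out$undefined <- undefined
  structure(out, class = "confusion")
}

#' ROC and precision-recall curves
#'
#' Ranks genes by a score (larger = more significant, e.g. `-p` or `|z|`),
#' groups tied scores at a single threshold, and returns the ROC curve
#' with its trapezoidal area plus the precision-recall step curve with the
#' step-wise area (average precision without interpolation).
#'
#' @param scores Numeric score per gene.
#' @param truth 0/1 truth vector; both classes must be present.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`), `auc`,
#'   `pr` (data frame `threshold`, `recall`, `precision`) and `pr_auc`.
#' @export
roc_pr <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  if (length(scores) != length(truth))
    stop("scores and truth must have the same length", call. = FALSE)
  P <- sum(truth == 1); Ng <- sum(truth == 0)
  if (P == 0 || Ng == 0)
    stop("truth must contain both classes", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  ## collapse ties: one operating point per distinct score
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(t)[last]
  fp <- cumsum(1 - t)[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / Ng)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / P
  ## step-wise PR area: precision held at each achieved level over the
  ## recall increment it covers
  pr_auc <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
       auc = auc,
       pr = data.frame(threshold = s[last], recall = rec,
                       precision = prec),
       pr_auc = pr_auc)
}

#' Calls per differential-expression group
#'
#' Tallies positive calls within each simulated DE group (number of
#' studies in which a gene is truly differentially expressed), the layout
#' behind the per-method histograms of detected genes.
#'
#' @param calls 0/1 vector of calls over genes.
#' @param group_id Per-gene group (0..k), e.g. `truth$group_id`.
#' @return Named integer vector of call counts for groups `0..max`.
#' @export
group_histogram <- function(calls, group_id) {
  if (length(calls) != length(group_id))
    stop("calls and group_id must have the same length", call. = FALSE)
  lv <- 0:max(group_id)
  counts <- vapply(lv, function(g) sum(calls[group_id == g] > 0), 0L)
  stats::setNames(counts, lv)
}

#' Benchmark metric table for one method's p-values
#'
#' Computes the headline benchmark summary for one method on one simulated
#' dataset: the number of calls at raw `p < alpha` (DE1) and at
#' Benjamini-Hochberg adjusted `p < fdr` (DE2), and the empirical false
#' discovery rates of those two call sets.  Consistent with the reported
#' benchmark arithmetic, the raw-threshold FDR is scored against the
#' union truth (DE in at least one study) and the adjusted-threshold FDR
#' against the majority truth (DE in at least `r` studies); see the
#' methods vignette for the reasoning.  Additionally returns the full
#' confusion metrics and ROC / PR areas against a chosen hypothesis truth.
#'
#' @param p Per-gene p-values in the simulated gene order.
#' @param truth An `"expr_sim_truth"` object.
#' @param hypothesis Hypothesis for the confusion/ROC block.
#' @param r Minimum DE studies for the majority truth.
#' @param alpha Raw p-value threshold.
#' @param fdr Adjusted p-value threshold.
#' @return One-row data frame with columns `de1`, `de2`, `fdr1`, `fdr2`,
#'   `precision`, `accuracy`, `fpr`, `sensitivity`, `mcc`, `auc`,
#'   `pr_auc`.
#' @export
benchmark_metrics <- function(p, truth, hypothesis = "H1", r = 3L,
                              alpha = 0.05, fdr = 0.05) {
  q <- bh_adjust(p)
  calls1 <- p < alpha
  calls2 <- q < fdr
  union_truth <- truth_labels(truth, "H2")
  major_truth <- truth_labels(truth, "H3", r = r)
  hyp_truth <- truth_labels(truth, hypothesis, r = r)
  cm <- confusion(calls1, hyp_truth)
  curves <- roc_pr(-p, hyp_truth)
  data.frame(de1 = sum(calls1), de2 = sum(calls2),
             fdr1 = confusion(calls1, union_truth)$fdr,
             fdr2 = confusion(calls2, major_truth)$fdr,
             precision = cm$precision, accuracy = cm$accuracy,
             fpr = cm$fpr, sensitivity = cm$sensitivity, mcc = cm$mcc,
             auc = curves$auc, pr_auc = curves$pr_auc)
}

#' Run the full expression benchmark
#'
#' Simulates one dataset, converts every study to effect sizes, runs the
#' requested combining methods on every gene, and summarizes each method
#' with [benchmark_metrics()].
#'
#' @param cfg An [expr_sim_config()].
#' @param methods Subset of [meta_methods()].
#' @param measure Effect-size measure for [studies_to_effects()].
#' @param hypothesis,r,alpha,fdr Passed to [benchmark_metrics()].
#' @return A list with `metrics` (one row per method), `results` (the
#'   per-gene [run_meta()] table), `truth` and `effects`.
#' @export
run_benchmark <- function(cfg = expr_sim_config(),
                          methods = meta_methods(),
                          measure = "SMD", hypothesis = "H1", r = 3L,
                          alpha = 0.05, fdr = 0.05) {
  truth <- simulate_dataset(cfg)
  effects <- studies_to_effects(truth$expr, truth$labels, measure)
  res <- run_meta(effects, methods)
  gene_order <- rownames(truth$expr[[1]])
  mets <- lapply(methods, function(m) {
    sub <- res[res$method == m, ]
    p <- sub$p[match(gene_order, sub$gene_id)]
    p[is.na(p)] <- 1  # genes excluded for degenerate variance: never called
    cbind(data.frame(method = m, stringsAsFactors = FALSE),
          benchmark_metrics(p, truth, hypothesis, r, alpha, fdr))
  })
  list(metrics = do.call(rbind, mets), results = res, truth = truth,
       effects = effects)
}
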