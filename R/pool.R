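#' Pool effect sizes at a given between-study variance
#'
#' Inverse-variance pooling with weights `w* = 1 / (s2 + tau2)`.  With
#' `tau2 = 0` this is exactly the fixed-effects model.  The confidence
#' interval uses the 1.96 normal multiplier and the p-value is the
#' two-sided standard-normal tail of `z = mean / sqrt(variance)` (no
#' Knapp-Hartung adjustment).  p-values are floored at `1e-300` so their
#' negative log stays finite.
#'
#' @inheritParams cochran_q
#' @param tau2 Between-study variance (>= 0).
#' @return An object of class `"pooled_result"`: list with `mean`,
#'   `variance`, `ci_low`, `ci_high`, `z`, `p`, `i2`, `weights`, `tau2`.
#' @export
#' @examples
#' pool(c(0, 2, 4), c(1, 1, 1), tau2 = 0)  # FEM: mean 2, variance 1/3
pool <- function(y, s2, tau2) {
  check_ys2(y, s2)
  stopifnot(is.finite(tau2), tau2 >= 0)
  w <- 1 / (s2 + tau2)
  m <- sum(w * y) / sum(w)
  v <- 1 / sum(w)
  z <- m / sqrt(v)
  structure(list(mean = m, variance = v,
                 ci_low = m - 1.96 * sqrt(v),
                 ci_high = m + 1.96 * sqrt(v),
                 z = z,
                 p = max(2 * stats::pnorm(-abs(z)), 1e-300),
                 i2 = i_squared(tau2, s2),
                 weights = w, tau2 = tau2),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf(
    "pooled mean %.4g (95%% CI %.4g to %.4g), z = %.3f, p = %.3g, I2 = %.1f%%\n",
    x$mean, x$ci_low, x$ci_high, x$z, x$p, 100 * x$i2))
  invisible(x)
}

#' Combining methods
#'
#' The seven methods compared by the package: the fixed-effects model and
#' six random-effects variants differing in their between-study variance
#' estimator.
#'
#' @return Character vector of method names.
#' @export
meta_methods <- function() {
  c("FEM", "DSL", "DSLR2", "PM", "RML", "SJ", "DSLD2")
}

tau2_fun <- function(method) {
  switch(method,
         DSL = tau2_dsl, DSLR2 = tau2_dslr2, PM = tau2_pm,
         RML = tau2_rml, SJ = tau2_sj, DSLD2 = tau2_dsld2,
         stop("unknown method: ", method, call. = FALSE))
}

#' Run one combining method on one gene
#'
#' Estimates the between-study variance with the requested method (fixed
#' at 0 for `"FEM"`) and pools at that value.
#'
#' @param method One of [meta_methods()].
#' @inheritParams cochran_q
#' @return A `pooled_result` with the `tau2_estimate` attached as element
#'   `tau2_est` (`NULL` for FEM).
#' @export
#' @examples
#' run_method("DSLD2", c(0, 2, 4), c(1, 1, 1))
run_method <- function(method, y, s2) {
  method <- match.arg(method, meta_methods())
  if (method == "FEM") {
    out <- pool(y, s2, 0)
    out$tau2_est <- NULL
  } else {
    est <- tau2_fun(method)(y, s2)
    out <- pool(y, s2, est$tau2)
    out$tau2_est <- est
  }
  out$method <- method
  out
}

#' Meta-analyze a long-format effects table
#'
#' Runs one or more combining methods on every gene of a long-format
#' effects table (columns `gene_id`, `study`, `y`, `s2`) and returns a
#' tidy results table with one row per gene and method, including the
#' Benjamini-Hochberg adjusted p-value computed within each method.
#'
#' @param effects Long-format effects data frame, e.g. from
#'   [studies_to_effects()] or [read_effects()].
#' @param methods Character vector, subset of [meta_methods()].
#' @return Data frame with columns `gene_id`, `method`, `k`, `tau2`,
#'   `mean`, `var`, `ci_low`, `ci_high`, `z`, `p`, `i2`, `p_adj`.
#' @export
run_meta <- function(effects, methods = meta_methods()) {
  methods <- match.arg(methods, meta_methods(), several.ok = TRUE)
  if (!all(c("gene_id", "study", "y", "s2") %in% names(effects)))
    stop("effects must have columns gene_id, study, y, s2", call. = FALSE)
  genes <- unique(effects$gene_id)
  idx <- split(seq_len(nrow(effects)), factor(effects$gene_id, genes))
  G <- length(genes)
  out <- vector("list", length(methods))
  for (j in seq_along(methods)) {
    m <- methods[j]
    num <- matrix(NA_real_, G, 9,
                  dimnames = list(NULL, c("k", "tau2", "mean", "var",
                                          "ci_low", "ci_high", "z", "p",
                                          "i2")))
    for (g in seq_len(G)) {
      i <- idx[[g]]
      r <- run_method(m, effects$y[i], effects$s2[i])
      num[g, ] <- c(length(i), r$tau2, r$mean, r$variance, r$ci_low,
                    r$ci_high, r$z, r$p, r$i2)
    }
    tab <- data.frame(gene_id = genes, method = m, num,
                      stringsAsFactors = FALSE)
    tab$p_adj <- bh_adjust(tab$p)
    out[[j]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
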