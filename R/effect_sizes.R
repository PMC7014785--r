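#' Two-group summary statistics
#'
#' Bundle the per-group sample sizes, means and standard deviations of a
#' case/control comparison for one gene in one study.  This is the input to
#' [md_effect()] and [smd_effect()].
#'
#' @param n_ctrl,n_case Group sample sizes; both must be at least 2.
#' @param mean_ctrl,mean_case Group sample means.
#' @param sd_ctrl,sd_case Group sample standard deviations; must be finite
#'   and non-negative.
#'
#' @return An object of class `"two_group_summary"`, a list with the six
#'   fields above.
#' @export
#' @examples
#' two_group_summary(10, 10, 0, 1, 1, 1)
two_group_summary <- function(n_ctrl, n_case, mean_ctrl, mean_case,
                              sd_ctrl, sd_case) {
  if (n_ctrl < 2 || n_case < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(c(mean_ctrl, mean_case, sd_ctrl, sd_case))))
    stop("group means and sds must be finite", call. = FALSE)
  if (sd_ctrl < 0 || sd_case < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  structure(list(n_ctrl = n_ctrl, n_case = n_case,
                 mean_ctrl = mean_ctrl, mean_case = mean_case,
                 sd_ctrl = sd_ctrl, sd_case = sd_case),
            class = "two_group_summary")
}

#' Mean-difference effect size
#'
#' Raw mean difference (case minus control) with its sampling variance
#' `sd_case^2 / n_case + sd_ctrl^2 / n_ctrl`.
#'
#' @param s A [two_group_summary()] object.
#' @return A list with elements `y` (effect size) and `s2` (within-study
#'   variance).
#' @export
#' @examples
#' md_effect(two_group_summary(4, 4, 1, 3, 2, 2))  # y = 2, s2 = 2
md_effect <- function(s) {
  stopifnot(inherits(s, "two_group_summary"))
  list(y = s$mean_case - s$mean_ctrl,
       s2 = s$sd_case^2 / s$n_case + s$sd_ctrl^2 / s$n_ctrl)
}

#' Standardized mean-difference effect size
#'
#' Cohen's d standardized by the pooled standard deviation, by default with
#' Hedges' small-sample bias correction `J = 1 - 3 / (4 * df - 1)` where
#' `df = n_case + n_ctrl - 2` (the convention of effect-size meta-analysis
#' of microarray studies).  The sampling variance is the usual large-sample
#' form `(n1 + n2) / (n1 * n2) + y^2 / (2 * (n1 + n2))`.
#'
#' @param s A [two_group_summary()] object.
#' @param hedges Apply Hedges' correction (default `TRUE`); `FALSE` gives
#'   uncorrected Cohen's d.
#' @return A list with elements `y` and `s2`.
#' @export
#' @examples
#' smd_effect(two_group_summary(10, 10, 0, 1, 1, 1))
smd_effect <- function(s, hedges = TRUE) {
  stopifnot(inherits(s, "two_group_summary"))
  df <- s$n_case + s$n_ctrl - 2
  sp2 <- ((s$n_case - 1) * s$sd_case^2 + (s$n_ctrl - 1) * s$sd_ctrl^2) / df
  if (sp2 <= 0)
    stop("zero pooled standard deviation: effect size undefined",
         call. = FALSE)
  d <- (s$mean_case - s$mean_ctrl) / sqrt(sp2)
  if (hedges) d <- d * (1 - 3 / (4 * df - 1))
  n1 <- s$n_case; n2 <- s$n_ctrl
  list(y = d, s2 = (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
}

#' Per-gene effect sizes from a case/control expression matrix
#'
#' Computes one effect size and within-study variance per gene (row) of an
#' expression matrix, given a case/control label per sample (column).
#' Genes whose pooled variance is zero under the SMD measure (or whose
#' sampling variance is zero under MD) are excluded with a warning rather
#' than given an arbitrary small variance, because a zero within-study
#' variance would receive infinite weight downstream.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.  Row
#'   names are used as gene ids (defaulting to `gene_1 ...`).
#' @param labels Character vector, one of `"case"`/`"ctrl"` per column.
#' @param measure `"SMD"` (default) or `"MD"`.
#' @param hedges Passed to [smd_effect()].
#'
#' @return A data frame with columns `gene_id`, `y`, `s2`, `measure`, in
#'   the input gene order, excluded genes dropped.
#' @export
matrix_to_effects <- function(expr, labels, measure = c("SMD", "MD"),
                              hedges = TRUE) {
  measure <- match.arg(measure)
  expr <- as.matrix(expr)
  if (ncol(expr) != length(labels))
    stop("one label per sample column is required", call. = FALSE)
  labels <- match.arg(as.character(labels), c("case", "ctrl"),
                      several.ok = TRUE)
  case <- labels == "case"
  if (sum(case) < 2 || sum(!case) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  ids <- rownames(expr)
  if (is.null(ids)) ids <- paste0("gene_", seq_len(nrow(expr)))

  f <- if (measure == "MD") md_effect else function(s) smd_effect(s, hedges)
  y <- s2 <- rep(NA_real_, nrow(expr))
  for (g in seq_len(nrow(expr))) {
    sm <- try(two_group_summary(
      n_ctrl = sum(!case), n_case = sum(case),
      mean_ctrl = mean(expr[g, !case]), mean_case = mean(expr[g, case]),
      sd_ctrl = stats::sd(expr[g, !case]), sd_case = stats::sd(expr[g, case])
    ), silent = TRUE)
    eff <- if (inherits(sm, "try-error")) sm else try(f(sm), silent = TRUE)
    if (!inherits(eff, "try-error") && eff$s2 > 0) {
      y[g] <- eff$y; s2[g] <- eff$s2
    }
  }
  bad <- is.na(s2)
  if (any(bad))
    warning(sum(bad), " gene(s) with degenerate variance excluded",
            call. = FALSE)
  data.frame(gene_id = ids[!bad], y = y[!bad], s2 = s2[!bad],
             measure = measure, stringsAsFactors = FALSE)
}

#' Long-format effect-size table across studies
#'
#' Applies [matrix_to_effects()] to each study matrix and stacks the
#' results, adding a `study` column.  Genes excluded in any study (for
#' degenerate variance) are dropped from all studies so every gene keeps a
#' complete vector of effects.
#'
#' @param expr_list List of genes-by-samples matrices, one per study, with
#'   identical row order.
#' @param labels_list List of per-study label vectors (`"case"`/`"ctrl"`),
#'   or a single vector recycled across studies.
#' @param measure,hedges Passed to [matrix_to_effects()].
#' @return Long data frame with columns `gene_id`, `study`, `y`, `s2`,
#'   `measure`.
#' @export
studies_to_effects <- function(expr_list, labels_list,
                               measure = c("SMD", "MD"), hedges = TRUE) {
  measure <- match.arg(measure)
  if (!is.list(labels_list)) labels_list <- rep(list(labels_list),
                                                length(expr_list))
  tabs <- lapply(seq_along(expr_list), function(i) {
    tab <- matrix_to_effects(expr_list[[i]], labels_list[[i]],
                             measure, hedges)
    tab$study <- i
    tab
  })
  out <- do.call(rbind, tabs)
  keep <- names(which(table(out$gene_id) == length(expr_list)))
  out <- out[out$gene_id %in% keep, c("gene_id", "study", "y", "s2",
                                      "measure")]
  rownames(out) <- NULL
  out
}

#' Read and write effect-size tables
#'
#' Effect tables are tab-separated with columns `gene_id`, `study`, `y`,
#' `s2` and optionally `measure`.
#'
#' @param path File path.
#' @param effects A long-format effects data frame.
#' @return `read_effects` returns the data frame; `write_effects` returns
#'   `path` invisibly.
#' @export
read_effects <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "study", "y", "s2")
  if (!all(need %in% names(tab)))
    stop("effects table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(tab$s2)) || any(tab$s2 <= 0))
    stop("all within-study variances must be positive", call. = FALSE)
  tab
}

#' @rdname read_effects
#' @export
write_effects <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
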