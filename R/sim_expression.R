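#' Configuration for the clustered expression simulator
#'
#' Defaults describe the benchmark scenario used throughout the package:
#' 5 studies of 2000 genes, 40 correlated clusters of 20 genes, and the
#' first 1000 genes differentially expressed in 1..5 of the studies in
#' blocks of 200.
#'
#' @param k_studies Number of studies.
#' @param n_genes Genes per study.
#' @param n_per_arm Samples per arm (N); each study has 2N samples, the
#'   first N controls and the last N cases.
#' @param n_clusters Number of correlated gene clusters.
#' @param cluster_size Genes per cluster.
#' @param wishart_df Inverse-Wishart degrees of freedom for the cluster
#'   correlation draws; must exceed `cluster_size - 1`.
#' @param mu_range Range of the uniform distribution of expression shifts
#'   for differentially expressed (gene, study) pairs.
#' @param sigma0_range Range of the uniform per-study variance of
#'   unclustered genes.
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   config.
#' @return A list of class `"expr_sim_config"`.
#' @export
expr_sim_config <- function(k_studies = 5, n_genes = 2000, n_per_arm = 50,
                            n_clusters = 40, cluster_size = 20,
                            wishart_df = 60, mu_range = c(0.5, 3),
                            sigma0_range = c(0.8, 1.2), seed = 1L) {
  cfg <- list(k_studies = k_studies, n_genes = n_genes,
              n_per_arm = n_per_arm, n_clusters = n_clusters,
              cluster_size = cluster_size, wishart_df = wishart_df,
              mu_range = mu_range, sigma0_range = sigma0_range,
              seed = as.integer(seed))
  if (n_clusters * cluster_size > n_genes)
    stop("clusters cannot cover more genes than exist", call. = FALSE)
  if (wishart_df <= cluster_size - 1)
    stop("wishart_df must exceed cluster_size - 1", call. = FALSE)
  if (n_per_arm < 2)
    stop("need at least 2 samples per arm", call. = FALSE)
  if (n_genes %% 2 != 0 || (n_genes / 2) %% k_studies != 0)
    stop("n_genes/2 must be a multiple of k_studies so DE groups form ",
         "equal blocks", call. = FALSE)
  structure(cfg, class = "expr_sim_config")
}

#' Draw one cluster correlation matrix
#'
#' Draws a covariance matrix from the inverse-Wishart distribution with
#' scale `psi = 0.5 I + 0.5 J` (exchangeable correlation 0.5) and `df`
#' degrees of freedom, then standardizes it to unit diagonal.  The draw
#' uses the identity that the inverse of a `Wishart(df, psi^{-1})` draw is
#' `InvWishart(psi, df)`.  Numerically non-positive-definite draws are
#' redrawn with a warning.
#'
#' @param cluster_size Matrix dimension.
#' @param df Degrees of freedom (> cluster_size - 1).
#' @return A symmetric positive-definite correlation matrix with unit
#'   diagonal.
#' @export
sample_cluster_correlation <- function(cluster_size = 20, df = 60) {
  stopifnot(df > cluster_size - 1)
  psi <- 0.5 * diag(cluster_size) + 0.5
  psi_inv <- solve(psi)
  for (attempt in 1:10) {
    W <- stats::rWishart(1, df, psi_inv)[, , 1]
    sig <- solve(W)
    d <- diag(sig)
    R <- sig / sqrt(outer(d, d))
    diag(R) <- 1
    ok <- !inherits(try(chol(R), silent = TRUE), "try-error")
    if (ok) return(R)
    warning("non-positive-definite inverse-Wishart draw; redrawing",
            call. = FALSE)
  }
  stop("failed to draw a positive-definite correlation matrix",
       call. = FALSE)
}

#' Simulate the clustered case/control expression benchmark
#'
#' Generates `k_studies` genes-by-samples matrices with known
#' differential-expression structure:
#' \itemize{
#'   \item Genes 1..800 fall in 40 clusters of 20; each (cluster, study)
#'     pair gets its own correlation matrix from
#'     [sample_cluster_correlation()] and samples are multivariate normal
#'     with mean 0 and that correlation.
#'   \item The remaining genes are i.i.d. normal with a per-study variance
#'     drawn uniformly from `sigma0_range`.
#'   \item Genes 1..1000 are differentially expressed in `k_g` studies,
#'     `k_g = 1..5` in consecutive blocks of 200 (genes 801..1000 are DE
#'     in all studies; genes 1001..2000 in none).  The affected studies
#'     are a uniform random subset of size `k_g`; in each, a shift drawn
#'     uniformly from `mu_range` is added to the case samples only.
#' }
#'
#' @param cfg An [expr_sim_config()].
#' @param null_shifts If `TRUE`, the shifts are left at zero (global-null
#'   hook for calibration checks); truth labels are generated as usual.
#' @return A list of class `"expr_sim_truth"` with elements `cluster_id`,
#'   `group_id` (k_g per gene), `delta` (genes x studies indicator),
#'   `mu` (genes x studies shifts, 0 where delta is 0), `expr` (list of
#'   study matrices), `labels` (case/ctrl per sample column) and `config`.
#' @export
simulate_dataset <- function(cfg = expr_sim_config(), null_shifts = FALSE) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes; K <- cfg$k_studies; N <- cfg$n_per_arm
  n_clustered <- cfg$n_clusters * cfg$cluster_size

  cluster_id <- integer(G)
  cluster_id[seq_len(n_clustered)] <-
    rep(seq_len(cfg$n_clusters), each = cfg$cluster_size)

  ## DE group: blocks of 200 genes with k_g = 1..K, rest k_g = 0
  n_de <- G / 2
  block <- n_de / K
  group_id <- integer(G)
  group_id[seq_len(n_de)] <- rep(seq_len(K), each = block)

  delta <- matrix(0L, G, K)
  mu <- matrix(0, G, K)
  for (g in seq_len(n_de)) {
    studies <- sample.int(K, group_id[g])
    delta[g, studies] <- 1L
    mu[g, studies] <- stats::runif(group_id[g], cfg$mu_range[1],
                                   cfg$mu_range[2])
  }

  expr <- vector("list", K)
  for (k in seq_len(K)) {
    X <- matrix(0, G, 2 * N)
    for (cl in seq_len(cfg$n_clusters)) {
      R <- sample_cluster_correlation(cfg$cluster_size, cfg$wishart_df)
      rows <- which(cluster_id == cl)
      Z <- matrix(stats::rnorm(2 * N * cfg$cluster_size), 2 * N)
      X[rows, ] <- t(Z %*% chol(R))
    }
    sigma0 <- sqrt(stats::runif(1, cfg$sigma0_range[1],
                                cfg$sigma0_range[2]))
    free <- which(cluster_id == 0)
    X[free, ] <- matrix(stats::rnorm(length(free) * 2 * N, sd = sigma0),
                        length(free))
    if (!null_shifts) {
      case_cols <- (N + 1):(2 * N)
      shift <- mu[, k] * delta[, k]
      X[, case_cols] <- X[, case_cols] + shift
    }
    rownames(X) <- paste0("gene_", seq_len(G))
    colnames(X) <- c(paste0("ctrl_", seq_len(N)), paste0("case_", seq_len(N)))
    expr[[k]] <- X
  }

  structure(list(cluster_id = cluster_id, group_id = group_id,
                 delta = delta, mu = mu, expr = expr,
                 labels = rep(c("ctrl", "case"), each = N),
                 config = cfg),
            class = "expr_sim_truth")
}

#' Truth labels under the three hypothesis frameworks
#'
#' Converts the simulated per-gene number of differentially expressed
#' studies `k_g` into a binary truth vector:
#' \describe{
#'   \item{H1}{non-zero effect in all studies (`k_g == k`);}
#'   \item{H2}{non-zero effect in at least one study (`k_g >= 1`);}
#'   \item{H3}{non-zero effect in at least `r` studies (`k_g >= r`).}
#' }
#' At the default configuration these mark 200, 1000 and 600 genes.
#'
#' @param truth An `"expr_sim_truth"` object (or any list with `group_id`
#'   and `config`).
#' @param hypothesis One of `"H1"`, `"H2"`, `"H3"`.
#' @param r Minimum number of DE studies for H3 (default 3 for 5 studies).
#' @return Integer 0/1 vector over genes.
#' @export
truth_labels <- function(truth, hypothesis = c("H1", "H2", "H3"), r = 3L) {
  hypothesis <- match.arg(hypothesis)
  k <- truth$config$k_studies
  if (r < 1 || r > k) stop("r must be in 1..k", call. = FALSE)
  kg <- truth$group_id
  as.integer(switch(hypothesis,
                    H1 = kg == k,
                    H2 = kg >= 1,
                    H3 = kg >= r))
}

#' Write a simulated dataset to plain-text files
#'
#' One expression TSV per study (genes x samples) plus a truth TSV with
#' the cluster id, DE group and per-study indicators and shifts.  The seed
#' is recorded in a header comment of the truth file.
#'
#' @param truth An `"expr_sim_truth"` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim_dataset <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  K <- truth$config$k_studies
  for (k in seq_len(K)) {
    utils::write.table(
      data.frame(gene_id = rownames(truth$expr[[k]]), truth$expr[[k]],
                 check.names = FALSE),
      file.path(dir, sprintf("study_%d.tsv", k)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tf <- file.path(dir, "truth.tsv")
  con <- file(tf, "w")
  writeLines(sprintf("# seed: %d", truth$config$seed), con)
  tt <- data.frame(gene_id = rownames(truth$expr[[1]]),
                   cluster = truth$cluster_id, group = truth$group_id)
  for (k in seq_len(K)) tt[[paste0("delta_", k)]] <- truth$delta[, k]
  for (k in seq_len(K)) tt[[paste0("mu_", k)]] <- truth$mu[, k]
  utils::write.table(tt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(dir)
}
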