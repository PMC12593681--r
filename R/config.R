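#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with validated defaults. The
#' network-inference thresholds follow common single-omics practice
#' (absolute correlation >= 0.5, FDR / family-wise alpha 0.05); the
#' diffusion parameters control the random walk with restart on the
#' multiplex heterogeneous network: `r` is the restart probability, `delta`
#' the probability of jumping between omics layers, `lambda` the
#' gene-drug transition probability and `tau` apportions restart mass
#' across a gene seed's layer projections.
#'
#' @param min_abs_cor minimum absolute correlation for an edge, in (0,1).
#' @param max_fdr BH-adjusted p-value ceiling for correlation edges.
#' @param beta_threshold methylation call cutoff on beta values, in (0,1).
#' @param bonferroni_alpha family-wise alpha for the Fisher co-occurrence scan.
#' @param posthoc_alpha alpha for the per-cell post-hoc stage.
#' @param r restart probability, in (0,1].
#' @param tau per-layer restart weights (non-negative, summing to 1), or
#'   `NULL` for uniform `1/L` resolved at run time.
#' @param delta inter-layer jump probability, in \[0,1\].
#' @param lambda gene-drug transition probability, in \[0,1\].
#' @param aggregation how a gene's per-layer proximities are collapsed:
#'   `"geometric"`, `"arithmetic"` or `"sum"`.
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter iteration cap for the power iteration.
#' @param weighted use intra-layer edge weights in the transition matrix.
#' @param embedding_method `"svd"` or `"passthrough"`.
#' @param embedding_d number of latent factors.
#' @param clustering_method `"kmeans"`, `"hierarchical"` or `"dbscan"`.
#' @param clustering_params list of method parameters (e.g. `list(k = 3)`).
#' @param seed integer seed for stochastic steps.
#' @return A validated `run_config` list.
#' @export
run_config <- function(min_abs_cor = 0.5, max_fdr = 0.05, beta_threshold = 0.3,
                       bonferroni_alpha = 0.05, posthoc_alpha = 0.05,
                       r = 0.7, tau = NULL, delta = 0.5, lambda = 0.5,
                       aggregation = c("geometric", "arithmetic", "sum"),
                       tol = 1e-10, max_iter = 1000L, weighted = FALSE,
                       embedding_method = c("svd", "passthrough"),
                       embedding_d = 128L,
                       clustering_method = c("kmeans", "hierarchical", "dbscan"),
                       clustering_params = list(k = 3L), seed = 17L) {
  aggregation <- match.arg(aggregation)
  embedding_method <- match.arg(embedding_method)
  clustering_method <- match.arg(clustering_method)
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1)
      stop("`", nm, "` must lie in (0, 1)")
  }
  chk01(min_abs_cor, "min_abs_cor"); chk01(max_fdr, "max_fdr")
  chk01(beta_threshold, "beta_threshold")
  chk01(bonferroni_alpha, "bonferroni_alpha"); chk01(posthoc_alpha, "posthoc_alpha")
  if (!is.numeric(r) || r <= 0 || r > 1) stop("`r` must lie in (0, 1]")
  if (delta < 0 || delta > 1) stop("`delta` must lie in [0, 1]")
  if (lambda < 0 || lambda > 1) stop("`lambda` must lie in [0, 1]")
  if (!is.null(tau)) {
    if (any(tau < 0) || abs(sum(tau) - 1) > 1e-8)
      stop("`tau` must be non-negative and sum to 1")
  }
  structure(
    list(min_abs_cor = min_abs_cor, max_fdr = max_fdr,
         beta_threshold = beta_threshold,
         bonferroni_alpha = bonferroni_alpha, posthoc_alpha = posthoc_alpha,
         r = r, tau = tau, delta = delta, lambda = lambda,
         aggregation = aggregation, tol = tol, max_iter = as.integer(max_iter),
         weighted = isTRUE(weighted),
         embedding_method = embedding_method, embedding_d = as.integer(embedding_d),
         clustering_method = clustering_method, clustering_params = clustering_params,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; absent keys take the
#' defaults.
#'
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param config a `run_config`.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
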