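#' Run the full multi-omics diffusion pipeline
#'
#' Convenience wrapper chaining the whole workflow: per-layer network
#' inference (Pearson correlation for expression, Spearman for proteome,
#' Fisher co-occurrence for binarized methylation and for the two CNV
#' event matrices), multiplex assembly, drug-bipartite attachment,
#' restart-walk diffusion, latent embedding and clustering.
#'
#' @param omics named list of [omics_matrix()] objects; modalities decide
#'   the inference route (`quantitative` -> correlation, `beta` ->
#'   binarize + co-occurrence, `cnv` -> split + co-occurrence, `binary` ->
#'   co-occurrence).
#' @param db a `drug_gene_bipartite` of known drug-target associations.
#' @param config a [run_config()].
#' @param spearman_layers layer names (of quantitative matrices) to test
#'   with Spearman instead of Pearson correlation.
#' @param strategy inter-layer coupling strategy.
#' @param cluster_k number of clusters (defaults to
#'   `config$clustering_params$k`).
#' @return List with `networks`, `multiplex`, `mh`, `similarity`,
#'   `embedding`, `clusters`.
#' @export
run_pipeline <- function(omics, db, config = run_config(),
                         spearman_layers = "proteome",
                         strategy = "node_coupling", cluster_k = NULL) {
  networks <- list()
  for (m in omics) {
    if (m$modality == "quantitative") {
      meth <- if (m$layer_name %in% spearman_layers) "spearman" else "pearson"
      networks[[m$layer_name]] <- infer_correlation_network(
        m, method = meth, min_abs_cor = config$min_abs_cor,
        max_fdr = config$max_fdr)
    } else if (m$modality == "beta") {
      bin <- binarize_methylation(m, beta_threshold = config$beta_threshold)
      networks[[m$layer_name]] <- infer_cooccurrence_network(
        bin, bonferroni_alpha = config$bonferroni_alpha,
        posthoc_alpha = config$posthoc_alpha)
    } else if (m$modality == "cnv") {
      halves <- split_cnv(m)
      for (h in halves)
        networks[[h$layer_name]] <- infer_cooccurrence_network(
          h, bonferroni_alpha = config$bonferroni_alpha,
          posthoc_alpha = config$posthoc_alpha)
    } else {
      networks[[m$layer_name]] <- infer_cooccurrence_network(
        m, bonferroni_alpha = config$bonferroni_alpha,
        posthoc_alpha = config$posthoc_alpha)
    }
  }
  multiplex <- build_multiplex(networks, strategy = strategy,
                               weighted_intra = config$weighted)
  mh <- build_mh_network(multiplex, filter_bipartite(db, multiplex$genes))
  S <- build_similarity_matrix(mh, config)
  d <- min(config$embedding_d, nrow(S))
  emb <- embed_similarity(S, d = d, method = config$embedding_method)
  k <- if (is.null(cluster_k)) config$clustering_params$k else cluster_k
  clusters <- cluster_nodes(emb, method = config$clustering_method,
                            params = utils::modifyList(config$clustering_params,
                                                       list(k = k)),
                            seed = config$seed)
  list(networks = networks, multiplex = multiplex, mh = mh,
       similarity = S, embedding = emb, clusters = clusters)
}
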