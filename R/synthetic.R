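#' Define a synthetic multi-omics scenario
#'
#' Parameters of the planted-module generator used for end-to-end
#' validation. Module genes share signal in every modality: a latent
#' factor drives their correlation in the quantitative layers, and a
#' hidden per-sample module event drives joint methylation / copy-number
#' calls; background genes are independent. Part of the drugs target one
#' module each, the rest target genes at random.
#'
#' @param n_genes total genes.
#' @param n_samples samples per omics layer.
#' @param n_modules number of planted modules.
#' @param module_size genes per module (`n_modules * module_size <=
#'   n_genes`).
#' @param cor_target within-module pairwise correlation of the
#'   quantitative layers, in (0,1).
#' @param event_prob per-sample probability of a module event in the
#'   binary-signal layers.
#' @param background_event_prob per-entry event probability for
#'   background genes.
#' @param n_drugs total drugs.
#' @param n_aligned drugs whose targets all lie in a single module.
#' @param targets_per_drug targets drawn per drug (`<= module_size`).
#' @param seed master seed; all generators derive their streams from it.
#' @return A `synthetic_scenario` list (with `module_of`: per-gene module
#'   id, 0 = background).
#' @export
synthetic_scenario <- function(n_genes = 150L, n_samples = 200L,
                               n_modules = 3L, module_size = 20L,
                               cor_target = 0.8, event_prob = 0.4,
                               background_event_prob = 0.1,
                               n_drugs = 12L, n_aligned = 8L,
                               targets_per_drug = 3L, seed = 17L) {
  if (n_modules * module_size > n_genes)
    stop("module sizes exceed the gene count")
  if (cor_target <= 0 || cor_target >= 1)
    stop("`cor_target` must lie in (0, 1)")
  if (event_prob < 0 || event_prob > 1 ||
      background_event_prob < 0 || background_event_prob > 1)
    stop("event probabilities must lie in [0, 1]")
  if (targets_per_drug > module_size)
    stop("`targets_per_drug` exceeds the module size")
  if (n_aligned > n_drugs) stop("`n_aligned` exceeds `n_drugs`")
  genes <- sprintf("g%03d", seq_len(n_genes))
  module_of <- integer(n_genes)
  for (m in seq_len(n_modules))
    module_of[((m - 1L) * module_size + 1L):(m * module_size)] <- m
  structure(
    list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
         n_modules = as.integer(n_modules), module_size = as.integer(module_size),
         cor_target = cor_target, event_prob = event_prob,
         background_event_prob = background_event_prob,
         n_drugs = as.integer(n_drugs), n_aligned = as.integer(n_aligned),
         targets_per_drug = as.integer(targets_per_drug),
         seed = as.integer(seed), genes = genes, module_of = module_of),
    class = "synthetic_scenario"
  )
}

# quantitative layer via a shared latent factor per module:
# x = sqrt(rho) * f_module + sqrt(1 - rho) * noise  =>  E[cor] = rho
r_quantitative_layer <- function(s, name, stream) {
  set.seed(s$seed + stream)
  v <- matrix(stats::rnorm(s$n_genes * s$n_samples), s$n_genes, s$n_samples)
  for (m in seq_len(s$n_modules)) {
    f <- stats::rnorm(s$n_samples)
    idx <- which(s$module_of == m)
    v[idx, ] <- sqrt(s$cor_target) * matrix(f, length(idx), s$n_samples,
                                            byrow = TRUE) +
      sqrt(1 - s$cor_target) * v[idx, ]
  }
  dimnames(v) <- list(s$genes, sprintf("s%03d", seq_len(s$n_samples)))
  omics_matrix(v, layer_name = name, modality = "quantitative")
}

# binary event statuses: module genes fire together on hidden per-sample
# module events; background genes fire independently
r_event_status <- function(s, stream) {
  set.seed(s$seed + stream)
  st <- matrix(stats::rbinom(s$n_genes * s$n_samples, 1L,
                             s$background_event_prob),
               s$n_genes, s$n_samples)
  for (m in seq_len(s$n_modules)) {
    ev <- stats::rbinom(s$n_samples, 1L, s$event_prob)
    st[s$module_of == m, ev == 1L] <- 1L
    st[s$module_of == m, ev == 0L] <- 0L
  }
  dimnames(st) <- list(s$genes, sprintf("s%03d", seq_len(s$n_samples)))
  st
}

#' Generate the synthetic multi-omics matrices of a scenario
#'
#' Emits four modality-faithful layers: `expression` and `proteome`
#' (quantitative, module correlation = `cor_target`), `methylation`
#' (beta values in \[0,1\]; methylated entries drawn from Beta(8,2),
#' unmethylated from Beta(2,8), with module-wise co-methylation events)
#' and `cnv` (calls in {-1,0,+1}; odd modules co-amplify, even modules
#' co-delete). Deterministic for a fixed scenario seed.
#'
#' @param s a [synthetic_scenario()].
#' @return Named list of [omics_matrix()] objects.
#' @export
generate_multiomics <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  out <- list(
    expression = r_quantitative_layer(s, "expression", stream = 101L),
    proteome = r_quantitative_layer(s, "proteome", stream = 202L)
  )
  # methylation: status -> beta draws
  st <- r_event_status(s, stream = 303L)
  set.seed(s$seed + 304L)
  beta <- matrix(0, s$n_genes, s$n_samples, dimnames = dimnames(st))
  n_me <- sum(st == 1L)
  beta[st == 1L] <- stats::rbeta(n_me, 8, 2)
  beta[st == 0L] <- stats::rbeta(length(st) - n_me, 2, 8)
  out$methylation <- omics_matrix(beta, "methylation", modality = "beta")
  # cnv: alternate amplification / deletion by module parity
  st <- r_event_status(s, stream = 505L)
  set.seed(s$seed + 506L)
  sign_of <- ifelse(seq_len(s$n_modules) %% 2L == 1L, 1L, -1L)
  cn <- matrix(0, s$n_genes, s$n_samples, dimnames = dimnames(st))
  for (m in seq_len(s$n_modules)) {
    idx <- which(s$module_of == m)
    cn[idx, ] <- st[idx, ] * sign_of[m]
  }
  bg <- which(s$module_of == 0L)
  bg_sign <- matrix(sample(c(-1L, 1L), length(bg) * s$n_samples, replace = TRUE),
                    length(bg), s$n_samples)
  cn[bg, ] <- st[bg, ] * bg_sign
  out$cnv <- omics_matrix(cn, "cnv", modality = "cnv")
  out
}

#' Generate the synthetic drug-target table of a scenario
#'
#' The first `n_aligned` drugs are module-aligned (all targets drawn from
#' one module, round-robin over modules); the remaining drugs draw
#' targets uniformly from all genes.
#'
#' @param s a [synthetic_scenario()].
#' @return A `drug_gene_bipartite` with attribute `"drug_module"`
#'   (aligned module id per drug, 0 for background drugs).
#' @export
generate_drug_targets <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  set.seed(s$seed + 707L)
  if (s$n_drugs == 0L) {
    out <- structure(list(edges = data.frame(drug = character(), gene = character()),
                          drugs = character(), genes = character()),
                     class = "drug_gene_bipartite")
    attr(out, "drug_module") <- integer(0)
    return(out)
  }
  drugs <- sprintf("d%02d", seq_len(s$n_drugs))
  drug_module <- integer(s$n_drugs)
  rows <- vector("list", s$n_drugs)
  for (k in seq_len(s$n_drugs)) {
    if (k <= s$n_aligned && s$n_modules > 0L) {
      m <- ((k - 1L) %% s$n_modules) + 1L
      drug_module[k] <- m
      pool <- s$genes[s$module_of == m]
    } else {
      pool <- s$genes
    }
    rows[[k]] <- data.frame(drug = drugs[k],
                            gene = sample(pool, s$targets_per_drug))
  }
  out <- drug_gene_bipartite(do.call(rbind, rows))
  attr(out, "drug_module") <- stats::setNames(drug_module, drugs)
  out
}

#' Ground-truth annotation of the planted modules
#'
#' One term per module (`MODULE_1`, ...), giving the truth labels for
#' enrichment and silhouette recovery checks.
#'
#' @param s a [synthetic_scenario()].
#' @return An `annotation_set` with disjoint terms.
#' @export
planted_annotation <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  sets <- lapply(seq_len(s$n_modules), function(m) s$genes[s$module_of == m])
  names(sets) <- paste0("MODULE_", seq_len(s$n_modules))
  annotation_set(sets)
}

#' Hand-checkable two-layer diffusion fixture
#'
#' A fixed 2-layer, 4-gene, 1-drug MH network small enough to enumerate
#' by hand: layer `L1` carries edges A-B and B-C, layer `L2` carries C-D,
#' and drug X targets gene A. The expected stationary distribution for
#' seed A is computed here by the direct linear solve
#' `(I - (1-r)H) p = r p_rs` — an independent route against which the
#' power iteration can be pinned.
#'
#' @param r restart probability used for the pinned expectation.
#' @return List with `mh`, `H` (a `transition_matrix`), `seed_id`, `r`
#'   and `p_expected` (named stationary vector from the linear solve).
#' @export
tiny_mh_example <- function(r = 0.7) {
  edge_df <- function(src, tgt) data.frame(
    source = src, target = tgt, weight = 1, sign = 1L,
    statistic = 1, adjusted_p = 0)
  n1 <- omics_network("L1", nodes = c("A", "B", "C", "D"),
                      edges = edge_df(c("A", "B"), c("B", "C")))
  n2 <- omics_network("L2", nodes = c("A", "B", "C", "D"),
                      edges = edge_df("C", "D"))
  mx <- build_multiplex(list(n1, n2), strategy = "node_coupling")
  db <- drug_gene_bipartite(data.frame(drug = "X", gene = "A"))
  mh <- build_mh_network(mx, filter_bipartite(db, mx$genes))
  H <- build_transition_matrix(mh, delta = 0.5, lambda = 0.5)
  sp <- seed_profile(H, "A")
  n <- H$index$n_nodes
  A <- diag(n) - (1 - r) * as.matrix(H$H)
  p <- solve(A, r * sp$p_rs)
  names(p) <- H$index$keys
  list(mh = mh, H = H, seed_id = "A", r = r, p_expected = p)
}

#' Random MH network fixture for fuzz testing
#'
#' Erdos-Renyi intra-layer gene graphs plus a random drug bipartite,
#' assembled exactly like real data; used to fuzz the transition-matrix
#' and diffusion contracts.
#'
#' @param n_genes,n_layers,n_drugs sizes.
#' @param edge_prob intra-layer edge probability.
#' @param strategy coupling strategy passed to [build_multiplex()].
#' @param seed integer seed.
#' @return An `mh_network`.
#' @export
random_mh_network <- function(n_genes = 20L, n_layers = 3L, n_drugs = 4L,
                              edge_prob = 0.15,
                              strategy = "node_coupling", seed = 1L) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  nets <- lapply(seq_len(n_layers), function(a) {
    pairs <- utils::combn(genes, 2L)
    keep <- stats::runif(ncol(pairs)) < edge_prob
    e <- if (any(keep)) data.frame(
      source = pairs[1L, keep], target = pairs[2L, keep],
      weight = stats::runif(sum(keep), 0.2, 1), sign = 1L,
      statistic = 1, adjusted_p = 0) else NULL
    omics_network(paste0("layer", a), nodes = genes, edges = e)
  })
  mx <- build_multiplex(nets, strategy = strategy)
  if (n_drugs > 0L) {
    edges <- data.frame(
      drug = rep(sprintf("d%02d", seq_len(n_drugs)),
                 times = pmax(1L, stats::rpois(n_drugs, 2L))))
    edges$gene <- sample(genes, nrow(edges), replace = TRUE)
    db <- filter_bipartite(drug_gene_bipartite(edges), mx$genes)
  } else {
    db <- structure(list(edges = data.frame(drug = character(), gene = character()),
                         drugs = character(), genes = character()),
                    class = "drug_gene_bipartite")
  }
  build_mh_network(mx, db)
}

#' Write a complete ready-to-run synthetic dataset to a directory
#'
#' Emits the four omics matrices, the drug-target table and the planted
#' annotation in exactly the TSV/GMT formats the pipeline readers expect.
#'
#' @param s a [synthetic_scenario()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scenario_dataset <- function(s, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  omics <- generate_multiomics(s)
  for (nm in names(omics))
    write_omics_matrix(omics[[nm]], file.path(dir, paste0(nm, ".tsv")))
  write_drug_gene_table(generate_drug_targets(s),
                        file.path(dir, "drug_targets.tsv"))
  write_gmt(planted_annotation(s), file.path(dir, "planted_modules.gmt"))
  invisible(dir)
}
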