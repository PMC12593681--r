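#' Assemble single-omics networks into a multiplex omics network
#'
#' The unified gene set is the union of all layer node sets; genes absent
#' from a layer are added there as isolated projections, so every gene
#' appears in every layer. Inter-layer coupling edges carry unit weight
#' and follow one of two strategies:
#' \describe{
#'   \item{`node_coupling`}{each gene's projection in layer alpha is linked
#'     only to its own projections in every other layer, giving exactly
#'     `|Genes| * L * (L-1) / 2` coupling edges;}
#'   \item{`neighborhood_coupling`}{additionally, each projection is linked
#'     to the projections in every other layer of its first-order
#'     intra-layer neighbours.}
#' }
#' With `weighted_intra = FALSE` all intra-layer weights are reset to 1.
#'
#' @param networks list of [omics_network()] objects (one per layer).
#' @param strategy `"node_coupling"` or `"neighborhood_coupling"`.
#' @param weighted_intra keep inferred intra-layer edge weights.
#' @return A `multiplex_network`: list with `genes` (sorted union),
#'   `layer_names`, `layers` (edge data.frames), `inter_layer` (data.frame
#'   `gene_a`,`layer_a`,`gene_b`,`layer_b`, one row per unordered coupling
#'   edge), `strategy` and `weighted_intra`.
#' @export
build_multiplex <- function(networks,
                            strategy = c("node_coupling", "neighborhood_coupling"),
                            weighted_intra = FALSE) {
  strategy <- match.arg(strategy)
  if (!length(networks)) stop("need at least one omics network")
  stopifnot(all(vapply(networks, inherits, logical(1L), "omics_network")))
  layer_names <- vapply(networks, `[[`, character(1L), "layer_name")
  if (anyDuplicated(layer_names)) stop("layer names must be unique")
  genes <- sort(unique(unlist(lapply(networks, `[[`, "nodes"))))
  L <- length(networks)
  layers <- lapply(networks, function(nw) {
    e <- nw$edges
    if (!weighted_intra && nrow(e)) e$weight <- rep(1, nrow(e))
    e
  })
  names(layers) <- layer_names

  inter <- NULL
  if (L >= 2L) {
    pairs <- utils::combn(L, 2L)
    # own-projection coupling, one row per unordered layer pair and gene
    inter <- data.frame(
      gene_a = rep(genes, times = ncol(pairs)),
      layer_a = rep(pairs[1L, ], each = length(genes)),
      gene_b = rep(genes, times = ncol(pairs)),
      layer_b = rep(pairs[2L, ], each = length(genes))
    )
    if (strategy == "neighborhood_coupling") {
      nb <- lapply(seq_len(L), function(a) {
        e <- layers[[a]]
        if (!nrow(e)) return(NULL)
        other <- setdiff(seq_len(L), a)
        do.call(rbind, lapply(other, function(b) {
          data.frame(gene_a = c(e$source, e$target), layer_a = a,
                     gene_b = c(e$target, e$source), layer_b = b)
        }))
      })
      nb <- do.call(rbind, nb[!vapply(nb, is.null, logical(1L))])
      if (!is.null(nb) && nrow(nb)) {
        inter <- rbind(inter, nb)
        # canonical orientation of the unordered node pair, then dedup
        ka <- paste(inter$gene_a, inter$layer_a, sep = "\r")
        kb <- paste(inter$gene_b, inter$layer_b, sep = "\r")
        swap <- ka > kb
        if (any(swap)) {
          tg <- inter$gene_a[swap]; tl <- inter$layer_a[swap]
          inter$gene_a[swap] <- inter$gene_b[swap]
          inter$layer_a[swap] <- inter$layer_b[swap]
          inter$gene_b[swap] <- tg; inter$layer_b[swap] <- tl
        }
        inter <- inter[!duplicated(paste(inter$gene_a, inter$layer_a,
                                         inter$gene_b, inter$layer_b,
                                         sep = "\r")), , drop = FALSE]
        rownames(inter) <- NULL
      }
    }
  } else {
    inter <- data.frame(gene_a = character(), layer_a = integer(),
                        gene_b = character(), layer_b = integer())
  }
  structure(list(genes = genes, layer_names = layer_names, layers = layers,
                 inter_layer = inter, strategy = strategy,
                 weighted_intra = isTRUE(weighted_intra)),
            class = "multiplex_network")
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat(sprintf("<multiplex_network> %d genes x %d layers (%s)\n",
              length(x$genes), length(x$layer_names), x$strategy))
  cat(sprintf("  intra-layer edges: %s\n",
              paste(sprintf("%s=%d", x$layer_names,
                            vapply(x$layers, nrow, integer(1L))), collapse = ", ")))
  cat(sprintf("  inter-layer edges: %d\n", nrow(x$inter_layer)))
  invisible(x)
}

#' Restrict a drug-gene bipartite to genes present in the multiplex
#'
#' Drugs left with zero surviving targets are removed (an isolated drug
#' would trap restart mass during diffusion) and reported.
#'
#' @param db a `drug_gene_bipartite`.
#' @param genes character vector of multiplex gene labels.
#' @return A filtered `drug_gene_bipartite` with attribute
#'   `"dropped_drugs"`.
#' @export
filter_bipartite <- function(db, genes) {
  stopifnot(inherits(db, "drug_gene_bipartite"))
  e <- db$edges[db$edges$gene %in% genes, , drop = FALSE]
  dropped <- setdiff(db$drugs, unique(e$drug))
  if (length(dropped))
    message("filter_bipartite: removing ", length(dropped),
            " drug(s) with no surviving target [reason=no_target_in_multiplex]")
  if (!nrow(e)) {
    warning("no drug-gene association involves a multiplex gene; bipartite is empty")
    out <- structure(list(edges = e, drugs = character(), genes = character()),
                     class = "drug_gene_bipartite")
  } else {
    out <- drug_gene_bipartite(e)
  }
  attr(out, "dropped_drugs") <- dropped
  out
}

#' Attach a drug bipartite to a multiplex omics network
#'
#' Each (drug, gene) association is replicated to the gene's projection in
#' every layer with unit weight, yielding `|E_DB| * L` drug-gene edges.
#' The node universe of the resulting multiplex heterogeneous network has
#' size `|Genes| * L + |drugs|`.
#'
#' @param multiplex a `multiplex_network`.
#' @param db a `drug_gene_bipartite` already filtered against
#'   `multiplex$genes` (see [filter_bipartite()]).
#' @return An `mh_network`: list with `multiplex`, `bipartite` and
#'   `drug_gene_edges` (data.frame `drug`,`gene`,`layer`).
#' @export
build_mh_network <- function(multiplex, db) {
  stopifnot(inherits(multiplex, "multiplex_network"),
            inherits(db, "drug_gene_bipartite"))
  stray <- setdiff(db$genes, multiplex$genes)
  if (length(stray))
    stop("bipartite contains target genes absent from the multiplex (filter first): ",
         paste(utils::head(stray, 5L), collapse = ", "))
  L <- length(multiplex$layer_names)
  ne <- nrow(db$edges)
  dg <- data.frame(
    drug = rep(db$edges$drug, times = L),
    gene = rep(db$edges$gene, times = L),
    layer = rep(seq_len(L), each = ne)
  )
  structure(list(multiplex = multiplex, bipartite = db, drug_gene_edges = dg),
            class = "mh_network")
}

#' @export
print.mh_network <- function(x, ...) {
  L <- length(x$multiplex$layer_names)
  cat(sprintf("<mh_network> %d genes x %d layers + %d drugs (%d nodes)\n",
              length(x$multiplex$genes), L, length(x$bipartite$drugs),
              length(x$multiplex$genes) * L + length(x$bipartite$drugs)))
  cat(sprintf("  drug-gene edges: %d (%d bipartite associations x %d layers)\n",
              nrow(x$drug_gene_edges), nrow(x$bipartite$edges), L))
  invisible(x)
}

# Node bookkeeping for an mh_network: gene projections are laid out
# layer-major (layer 1 genes, layer 2 genes, ...), drugs last.
mh_node_index <- function(mh) {
  genes <- mh$multiplex$genes
  L <- length(mh$multiplex$layer_names)
  G <- length(genes)
  keys <- c(paste0(rep(genes, times = L), "@",
                   rep(mh$multiplex$layer_names, each = G)),
            mh$bipartite$drugs)
  list(genes = genes, drugs = mh$bipartite$drugs, L = L, G = G,
       layer_names = mh$multiplex$layer_names,
       n_nodes = G * L + length(mh$bipartite$drugs), keys = keys)
}

#' Write a multiplex heterogeneous network to a TSV bundle
#'
#' Emits `<prefix>_intra.tsv` (source, target, layer, weight),
#' `<prefix>_inter.tsv`, `<prefix>_drug_gene.tsv` and a
#' `<prefix>_manifest.yaml` with layer order and audited counts.
#'
#' @param mh an `mh_network`.
#' @param prefix output path prefix.
#' @return The manifest path, invisibly.
#' @export
write_mh_network <- function(mh, prefix) {
  mx <- mh$multiplex
  intra <- do.call(rbind, lapply(seq_along(mx$layers), function(a) {
    e <- mx$layers[[a]]
    if (!nrow(e)) return(NULL)
    data.frame(source = e$source, target = e$target,
               layer = mx$layer_names[a], weight = e$weight)
  }))
  if (is.null(intra))
    intra <- data.frame(source = character(), target = character(),
                        layer = character(), weight = numeric())
  utils::write.table(intra, paste0(prefix, "_intra.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mx$inter_layer, paste0(prefix, "_inter.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mh$drug_gene_edges, paste0(prefix, "_drug_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    layers = as.list(mx$layer_names), strategy = mx$strategy,
    n_genes = length(mx$genes), n_drugs = length(mh$bipartite$drugs),
    n_intra_edges = nrow(intra), n_inter_edges = nrow(mx$inter_layer),
    n_drug_gene_edges = nrow(mh$drug_gene_edges),
    n_nodes = length(mx$genes) * length(mx$layer_names) + length(mh$bipartite$drugs)
  )
  path <- paste0(prefix, "_manifest.yaml")
  yaml::write_yaml(manifest, path)
  message(sprintf(
    "write_mh_network: %d genes x %d layers, %d drugs; intra=%d inter=%d drug-gene=%d",
    manifest$n_genes, length(mx$layer_names), manifest$n_drugs,
    manifest$n_intra_edges, manifest$n_inter_edges, manifest$n_drug_gene_edges))
  invisible(path)
}
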