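#' Gene-gene functional co-participation matrix
#'
#' Binary symmetric matrix over `nodes`: entry 1 iff the two genes share
#' at least one annotation term; diagonal 0. Genes absent from every term
#' get all-zero rows and are marked unannotated (they are later excluded
#' both as silhouette anchors and as comparison points).
#'
#' @param ann an `annotation_set`.
#' @param nodes ordered node (gene) IDs.
#' @return Binary matrix with attribute `"annotated"` (logical per node).
#' @export
coparticipation_matrix <- function(ann, nodes) {
  B <- vapply(ann, function(g) as.numeric(nodes %in% g),
              numeric(length(nodes)))
  if (is.null(dim(B))) B <- matrix(B, nrow = length(nodes))
  C <- (tcrossprod(B) > 0) + 0
  diag(C) <- 0
  dimnames(C) <- list(nodes, nodes)
  attr(C, "annotated") <- rowSums(B) > 0
  C
}

#' Drug-gene co-participation matrix
#'
#' Entry (drug, gene) is 1 iff the gene appears in at least one pathway
#' gene set associated with that drug. Drugs with no pathway get all-zero
#' rows and are skipped as anchors.
#'
#' @param drug_pathways named list: drug ID -> list (or vector) of pathway
#'   gene sets.
#' @param drugs ordered drug IDs (rows).
#' @param genes ordered gene IDs (columns).
#' @return Binary drugs x genes matrix with attributes `"annotated"`
#'   (per drug) and `"annotated_genes"` (per gene: appears in any drug
#'   pathway).
#' @export
drug_gene_coparticipation <- function(drug_pathways, drugs, genes) {
  M <- matrix(0, length(drugs), length(genes), dimnames = list(drugs, genes))
  for (d in intersect(drugs, names(drug_pathways))) {
    members <- unique(unlist(drug_pathways[[d]], use.names = FALSE))
    M[d, genes %in% members] <- 1
  }
  attr(M, "annotated") <- rowSums(M) > 0
  attr(M, "annotated_genes") <- colSums(M) > 0
  M
}

#' Binary silhouette score of one anchor
#'
#' `a` = mean distance from the anchor to its co-participants, `b` = mean
#' distance to the labeled non-co-participants; score = `(b - a) /
#' max(a, b)`. Non-finite distances are excluded from both means. When
#' both means are zero the score is 0 by convention.
#'
#' @param distances numeric vector of the anchor's distances to every
#'   candidate node (same order as `labels`).
#' @param labels 0/1 vector: 1 marks co-participants.
#' @param eligible logical vector marking nodes allowed as comparison
#'   points (the anchor itself must be FALSE).
#' @return List with `score`, `n_within`, `n_between`, or `NULL` with a
#'   `"skip_reason"` when the anchor lacks a co-participant or
#'   non-co-participant at finite distance.
#' @export
node_silhouette <- function(distances, labels, eligible) {
  ok <- eligible & is.finite(distances)
  within <- ok & labels == 1
  between <- ok & labels == 0
  if (!any(within)) return(structure(list(score = NA_real_), skip_reason = "no_coparticipant"))
  if (!any(between)) return(structure(list(score = NA_real_), skip_reason = "no_noncoparticipant"))
  a <- mean(distances[within])
  b <- mean(distances[between])
  s <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  list(score = s, n_within = sum(within), n_between = sum(between))
}

#' Silhouette report over all eligible anchors
#'
#' Core of the functional evaluation: for each annotated anchor, compares
#' its mean distance to functional co-participants against its mean
#' distance to the other annotated nodes.
#'
#' @param D square distance matrix (anchor rows; for drug mode a
#'   drugs x genes rectangle).
#' @param C co-participation matrix aligned with `D` (same row/column
#'   order).
#' @param anchor_annotated logical per row; defaults to the `"annotated"`
#'   attribute of `C`, else rows with any 1.
#' @param point_annotated logical per column; defaults to
#'   `"annotated_genes"` for rectangular `C`, else `anchor_annotated`.
#' @param distance_source tag recorded in the report (e.g. `"embedding"`,
#'   `"shortest-path"`).
#' @return A `silhouette_report`: data.frame `anchor`, `score`,
#'   `n_within`, `n_between` with attributes `"summary"` (mean, median,
#'   quartiles, n), `"skipped"` (data.frame anchor, reason) and
#'   `"distance_source"`.
#' @export
silhouette_report <- function(D, C, anchor_annotated = NULL,
                              point_annotated = NULL,
                              distance_source = "embedding") {
  square <- nrow(C) == ncol(C) && identical(rownames(C), colnames(C))
  if (is.null(anchor_annotated)) {
    anchor_annotated <- attr(C, "annotated")
    if (is.null(anchor_annotated)) anchor_annotated <- rowSums(C) > 0
  }
  if (is.null(point_annotated)) {
    point_annotated <- if (square) anchor_annotated
                       else attr(C, "annotated_genes")
    if (is.null(point_annotated)) point_annotated <- colSums(C) > 0
  }
  rows <- list(); skipped <- list()
  for (i in which(anchor_annotated)) {
    eligible <- point_annotated
    if (square) eligible[i] <- FALSE
    res <- node_silhouette(D[i, ], C[i, ], eligible)
    if (is.na(res$score)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(anchor = rownames(C)[i], reason = attr(res, "skip_reason"))
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(anchor = rownames(C)[i], score = res$score,
                   n_within = res$n_within, n_between = res$n_between)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(anchor = character(), score = numeric(),
                         n_within = integer(), n_between = integer())
  sk <- if (length(skipped)) do.call(rbind, skipped)
        else data.frame(anchor = character(), reason = character())
  attr(out, "summary") <- if (nrow(out)) {
    q <- stats::quantile(out$score, c(0.25, 0.5, 0.75))
    list(mean = mean(out$score), median = unname(q[2L]),
         q1 = unname(q[1L]), q3 = unname(q[3L]), n = nrow(out))
  } else list(mean = NA_real_, median = NA_real_, q1 = NA_real_,
              q3 = NA_real_, n = 0L)
  attr(out, "skipped") <- sk
  attr(out, "distance_source") <- distance_source
  class(out) <- c("silhouette_report", class(out))
  out
}

#' @export
print.silhouette_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<silhouette_report> %d anchors (%s distances): mean %.4f, median %.4f [Q1 %.4f, Q3 %.4f]; %d skipped\n",
              s$n, attr(x, "distance_source"), s$mean, s$median, s$q1, s$q3,
              nrow(attr(x, "skipped"))))
  invisible(x)
}

#' Unweighted shortest-path distances on a PPI network
#'
#' Breadth-first hop counts on the undirected, unweighted interaction
#' graph; nodes absent from the edge list are isolated, and unreachable
#' pairs stay infinite (downstream silhouette means exclude them).
#'
#' @param edges two-column data.frame (or matrix) of interaction partners.
#' @param nodes node subset defining the output order.
#' @return `length(nodes)` square matrix of hop counts (Inf when
#'   disconnected).
#' @export
shortest_path_distances <- function(edges, nodes) {
  edges <- as.data.frame(edges)[, 1:2]
  names(edges) <- c("from", "to")
  verts <- unique(c(edges$from, edges$to, nodes))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = verts))
  D <- igraph::distances(g, v = nodes, to = nodes, mode = "all")
  n_inf <- sum(is.infinite(D[upper.tri(D)]))
  if (n_inf)
    message("shortest_path_distances: ", n_inf,
            " unordered pair(s) disconnected [reason=disconnected]; ",
            "excluded from silhouette means")
  D[nodes, nodes, drop = FALSE]
}

#' Functional silhouette evaluation of an embedding
#'
#' Scores how well euclidean distances in the embedded factor space
#' respect functional co-participation: for gene mode, anchors are
#' annotated genes and co-participants are genes sharing a term; for drug
#' mode, anchors are drugs with pathway annotations and co-participants
#' are the genes of their pathways.
#'
#' @param e an `embedding`.
#' @param ann an `annotation_set` (gene mode).
#' @param mode `"gene"` or `"drug"`.
#' @param drug_pathways named list drug -> pathway gene sets (drug mode).
#' @return A [silhouette_report()].
#' @export
evaluate_embedding <- function(e, ann = NULL, mode = c("gene", "drug"),
                               drug_pathways = NULL) {
  mode <- match.arg(mode)
  X <- as_factor_matrix(e)
  types <- attr(e, "node_type")
  if (is.null(types)) types <- rep("gene", nrow(X))
  genes <- rownames(X)[types == "gene"]
  if (mode == "gene") {
    if (is.null(ann)) stop("gene mode needs an annotation_set")
    C <- coparticipation_matrix(ann, genes)
    if (sum(attr(C, "annotated")) < 2L)
      stop("need at least 2 annotated genes to evaluate")
    D <- as.matrix(stats::dist(X[genes, , drop = FALSE]))
    silhouette_report(D, C, distance_source = "embedding")
  } else {
    if (is.null(drug_pathways)) stop("drug mode needs `drug_pathways`")
    drugs <- rownames(X)[types == "drug"]
    if (!length(drugs)) stop("embedding contains no drug nodes")
    C <- drug_gene_coparticipation(drug_pathways, drugs, genes)
    if (!any(attr(C, "annotated")))
      stop("no drug carries a pathway annotation")
    Xd <- X[drugs, , drop = FALSE]; Xg <- X[genes, , drop = FALSE]
    D <- outer(rowSums(Xd^2), rowSums(Xg^2), `+`) - 2 * tcrossprod(Xd, Xg)
    D <- sqrt(pmax(D, 0))
    dimnames(D) <- list(drugs, genes)
    silhouette_report(D, C, distance_source = "embedding")
  }
}

#' Write a silhouette report to TSV (+ JSON-ready summary)
#' @param report a `silhouette_report`.
#' @param path output TSV path.
#' @export
write_silhouette_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
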