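#' Embed the diffusion similarity matrix in a latent factor space
#'
#' With `method = "svd"` the similarity is first rescaled as
#' `log(1 + S / s_bar)` (`s_bar` = mean positive entry), which tames the
#' heavy tail of diffusion scores, and a truncated singular value
#' decomposition is taken; the factors are the left singular vectors
#' scaled by their singular values. Factor signs are fixed by forcing the
#' largest-absolute loading of each singular vector positive, so the
#' embedding is fully deterministic. `method = "passthrough"` uses the
#' raw similarity columns as coordinates (`d` is ignored).
#'
#' @param S a `similarity_matrix` (or plain numeric matrix with dimnames).
#' @param d number of factors to keep.
#' @param method `"svd"` or `"passthrough"`.
#' @return An `embedding`: numeric matrix (nodes x factors) with node row
#'   names and attributes `"method"` and `"node_type"`.
#' @export
embed_similarity <- function(S, d = 128L, method = c("svd", "passthrough")) {
  method <- match.arg(method)
  node_type <- attr(S, "node_type")
  M <- unclass(S)
  attr(M, "node_type") <- NULL; attr(M, "convergence") <- NULL
  n <- nrow(M)
  if (method == "passthrough") {
    fac <- M
    colnames(fac) <- paste0("factor", seq_len(ncol(fac)))
  } else {
    if (d > n) stop("`d` (", d, ") exceeds the node count (", n, ")")
    pos <- M[M > 0]
    s_bar <- if (length(pos)) mean(pos) else 1
    Mt <- log1p(M / s_bar)
    sv <- svd(Mt, nu = d, nv = 0)
    U <- sv$u
    # sign convention: largest-|loading| entry of each vector positive
    for (k in seq_len(d)) {
      i <- which.max(abs(U[, k]))
      if (U[i, k] < 0) U[, k] <- -U[, k]
    }
    fac <- U %*% diag(sv$d[seq_len(d)], nrow = d)
    colnames(fac) <- paste0("factor", seq_len(d))
  }
  rownames(fac) <- rownames(M)
  structure(fac, method = method, node_type = node_type, class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d nodes x %d factors (%s)\n",
              nrow(x), ncol(x), attr(x, "method")))
  invisible(x)
}

# strip the embedding class for matrix work
as_factor_matrix <- function(e) {
  m <- unclass(e)
  attr(m, "method") <- NULL; attr(m, "node_type") <- NULL
  m
}

#' Reduce an embedding to plotting coordinates
#'
#' `"pca"` projects onto the top `k` principal components, with component
#' signs fixed (largest-absolute rotation loading positive) so the result
#' is deterministic. `"tsne"` runs a seeded exact t-SNE (suited to the
#' few-hundred-node scale this package targets). `"umap"` dispatches to
#' the uwot package when it is available.
#'
#' @param e an `embedding`.
#' @param method `"pca"`, `"umap"` or `"tsne"`.
#' @param k output dimensionality (usually 2).
#' @param seed integer seed for the stochastic methods.
#' @param ... extra parameters for t-SNE (`perplexity`, `max_iter`) or
#'   UMAP.
#' @return Numeric matrix (nodes x k) with node row names.
#' @export
reduce_dimensions <- function(e, method = c("pca", "umap", "tsne"), k = 2L,
                              seed = 17L, ...) {
  method <- match.arg(method)
  X <- as_factor_matrix(e)
  if (k > ncol(X)) stop("`k` (", k, ") exceeds the factor count (", ncol(X), ")")
  coords <- switch(method,
    pca = {
      pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
      rot <- pc$rotation
      sc <- pc$x
      for (j in seq_len(ncol(rot))) {
        i <- which.max(abs(rot[, j]))
        if (rot[i, j] < 0) sc[, j] <- -sc[, j]
      }
      sc
    },
    tsne = tsne_exact(X, k = k, seed = seed, ...),
    umap = {
      if (!requireNamespace("uwot", quietly = TRUE))
        stop("method 'umap' needs the uwot package; use 'pca' or 'tsne' instead")
      set.seed(seed)
      um <- uwot::umap(X, n_components = k, ...)
      rownames(um) <- rownames(X)
      um
    })
  colnames(coords) <- paste0("dim", seq_len(k))
  rownames(coords) <- rownames(X)
  coords
}

# Exact (non-approximated) t-SNE; quadratic in n, fine below ~2000 nodes.
tsne_exact <- function(X, k = 2L, seed = 17L, perplexity = NULL,
                       max_iter = 400L, eta = 100) {
  n <- nrow(X)
  if (is.null(perplexity)) perplexity <- max(2, min(30, floor((n - 1) / 3)))
  if (3 * perplexity > n - 1) stop("perplexity too large for ", n, " points")
  D2 <- as.matrix(stats::dist(X))^2
  # per-point precision by bisection on the perplexity
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) { Pi <- rep(1 / length(Di), length(Di)); break }
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
      Pi <- exp(-Di * beta)
    }
    P[i, -i] <- Pi / sum(Pi)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * k, sd = 1e-4), n, k)
  G <- matrix(0, n, k)    # momentum buffer
  exag <- 4
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= 100) P * exag else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (iter <= 250) 0.5 else 0.8
    G <- mom * G - eta * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  rownames(Y) <- rownames(X)
  Y
}

#' Cluster nodes in the embedded space
#'
#' @param e an `embedding` (or coordinate matrix).
#' @param method `"kmeans"`, `"hierarchical"` or `"dbscan"`.
#' @param params list of parameters: `k` (kmeans/hierarchical), `eps` and
#'   `min_pts` (dbscan), optionally `linkage` (default `"average"`) and
#'   `nstart` (default 10).
#' @param seed seed for k-means initialisation.
#' @return Named integer vector of cluster labels (noise = 0 under
#'   dbscan), with attributes `"method"` and `"params"`.
#' @export
cluster_nodes <- function(e, method = c("kmeans", "hierarchical", "dbscan"),
                          params = list(k = 3L), seed = 17L) {
  method <- match.arg(method)
  X <- as_factor_matrix(e)
  n <- nrow(X)
  labels <- switch(method,
    kmeans = {
      k <- params$k
      if (is.null(k)) stop("kmeans needs params$k")
      if (k > n) stop("k (", k, ") exceeds the node count (", n, ")")
      nstart <- if (is.null(params$nstart)) 10L else params$nstart
      set.seed(seed)
      stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100L)$cluster
    },
    hierarchical = {
      k <- params$k
      if (is.null(k)) stop("hierarchical clustering needs params$k")
      if (k > n) stop("k (", k, ") exceeds the node count (", n, ")")
      linkage <- if (is.null(params$linkage)) "average" else params$linkage
      stats::cutree(stats::hclust(stats::dist(X), method = linkage), k = k)
    },
    dbscan = {
      if (is.null(params$eps)) stop("dbscan needs params$eps")
      min_pts <- if (is.null(params$min_pts)) 5L else params$min_pts
      dbscan_labels(X, eps = params$eps, min_pts = min_pts)
    })
  names(labels) <- rownames(X)
  attr(labels, "method") <- method
  attr(labels, "params") <- params
  labels
}

# Plain DBSCAN on a distance matrix: core points have >= min_pts
# neighbours (self included) within eps; clusters grow by BFS over core
# points; border points join the first cluster that reaches them; label 0
# marks noise.
dbscan_labels <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1L)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      for (q in nb[[j]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Over-representation analysis of a gene cluster
#'
#' Hypergeometric upper-tail test of the overlap between the cluster and
#' each term's gene set (both intersected with the universe), BH-adjusted
#' across terms and sorted by adjusted p.
#'
#' @param cluster_genes character vector of cluster member genes (drug
#'   nodes must be excluded upstream).
#' @param ann an `annotation_set`.
#' @param universe character vector of background genes.
#' @return data.frame with columns `term`, `overlap`, `term_size`,
#'   `cluster_size`, `universe_size`, `p`, `adjusted_p`.
#' @export
enrich_cluster <- function(cluster_genes, ann, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  cluster_genes <- intersect(unique(cluster_genes), universe)
  N <- length(universe)
  n_c <- length(cluster_genes)
  res <- lapply(names(ann), function(term) {
    tg <- intersect(ann[[term]], universe)
    m <- length(tg)
    x <- length(intersect(tg, cluster_genes))
    p <- if (m == 0L) 1 else stats::phyper(x - 1L, m, N - m, n_c, lower.tail = FALSE)
    data.frame(term = term, overlap = x, term_size = m, cluster_size = n_c,
               universe_size = N, p = p)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$adjusted_p, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' k nearest neighbours of a node in the embedded space
#'
#' Euclidean distance in factor space, self excluded, ties broken by
#' lexicographic node ID.
#'
#' @param e an `embedding`.
#' @param node query node ID.
#' @param k neighbourhood size (< node count).
#' @return data.frame `node`, `type`, `distance`, nearest first.
#' @export
knn_neighborhood <- function(e, node, k = 10L) {
  X <- as_factor_matrix(e)
  types <- attr(e, "node_type")
  i <- match(node, rownames(X))
  if (is.na(i)) stop("unknown node: ", node)
  if (k >= nrow(X)) stop("`k` must be smaller than the node count")
  d <- sqrt(colSums((t(X) - X[i, ])^2))
  ord <- order(d, rownames(X))
  ord <- ord[ord != i][seq_len(k)]
  data.frame(node = rownames(X)[ord],
             type = if (!is.null(types)) types[ord] else NA_character_,
             distance = d[ord], row.names = NULL)
}

#' Write 2-D/3-D coordinates to TSV
#' @param coords coordinate matrix from [reduce_dimensions()].
#' @param node_type optional per-node type vector.
#' @param path output path.
#' @export
write_coordinates <- function(coords, path, node_type = NULL) {
  df <- data.frame(node = rownames(coords),
                   type = if (is.null(node_type)) NA_character_ else node_type,
                   coords, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
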