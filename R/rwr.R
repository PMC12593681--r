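#' Build the column-stochastic transition matrix of an MH network
#'
#' Encodes the moves of the random walker on the multiplex heterogeneous
#' network. The column of a gene projection `g@alpha` distributes its mass
#' as follows: if the gene has drug associations, probability `lambda`
#' goes to its drug neighbours (uniformly); the remainder is split with
#' proportion `1 - delta` over intra-layer neighbours (weight-proportional
#' when `weighted`, else uniform) and `delta` over the projection's
#' inter-layer coupling partners (uniformly). When one of the two
#' gene-side destinations is empty its share is reassigned to the other;
#' when both are empty the remainder becomes a self-loop. A drug column
#' sends `lambda` to its target-gene projections (uniformly over all
#' targets times layers) and keeps `1 - lambda` as a self-loop, since the
#' model has no drug-drug edges.
#'
#' @param mh an `mh_network`.
#' @param delta inter-layer jump probability, in \[0,1\].
#' @param lambda gene-drug transition probability, in \[0,1\].
#' @param weighted use intra-layer edge weights.
#' @return A `transition_matrix`: list with sparse column-stochastic `H`
#'   (`Matrix::dgCMatrix`), the node `index` bookkeeping and the
#'   parameters used.
#' @export
build_transition_matrix <- function(mh, delta = 0.5, lambda = 0.5,
                                    weighted = FALSE) {
  stopifnot(inherits(mh, "mh_network"))
  if (delta < 0 || delta > 1) stop("`delta` must lie in [0, 1]")
  if (lambda < 0 || lambda > 1) stop("`lambda` must lie in [0, 1]")
  ix <- mh_node_index(mh)
  G <- ix$G; L <- ix$L
  gid <- function(g, a) (a - 1L) * G + match(g, ix$genes)   # gene-projection index
  did <- function(d) G * L + match(d, ix$drugs)             # drug index

  # adjacency lookups -------------------------------------------------
  # intra-layer: per layer, per gene, neighbour indices + weights
  intra_nb <- vector("list", G * L)
  intra_w <- vector("list", G * L)
  for (a in seq_len(L)) {
    e <- mh$multiplex$layers[[a]]
    if (!nrow(e)) next
    si <- match(e$source, ix$genes); ti <- match(e$target, ix$genes)
    from <- c(si, ti); to <- c(ti, si); w <- c(e$weight, e$weight)
    off <- (a - 1L) * G
    sp <- split(seq_along(from), from)
    for (nm in names(sp)) {
      i <- off + as.integer(nm)
      intra_nb[[i]] <- off + to[sp[[nm]]]
      intra_w[[i]] <- w[sp[[nm]]]
    }
  }
  # inter-layer coupling partners per projection
  inter_nb <- vector("list", G * L)
  il <- mh$multiplex$inter_layer
  if (nrow(il)) {
    ia <- (il$layer_a - 1L) * G + match(il$gene_a, ix$genes)
    ib <- (il$layer_b - 1L) * G + match(il$gene_b, ix$genes)
    from <- c(ia, ib); to <- c(ib, ia)
    sp <- split(to, from)
    inter_nb[as.integer(names(sp))] <- sp
  }
  # drug attachments: drugs per gene (same set for every projection)
  be <- mh$bipartite$edges
  drugs_of_gene <- vector("list", G)
  targets_of_drug <- list()
  if (nrow(be)) {
    sp <- split(match(be$drug, ix$drugs), match(be$gene, ix$genes))
    drugs_of_gene[as.integer(names(sp))] <- sp
    targets_of_drug <- split(match(be$gene, ix$genes), match(be$drug, ix$drugs))
  }

  # assemble triplets --------------------------------------------------
  ti <- tj <- integer(0); tx <- numeric(0)
  push <- function(rows, col, vals) {
    ti <<- c(ti, rows); tj <<- c(tj, rep.int(col, length(rows))); tx <<- c(tx, vals)
  }
  for (a in seq_len(L)) {
    off <- (a - 1L) * G
    for (g in seq_len(G)) {
      col <- off + g
      dn <- drugs_of_gene[[g]]
      m_drug <- if (length(dn)) lambda else 0
      rem <- 1 - m_drug
      if (length(dn) && m_drug > 0)
        push(G * L + dn, col, rep(m_drug / length(dn), length(dn)))
      nb_in <- intra_nb[[col]]; nb_out <- inter_nb[[col]]
      has_in <- length(nb_in) > 0L; has_out <- length(nb_out) > 0L
      m_in <- if (has_in && has_out) rem * (1 - delta)
              else if (has_in) rem else 0
      m_out <- if (has_in && has_out) rem * delta
               else if (has_out) rem else 0
      if (m_in > 0) {
        w <- if (weighted) intra_w[[col]] else rep(1, length(nb_in))
        push(nb_in, col, m_in * w / sum(w))
      }
      if (m_out > 0)
        push(nb_out, col, rep(m_out / length(nb_out), length(nb_out)))
      leftover <- rem - m_in - m_out
      if (leftover > 0)  # no gene-side destination: remainder self-loops
        push(col, col, leftover)
    }
  }
  for (k in seq_along(ix$drugs)) {
    col <- G * L + k
    tg <- targets_of_drug[[as.character(k)]]
    proj <- as.vector(outer(tg, (seq_len(L) - 1L) * G, `+`))
    if (lambda > 0)
      push(proj, col, rep(lambda / length(proj), length(proj)))
    if (1 - lambda > 0)
      push(col, col, 1 - lambda)
  }
  H <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                            dims = c(ix$n_nodes, ix$n_nodes),
                            dimnames = list(ix$keys, ix$keys))
  # guard: any all-zero column becomes a self-loop
  cs <- Matrix::colSums(H)
  zero <- which(cs == 0)
  if (length(zero))
    H <- H + Matrix::sparseMatrix(i = zero, j = zero, x = rep(1, length(zero)),
                                  dims = dim(H))
  structure(list(H = H, index = ix, delta = delta, lambda = lambda,
                 weighted = isTRUE(weighted)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d x %d, %d non-zeros (delta=%g, lambda=%g%s)\n",
              nrow(x$H), ncol(x$H), Matrix::nnzero(x$H), x$delta, x$lambda,
              if (x$weighted) ", weighted" else ""))
  invisible(x)
}

#' Restart profile of a seed node
#'
#' A gene seed restarts over its `L` layer projections with per-layer
#' weights `tau` (uniform by default); a drug seed restarts wholly at its
#' own node. The profile is rescaled to sum to 1.
#'
#' @param H a `transition_matrix`.
#' @param seed_id gene or drug identifier.
#' @param tau per-layer restart weights (non-negative, summing to 1), or
#'   `NULL` for uniform.
#' @return A `seed_profile`: list with `seed_id`, `type` and sparse-free
#'   numeric `p_rs` of length `n_nodes`.
#' @export
seed_profile <- function(H, seed_id, tau = NULL) {
  ix <- H$index
  p <- numeric(ix$n_nodes)
  if (seed_id %in% ix$genes) {
    if (is.null(tau)) tau <- rep(1 / ix$L, ix$L)
    if (length(tau) != ix$L || any(tau < 0) || abs(sum(tau) - 1) > 1e-8)
      stop("`tau` needs one non-negative entry per layer, summing to 1")
    g <- match(seed_id, ix$genes)
    p[(seq_len(ix$L) - 1L) * ix$G + g] <- tau
    type <- "gene"
  } else if (seed_id %in% ix$drugs) {
    p[ix$G * ix$L + match(seed_id, ix$drugs)] <- 1
    type <- "drug"
  } else {
    stop("unknown seed node: ", seed_id)
  }
  p <- p / sum(p)
  names(p) <- ix$keys
  structure(list(seed_id = seed_id, type = type, p_rs = p),
            class = "seed_profile")
}

#' Random walk with restart from one seed
#'
#' Power iteration of `p <- (1 - r) * H %*% p + r * p_rs` starting from
#' the restart profile, stopped when the L1 change drops below `tol` or
#' after `max_iter` iterations (the latter is flagged, not fatal).
#'
#' @param H a `transition_matrix`.
#' @param seed a `seed_profile` (or a seed ID, resolved with uniform tau).
#' @param r restart probability, in (0,1].
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @return A `proximity_vector`: list with `seed_id`, stationary `p`
#'   (named), `iterations` and `converged`.
#' @export
rwr_from_seed <- function(H, seed, r = 0.7, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(H, "transition_matrix"))
  if (r <= 0 || r > 1) stop("`r` must lie in (0, 1]")
  if (is.character(seed)) seed <- seed_profile(H, seed)
  p_rs <- seed$p_rs
  p <- p_rs
  it <- 0L
  converged <- FALSE
  if (r == 1) {
    converged <- TRUE   # walk degenerates to the restart profile
  } else {
    M <- H$H
    repeat {
      it <- it + 1L
      p_new <- (1 - r) * as.numeric(M %*% p) + r * p_rs
      delta <- sum(abs(p_new - p))
      p <- p_new
      if (delta < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
    }
    if (!converged)
      message("rwr_from_seed: seed '", seed$seed_id, "' hit max_iter = ",
              max_iter, " without converging [reason=max_iter]")
  }
  names(p) <- H$index$keys
  structure(list(seed_id = seed$seed_id, p = p, iterations = it,
                 converged = converged),
            class = "proximity_vector")
}

#' Collapse a proximity vector over layers
#'
#' Each gene's `L` projection values are collapsed by the geometric mean,
#' arithmetic mean or sum; drug entries pass through; the result is
#' rescaled to sum to 1. A gene with a zero proximity in any layer has
#' geometric-mean zero (no epsilon), keeping the similarity sparse.
#'
#' @param p_s a `proximity_vector`.
#' @param index the `index` element of a `transition_matrix`.
#' @param method `"geometric"`, `"arithmetic"` or `"sum"`.
#' @return Named numeric vector of length `|Genes| + |drugs|` summing
#'   to 1.
#' @export
aggregate_proximity <- function(p_s, index,
                                method = c("geometric", "arithmetic", "sum")) {
  method <- match.arg(method)
  stopifnot(inherits(p_s, "proximity_vector"))
  G <- index$G; L <- index$L
  gm <- matrix(p_s$p[seq_len(G * L)], nrow = G, ncol = L)
  agg <- switch(method,
    geometric = apply(gm, 1L, function(v) if (any(v == 0)) 0 else exp(mean(log(v)))),
    arithmetic = rowMeans(gm),
    sum = rowSums(gm))
  out <- c(agg, p_s$p[G * L + seq_along(index$drugs)])
  names(out) <- c(index$genes, index$drugs)
  tot <- sum(out)
  if (tot > 0) out <- out / tot
  out
}

#' Diffuse from every node and assemble the similarity matrix
#'
#' Runs one restart walk per node of the MH network (genes restart over
#' their tau-weighted layer projections, drugs at their own node),
#' collapses each stationary distribution over layers and concatenates the
#' scaled vectors column-wise: column `j` holds the multi-omics proximity
#' of every node to seed `j`. Deterministic for fixed inputs.
#'
#' @param mh an `mh_network`.
#' @param config a [run_config()].
#' @return A `(|Genes|+|drugs|) x (|Genes|+|drugs|)` numeric matrix with
#'   node names on both dimensions, attribute `"node_type"`
#'   (`"gene"`/`"drug"` per node) and attribute `"convergence"` (data.frame
#'   seed, iterations, converged).
#' @export
build_similarity_matrix <- function(mh, config = run_config()) {
  stopifnot(inherits(mh, "mh_network"))
  H <- build_transition_matrix(mh, delta = config$delta, lambda = config$lambda,
                               weighted = config$weighted)
  ix <- H$index
  seeds <- c(ix$genes, ix$drugs)
  n <- length(seeds)
  S <- matrix(0, n, n, dimnames = list(seeds, seeds))
  conv <- data.frame(seed = seeds, iterations = 0L, converged = NA)
  for (j in seq_len(n)) {
    ps <- rwr_from_seed(H, seed_profile(H, seeds[j], tau = config$tau),
                        r = config$r, tol = config$tol,
                        max_iter = config$max_iter)
    S[, j] <- aggregate_proximity(ps, ix, method = config$aggregation)
    conv$iterations[j] <- ps$iterations
    conv$converged[j] <- ps$converged
  }
  if (any(!conv$converged))
    message("build_similarity_matrix: ", sum(!conv$converged),
            " seed(s) did not converge; see the convergence report")
  attr(S, "node_type") <- c(rep("gene", ix$G), rep("drug", length(ix$drugs)))
  attr(S, "convergence") <- conv
  class(S) <- c("similarity_matrix", class(S))
  S
}

#' Per-layer contribution of a proximity score
#'
#' Decomposes the proximity from a seed to a gene into the fractions
#' carried by each omics layer: the target gene's `L` projection values in
#' the seed's stationary distribution, normalised to sum to 1.
#'
#' @param p_s a `proximity_vector` (the seed's stationary distribution).
#' @param index the `index` element of a `transition_matrix`.
#' @param node2 target gene ID (drugs occupy a single compartment; ask for
#'   their raw proximity instead).
#' @return Named numeric vector of `L` fractions (layer names), summing to
#'   1 when the total proximity is positive; all zero (with a warning)
#'   otherwise.
#' @export
layer_contribution <- function(p_s, index, node2) {
  stopifnot(inherits(p_s, "proximity_vector"))
  if (node2 %in% index$drugs)
    stop("'", node2, "' is a drug: it has a single compartment; ",
         "use its raw proximity value instead")
  g <- match(node2, index$genes)
  if (is.na(g)) stop("unknown gene: ", node2)
  v <- p_s$p[(seq_len(index$L) - 1L) * index$G + g]
  names(v) <- if (!is.null(index$layer_names)) index$layer_names
              else paste0("layer", seq_len(index$L))
  tot <- sum(v)
  if (tot == 0) {
    warning("zero total proximity from '", p_s$seed_id, "' to '", node2,
            "'; returning an all-zero profile")
    return(v)
  }
  v / tot
}

#' Write a similarity matrix and its node order to disk
#'
#' Dense TSV (nodes x nodes) plus a `<prefix>_nodes.tsv` with node order
#' and type, and a `<prefix>_convergence.tsv` report.
#'
#' @param S a `similarity_matrix`.
#' @param prefix output path prefix.
#' @export
write_similarity_matrix <- function(S, prefix) {
  df <- data.frame(node = rownames(S), unclass(S)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, paste0(prefix, "_similarity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(node = rownames(S), type = attr(S, "node_type")),
    paste0(prefix, "_nodes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  conv <- attr(S, "convergence")
  if (!is.null(conv))
    utils::write.table(conv, paste0(prefix, "_convergence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
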