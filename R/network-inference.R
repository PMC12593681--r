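#' Construct an omics network
#'
#' Undirected weighted gene network inferred from one omics layer. Each
#' unordered gene pair appears at most once; weights are non-negative with
#' the association sign stored separately so the diffusion engine never
#' sees negative weights.
#'
#' @param layer_name layer label.
#' @param nodes character vector of gene IDs covered by the layer
#'   (including genes that end up with no edge).
#' @param edges data.frame with columns `source`, `target`, `weight`,
#'   `sign`, `statistic`, `adjusted_p`.
#' @param inference list of metadata (test name, thresholds, skipped genes).
#' @return An `omics_network`.
#' @export
omics_network <- function(layer_name, nodes, edges = NULL, inference = list()) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), sign = integer(),
                        statistic = numeric(), adjusted_p = numeric())
  }
  stopifnot(all(c("source", "target", "weight", "sign", "statistic", "adjusted_p")
                %in% names(edges)))
  if (any(edges$source == edges$target)) stop("self-loops are not allowed")
  # canonical unordered orientation: source < target
  flip <- edges$source > edges$target
  if (any(flip)) {
    tmp <- edges$source[flip]
    edges$source[flip] <- edges$target[flip]
    edges$target[flip] <- tmp
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) stop("duplicated unordered gene pair in edge set")
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    stop("edge weights must be finite and non-negative")
  missing <- setdiff(unique(c(edges$source, edges$target)), nodes)
  if (length(missing)) stop("edges refer to genes absent from `nodes`: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  rownames(edges) <- NULL
  structure(list(layer_name = layer_name, nodes = nodes, edges = edges,
                 inference = inference),
            class = "omics_network")
}

#' @export
print.omics_network <- function(x, ...) {
  cat(sprintf("<omics_network> layer '%s': %d genes, %d edges (%s)\n",
              x$layer_name, length(x$nodes), nrow(x$edges),
              if (length(x$inference$test)) x$inference$test else "unspecified test"))
  invisible(x)
}

#' Infer a correlation network from a quantitative layer
#'
#' All unordered gene pairs are tested for (Pearson or Spearman)
#' correlation; p-values come from the t-distribution transform
#' `t = rho * sqrt((n-2)/(1-rho^2))` (for Spearman this is the standard
#' large-sample approximation applied to rank correlations) and are
#' BH-adjusted across all tested pairs in the layer. An edge is kept iff
#' `|rho| >= min_abs_cor` and adjusted p `< max_fdr`; its weight is
#' `|rho|` with the sign stored separately. Genes with zero variance are
#' excluded from testing and reported in the inference metadata.
#'
#' @param m an [omics_matrix()] with modality `"quantitative"`.
#' @param method `"pearson"` or `"spearman"`.
#' @param min_abs_cor minimum absolute correlation, in (0,1).
#' @param max_fdr BH-adjusted p ceiling.
#' @return An [omics_network()].
#' @export
infer_correlation_network <- function(m, method = c("pearson", "spearman"),
                                      min_abs_cor = 0.5, max_fdr = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(m, "omics_matrix"))
  if (m$modality != "quantitative")
    stop("correlation networks require a quantitative layer")
  if (min_abs_cor <= 0 || min_abs_cor >= 1) stop("`min_abs_cor` must lie in (0, 1)")
  v <- m$values
  n <- ncol(v)
  if (n < 3L) stop("need at least 3 samples to test correlations, got ", n)
  if (anyNA(v)) stop("missing values present; preprocess/impute first")
  sds <- apply(v, 1L, stats::sd)
  constant <- rownames(v)[sds == 0]
  if (length(constant))
    message("infer_correlation_network [", m$layer_name, "]: excluding ",
            length(constant), " zero-variance gene(s) [reason=constant_profile]")
  keep <- setdiff(rownames(v), constant)
  edges <- NULL
  if (length(keep) >= 2L) {
    vv <- v[keep, , drop = FALSE]
    rho <- stats::cor(t(vv), method = method)
    ut <- upper.tri(rho)
    idx <- which(ut, arr.ind = TRUE)
    r_ij <- rho[ut]
    # t transform; |rho| = 1 collapses to p = 0
    tstat <- r_ij * sqrt((n - 2) / pmax(1 - r_ij^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(r_ij) >= 1 - 1e-12] <- 0
    padj <- stats::p.adjust(p, method = "BH")
    sel <- abs(r_ij) >= min_abs_cor & padj < max_fdr
    if (any(sel)) {
      edges <- data.frame(
        source = rownames(vv)[idx[sel, 1L]],
        target = rownames(vv)[idx[sel, 2L]],
        weight = abs(r_ij[sel]),
        sign = as.integer(sign(r_ij[sel])),
        statistic = r_ij[sel],
        adjusted_p = padj[sel]
      )
    }
  }
  omics_network(
    layer_name = m$layer_name, nodes = keep, edges = edges,
    inference = list(test = paste0(method, "_correlation"),
                     min_abs_cor = min_abs_cor, max_fdr = max_fdr,
                     n_samples = n, excluded_genes = constant,
                     n_tested_pairs = if (length(keep) >= 2L) choose(length(keep), 2L) else 0)
  )
}

#' Binarize methylation beta values
#'
#' Entry becomes 1 (methylated) iff beta >= `beta_threshold`, else 0.
#'
#' @param m an [omics_matrix()] with modality `"beta"`, no missing values.
#' @param beta_threshold cutoff in (0,1).
#' @return An [omics_matrix()] with modality `"binary"`.
#' @export
binarize_methylation <- function(m, beta_threshold = 0.3) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$modality != "beta") stop("binarize_methylation expects a beta layer")
  if (beta_threshold <= 0 || beta_threshold >= 1)
    stop("`beta_threshold` must lie in (0, 1)")
  if (anyNA(m$values)) stop("missing values present; run preprocess_methylation first")
  b <- (m$values >= beta_threshold) + 0
  dimnames(b) <- dimnames(m$values)
  omics_matrix(b, layer_name = m$layer_name, modality = "binary")
}

#' Split signed CNV calls into amplification and deletion event matrices
#'
#' @param m an [omics_matrix()] with modality `"cnv"`.
#' @return List with `amplification` (1 iff value > 0) and `deletion`
#'   (1 iff value < 0) binary [omics_matrix()] objects.
#' @export
split_cnv <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$modality != "cnv") stop("split_cnv expects a cnv layer")
  if (anyNA(m$values)) stop("missing values present; impute or filter first")
  amp <- (m$values > 0) + 0
  del <- (m$values < 0) + 0
  dimnames(amp) <- dimnames(del) <- dimnames(m$values)
  list(
    amplification = omics_matrix(amp, paste0(m$layer_name, "_amplification"), "binary"),
    deletion = omics_matrix(del, paste0(m$layer_name, "_deletion"), "binary")
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value obtained by summing, over the hypergeometric
#' support fixed by the table margins, every outcome whose probability does
#' not exceed that of the observed table (with the customary relative
#' tolerance guarding ties against floating-point noise). Vectorised over
#' thousands of tables, which is what the all-pairs co-occurrence scan
#' needs.
#'
#' @param table 2x2 matrix of non-negative integer counts, or a numeric
#'   vector `c(a, b, c, d)` read row-wise.
#' @return Two-sided p-value in \[0,1\].
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4L) stop("expected a 2x2 table")
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(x != round(x))) stop("counts must be integers")
  if (is.matrix(table)) {
    a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- x[1L]; b <- x[2L]; cc <- x[3L]; d <- x[4L]  # row-wise c(a, b, c, d)
  }
  n <- a + b + cc + d
  if (n == 0) stop("table total must be positive")
  m1 <- a + b      # row-1 margin
  k1 <- a + cc     # column-1 margin
  lo <- max(0, k1 - (n - m1))
  hi <- min(k1, m1)
  support <- lo:hi
  probs <- stats::dhyper(support, m1, n - m1, k1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Fisher two-sided p-values for many tables at once (equal-length count
# vectors a, b, c, d); same tie rule as fisher_exact_2x2.
fisher_many <- function(a, b, cc, d) {
  n <- a + b + cc + d
  vapply(seq_along(a), function(i) {
    m1 <- a[i] + b[i]; k1 <- a[i] + cc[i]
    lo <- max(0, k1 - (n[i] - m1)); hi <- min(k1, m1)
    support <- lo:hi
    probs <- stats::dhyper(support, m1, n[i] - m1, k1)
    p_obs <- probs[support == a[i]]
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1L))
}

# Per-cell chi-square goodness of fit of an observed count o (out of n)
# against a theoretical proportion p; returns c(statistic, p_value).
cell_chisq_gof <- function(o, n, p) {
  stat <- (o - n * p)^2 / (n * p * (1 - p))
  c(stat, stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Infer a co-occurrence network from a binary event layer
#'
#' For every unordered gene pair the 2x2 table of joint event statuses
#' across samples is tested with Fisher's exact test; p-values are
#' Bonferroni-adjusted by the number of actually tested pairs. Surviving
#' pairs enter a post-hoc stage: each of the four observed cells is
#' compared to its expectation under independence by a per-cell chi-square
#' goodness-of-fit test, Bonferroni-adjusted across the four cells. The
#' edge is retained only if the joint-presence cell is a significant
#' EXCESS (co-occurrence, not mutual exclusivity); its weight is the
#' joint-presence-cell chi-square statistic. Genes with constant status
#' are skipped and reported.
#'
#' @param m an [omics_matrix()] with modality `"binary"`.
#' @param bonferroni_alpha family-wise alpha for the Fisher scan.
#' @param posthoc_alpha alpha for the post-hoc cell test.
#' @return An [omics_network()].
#' @export
infer_cooccurrence_network <- function(m, bonferroni_alpha = 0.05,
                                       posthoc_alpha = 0.05) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$modality != "binary") stop("co-occurrence networks require a binary layer")
  v <- m$values
  n <- ncol(v)
  if (n < 2L) stop("need at least 2 samples, got ", n)
  rs <- rowSums(v)
  constant <- rownames(v)[rs == 0 | rs == n]
  if (length(constant))
    message("infer_cooccurrence_network [", m$layer_name, "]: skipping ",
            length(constant), " constant-status gene(s) [reason=constant_status]")
  keep <- setdiff(rownames(v), constant)
  edges <- NULL
  n_pairs <- if (length(keep) >= 2L) choose(length(keep), 2L) else 0
  if (length(keep) >= 2L) {
    vv <- v[keep, , drop = FALSE]
    co <- tcrossprod(vv)               # joint-presence counts
    r <- rowSums(vv)
    ut <- upper.tri(co)
    idx <- which(ut, arr.ind = TRUE)
    a <- co[ut]                        # (1,1)
    b <- r[idx[, 1L]] - a              # (1,0)
    cc <- r[idx[, 2L]] - a             # (0,1)
    d <- n - a - b - cc                # (0,0)
    p_fisher <- fisher_many(a, b, cc, d)
    p_bonf <- pmin(1, p_fisher * n_pairs)
    surv <- which(p_bonf < bonferroni_alpha)
    if (length(surv)) {
      pi_ <- r[idx[surv, 1L]] / n
      pj_ <- r[idx[surv, 2L]] / n
      exp_p <- cbind(pi_ * pj_, pi_ * (1 - pj_), (1 - pi_) * pj_,
                     (1 - pi_) * (1 - pj_))
      obs <- cbind(a[surv], b[surv], cc[surv], d[surv])
      stat <- (obs - n * exp_p)^2 / (n * exp_p * (1 - exp_p))
      pcell <- matrix(stats::pchisq(stat, df = 1L, lower.tail = FALSE),
                      nrow = nrow(stat))
      pcell_adj <- pcell * 4
      pcell_adj[pcell_adj > 1] <- 1
      ok <- pcell_adj[, 1L] < posthoc_alpha & obs[, 1L] > n * exp_p[, 1L]
      if (any(ok)) {
        sel <- surv[ok]
        edges <- data.frame(
          source = rownames(vv)[idx[sel, 1L]],
          target = rownames(vv)[idx[sel, 2L]],
          weight = stat[ok, 1L],
          sign = 1L,
          statistic = stat[ok, 1L],
          adjusted_p = p_bonf[sel]
        )
      }
    }
  }
  omics_network(
    layer_name = m$layer_name, nodes = keep, edges = edges,
    inference = list(test = "fisher_cooccurrence",
                     bonferroni_alpha = bonferroni_alpha,
                     posthoc_alpha = posthoc_alpha,
                     n_samples = n, excluded_genes = constant,
                     n_tested_pairs = n_pairs)
  )
}

#' Write an omics network edge list to TSV
#'
#' Columns: source, target, layer, weight, sign, adjusted_p.
#'
#' @param net an [omics_network()].
#' @param path output path.
#' @export
write_network <- function(net, path) {
  df <- data.frame(source = net$edges$source, target = net$edges$target,
                   layer = net$layer_name, weight = net$edges$weight,
                   sign = net$edges$sign, adjusted_p = net$edges$adjusted_p)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
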