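# Independent brute-force re-implementations used as oracles. These go
# pair-by-pair through stats::cor.test / stats::fisher.test and never
# share code with the package's vectorised scan.

oracle_correlation_edges <- function(values, method, min_abs_cor, max_fdr) {
  keep <- rownames(values)[apply(values, 1, sd) > 0]
  v <- values[keep, , drop = FALSE]
  if (length(keep) < 2) return(data.frame(source = character(), target = character()))
  pairs <- t(combn(keep, 2))
  res <- apply(pairs, 1, function(pr) {
    ct <- suppressWarnings(cor.test(v[pr[1], ], v[pr[2], ], method = method,
                                    exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  rho <- res["rho", ]; p <- res["p", ]
  # cor.test spearman uses the same t approximation when exact = FALSE
  padj <- p.adjust(p, method = "BH")
  sel <- abs(rho) >= min_abs_cor & padj < max_fdr
  data.frame(source = pmin(pairs[sel, 1], pairs[sel, 2]),
             target = pmax(pairs[sel, 1], pairs[sel, 2]),
             rho = rho[sel])
}

oracle_cooccurrence_edges <- function(values, bonferroni_alpha, posthoc_alpha) {
  n <- ncol(values)
  rs <- rowSums(values)
  keep <- rownames(values)[rs > 0 & rs < n]
  if (length(keep) < 2) return(data.frame(source = character(), target = character()))
  v <- values[keep, , drop = FALSE]
  pairs <- t(combn(keep, 2))
  n_pairs <- nrow(pairs)
  out <- list()
  for (i in seq_len(n_pairs)) {
    x <- v[pairs[i, 1], ]; y <- v[pairs[i, 2], ]
    tab <- table(factor(x, levels = c(1, 0)), factor(y, levels = c(1, 0)))
    p <- fisher.test(tab)$p.value
    if (min(1, p * n_pairs) >= bonferroni_alpha) next
    # post hoc: each cell vs its independence expectation, chi-square GOF,
    # Bonferroni over the 4 cells; keep only a joint-presence excess
    pi_ <- mean(x); pj_ <- mean(y)
    o11 <- sum(x == 1 & y == 1)
    e11 <- pi_ * pj_
    gof <- chisq.test(c(o11, n - o11), p = c(e11, 1 - e11), correct = FALSE)
    if (min(1, gof$p.value * 4) < posthoc_alpha && o11 > n * e11)
      out[[length(out) + 1L]] <- data.frame(
        source = min(pairs[i, ]), target = max(pairs[i, ]),
        weight = unname(gof$statistic))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(source = character(), target = character())
}

# direct linear-system solve of the restart-walk stationary state
oracle_rwr_solve <- function(H, p_rs, r) {
  n <- length(p_rs)
  solve(diag(n) - (1 - r) * as.matrix(H), r * p_rs)
}

edge_key <- function(df) {
  if (!nrow(df)) return(character())
  sort(paste(pmin(df$source, df$target), pmax(df$source, df$target)))
}
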