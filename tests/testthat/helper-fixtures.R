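# shared fixtures built in code at test time

# values listed gene-by-gene (row-wise)
mat_with_names <- function(v, genes, samples = NULL) {
  m <- matrix(v, nrow = length(genes), byrow = TRUE)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# 50 genes x 30 samples with a planted 10-gene correlated block
planted_block_matrix <- function(seed = 42, n_genes = 50, n_samples = 30,
                                 block = 10, rho = 0.9) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  f <- rnorm(n_samples)
  v[1:block, ] <- sqrt(rho) * matrix(f, block, n_samples, byrow = TRUE) +
    sqrt(1 - rho) * v[1:block, ]
  dimnames(v) <- list(sprintf("g%02d", 1:n_genes), sprintf("s%02d", 1:n_samples))
  v
}

# small scenario used where the default would be overkill
small_scenario <- function(seed = 7, ...) {
  synthetic_scenario(n_genes = 40, n_samples = 60, n_modules = 2,
                     module_size = 8, n_drugs = 4, n_aligned = 2,
                     targets_per_drug = 3, seed = seed, ...)
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
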