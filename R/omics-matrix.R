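#' Construct an omics matrix
#'
#' A gene-by-sample numeric grid tagged with a layer name and a modality.
#' Modalities: `"quantitative"` (expression / proteome), `"beta"`
#' (methylation fractions in \[0,1\]), `"cnv"` (signed integer copy-number
#' calls) and `"binary"` (0/1 event calls). Missing entries are allowed
#' before preprocessing.
#'
#' @param values numeric matrix, genes on rows, samples on columns, with
#'   row and column names.
#' @param layer_name label for the omics layer.
#' @param modality one of `"quantitative"`, `"beta"`, `"cnv"`, `"binary"`.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, layer_name, modality = c("quantitative", "beta", "cnv", "binary")) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene row names and sample column names")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicated gene IDs: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicated sample IDs: ", paste(dup_s, collapse = ", "))
  obs <- values[!is.na(values)]
  if (modality == "beta" && length(obs) && (min(obs) < 0 || max(obs) > 1))
    stop("beta values must lie in [0, 1]; observed range [",
         signif(min(obs), 4), ", ", signif(max(obs), 4), "]")
  if (modality == "cnv" && length(obs) && any(obs != round(obs)))
    stop("cnv values must be integers (sign encodes amplification/deletion)")
  if (modality == "binary" && length(obs) && !all(obs %in% c(0, 1)))
    stop("binary values must be 0/1")
  structure(
    list(values = values, layer_name = layer_name, modality = modality),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> layer '%s' (%s): %d genes x %d samples, %d missing\n",
              x$layer_name, x$modality, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Read an omics matrix from TSV
#'
#' Expects a header row of sample IDs and gene IDs in the first column;
#' empty cells are recorded as missing.
#'
#' @param path path to a tab-separated file.
#' @inheritParams omics_matrix
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, layer_name, modality = "quantitative") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  if (ncol(raw) < 2L) stop("expected gene IDs plus at least one sample column in ", path)
  genes <- raw[[1L]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) stop("duplicated gene IDs in ", path, ": ", paste(dup, collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at row %d (gene %s), column %d (%s) in %s",
                 cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], genes[bad[1L, 1L]],
                 bad[1L, 2L], colnames(cells)[bad[1L, 2L]], path))
  }
  dimnames(num) <- list(genes, colnames(cells))
  omics_matrix(num, layer_name = layer_name, modality = modality)
}

#' Write an omics matrix to TSV
#'
#' @param m an [omics_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  df <- data.frame(gene = rownames(m$values), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recover methylation beta values and impute missing entries
#'
#' Shifted methylation matrices (stored as beta - offset) are restored by
#' adding a constant `offset` to every entry; each remaining missing entry
#' is then replaced by the median of that gene's observed values. Genes
#' with no observed value at all are dropped (and reported via the
#' `"dropped_genes"` attribute and a message).
#'
#' @param m an [omics_matrix()] whose values become beta after the offset.
#' @param offset constant added to every entry (0.5 for matrices stored as
#'   beta - 0.5; 0 when values are already beta).
#' @param impute replace missing entries by the per-gene median.
#' @return An [omics_matrix()] with modality `"beta"`.
#' @export
preprocess_methylation <- function(m, offset = 0.5, impute = TRUE) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values + offset
  obs <- v[!is.na(v)]
  if (length(obs) && (min(obs) < 0 || max(obs) > 1))
    stop("post-offset values outside [0, 1]; check the offset (range [",
         signif(min(obs), 4), ", ", signif(max(obs), 4), "])")
  all_missing <- rowSums(!is.na(v)) == 0L
  dropped <- rownames(v)[all_missing]
  if (length(dropped)) {
    message("preprocess_methylation: dropping ", length(dropped),
            " gene(s) with no observed value [reason=all_missing]: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
    v <- v[!all_missing, , drop = FALSE]
  }
  if (impute && anyNA(v)) {
    med <- apply(v, 1L, stats::median, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- med[idx[, 1L]]
  }
  out <- omics_matrix(v, layer_name = m$layer_name, modality = "beta")
  attr(out, "dropped_genes") <- dropped
  out
}

#' Read a two-column drug-target table
#'
#' The file must carry a header and two columns: drug identifier and target
#' gene identifier (order detected from header names when possible,
#' otherwise first column = drug). Duplicate pairs are collapsed.
#'
#' @param path TSV path.
#' @return A `drug_gene_bipartite`: list with `edges` (data.frame
#'   `drug`,`gene`), `drugs` and `genes` character vectors.
#' @export
read_drug_gene_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) != 2L)
    stop("drug-target table must have exactly two columns, found ", ncol(raw))
  if (nrow(raw) == 0L) stop("drug-target table is empty: ", path)
  nm <- tolower(names(raw))
  if (grepl("gene|target", nm[1L]) && grepl("drug", nm[2L])) raw <- raw[, 2:1]
  names(raw) <- c("drug", "gene")
  drug_gene_bipartite(raw)
}

#' Construct a drug-gene bipartite graph
#'
#' @param edges data.frame with columns `drug` and `gene`; duplicate pairs
#'   are removed.
#' @return A `drug_gene_bipartite`.
#' @export
drug_gene_bipartite <- function(edges) {
  stopifnot(all(c("drug", "gene") %in% names(edges)))
  edges <- unique(edges[, c("drug", "gene")])
  rownames(edges) <- NULL
  structure(
    list(edges = edges,
         drugs = sort(unique(edges$drug)),
         genes = sort(unique(edges$gene))),
    class = "drug_gene_bipartite"
  )
}

#' @export
print.drug_gene_bipartite <- function(x, ...) {
  cat(sprintf("<drug_gene_bipartite> %d drugs, %d target genes, %d edges\n",
              length(x$drugs), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Write a drug-gene bipartite table to TSV
#' @param db a `drug_gene_bipartite`.
#' @param path output path.
#' @export
write_drug_gene_table <- function(db, path) {
  utils::write.table(db$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one term per line, fields tab-separated — term name,
#' description, then member gene IDs. Terms with no genes are dropped with
#' a warning.
#'
#' @param path GMT path.
#' @return An `annotation_set`: named list of unique gene-ID vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " (", length(f), " fields, need >= 3)")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning("GMT term '", f[1L], "' has no genes; dropped")
      next
    }
    sets[[f[1L]]] <- genes
  }
  annotation_set(sets)
}

#' Construct an annotation set (term -> gene set)
#' @param sets named list of character vectors of gene IDs.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  structure(sets, class = "annotation_set")
}

#' Write an annotation set to GMT
#' @param ann an `annotation_set`.
#' @param path output path.
#' @param descriptions optional character vector of term descriptions.
#' @export
write_gmt <- function(ann, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(ann))
  lines <- vapply(seq_along(ann), function(i) {
    paste(c(names(ann)[i], descriptions[i], ann[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
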