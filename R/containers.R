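#' Expression study container
#'
#' Bundles a sample-by-gene expression matrix (RPKM or normalized log2 units)
#' with per-sample metadata. Rows of `values` are samples, columns are genes;
#' this is the orientation the simulators and readers produce and every
#' downstream operation expects.
#'
#' @param values numeric matrix, samples in rows, genes in columns; both
#'   dimnames must be set.
#' @param sample_meta data.frame with one row per sample and at least the
#'   columns `id`, `genotype`, `age`, `batch`; `treatment` is optional and
#'   defaults to `"none"`.
#' @param gene_lengths optional named numeric vector of gene lengths in bp,
#'   used to compute RPKM views.
#'
#' @return An object of class `expression_study` with elements `values`,
#'   `sample_meta`, `gene_ids`, `gene_lengths`.
#' @export
expression_study <- function(values, sample_meta, gene_lengths = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x genes)")
  if (is.null(rownames(values)) || (ncol(values) > 0 &&
                                    is.null(colnames(values))))
    stop("`values` must carry sample (row) and gene (column) names")
  if (ncol(values) == 0) colnames(values) <- character(0)
  required <- c("id", "genotype", "age", "batch")
  missing_cols <- setdiff(required, names(sample_meta))
  if (length(missing_cols))
    stop("sample metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(values) != nrow(sample_meta))
    stop("values has ", nrow(values), " samples but metadata has ",
         nrow(sample_meta), " rows")
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene identifiers in `values`")
  if (anyDuplicated(sample_meta$id))
    stop("duplicate sample ids in metadata")
  if (!is.numeric(sample_meta$age) || any(sample_meta$age < 0))
    stop("`age` must be numeric and non-negative (months)")
  if (is.null(sample_meta$treatment)) sample_meta$treatment <- "none"
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  rownames(values) <- sample_meta$id
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths)))
      names(gene_lengths) <- colnames(values)
    gene_lengths <- gene_lengths[colnames(values)]
  }
  structure(
    list(values = values, sample_meta = sample_meta,
         gene_ids = colnames(values), gene_lengths = gene_lengths),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$values), "samples x",
      ncol(x$values), "genes\n")
  cat("  genotypes:", paste(unique(x$sample_meta$genotype), collapse = ", "),
      "| ages:", paste(sort(unique(x$sample_meta$age)), collapse = ", "),
      "| batches:", length(unique(x$sample_meta$batch)), "\n")
  tr <- setdiff(unique(x$sample_meta$treatment), "none")
  if (length(tr)) cat("  treatments:", paste(tr, collapse = ", "), "\n")
  invisible(x)
}

#' Gene set
#'
#' @param name set name.
#' @param genes character vector of member gene ids; duplicates are an error.
#' @param description optional free-text description.
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (!length(genes)) stop("gene set '", name, "' has no members")
  if (anyDuplicated(genes))
    stop("gene set '", name, "' contains duplicate members")
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' Signature pair (up- and down-regulated disease signatures)
#'
#' Holds the two disjoint signature gene lists together with the per-gene
#' interaction statistics they were derived from.
#'
#' @param up_genes,dw_genes character vectors (disjoint, no duplicates).
#' @param stats optional data.frame of per-gene interaction statistics.
#' @param name base name; the two sets are `<name>_UP` / `<name>_DW`.
#' @return Object of class `signature_pair`.
#' @export
signature_pair <- function(up_genes, dw_genes, stats = NULL, name = "AD") {
  up_genes <- as.character(up_genes); dw_genes <- as.character(dw_genes)
  if (anyDuplicated(up_genes) || anyDuplicated(dw_genes))
    stop("signature gene lists must not contain duplicates")
  if (length(intersect(up_genes, dw_genes)))
    stop("up and down signatures must be disjoint")
  structure(list(name = name, up_genes = up_genes, dw_genes = dw_genes,
                 stats = stats),
            class = "signature_pair")
}

#' @export
print.signature_pair <- function(x, ...) {
  cat("signature_pair '", x$name, "': ", length(x$up_genes), " UP / ",
      length(x$dw_genes), " DW genes\n", sep = "")
  invisible(x)
}

#' Ranked gene list
#'
#' A gene list sorted by a real-valued metric, descending. Ties in the metric
#' are broken by gene id ascending so that every downstream enrichment score
#' is deterministic.
#'
#' @param ids character gene ids (unique).
#' @param metric numeric ranking metric, same length as `ids`.
#' @return Object of class `ranked_list` with `ids` and `metric` sorted
#'   descending by metric (ties: id ascending), plus a `ties` count.
#' @export
ranked_list <- function(ids, metric) {
  ids <- as.character(ids)
  if (length(ids) != length(metric))
    stop("ids and metric lengths differ")
  if (anyDuplicated(ids)) stop("duplicate gene ids in ranked list")
  if (any(!is.finite(metric))) stop("ranking metric must be finite")
  ord <- order(-metric, ids)
  structure(list(ids = ids[ord], metric = as.numeric(metric[ord]),
                 n_ties = sum(duplicated(metric))),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("ranked_list:", length(x$ids), "genes, metric range [",
      round(min(x$metric), 3), ",", round(max(x$metric), 3), "]\n")
  invisible(x)
}

#' RPKM view of a count study
#'
#' Converts raw counts to reads per kilobase per million mapped reads using
#' the study's gene lengths: counts / (length/1e3) / (libsize/1e6).
#'
#' @param study `expression_study` whose `values` are raw counts and which
#'   carries `gene_lengths`.
#' @return A new `expression_study` on the RPKM scale.
#' @export
rpkm <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(study$gene_lengths))
    stop("gene lengths are required to compute RPKM")
  lib <- rowSums(study$values)
  v <- study$values / (lib / 1e6)
  v <- sweep(v, 2, study$gene_lengths / 1e3, "/")
  expression_study(v, study$sample_meta, study$gene_lengths)
}
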