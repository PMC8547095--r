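# Readers and writers for the plain-text formats the pipeline touches:
# TSV matrices with a metadata sidecar, GMT gene sets, RNK ranked lists.
# All TSV is tab-separated, UTF-8, '.' decimal.

meta_path <- function(path) paste0(path, ".meta.tsv")

#' Write / read an expression study as TSV
#'
#' The value matrix is written to `path` (first column `sample_id`, remaining
#' columns one per gene) and the sample metadata to `<path>.meta.tsv`.
#' Gene lengths, when present, travel in a `<path>.lengths.tsv` sidecar.
#' `read_expression(write_expression(x, p))` is an identity on values and
#' metadata.
#'
#' @param study an `expression_study`.
#' @param path output TSV path for the matrix.
#' @return `write_expression` returns `path` invisibly; `read_expression`
#'   returns an `expression_study`.
#' @export
write_expression <- function(study, path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(sample_id = rownames(study$values),
                   study$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$sample_meta, meta_path(path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(study$gene_lengths)) {
    utils::write.table(
      data.frame(gene = names(study$gene_lengths),
                 length_bp = as.numeric(study$gene_lengths)),
      paste0(path, ".lengths.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  mp <- meta_path(path)
  if (!file.exists(mp)) stop("metadata sidecar not found: ", mp)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id")
    stop("expression TSV must start with a 'sample_id' column")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  meta <- utils::read.table(mp, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  required <- c("id", "genotype", "age", "batch")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(meta) != nrow(values))
    stop("matrix has ", nrow(values), " samples but metadata has ",
         nrow(meta), " rows")
  lengths <- NULL
  lp <- paste0(path, ".lengths.tsv")
  if (file.exists(lp)) {
    ldf <- utils::read.table(lp, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    lengths <- stats::setNames(ldf$length_bp, ldf$gene)
  }
  expression_study(values, meta, lengths)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then members, tab-separated.
#'
#' @param sets a list of `gene_set` objects (or a `signature_pair`, which is
#'   written as two sets `<name>_UP` and `<name>_DW`).
#' @param path file path.
#' @return `write_gmt` returns `path` invisibly; `read_gmt` returns a named
#'   list of `gene_set` objects.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "signature_pair")) {
    sets <- list(
      gene_set(paste0(sets$name, "_UP"), sets$up_genes),
      gene_set(paste0(sets$name, "_DW"), sets$dw_genes))
  }
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line (need name, description, >=1 member): ",
           substr(l, 1, 40))
    gene_set(f[1], f[-(1:2)], description = f[2])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write / read a ranked list in RNK format
#'
#' Two tab-separated columns (gene, metric), written sorted descending with
#' ties broken by gene id ascending.
#'
#' @param rl a `ranked_list`.
#' @param path file path.
#' @return `write_rnk` returns `path` invisibly; `read_rnk` a `ranked_list`.
#' @export
write_rnk <- function(rl, path) {
  stopifnot(inherits(rl, "ranked_list"))
  utils::write.table(data.frame(gene = rl$ids, metric = rl$metric),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("gene", "metric"))
  ranked_list(df$gene, df$metric)
}
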