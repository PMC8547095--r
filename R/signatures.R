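# Disease-signature derivation from the continuous-age interaction model,
# and overlap statistics between differential gene/protein sets.

#' Per-gene genotype-by-age interaction model
#'
#' Fits `value ~ age + genotype + age:genotype + batch` per gene with age
#' continuous (months), reusing the moderated inference of
#' [fit_moderated()] on the interaction coefficient. A positive coefficient
#' means the gene's age trajectory rises faster in the mutant than in the
#' wild type.
#'
#' @param study `expression_study` of normalized log2 values with at least
#'   two genotypes and two ages.
#' @return `diff_result` whose `logFC` column is the interaction
#'   coefficient in log2 units per month.
#' @export
fit_age_interaction <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  meta <- study$sample_meta
  if (length(unique(meta$genotype)) < 2)
    stop("need at least two genotypes")
  if (length(unique(meta$age)) < 2)
    stop("need at least two ages for a continuous-age model")
  design <- if (length(unique(meta$batch)) > 1)
    ~ age * genotype + batch else ~ age * genotype
  df <- design_frame(meta)
  X <- stats::model.matrix(design, df)
  coef <- grep("^age:genotype", colnames(X), value = TRUE)
  if (length(coef) != 1)
    stop("could not identify a single interaction column")
  fit_moderated(study, design, coef = coef)
}

#' Derive up/down disease signatures
#'
#' The up signature is the `k` genes with positive interaction ranked by
#' moderated t descending (most significant first); the down signature the
#' `k` genes with negative interaction ranked by t ascending. The two are
#' disjoint by construction. With `by = "coefficient"` genes are ranked by
#' the raw interaction coefficient instead.
#'
#' @param ir `diff_result` from [fit_age_interaction()].
#' @param k signature size per direction; if fewer genes carry the required
#'   sign, all of them are returned with a warning.
#' @param by ranking statistic, `"t"` (default) or `"coefficient"`.
#' @param name signature base name.
#' @return A `signature_pair`.
#' @export
derive_signatures <- function(ir, k = 250, by = c("t", "coefficient"),
                              name = "AD") {
  stopifnot(inherits(ir, "diff_result"))
  by <- match.arg(by)
  tab <- ir$table
  stat <- if (by == "t") tab$t else tab$logFC
  pick <- function(side) {
    sel <- if (side > 0) stat > 0 else stat < 0
    sub <- tab[sel, , drop = FALSE]
    s <- stat[sel] * side                # larger = more extreme
    ord <- order(-s, sub$gene)
    if (nrow(sub) < k)
      warning("only ", nrow(sub), " genes with ",
              if (side > 0) "positive" else "negative",
              " interaction; returning all")
    sub$gene[ord][seq_len(min(k, nrow(sub)))]
  }
  signature_pair(pick(+1), pick(-1), stats = tab, name = name)
}

#' Overlap enrichment between two gene sets
#'
#' Builds the 2x2 membership table of `set_a` and `set_b` over a gene
#' universe and reports the cross-product odds ratio (with a
#' Haldane-Anscombe 0.5 correction only when a zero cell occurs, flagged),
#' the conditional-MLE odds ratio, and the two-sided Fisher exact p from
#' hypergeometric enumeration.
#'
#' @param set_a,set_b character vectors (or `gene_set`s), subsets of
#'   `universe`.
#' @param universe character vector of tested genes.
#' @return Object of class `overlap_result` with the table counts
#'   `(a, b, c, d)`, `odds_ratio`, `cmle_odds_ratio`, `p`,
#'   `haldane_corrected`, and `universe_size`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  if (inherits(set_a, "gene_set")) set_a <- set_a$genes
  if (inherits(set_b, "gene_set")) set_b <- set_b$genes
  if (!length(universe)) stop("empty universe")
  universe <- unique(as.character(universe))
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop("sets must be subsets of the universe (",
         length(out_a) + length(out_b), " genes outside)")
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  a <- sum(in_a & in_b); b <- sum(in_a & !in_b)
  cc <- sum(!in_a & in_b); d <- sum(!in_a & !in_b)
  zero_cell <- any(c(a, b, cc, d) == 0)
  or <- if (zero_cell) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))
  structure(list(table = c(a = a, b = b, c = cc, d = d),
                 odds_ratio = or,
                 cmle_odds_ratio = unname(ft$estimate),
                 p = ft$p.value,
                 haldane_corrected = zero_cell,
                 universe_size = length(universe)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap_result: a=", x$table["a"], " b=", x$table["b"],
      " c=", x$table["c"], " d=", x$table["d"],
      " (universe ", x$universe_size, ")\n", sep = "")
  cat("  OR =", signif(x$odds_ratio, 5),
      if (x$haldane_corrected) "(Haldane-corrected)" else "",
      "| CMLE OR =", signif(x$cmle_odds_ratio, 5),
      "| Fisher p =", format(x$p, digits = 4), "\n")
  invisible(x)
}
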