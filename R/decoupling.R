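# mRNA-protein concordance and decoupling: match differential results
# across omics layers, classify pairs by dual log fold-change thresholds,
# and summarize protein half-lives per class.

diff_table <- function(x) {
  if (inherits(x, "diff_result")) return(x$table)
  if (is.data.frame(x)) {
    tab <- as.data.frame(x)
    if (is.null(tab$gene) && !is.null(tab$protein)) tab$gene <- tab$protein
    stopifnot(all(c("gene", "logFC", "q") %in% names(tab)))
    return(tab)
  }
  stop("expected a diff_result or a data.frame with gene/logFC/q")
}

#' Match mRNA and protein differential results
#'
#' Pairs genes present in both results through a gene-to-protein mapping
#' (identity by default). Unmatched features are counted and reported.
#'
#' @param diff_mrna,diff_protein `diff_result` / `protein_diff` objects or
#'   data.frames with `gene`, `logFC`, `q`.
#' @param mapping optional data.frame with columns `gene`, `protein`; must
#'   be one-to-one.
#' @return data.frame of class `feature_pairs` with per-feature mRNA and
#'   protein logFC and q.
#' @export
match_features <- function(diff_mrna, diff_protein, mapping = NULL) {
  mt <- diff_table(diff_mrna)
  pt <- diff_table(diff_protein)
  if (is.null(mapping)) {
    mapping <- data.frame(gene = mt$gene, protein = mt$gene,
                          stringsAsFactors = FALSE)
  }
  if (anyDuplicated(mapping$gene) || anyDuplicated(mapping$protein)) {
    dup <- c(mapping$gene[duplicated(mapping$gene)],
             mapping$protein[duplicated(mapping$protein)])
    stop("mapping must be one-to-one; duplicated: ",
         paste(unique(dup), collapse = ", "))
  }
  mapping <- mapping[mapping$gene %in% mt$gene &
                       mapping$protein %in% pt$gene, , drop = FALSE]
  n_unmatched <- (nrow(mt) - nrow(mapping)) +
    (nrow(pt) - nrow(mapping))
  if (!nrow(mapping))
    warning("no features shared between the two results")
  message(nrow(mapping), " features matched; ", n_unmatched,
          " unmatched across the two results")
  mi <- match(mapping$gene, mt$gene)
  pi <- match(mapping$protein, pt$gene)
  out <- data.frame(
    gene = mapping$gene, protein = mapping$protein,
    mrna_logFC = mt$logFC[mi], mrna_q = mt$q[mi],
    prot_logFC = pt$logFC[pi], prot_q = pt$q[pi],
    stringsAsFactors = FALSE)
  class(out) <- c("feature_pairs", "data.frame")
  out
}

#' Classify mRNA-protein pairs by decoupling
#'
#' Among protein-significant pairs (`prot_q < fdr`), strict dual-threshold
#' classification: coupled-up when protein logFC > `prot_thr` and mRNA
#' logFC > `mrna_thr`; decoupled-up when protein logFC > `prot_thr` but
#' mRNA logFC < `mrna_thr`; mirrored for the down classes. Everything
#' else - including values falling exactly on a threshold - is `none`.
#'
#' @param pairs `feature_pairs` from [match_features()].
#' @param prot_thr protein logFC threshold (strict).
#' @param mrna_thr mRNA logFC threshold (strict).
#' @param fdr protein FDR cut (strict).
#' @return `pairs` with an added `class` factor (coupled-up, decoupled-up,
#'   coupled-down, decoupled-down, none).
#' @export
decoupling_classes <- function(pairs, prot_thr = 0.25, mrna_thr = 0.5,
                               fdr = 0.05) {
  stopifnot(inherits(pairs, "feature_pairs"))
  cl <- rep("none", nrow(pairs))
  sig <- !is.na(pairs$prot_q) & pairs$prot_q < fdr
  up <- sig & pairs$prot_logFC > prot_thr
  dw <- sig & pairs$prot_logFC < -prot_thr
  cl[up & pairs$mrna_logFC > mrna_thr] <- "coupled-up"
  cl[up & pairs$mrna_logFC < mrna_thr] <- "decoupled-up"
  cl[dw & pairs$mrna_logFC < -mrna_thr] <- "coupled-down"
  cl[dw & pairs$mrna_logFC > -mrna_thr] <- "decoupled-down"
  pairs$class <- factor(cl, levels = c("coupled-up", "decoupled-up",
                                       "coupled-down", "decoupled-down",
                                       "none"))
  pairs
}

#' mRNA-protein concordance
#'
#' Spearman rank correlation between protein and mRNA log fold changes,
#' by default restricted to protein-significant pairs.
#'
#' @param pairs `feature_pairs`.
#' @param restrict `"protein-significant"` (default), `"all"`, or
#'   `"protein-significant-lfc"` (adds a `|prot logFC| > lfc_thr` cut).
#' @param fdr FDR cut used by the restriction.
#' @param lfc_thr logFC cut for the `-lfc` restriction.
#' @return List with `rho`, `p`, and `n` pairs used.
#' @export
concordance <- function(pairs,
                        restrict = c("protein-significant", "all",
                                     "protein-significant-lfc"),
                        fdr = 0.05, lfc_thr = 0.25) {
  stopifnot(inherits(pairs, "feature_pairs"))
  restrict <- match.arg(restrict)
  keep <- switch(restrict,
    "all" = rep(TRUE, nrow(pairs)),
    "protein-significant" = !is.na(pairs$prot_q) & pairs$prot_q < fdr,
    "protein-significant-lfc" = !is.na(pairs$prot_q) &
      pairs$prot_q < fdr & abs(pairs$prot_logFC) > lfc_thr)
  sub <- pairs[keep, , drop = FALSE]
  if (nrow(sub) < 3)
    stop("fewer than 3 pairs after restriction; correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(sub$prot_logFC, sub$mrna_logFC, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(sub))
}

#' Half-life summary of significant proteins
#'
#' Mean half-life (hours) over annotated, protein-significant pairs, with
#' the annotation coverage fraction; optionally split by decoupling class.
#'
#' @param pairs `feature_pairs` (classified or not).
#' @param annotation named numeric vector protein -> half-life hours, or a
#'   data.frame with `protein` and `half_life`.
#' @param fdr FDR cut defining significance.
#' @param by_class also return per-class means (requires classified pairs).
#' @return List with `mean_half_life`, `coverage`, `n`, and optionally
#'   `by_class`.
#' @export
halflife_summary <- function(pairs, annotation, fdr = 0.05,
                             by_class = FALSE) {
  stopifnot(inherits(pairs, "feature_pairs"))
  if (is.data.frame(annotation))
    annotation <- stats::setNames(annotation$half_life,
                                  annotation$protein)
  sig <- pairs[!is.na(pairs$prot_q) & pairs$prot_q < fdr, , drop = FALSE]
  hl <- annotation[sig$protein]
  ok <- !is.na(hl)
  if (!any(ok)) {
    warning("no annotated significant proteins; half-life undefined")
    return(list(mean_half_life = NA_real_, coverage = 0, n = 0))
  }
  out <- list(mean_half_life = mean(hl[ok]),
              coverage = mean(ok), n = sum(ok))
  if (by_class) {
    if (is.null(sig$class)) stop("run decoupling_classes() first")
    out$by_class <- tapply(hl[ok], droplevels(sig$class[ok]), mean)
  }
  out
}
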