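# Multi-query virtual compound screening over a bioactivity universe:
# per-query raw affinities are converted to empirical -log10 p-values over
# the universe, shortlisted by union, and complemented by cross-validated
# compound-property classifiers.

#' Empirical -log10 p score over a universe
#'
#' Converts raw per-compound values to empirical significance over the
#' universe: `p(c) = (1 + #{c' != c : value(c') >= value(c)}) / (n + 1)`,
#' so the unique best of n compounds scores `-log10(1/(n+1))` and tied
#' values share a p. `NA` values stay `NA` (compound not covered).
#'
#' @param values numeric vector (larger = stronger unless
#'   `direction = "less"`).
#' @param direction `"greater"` or `"less"`.
#' @return `-log10` empirical p per compound, names preserved.
#' @export
empirical_score <- function(values, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  v <- if (direction == "less") -values else values
  ok <- !is.na(v)
  n <- sum(ok)
  if (n < 2) stop("need at least two covered compounds")
  out <- rep(NA_real_, length(values))
  r <- rank(v[ok], ties.method = "min")       # 1 = worst
  out[ok] <- -log10((1 + (n - r)) / (n + 1))
  names(out) <- names(values)
  out
}

cosine_to_refs <- function(space, refs) {
  refs <- intersect(refs, rownames(space))
  if (!length(refs)) stop("no reference drugs covered by this space")
  nrm <- sqrt(rowSums(space^2))
  sims <- (space %*% t(space[refs, , drop = FALSE])) /
    outer(nrm, nrm[refs])
  apply(sims, 1, max)
}

#' Screening queries
#'
#' The five queries of the virtual screen, each returning per-compound raw
#' affinities converted by [empirical_score()]:
#' \describe{
#'   \item{chem_similar}{max cosine similarity to any reference drug in the
#'     chemistry space.}
#'   \item{pheno_similar}{max cosine similarity to any reference drug in the
#'     transcriptional and cell-sensitivity spaces (best across spaces).}
#'   \item{target}{Jaccard overlap between the compound's annotated targets
#'     and the designated disease-target list.}
#'   \item{reversion}{negative correlation between the compound's
#'     transcriptional vector and the disease-signature vector (up genes
#'     weighted +1, down genes -1); higher = stronger reversion.}
#'   \item{shrna}{knockdown profiles are scored by the reversion logic, the
#'     top knockdowns' genes become putative targets, and compounds are
#'     scored against those targets by the target-query logic.}
#' }
#'
#' @param universe a `compound_universe`.
#' @param signature optional named signature vector (defaults to the one
#'   stored in the universe).
#' @param targets optional character vector of disease targets (defaults to
#'   the universe's annotation).
#' @param kd_quantile for `query_shrna`: knockdowns above this quantile of
#'   reversion affinity are taken as hits.
#' @return Named numeric vector of empirical scores (NA where a required
#'   space does not cover the compound).
#' @name screening_queries
NULL

#' @rdname screening_queries
#' @export
query_chem_similar <- function(universe) {
  sims <- cosine_to_refs(universe$spaces$chemistry,
                         universe$reference_drugs$id)
  empirical_score(sims[universe$compounds])
}

#' @rdname screening_queries
#' @export
query_pheno_similar <- function(universe) {
  best <- rep(NA_real_, length(universe$compounds))
  names(best) <- universe$compounds
  for (sp in c("transcription", "cell_sensitivity")) {
    m <- universe$spaces[[sp]]
    if (is.null(m)) next
    sims <- cosine_to_refs(m, universe$reference_drugs$id)
    idx <- names(sims)
    best[idx] <- pmax(best[idx], sims, na.rm = TRUE)
  }
  empirical_score(best)
}

#' @rdname screening_queries
#' @export
query_target <- function(universe, targets = NULL) {
  if (is.null(targets)) targets <- universe$ad_targets
  jac <- vapply(universe$targets, function(ts) {
    u <- length(union(ts, targets))
    if (u == 0) 0 else length(intersect(ts, targets)) / u
  }, 0)
  empirical_score(jac[universe$compounds])
}

reversion_affinity <- function(profiles, signature) {
  genes <- intersect(colnames(profiles), names(signature)[signature != 0])
  if (length(genes) < 3) stop("signature and profile genes barely overlap")
  s <- signature[genes]
  as.numeric(-stats::cor(t(profiles[, genes, drop = FALSE]), s))
}

#' @rdname screening_queries
#' @export
query_reversion <- function(universe, signature = NULL) {
  if (is.null(signature)) signature <- universe$signature
  m <- universe$spaces$transcription
  aff <- stats::setNames(rep(NA_real_, length(universe$compounds)),
                         universe$compounds)
  aff[rownames(m)] <- reversion_affinity(m, signature)
  empirical_score(aff)
}

#' @rdname screening_queries
#' @export
query_shrna <- function(universe, signature = NULL, kd_quantile = 0.9) {
  if (is.null(signature)) signature <- universe$signature
  kd_aff <- reversion_affinity(universe$knockdowns$profiles, signature)
  hits <- rownames(universe$knockdowns$profiles)[
    kd_aff >= stats::quantile(kd_aff, kd_quantile)]
  putative <- unique(universe$knockdowns$gene[hits])
  query_target(universe, targets = putative)
}

#' Run the full five-query screen
#'
#' @param universe a `compound_universe`.
#' @param signature optional signature vector override.
#' @param aggregate `"max"` (default; one strong query suffices, matching
#'   the union shortlisting rule) or `"mean"`.
#' @return `screen_result`: data.frame with one row per compound, the five
#'   per-query scores, and an `aggregate` column.
#' @export
screen_compounds <- function(universe, signature = NULL,
                             aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  scores <- data.frame(
    compound = universe$compounds,
    chem_similar = query_chem_similar(universe),
    pheno_similar = query_pheno_similar(universe),
    target = query_target(universe),
    reversion = query_reversion(universe, signature),
    shrna = query_shrna(universe, signature),
    stringsAsFactors = FALSE, row.names = universe$compounds)
  qcols <- setdiff(names(scores), "compound")
  agg_fun <- if (aggregate == "max") function(x) max(x, na.rm = TRUE)
             else function(x) mean(x, na.rm = TRUE)
  scores$aggregate <- apply(scores[qcols], 1, agg_fun)
  class(scores) <- c("screen_result", "data.frame")
  scores
}

#' Shortlist compounds selected in at least one query
#'
#' A compound is kept when any per-query score reaches that query's
#' threshold (default `-log10(0.001) = 3`, i.e. empirical p < 0.001).
#'
#' @param result a `screen_result`.
#' @param thresholds single number or named per-query vector of score
#'   thresholds.
#' @return Character vector of shortlisted compound ids.
#' @export
shortlist <- function(result, thresholds = 3) {
  qcols <- setdiff(names(result), c("compound", "aggregate"))
  if (length(thresholds) == 1)
    thresholds <- stats::setNames(rep(thresholds, length(qcols)), qcols)
  keep <- rep(FALSE, nrow(result))
  for (q in qcols) {
    thr <- thresholds[[q]]
    if (is.null(thr)) next
    keep <- keep | (!is.na(result[[q]]) & result[[q]] >= thr)
  }
  result$compound[keep]
}

#' Binarize a continuous compound property
#'
#' @param values numeric responses.
#' @param cutoff threshold; values at or above it are labeled `"high"`.
#' @return Factor with levels `low`, `high`.
#' @export
binarize_labels <- function(values, cutoff) {
  factor(ifelse(values >= cutoff, "high", "low"),
         levels = c("low", "high"))
}

#' Cross-validated compound-property classifier
#'
#' Stratified k-fold cross-validation of an extremely randomized trees
#' classifier (ranger with `splitrule = "extratrees"`) on per-compound
#' features, reporting ROC AUC per fold and on average, plus a final scorer
#' fitted on all data.
#'
#' @param features numeric matrix (compounds x features).
#' @param labels two-level factor (or anything coercible), positive class =
#'   second level.
#' @param folds number of CV folds.
#' @param seed RNG seed for fold assignment and tree fitting.
#' @param num_trees trees per forest.
#' @return List with `fold_auc`, `mean_auc`, `model` (ranger fit on all
#'   data), and `oof_scores` (out-of-fold positive-class probabilities).
#' @export
cv_property_classifier <- function(features, labels, folds = 5, seed = 1,
                                   num_trees = 300) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  if (min(table(labels)) < folds)
    stop("each class needs at least `folds` members for stratified CV")
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (all(apply(features, 2, stats::sd) == 0))
    warning("all features are constant; expect AUC near 0.5")
  pos <- levels(labels)[2]
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    oof <- rep(NA_real_, length(labels))
    fold_auc <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fold != k
      fit <- ranger::ranger(
        x = features[tr, , drop = FALSE], y = labels[tr],
        probability = TRUE, splitrule = "extratrees",
        num.trees = num_trees, seed = seed + k)
      pr <- stats::predict(fit, features[!tr, , drop = FALSE])$
        predictions[, pos]
      oof[!tr] <- pr
      fold_auc[k] <- as.numeric(pROC::auc(
        pROC::roc(labels[!tr], pr, levels = levels(labels),
                  direction = "<", quiet = TRUE)))
    }
    final <- ranger::ranger(
      x = features, y = labels, probability = TRUE,
      splitrule = "extratrees", num.trees = num_trees, seed = seed)
    list(fold_auc = fold_auc, mean_auc = mean(fold_auc), model = final,
         oof_scores = oof)
  })
}
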