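# Signature-reversion scoring: weighted Kolmogorov-Smirnov running
# enrichment score on a ranked drug-vs-vehicle list, a randomized-signature
# null, leading-edge extraction, cross-treatment reversion-rank tables and
# restoration checks.

# ES from hit positions and weights (|metric|^alpha), by the same cumsum
# arithmetic as running_es() so sampled null scores and observed scores
# agree bit-for-bit (a |max| vs |min| tie, up to 1e-12, resolves to the
# positive side in both). Zero total hit weight falls back to equal
# weights.
es_core <- function(positions, w, N) {
  k <- length(positions)
  if (k == 0 || k >= N) stop("gene set must hit some but not all ranks")
  W <- sum(w)
  steps <- rep(-1 / (N - k), N)
  steps[positions] <- if (W == 0) rep(1 / k, k) else w / W
  profile <- cumsum(steps)
  max_p <- max(0, profile)
  min_p <- min(0, profile)
  if (max_p >= -min_p - 1e-12) max_p else min_p
}

#' Weighted running enrichment score
#'
#' Computes the weighted Kolmogorov-Smirnov running sum of a gene set along
#' a ranked list: a hit at rank i adds `|metric_i|^weight` normalized by
#' the total hit weight, a miss subtracts `1/(N - |S|)`. The enrichment
#' score is the signed maximum deviation from zero, and the leading edge
#' contains the hits at or before the maximum (positive ES) or at or after
#' the minimum (negative ES).
#'
#' @param ranked a `ranked_list`.
#' @param set a `gene_set` or character vector of member genes.
#' @param weight metric exponent (0 = classical unweighted KS; default 1).
#' @return Object of class `running_es`: `es`, `profile` (length-N running
#'   score), `hit_ranks`, `leading_edge`, `n_hits`, `extremum` (rank of the
#'   ES).
#' @export
running_es <- function(ranked, set, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  genes <- if (inherits(set, "gene_set")) set$genes else as.character(set)
  N <- length(ranked$ids)
  hit <- ranked$ids %in% genes
  k <- sum(hit)
  if (k == 0) stop("gene set does not intersect the ranked universe")
  if (k == N) stop("gene set covers the whole universe (no misses)")
  w <- abs(ranked$metric[hit])^weight
  W <- sum(w)
  w_norm <- if (W == 0) rep(1 / k, k) else w / W
  steps <- rep(-1 / (N - k), N)
  steps[hit] <- w_norm
  profile <- cumsum(steps)
  i_max <- which.max(profile); i_min <- which.min(profile)
  max_p <- max(0, profile[i_max]); min_p <- min(0, profile[i_min])
  if (max_p >= -min_p - 1e-12) {
    es <- max_p; ext <- i_max
    le <- ranked$ids[hit & seq_len(N) <= ext]
  } else {
    es <- min_p; ext <- i_min
    # the score keeps falling through the extremum's own rank, so a hit at
    # the minimum itself belongs to the trailing (leading-edge) block
    le <- ranked$ids[hit & seq_len(N) >= ext]
  }
  structure(list(es = es, profile = profile,
                 hit_ranks = which(hit), leading_edge = le,
                 n_hits = k, extremum = ext, weight = weight),
            class = "running_es")
}

#' @export
print.running_es <- function(x, ...) {
  cat("running_es: ES =", signif(x$es, 4), "at rank", x$extremum,
      "|", x$n_hits, "hits,", length(x$leading_edge),
      "leading-edge genes\n")
  invisible(x)
}

#' Randomized-signature null for the enrichment score
#'
#' Draws `B` gene sets of the observed size uniformly without replacement
#' from the ranked universe, computes their enrichment scores, and (when an
#' observed ES is supplied) the empirical tail probability of its
#' magnitude with add-one smoothing (see [empirical_p()]); the sign of the
#' observed ES carries the direction.
#'
#' @param ranked a `ranked_list`.
#' @param set_size gene-set size (< universe size).
#' @param B null draws (a warning below 100).
#' @param seed RNG seed.
#' @param observed_es optional observed ES.
#' @param weight metric exponent, as in [running_es()].
#' @return List with `null_es` (length B), `p` (or NA), `ci95` (2.5/97.5%
#'   quantiles of the null ES), `B`, `seed`.
#' @export
randomized_null <- function(ranked, set_size, B = 10000, seed = 1,
                            observed_es = NULL, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  N <- length(ranked$ids)
  if (set_size >= N) stop("set_size must be below the universe size")
  if (B < 100) warning("B < 100 gives a very coarse empirical p")
  absw <- abs(ranked$metric)^weight
  null_es <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      pos <- sort.int(sample.int(N, set_size))
      es_core(pos, absw[pos], N)
    }, 0)
  })
  p <- NA_real_
  if (!is.null(observed_es)) p <- empirical_p(null_es, observed_es)
  list(null_es = null_es, p = p,
       ci95 = stats::quantile(null_es, c(0.025, 0.975), names = FALSE),
       B = B, seed = seed)
}

#' Empirical p with add-one smoothing
#'
#' Tail probability of the observed score's magnitude under the null:
#' `p = (1 + #{|null| >= |obs|}) / (B + 1)`. Comparing magnitudes keeps p
#' uniform under the null whatever the null's asymmetry; the direction of
#' the effect is judged separately from the sign of the observed ES (see
#' [reversion_test()]). An observed value of 0 returns exactly 1.
#'
#' @param null_es numeric null sample.
#' @param observed observed statistic.
#' @return p in `(0, 1]`, never exactly 0.
#' @export
empirical_p <- function(null_es, observed) {
  (1 + sum(abs(null_es) >= abs(observed))) / (length(null_es) + 1)
}

#' Test a treatment for signature reversion
#'
#' Ranks genes by the drug-vs-vehicle contrast (`sign(logFC) * -log10 p`)
#' and scores both halves of the disease signature. The up signature is
#' "reverted" when its ES is negative with empirical p below `alpha`
#' (disease-upregulated genes enriched among drug-downregulated genes);
#' the down signature when its ES is positive with p below `alpha`.
#' Signature genes absent from the treated universe are dropped and
#' counted, with a warning past 50%.
#'
#' @param drug_vs_vehicle `diff_result` of the drug-vs-vehicle contrast
#'   (or a ready `ranked_list`).
#' @param sig a `signature_pair`.
#' @param B null draws.
#' @param seed RNG seed.
#' @param alpha significance level for the verdict.
#' @param weight metric exponent.
#' @param treatment label carried into the result.
#' @return Object of class `reversion_result`: per side (`up`, `dw`) the
#'   ES, running profile, empirical p, null 95% band, leading edge, number
#'   of dropped genes, and the reverted verdict.
#' @export
reversion_test <- function(drug_vs_vehicle, sig, B = 1000, seed = 1,
                           alpha = 0.05, weight = 1,
                           treatment = "treatment") {
  ranked <- if (inherits(drug_vs_vehicle, "ranked_list")) drug_vs_vehicle
            else rank_metric(drug_vs_vehicle)
  stopifnot(inherits(sig, "signature_pair"))
  score_side <- function(genes, side, seed_off) {
    present <- intersect(genes, ranked$ids)
    dropped <- length(genes) - length(present)
    if (dropped > 0.5 * length(genes))
      warning("more than half of the ", side,
              " signature is absent from the ranked universe")
    es <- running_es(ranked, present, weight = weight)
    nul <- randomized_null(ranked, length(present), B = B,
                           seed = seed + seed_off, observed_es = es$es,
                           weight = weight)
    reverted <- if (side == "up") es$es < 0 && nul$p < alpha
                else es$es > 0 && nul$p < alpha
    list(es = es$es, profile = es$profile, p = nul$p,
         null_ci95 = nul$ci95, leading_edge = es$leading_edge,
         n_dropped = dropped, reverted = reverted,
         extremum = es$extremum)
  }
  structure(list(up = score_side(sig$up_genes, "up", 0),
                 dw = score_side(sig$dw_genes, "dw", 1),
                 treatment = treatment, signature = sig$name,
                 ranked = ranked, B = B, alpha = alpha),
            class = "reversion_result")
}

#' @export
print.reversion_result <- function(x, ...) {
  cat("reversion_result for", x$treatment, "vs signature", x$signature,
      "\n")
  for (s in c("up", "dw")) {
    r <- x[[s]]
    cat(sprintf("  %s: ES = %.3f, p = %.4g, %sreverted (%d leading-edge)\n",
                toupper(s), r$es, r$p, if (r$reverted) "" else "not ",
                length(r$leading_edge)))
  }
  invisible(x)
}

#' Cross-treatment reversion-rank table
#'
#' For one signature side, collects the leading-edge genes appearing in at
#' least `min_treatments` treatments and tabulates their reversion rank per
#' treatment: the gene's position counted from the drug-downregulated end
#' of the ranking for the up signature, or from the upregulated end for the
#' down signature (1 = most strongly reverted). Rows are the `top_n` genes
#' with the smallest average rank, sorted by row mean.
#'
#' @param results named list of `reversion_result`s (one per treatment).
#' @param side `"up"` or `"dw"`.
#' @param top_n maximum rows.
#' @param min_treatments minimum number of leading edges a gene must
#'   appear in.
#' @return Numeric gene-by-treatment matrix of ranks (NA where the gene is
#'   not in that treatment's leading edge); empty when nothing qualifies.
#' @export
reversion_rank_table <- function(results, side = c("up", "dw"),
                                 top_n = 40, min_treatments = 2) {
  side <- match.arg(side)
  if (length(results) < 2) {
    le <- character(0)
  } else {
    le <- table(unlist(lapply(results, function(r)
      unique(r[[side]]$leading_edge))))
    le <- names(le)[le >= min_treatments]
  }
  if (!length(le))
    return(matrix(numeric(0), 0, length(results),
                  dimnames = list(NULL, names(results))))
  m <- sapply(results, function(r) {
    ranked <- r$ranked
    N <- length(ranked$ids)
    pos <- match(le, ranked$ids)
    rk <- if (side == "up") N - pos + 1 else pos
    rk[!le %in% r[[side]]$leading_edge] <- NA
    rk
  })
  m <- matrix(m, nrow = length(le),
              dimnames = list(le, names(results)))
  avg <- rowMeans(m, na.rm = TRUE)
  m <- m[order(avg), , drop = FALSE]
  m[seq_len(min(top_n, nrow(m))), , drop = FALSE]
}

#' Restoration check against the wild-type reference
#'
#' Compares, for each signature gene, its t-score in the vehicle-treated
#' mutant vs wild-type contrast with its t-score in the drug-treated mutant
#' vs wild-type contrast (both sharing the wild-type vehicle reference). A
#' gene is restored when the drug shifts its t toward (or across) zero.
#'
#' @param drug_vs_wt,vehicle_vs_wt `diff_result`s sharing the wild-type
#'   vehicle reference.
#' @param sig a `signature_pair`.
#' @return data.frame with gene, side, `t_vehicle`, `t_drug`, `restored`
#'   (|t_drug| < |t_vehicle|), and `restoration` (1 - t_drug/t_vehicle;
#'   1 = fully restored, 0 = unchanged). Genes missing from either
#'   contrast are excluded; their count is attached as attribute
#'   `n_excluded`.
#' @export
restoration_check <- function(drug_vs_wt, vehicle_vs_wt, sig) {
  stopifnot(inherits(drug_vs_wt, "diff_result"),
            inherits(vehicle_vs_wt, "diff_result"),
            inherits(sig, "signature_pair"))
  genes <- c(sig$up_genes, sig$dw_genes)
  side <- rep(c("up", "dw"), c(length(sig$up_genes),
                               length(sig$dw_genes)))
  iv <- match(genes, vehicle_vs_wt$table$gene)
  id <- match(genes, drug_vs_wt$table$gene)
  ok <- !is.na(iv) & !is.na(id)
  tv <- vehicle_vs_wt$table$t[iv[ok]]
  td <- drug_vs_wt$table$t[id[ok]]
  out <- data.frame(
    gene = genes[ok], side = side[ok],
    t_vehicle = tv, t_drug = td,
    restored = abs(td) < abs(tv),
    restoration = ifelse(tv != 0, 1 - td / tv, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!ok)
  out
}
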