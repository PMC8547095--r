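# Expression filtering, quantile normalization, empirical-Bayes moderated
# differential expression with batch covariates, BH correction and
# GSEA-ready ranking.

#' Filter lowly expressed genes
#'
#' Keeps genes detected at `min_value` RPKM or above in at least `min_frac`
#' of samples (both boundaries inclusive). The detection filter defines the
#' tested gene universe for every downstream comparison.
#'
#' @param study `expression_study` on the RPKM scale.
#' @param min_value detection threshold (RPKM), inclusive.
#' @param min_frac minimum fraction of samples at or above `min_value`,
#'   inclusive.
#' @return Filtered `expression_study`; kept/dropped counts are attached as
#'   attribute `filter_counts` and reported via `message()`.
#' @export
filter_expressed <- function(study, min_value = 0.2, min_frac = 0.9) {
  stopifnot(inherits(study, "expression_study"))
  frac <- colMeans(study$values >= min_value)
  keep <- frac >= min_frac
  if (!any(keep))
    warning("no genes pass the expression filter")
  message(sum(keep), " genes kept, ", sum(!keep), " dropped by the ",
          min_value, " RPKM / ", min_frac * 100, "% filter")
  out <- expression_study(study$values[, keep, drop = FALSE],
                          study$sample_meta,
                          study$gene_lengths[keep])
  attr(out, "filter_counts") <- c(kept = sum(keep), dropped = sum(!keep))
  out
}

#' Quantile normalization
#'
#' Forces every sample to share the mean quantile vector while preserving
#' within-sample ranks; ties are resolved by mean rank. Idempotent.
#'
#' @param x numeric sample-by-gene matrix or an `expression_study`.
#' @return Object of the same type with normalized values.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "expression_study")) {
    x$values <- quantile_normalize(x$values)
    return(x)
  }
  if (anyNA(x)) stop("quantile normalization requires complete values")
  out <- t(limma::normalizeQuantiles(t(x), ties = TRUE))
  dimnames(out) <- dimnames(x)
  out
}

#' Subset a study by samples
#'
#' @param study `expression_study`.
#' @param idx logical or integer index over samples.
#' @return `expression_study` restricted to those samples.
#' @export
subset_samples <- function(study, idx) {
  stopifnot(inherits(study, "expression_study"))
  expression_study(study$values[idx, , drop = FALSE],
                   study$sample_meta[idx, , drop = FALSE],
                   study$gene_lengths)
}

# Model frame used for all designs: genotype releveled so any 'wt' label is
# the reference; batch always a factor.
design_frame <- function(meta) {
  df <- meta
  gl <- unique(df$genotype)
  if ("wt" %in% gl) gl <- c("wt", setdiff(gl, "wt"))
  df$genotype <- factor(df$genotype, levels = gl)
  df$batch <- factor(df$batch)
  if (!is.null(df$treatment)) {
    tl <- unique(df$treatment)
    ref <- intersect(c("vehicle", "none"), tl)
    if (length(ref)) tl <- c(ref[1], setdiff(tl, ref[1]))
    df$treatment <- factor(df$treatment, levels = tl)
  }
  df
}

# trigamma inverse by Newton iteration, with the standard asymptotic
# endpoints for very small / very large arguments.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# Method-of-moments fit of the scaled inverse-chi-square prior on residual
# variances: on e = log(s^2) - digamma(d/2) + log(d/2), the prior df d0
# solves trigamma(d0/2) = var(e) - trigamma(d/2) and
# s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2)). A non-positive moment
# estimate means no excess dispersion: d0 = Inf and s0^2 = exp(mean(e)).
estimate_prior <- function(s2, df) {
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  # all-but-constant genes would drag the prior to absurd values; they are
  # excluded here and handled as degenerate downstream
  e_ok <- e[is.finite(e) & s2 > max(s2) * 1e-12]
  if (length(e_ok) < 2)
    stop("need at least two finite residual variances to moderate")
  emean <- mean(e_ok)
  evar <- stats::var(e_ok)
  rhs <- evar - trigamma(df / 2)
  if (is.finite(rhs) && rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion: pool completely, plain mean of the variances
    d0 <- Inf
    s02 <- mean(s2[is.finite(e) & s2 > max(s2) * 1e-12])
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated differential expression
#'
#' Per-gene ordinary least squares on an arbitrary design (typically
#' including the processing batch as covariate), with residual variances
#' shrunk toward a prior by the standard empirical-Bayes construction:
#' the posterior variance is `(d0*s0^2 + d*s^2) / (d0 + d)` and the
#' moderated t uses `d0 + d` degrees of freedom. The prior `(d0, s0^2)` is
#' estimated by the method of moments on log residual variances; a
#' non-finite moment estimate falls back to complete pooling (`d0 = Inf`).
#'
#' @param study `expression_study` of normalized (log2) values.
#' @param design model formula over the sample metadata columns, e.g.
#'   `~ genotype + batch`.
#' @param coef name of the design-matrix column to test.
#' @param contrast alternatively, a numeric contrast vector over the design
#'   columns (overrides `coef`).
#' @param d0_override optional fixed prior df (e.g. `0` for ordinary t,
#'   `Inf` for fully pooled variance) in place of the estimate.
#' @return Object of class `diff_result`: a list with `table` (gene, logFC,
#'   ave_expr, t, p, q), `eb` (d0, s02, s2, s2_post), `df_residual`, the
#'   contrast label, and the design formula.
#' @export
fit_moderated <- function(study, design = ~ genotype + batch, coef = NULL,
                          contrast = NULL, d0_override = NULL) {
  stopifnot(inherits(study, "expression_study"))
  df <- design_frame(study$sample_meta)
  X <- stats::model.matrix(design, df)
  n <- nrow(X); p <- qr(X)$rank
  if (p < ncol(X)) stop("design matrix is not full rank")
  dfr <- n - p
  if (dfr < 1) stop("no residual degrees of freedom")
  if (is.null(contrast)) {
    if (is.null(coef)) coef <- colnames(X)[ncol(X)]
    if (!coef %in% colnames(X))
      stop("coefficient '", coef, "' not in design columns: ",
           paste(colnames(X), collapse = ", "))
    contrast <- as.numeric(colnames(X) == coef)
    label <- coef
  } else {
    if (length(contrast) != ncol(X))
      stop("contrast length must match the number of design columns")
    label <- paste0("contrast(", paste(signif(contrast, 3), collapse = ","),
                    ")")
  }
  Y <- study$values                      # samples x genes
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Y)          # p x genes
  res <- Y - X %*% B
  s2 <- colSums(res^2) / dfr
  cb <- as.numeric(crossprod(contrast, B))
  se_unscaled <- sqrt(as.numeric(crossprod(contrast, XtXi %*% contrast)))

  prior <- estimate_prior(s2, dfr)
  if (!is.null(d0_override)) prior$d0 <- d0_override
  d0 <- prior$d0; s02 <- prior$s02
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- dfr
  } else {
    s2_post <- (d0 * s02 + dfr * s2) / (d0 + dfr)
    df_total <- d0 + dfr
  }
  tstat <- cb / (sqrt(s2_post) * se_unscaled)
  tstat[!is.finite(tstat)] <- 0
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  # genes with (numerically) no signal and no variance: t = 0, p = 1
  degenerate <- s2 < 1e-24 & abs(cb) < 1e-10
  tstat[degenerate] <- 0
  pval[degenerate] <- 1
  tab <- data.frame(
    gene = colnames(Y),
    logFC = cb,
    ave_expr = colMeans(Y),
    t = tstat,
    p = pval,
    q = bh_adjust(pval),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$gene
  structure(list(table = tab,
                 eb = list(d0 = d0, s02 = s02, s2 = s2, s2_post = s2_post,
                           se_unscaled = se_unscaled),
                 df_residual = dfr, df_total = df_total,
                 contrast = label, design = design),
            class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat("diff_result for", x$contrast, "-", nrow(x$table), "genes\n")
  cat("  prior df d0 =", signif(x$eb$d0, 4), "| prior variance s0^2 =",
      signif(x$eb$s02, 4), "| residual df =", x$df_residual, "\n")
  cat("  genes at q < 0.05:", sum(x$table$q < 0.05), "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`stats::p.adjust` with `method = "BH"`); NaN
#' inputs are propagated with a warning rather than dropped.
#'
#' @param p numeric p-values in `[0, 1]` (NaN allowed).
#' @return Adjusted q-values, capped at 1, monotone in the sorted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.nan(p))) warning("NaN p-values propagated through BH")
  ok <- is.finite(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NaN, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' GSEA ranking metric
#'
#' Ranks genes by `sign(logFC) * -log10(p)`; p-values are floored at 1e-300
#' before the log so the metric stays finite.
#'
#' @param diff a `diff_result`.
#' @return A `ranked_list` sorted descending (ties broken by gene id).
#' @export
rank_metric <- function(diff) {
  stopifnot(inherits(diff, "diff_result"))
  tab <- diff$table
  p <- pmax(tab$p, 1e-300)
  ranked_list(tab$gene, sign(tab$logFC) * -log10(p))
}

#' Count significant genes
#'
#' Counts genes passing a strict FDR cut (`q < fdr`) and a strict absolute
#' log fold-change cut, split by direction.
#'
#' @param diff a `diff_result`.
#' @param fdr FDR threshold (strict `<`).
#' @param min_abs_lfc minimum |logFC| (strict `>`).
#' @return Named integer vector `c(n_up, n_down)`.
#' @export
count_significant <- function(diff, fdr = 0.05, min_abs_lfc = 0.5) {
  stopifnot(inherits(diff, "diff_result"))
  tab <- diff$table
  sig <- !is.na(tab$q) & tab$q < fdr
  c(n_up = sum(sig & tab$logFC > min_abs_lfc),
    n_down = sum(sig & tab$logFC < -min_abs_lfc))
}
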