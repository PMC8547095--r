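# PSM filtering, master-protein assignment, median-ratio size-factor
# normalization within processing batches, and per-protein differential
# abundance via fixed/mixed models with a structural fallback hierarchy.

psm_required <- c("peptide", "proteins", "fraction", "batch", "sample",
                  "intensity", "avg_sn", "contaminant", "quan_usage")

check_psm <- function(psm) {
  miss <- setdiff(psm_required, names(psm))
  if (length(miss))
    stop("PSM table is missing column(s): ", paste(miss, collapse = ", "))
}

#' Filter PSM rows
#'
#' Applies the four reporter-level quality rules: contaminant flag must be
#' "False", average reporter signal-to-noise strictly larger than 3,
#' reporter intensity strictly larger than 1000, and the quan-usage flag
#' "Use". Per-rule removal counts are reported and attached as attribute
#' `filter_counts`.
#'
#' @param psm PSM data.frame (see [simulate_proteomics()] for columns).
#' @return Filtered PSM table (a subset of the input rows).
#' @export
filter_psms <- function(psm) {
  check_psm(psm)
  fail_cont <- psm$contaminant != "False"
  fail_sn <- !(psm$avg_sn > 3)
  fail_int <- !(psm$intensity > 1000)
  fail_use <- psm$quan_usage != "Use"
  counts <- c(contaminant = sum(fail_cont), low_sn = sum(fail_sn),
              low_intensity = sum(fail_int), quan_unused = sum(fail_use))
  keep <- !(fail_cont | fail_sn | fail_int | fail_use)
  message("PSM filter removed ", sum(!keep), "/", nrow(psm), " rows (",
          paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  out <- psm[keep, , drop = FALSE]
  attr(out, "filter_counts") <- counts
  out
}

#' Assign one master protein per peptide
#'
#' For peptides with several candidate accessions (semicolon-separated in
#' `proteins`), the candidate with the largest total intensity across the
#' whole table becomes the master protein; ties go to the lexicographically
#' smallest accession with a warning. Unique-protein peptides keep their
#' protein.
#'
#' @param psm filtered PSM table.
#' @return The table with an added `master_protein` column.
#' @export
assign_master_protein <- function(psm) {
  check_psm(psm)
  cand <- strsplit(psm$proteins, ";", fixed = TRUE)
  acc <- unlist(cand)
  totals <- rowsum(rep(psm$intensity, lengths(cand)), acc)
  totals <- stats::setNames(totals[, 1], rownames(totals))
  had_tie <- FALSE
  psm$master_protein <- vapply(cand, function(a) {
    if (length(a) == 1) return(a)
    tt <- totals[a]
    best <- a[tt == max(tt)]
    if (length(best) > 1) {
      had_tie <<- TRUE
      best <- sort(best)
    }
    best[1]
  }, "")
  if (had_tie)
    warning("master-protein total-intensity tie(s) broken by smallest ",
            "accession")
  psm
}

#' Median-ratio size-factor normalization
#'
#' Within each processing batch (or globally with `by_batch = FALSE`):
#' intensities are summarized as the median per protein and sample, a
#' reference profile is the per-protein mean over samples, and each
#' sample's size factor is the median over proteins of its ratio to the
#' reference (proteins with zero reference are skipped). All PSM
#' intensities are divided by their sample's factor and `log2(x + 1)` is
#' taken.
#'
#' @param psm PSM table with `master_protein` assigned.
#' @param by_batch normalize within batches (default) or globally.
#' @return List with `psm` (input plus `norm_intensity` and
#'   `log2_intensity` columns) and `size_factors` (data.frame batch,
#'   sample, sf).
#' @export
size_factor_normalize <- function(psm, by_batch = TRUE) {
  check_psm(psm)
  if (is.null(psm$master_protein))
    stop("run assign_master_protein() first")
  groups <- if (by_batch) unique(psm$batch) else "all"
  sf_rows <- list()
  psm$norm_intensity <- NA_real_
  for (b in groups) {
    sel <- if (by_batch) psm$batch == b else rep(TRUE, nrow(psm))
    sub <- psm[sel, ]
    med <- tapply(sub$intensity,
                  list(sub$master_protein, sub$sample),
                  stats::median)
    ref <- rowMeans(med, na.rm = TRUE)
    ok <- is.finite(ref) & ref > 0
    ratios <- med[ok, , drop = FALSE] / ref[ok]
    sf <- apply(ratios, 2, stats::median, na.rm = TRUE)
    psm$norm_intensity[sel] <- sub$intensity / sf[sub$sample]
    sf_rows[[as.character(b)]] <- data.frame(
      batch = b, sample = names(sf), sf = as.numeric(sf),
      stringsAsFactors = FALSE)
  }
  psm$log2_intensity <- log2(psm$norm_intensity + 1)
  list(psm = psm, size_factors = do.call(rbind, sf_rows))
}

# Fallback hierarchy for one protein's model. Random effects are included
# only when the data can identify them: peptide when >1 peptide, fraction
# within peptide when any peptide spans >1 fraction, sample when samples
# carry repeated measures. A failed mixed fit cascades to a fixed-effects
# model with a peptide covariate and finally to a plain fixed model.
protein_formula <- function(dat) {
  n_pep <- length(unique(dat$peptide))
  multi_frac <- any(tapply(dat$fraction, dat$peptide,
                           function(f) length(unique(f))) > 1)
  repeated <- any(table(dat$sample) > 1)
  re <- c(if (n_pep > 1) "(1 | peptide)",
          if (n_pep > 1 && multi_frac) "(1 | peptide:fraction)",
          if (n_pep == 1 && multi_frac) "(1 | fraction)",
          if (repeated) "(1 | sample)")
  fixed <- if (length(unique(dat$batch)) > 1) "0 + group + batch"
           else "0 + group"
  list(re = re, fixed = fixed,
       type = if (length(re)) "mixed" else "simple")
}

fit_one_protein <- function(dat, contrast_groups) {
  spec <- protein_formula(dat)
  K <- NULL
  mk_K <- function(coefs) {
    k <- stats::setNames(rep(0, length(coefs)), coefs)
    g1 <- paste0("group", contrast_groups[1])
    g2 <- paste0("group", contrast_groups[2])
    if (!all(c(g1, g2) %in% coefs)) return(NULL)
    k[g1] <- 1; k[g2] <- -1
    matrix(k, 1, dimnames = list("contrast", coefs))
  }
  glht_est <- function(model) {
    coefs <- names(if (inherits(model, "merMod")) lme4::fixef(model)
                   else stats::coef(model))
    K <- mk_K(coefs)
    if (is.null(K)) stop("contrast groups absent from this protein's data")
    g <- summary(multcomp::glht(model, linfct = K),
                 test = multcomp::adjusted("none"))
    est <- as.numeric(g$test$coefficients)
    p <- as.numeric(g$test$pvalues)
    # degenerate zero-variance data: a null contrast is simply not rejected
    if (!is.finite(p)) p <- if (abs(est) < 1e-12) 1 else 0
    c(estimate = est, se = as.numeric(g$test$sigma), p = p)
  }
  attempts <- list()
  if (spec$type == "mixed")
    attempts$mixed <- stats::as.formula(
      paste("log2_intensity ~", spec$fixed, "+",
            paste(spec$re, collapse = " + ")))
  if (length(unique(dat$peptide)) > 1)
    attempts$fixed <- stats::as.formula(
      paste("log2_intensity ~", spec$fixed, "+ peptide"))
  attempts$simple <- stats::as.formula(
    paste("log2_intensity ~", spec$fixed))
  for (type in names(attempts)) {
    est <- tryCatch({
      model <- if (type == "mixed")
        lme4::lmer(attempts[[type]], data = dat, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     calc.derivs = FALSE))
      else stats::lm(attempts[[type]], data = dat)
      out <- glht_est(model)
      c(out, model_rank = which(names(attempts) == type))
    }, error = function(e) NULL)
    if (!is.null(est)) {
      if (type != names(attempts)[1] && names(attempts)[1] == "mixed")
        attr(est, "fallback") <- TRUE
      attr(est, "model_type") <- type
      return(est)
    }
  }
  NULL
}

#' Fit one protein's abundance model
#'
#' Fits the richest model the protein's data identify (see
#' [protein_diffexp()] for the hierarchy) and tests one group contrast.
#'
#' @param dat data.frame with one row per PSM observation and columns
#'   `log2_intensity`, `peptide`, `fraction`, `sample`, `batch`, `group`
#'   (factors).
#' @param contrast_groups length-2 character vector of group levels;
#'   the estimate is group1 - group2.
#' @return Named vector with `estimate`, `se`, `p`, `model_rank`, plus a
#'   `model_type` attribute ("mixed", "fixed" or "simple"); NULL when no
#'   model can be fitted.
#' @export
fit_protein_model <- function(dat, contrast_groups) {
  needed <- c("log2_intensity", "peptide", "fraction", "sample",
              "batch", "group")
  miss <- setdiff(needed, names(dat))
  if (length(miss))
    stop("protein data is missing column(s): ",
         paste(miss, collapse = ", "))
  for (cn in c("peptide", "fraction", "sample", "batch", "group"))
    dat[[cn]] <- droplevels(factor(dat[[cn]]))
  fit_one_protein(dat, contrast_groups)
}

#' Per-protein differential abundance
#'
#' Fits one model per protein on normalized log2 PSM intensities with
#' age-by-genotype cell means and batch as fixed effects and peptide,
#' fraction (within peptide) and sample as random effects where the data
#' support them ("mixed"); proteins with a single peptide/fraction or no
#' repeated measures drop the corresponding terms, down to a plain fixed
#' model ("simple"). A non-converging mixed fit falls back one level with a
#' warning. The requested group contrast is tested without adjustment and
#' BH correction is applied a posteriori across proteins.
#'
#' @param norm output of [size_factor_normalize()] (or its `psm` element).
#' @param meta sample metadata data.frame with `id`, `genotype`, `age`,
#'   `batch`.
#' @param group1,group2 group labels `"<genotype>.<age>"` to contrast
#'   (logFC = group1 - group2).
#' @param min_psms proteins with fewer observations are skipped.
#' @return `protein_diff` data.frame: protein, logFC, se, p, q, model type.
#' @export
protein_diffexp <- function(norm, meta, group1, group2, min_psms = 6) {
  psm <- if (is.list(norm) && !is.data.frame(norm)) norm$psm else norm
  if (is.null(psm$log2_intensity))
    stop("run size_factor_normalize() first")
  m <- meta[match(psm$sample, meta$id), ]
  dat <- data.frame(
    log2_intensity = psm$log2_intensity,
    peptide = factor(psm$peptide),
    fraction = factor(psm$fraction),
    sample = factor(psm$sample),
    batch = factor(m$batch),
    group = factor(paste(m$genotype, m$age, sep = ".")),
    master_protein = psm$master_protein,
    stringsAsFactors = FALSE)
  res <- lapply(split(dat, dat$master_protein), function(d) {
    if (nrow(d) < min_psms) return(NULL)
    d$peptide <- droplevels(d$peptide)
    d$group <- droplevels(d$group)
    if (!all(c(group1, group2) %in% levels(d$group))) return(NULL)
    fit_one_protein(d, c(group1, group2))
  })
  kept <- !vapply(res, is.null, TRUE)
  if (!any(kept)) stop("no protein could be fitted for this contrast")
  fell_back <- vapply(res[kept], function(r)
    isTRUE(attr(r, "fallback")), TRUE)
  if (any(fell_back))
    warning(sum(fell_back), " protein(s) fell back from a mixed fit")
  tab <- data.frame(
    protein = names(res)[kept],
    logFC = vapply(res[kept], `[[`, 0, "estimate"),
    se = vapply(res[kept], `[[`, 0, "se"),
    p = vapply(res[kept], `[[`, 0, "p"),
    model = vapply(res[kept], function(r) attr(r, "model_type"), ""),
    stringsAsFactors = FALSE)
  tab$q <- bh_adjust(tab$p)
  rownames(tab) <- tab$protein
  class(tab) <- c("protein_diff", "data.frame")
  tab
}
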