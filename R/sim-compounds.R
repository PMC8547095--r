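# Synthetic compound universe: a small stand-in for a large bioactivity
# resource, with typed signature spaces (chemistry, transcription,
# cell sensitivity), target annotations, knockdown profiles and planted
# hits so that every screening query has recoverable ground truth.

#' Simulate a multi-space compound universe
#'
#' Builds per-space real-valued signature matrices with coverage masks
#' (not every compound is present in every space), target annotations, a
#' reference-drug list, shRNA-like knockdown profiles, and three kinds of
#' planted hits: compounds chemically/phenotypically near the reference
#' drugs, compounds whose transcriptional vector anticorrelates with the
#' disease signature (reverters), and compounds binding designated disease
#' targets.
#'
#' @param n_compounds universe size (>= 100).
#' @param signature named numeric disease-signature vector over genes
#'   (+1 for up-signature genes, -1 for down-signature genes); defines the
#'   dimensions of the transcriptional space together with `n_extra_genes`
#'   unrelated genes.
#' @param n_planted_reverters,n_planted_similar,n_planted_binders planted
#'   hit counts.
#' @param n_reference_drugs reference drugs (sampled from the universe).
#' @param n_targets size of the target vocabulary.
#' @param n_ad_targets designated disease targets among them.
#' @param chem_dim dimensionality of the chemistry and cell-sensitivity
#'   spaces.
#' @param n_extra_genes non-signature genes added to the transcriptional
#'   space.
#' @param coverage fraction of compounds covered by each optional space.
#' @param n_knockdowns knockdown profiles (3 of them planted as reverting).
#' @param seed RNG seed.
#' @return Object of class `compound_universe`.
#' @export
simulate_compound_universe <- function(n_compounds = 5000,
                                       signature,
                                       n_planted_reverters = 20,
                                       n_planted_similar = 10,
                                       n_planted_binders = 10,
                                       n_reference_drugs = 5,
                                       n_targets = 60,
                                       n_ad_targets = 10,
                                       chem_dim = 64,
                                       n_extra_genes = 100,
                                       coverage = 0.9,
                                       n_knockdowns = 30,
                                       seed = 1) {
  if (n_compounds < 100) stop("need at least 100 compounds")
  n_planted <- n_planted_reverters + n_planted_similar + n_planted_binders
  if (n_planted > n_compounds)
    stop("more planted compounds than the universe holds")
  if (is.null(names(signature))) stop("`signature` must be a named vector")
  with_seed(seed, {
    ids <- sprintf("c%05d", seq_len(n_compounds))
    free <- sample(ids)                 # random disjoint planted slots
    reverters <- free[seq_len(n_planted_reverters)]
    similar <- free[n_planted_reverters + seq_len(n_planted_similar)]
    binders <- free[n_planted_reverters + n_planted_similar +
                      seq_len(n_planted_binders)]
    refs <- sample(setdiff(ids, c(reverters, similar, binders)),
                   n_reference_drugs)

    genes <- c(names(signature),
               sprintf("x%04d", seq_len(n_extra_genes)))
    sig_full <- stats::setNames(c(signature, rep(0, n_extra_genes)), genes)

    rmat <- function(n, d, rn, cn)
      matrix(stats::rnorm(n * d), n, d, dimnames = list(rn, cn))

    chem <- rmat(n_compounds, chem_dim, ids, NULL)
    cellsens <- rmat(n_compounds, chem_dim, ids, NULL)
    for (s in similar) {
      r <- sample(refs, 1)
      chem[s, ] <- chem[r, ] + stats::rnorm(chem_dim, 0, 0.1)
      cellsens[s, ] <- cellsens[r, ] + stats::rnorm(chem_dim, 0, 0.1)
    }

    covered <- sort(sample(ids, round(coverage * n_compounds)))
    covered <- union(covered, c(reverters, refs))
    transc <- rmat(length(covered), length(genes), covered, genes)
    for (s in reverters)
      transc[s, ] <- -sig_full + stats::rnorm(length(genes), 0, 0.3)

    pool <- sprintf("t%03d", seq_len(n_targets))
    ad_targets <- pool[seq_len(n_ad_targets)]
    targets <- lapply(ids, function(i)
      sample(pool, stats::rbinom(1, 3, 0.5)))
    names(targets) <- ids
    for (s in binders)
      targets[[s]] <- unique(c(sample(ad_targets, 2), targets[[s]]))

    # knockdown profiles over the same gene space; their "gene" labels are
    # drawn from the target vocabulary so reverting knockdowns point to
    # actionable targets
    kd_ids <- sprintf("kd%03d", seq_len(n_knockdowns))
    kd_genes <- stats::setNames(sample(pool, n_knockdowns), kd_ids)
    kd <- rmat(n_knockdowns, length(genes), kd_ids, genes)
    kd_revert <- kd_ids[1:3]
    for (k in kd_revert)
      kd[k, ] <- -sig_full + stats::rnorm(length(genes), 0, 0.3)
    # some non-planted compounds bind the reverting-knockdown genes too
    kd_binders <- sample(setdiff(ids, binders), 5)
    for (s in c(binders, kd_binders))
      targets[[s]] <- unique(c(targets[[s]],
                               sample(kd_genes[kd_revert], 1)))

    structure(list(
      compounds = ids,
      spaces = list(chemistry = chem, transcription = transc,
                    cell_sensitivity = cellsens),
      targets = targets,
      ad_targets = ad_targets,
      knockdowns = list(profiles = kd, gene = kd_genes),
      reference_drugs = data.frame(
        id = refs,
        category = sample(c("amyloid", "tau", "inflammation",
                            "neurotransmitter", "cholesterol"),
                          n_reference_drugs, replace = TRUE),
        stringsAsFactors = FALSE),
      signature = sig_full,
      planted = list(reverters = reverters, similar = similar,
                     binders = binders)),
      class = "compound_universe")
  })
}

#' @export
print.compound_universe <- function(x, ...) {
  cat("compound_universe:", length(x$compounds), "compounds,",
      length(x$spaces), "signature spaces,",
      length(x$ad_targets), "disease targets,",
      nrow(x$reference_drugs), "reference drugs\n")
  invisible(x)
}
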