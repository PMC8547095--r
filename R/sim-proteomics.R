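# iTRAQ-like PSM-level proteomics simulator. Reporter channels are the
# samples within a processing batch; intensities are log-normal around a
# per-protein per-sample abundance with peptide, fraction-within-peptide and
# sample offsets, matching the variance components the per-protein models
# assume.

#' Simulate a PSM-level proteomics table
#'
#' Each simulated protein corresponds to a gene of the companion expression
#' study and inherits its mRNA-level genotype/age effects; decoupled
#' proteins instead receive a protein-only genotype-by-age effect (their
#' mRNA is flat) reaching `decoupled_effect` log2 units at the final age.
#' Contaminant, low signal-to-noise and low-intensity rows are injected at
#' configurable rates, and a fraction of peptides is shared between two
#' accessions to exercise master-protein assignment.
#'
#' @param config a [sim_config()].
#' @param truth `sim_truth` from [simulate_expression_study()].
#' @param n_proteins proteins to simulate (all decoupled genes are always
#'   included).
#' @param peptide_sd,fraction_sd,sample_sd,noise_sd log2 SDs of the peptide,
#'   fraction-within-peptide, sample and residual components.
#' @param contaminant_rate,low_sn_rate,low_intensity_rate,quan_unused_rate
#'   row-level corruption rates.
#' @param shared_peptide_rate fraction of peptides listing a second
#'   candidate accession.
#' @param peptides_lambda Poisson mean of extra peptides per protein (each
#'   protein gets `1 + Poisson(peptides_lambda)` peptides).
#' @param max_fractions each peptide spans 1..`max_fractions` fractions.
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return A `data.frame` PSM table with columns `psm_id`, `peptide`,
#'   `proteins` (semicolon-separated candidate accessions), `fraction`,
#'   `batch`, `sample`, `intensity`, `avg_sn`, `contaminant`
#'   ("True"/"False"), `quan_usage` ("Use"/"NotUsed").
#' @export
simulate_proteomics <- function(config, truth, n_proteins = 300,
                                peptide_sd = 0.3, fraction_sd = 0.15,
                                sample_sd = 0.1, noise_sd = 0.2,
                                contaminant_rate = 0.02,
                                low_sn_rate = 0.02,
                                low_intensity_rate = 0.02,
                                quan_unused_rate = 0.01,
                                shared_peptide_rate = 0.05,
                                peptides_lambda = 2,
                                max_fractions = 2,
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(truth, "sim_truth"))
    stop("`truth` from simulate_expression_study() is required")
  if (is.null(seed)) seed <- config$seed + 1
  prm <- truth$params
  genes <- names(truth$classes)
  with_seed(seed, {
    dec <- names(truth$decoupled)
    pool <- setdiff(genes, dec)
    prots <- c(dec, sample(pool, max(0, n_proteins - length(dec))))
    np <- length(prots)

    meta <- expand.grid(rep = seq_len(config$n_per_cell),
                        age = config$ages,
                        genotype = config$genotypes,
                        stringsAsFactors = FALSE)
    meta$batch <- ((meta$rep - 1) %% config$n_batches) + 1
    meta$id <- sprintf("%s_%gm_r%d", meta$genotype, meta$age, meta$rep)
    g_ind <- as.numeric(meta$genotype == config$genotypes[2])
    age_span <- max(config$ages) - min(config$ages)

    # protein x sample log2 abundance
    base <- stats::runif(np, 11.5, 15)
    abund <- matrix(0, np, nrow(meta), dimnames = list(prots, meta$id))
    for (i in seq_len(nrow(meta))) {
      idx <- match(prots, genes)
      eff <- prm$beta_age[idx] * meta$age[i] +
        prm$beta_geno[idx] * g_ind[i] +
        prm$beta3[idx] * meta$age[i] * g_ind[i]
      dsel <- prots %in% dec
      eff[dsel] <- eff[dsel] + truth$decoupled[prots[dsel]] *
        (meta$age[i] - min(config$ages)) / age_span * g_ind[i]
      abund[, i] <- base + eff
    }
    sample_off <- stats::rnorm(nrow(meta), 0, sample_sd)

    rows <- vector("list", np)
    for (k in seq_len(np)) {
      n_pep <- 1 + stats::rpois(1, peptides_lambda)
      pep_off <- stats::rnorm(n_pep, 0, peptide_sd)
      prot_rows <- list()
      for (j in seq_len(n_pep)) {
        pep <- sprintf("%s_pep%d", prots[k], j)
        accs <- prots[k]
        if (stats::runif(1) < shared_peptide_rate && np > 1) {
          other <- sample(prots[-k], 1)
          accs <- paste(sort(c(prots[k], other)), collapse = ";")
        }
        n_frac <- sample.int(max_fractions, 1)
        frac_off <- stats::rnorm(n_frac, 0, fraction_sd)
        for (f in seq_len(n_frac)) {
          # one PSM per batch; channels are the batch's samples
          for (b in unique(meta$batch)) {
            sel <- which(meta$batch == b)
            log2_int <- abund[k, sel] + pep_off[j] + frac_off[f] +
              sample_off[sel] +
              stats::rnorm(length(sel), 0, noise_sd)
            prot_rows[[length(prot_rows) + 1L]] <- data.frame(
              peptide = pep, proteins = accs, fraction = f, batch = b,
              sample = meta$id[sel], intensity = 2^log2_int,
              stringsAsFactors = FALSE)
          }
        }
      }
      rows[[k]] <- do.call(rbind, prot_rows)
    }
    psm <- do.call(rbind, rows)
    n <- nrow(psm)
    psm$psm_id <- sprintf("psm%06d", seq_len(n))
    psm$avg_sn <- stats::rlnorm(n, log(15), 0.5) + 3
    psm$contaminant <- ifelse(stats::runif(n) < contaminant_rate,
                              "True", "False")
    psm$quan_usage <- ifelse(stats::runif(n) < quan_unused_rate,
                             "NotUsed", "Use")
    low_sn <- stats::runif(n) < low_sn_rate
    psm$avg_sn[low_sn] <- stats::runif(sum(low_sn), 0, 3)
    low_int <- stats::runif(n) < low_intensity_rate
    psm$intensity[low_int] <- stats::runif(sum(low_int), 0, 1000)
    rownames(psm) <- NULL
    psm[, c("psm_id", "peptide", "proteins", "fraction", "batch", "sample",
            "intensity", "avg_sn", "contaminant", "quan_usage")]
  })
}
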