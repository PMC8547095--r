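# Synthetic multi-omic study generator. Emulates the blocked two-genotype,
# three-age design with n mice per cell, one replicate per cell per
# processing batch, negative-binomial counts, and planted genotype-by-age
# interaction genes (the future AD-UP / AD-DW signatures).

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state. All simulator randomness flows through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic study generator. Defaults emulate the blocked
#' design of the mouse cohorts the pipeline targets: 2 genotypes x 3 ages x
#' 4 mice per cell, with biological replicates confounded with 4 processing
#' batches, and 5% of genes planted with a positive (and 5% with a negative)
#' genotype-by-age interaction of 0.15 log2 units per month.
#'
#' @param n_genes number of genes.
#' @param genotypes two genotype labels; the first is the wild-type
#'   reference.
#' @param ages ages in months, strictly increasing.
#' @param n_per_cell mice per genotype-by-age cell (>= 2).
#' @param n_batches processing batches; replicate i of every cell is
#'   assigned to batch `((i - 1) %% n_batches) + 1`.
#' @param frac_up_sig,frac_dw_sig fractions of genes with positive /
#'   negative interaction; must sum below 1.
#' @param beta_interaction interaction effect size, log2 units per month in
#'   the mutant.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param batch_sd SD of per-gene log2 batch effects.
#' @param beta_age_sd SD of per-gene common aging slopes (log2/month).
#' @param beta_genotype_sd SD of per-gene constant genotype offsets.
#' @param n_decoupled number of null genes whose protein receives a
#'   protein-only genotype-by-age effect (mRNA stays flat).
#' @param decoupled_effect protein-level log2 fold change reached at the
#'   final age for decoupled proteins.
#' @param seed RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       genotypes = c("wt", "mut"),
                       ages = c(3, 6, 9),
                       n_per_cell = 4,
                       n_batches = 4,
                       frac_up_sig = 0.05,
                       frac_dw_sig = 0.05,
                       beta_interaction = 0.15,
                       dispersion = 0.1,
                       batch_sd = 0.1,
                       beta_age_sd = 0.01,
                       beta_genotype_sd = 0.05,
                       n_decoupled = 40,
                       decoupled_effect = 0.5,
                       seed = 1) {
  if (n_genes < 1 || n_per_cell < 2 || n_batches < 1)
    stop("non-positive or degenerate design dimensions")
  if (length(genotypes) != 2 || anyDuplicated(genotypes))
    stop("exactly two distinct genotype labels are required")
  if (length(ages) < 2 || any(diff(ages) <= 0))
    stop("ages must be strictly increasing with at least two levels")
  if (frac_up_sig < 0 || frac_dw_sig < 0 || frac_up_sig + frac_dw_sig >= 1)
    stop("signature fractions must be in [0,1] and sum below 1")
  if (dispersion < 0) stop("dispersion must be non-negative")
  structure(list(
    n_genes = n_genes, genotypes = genotypes, ages = ages,
    n_per_cell = n_per_cell, n_batches = n_batches,
    frac_up_sig = frac_up_sig, frac_dw_sig = frac_dw_sig,
    beta_interaction = beta_interaction, dispersion = dispersion,
    batch_sd = batch_sd, beta_age_sd = beta_age_sd,
    beta_genotype_sd = beta_genotype_sd,
    n_decoupled = n_decoupled, decoupled_effect = decoupled_effect,
    seed = seed), class = "sim_config")
}

nb_draw <- function(mu, dispersion) {
  if (dispersion > 0) stats::rnbinom(length(mu), mu = mu,
                                     size = 1 / dispersion)
  else stats::rpois(length(mu), mu)
}

#' Simulate an expression study with ground truth
#'
#' Counts are negative binomial with
#' `log2 mean = baseline + batch + b1*age + b2*genotype + b3*age*genotype`,
#' where `b3 = +beta_interaction` for up-signature genes,
#' `-beta_interaction` for down-signature genes and 0 for null genes.
#' Gene lengths are emitted so an RPKM view can be computed with [rpkm()].
#'
#' @param config a [sim_config()].
#' @return List with `study` (an `expression_study` of raw counts) and
#'   `truth` (a `sim_truth`: per-gene class, decoupled-protein effects,
#'   half-life annotation, and the latent per-gene parameters reused by the
#'   treatment and proteomics simulators).
#' @export
simulate_expression_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ng <- config$n_genes
    genes <- sprintf("g%05d", seq_len(ng))
    n_up <- round(config$frac_up_sig * ng)
    n_dw <- round(config$frac_dw_sig * ng)
    cls <- rep("null", ng)
    sig_idx <- sample(ng, n_up + n_dw)
    cls[sig_idx[seq_len(n_up)]] <- "up-signature"
    if (n_dw > 0) cls[sig_idx[n_up + seq_len(n_dw)]] <- "dw-signature"

    baseline <- stats::runif(ng, 3, 8)
    beta_age <- stats::rnorm(ng, 0, config$beta_age_sd)
    beta_geno <- stats::rnorm(ng, 0, config$beta_genotype_sd)
    beta3 <- ifelse(cls == "up-signature", config$beta_interaction,
                    ifelse(cls == "dw-signature", -config$beta_interaction,
                           0))
    batch_eff <- matrix(stats::rnorm(config$n_batches * ng, 0,
                                     config$batch_sd),
                        nrow = config$n_batches,
                        dimnames = list(NULL, genes))
    gene_lengths <- stats::setNames(sample(500:5000, ng, replace = TRUE),
                                    genes)

    meta <- expand.grid(rep = seq_len(config$n_per_cell),
                        age = config$ages,
                        genotype = config$genotypes,
                        stringsAsFactors = FALSE)
    meta$batch <- ((meta$rep - 1) %% config$n_batches) + 1
    meta$id <- sprintf("%s_%gm_r%d", meta$genotype, meta$age, meta$rep)
    meta$treatment <- "none"
    g_ind <- as.numeric(meta$genotype == config$genotypes[2])

    counts <- matrix(0L, nrow(meta), ng,
                     dimnames = list(meta$id, genes))
    for (i in seq_len(nrow(meta))) {
      log2mu <- baseline + batch_eff[meta$batch[i], ] +
        beta_age * meta$age[i] + beta_geno * g_ind[i] +
        beta3 * meta$age[i] * g_ind[i]
      counts[i, ] <- nb_draw(2^log2mu, config$dispersion)
    }

    null_genes <- genes[cls == "null"]
    n_dec <- min(config$n_decoupled, length(null_genes))
    dec_genes <- sample(null_genes, n_dec)
    dec_eff <- stats::setNames(rep(config$decoupled_effect, n_dec),
                               dec_genes)
    # half-lives (hours): decoupled proteins are drawn short-lived so that
    # planted post-transcriptional accumulation is visible in the
    # half-life-stratified summaries
    half_life <- stats::setNames(stats::rlnorm(ng, log(30), 0.4), genes)
    half_life[dec_genes] <- stats::rlnorm(n_dec, log(8), 0.3)

    study <- expression_study(
      counts, meta[, c("id", "genotype", "age", "batch", "treatment")],
      gene_lengths)
    truth <- structure(list(
      classes = stats::setNames(cls, genes),
      decoupled = dec_eff,
      half_life = half_life,
      arms = NULL,
      config = config,
      params = list(baseline = baseline, beta_age = beta_age,
                    beta_geno = beta_geno, beta3 = beta3,
                    gene_lengths = gene_lengths)),
      class = "sim_truth")
    list(study = study, truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", sum(x$classes == "up-signature"), "up /",
      sum(x$classes == "dw-signature"), "dw /",
      sum(x$classes == "null"), "null genes;",
      length(x$decoupled), "decoupled proteins\n")
  invisible(x)
}

#' Simulate a drug-treatment study
#'
#' Generates a single-age study with a wild-type vehicle arm, a mutant
#' vehicle arm, and one mutant arm per drug. For signature genes, the drug
#' arm's log2 mean is moved a fraction `rho` of the way from the mutant mean
#' back to the wild-type mean; null genes are untouched.
#'
#' @param truth `sim_truth` from [simulate_expression_study()].
#' @param arms named numeric vector mapping treatment labels to reversion
#'   strengths `rho` in `[0, 1]`; must contain a `vehicle` entry (its rho is
#'   forced to 0).
#' @param n_per_arm mice per arm.
#' @param seed RNG seed.
#' @param age age in months at treatment (default: final age of the design).
#' @return `expression_study` of raw counts with a `treatment` metadata
#'   column; the arm table is attached as attribute `arms`.
#' @export
simulate_treatment_study <- function(truth, arms, n_per_arm = 4, seed = 1,
                                     age = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(names(arms)) || any(!nzchar(names(arms))))
    stop("`arms` must be a named treatment -> rho vector")
  if (!"vehicle" %in% names(arms))
    stop("drug arms without a matching vehicle arm")
  if (any(arms < 0 | arms > 1)) stop("rho must lie in [0, 1]")
  arms["vehicle"] <- 0
  cfg <- truth$config
  prm <- truth$params
  if (is.null(age)) age <- max(cfg$ages)
  genes <- names(truth$classes)
  is_sig <- truth$classes != "null"

  with_seed(seed, {
    lm_wt <- prm$baseline + prm$beta_age * age
    lm_mut <- lm_wt + prm$beta_geno + prm$beta3 * age
    batch_eff <- matrix(stats::rnorm(n_per_arm * length(genes), 0,
                                     cfg$batch_sd),
                        nrow = n_per_arm, dimnames = list(NULL, genes))
    rows <- list(); metas <- list()
    add_arm <- function(genotype, treatment, log2mu_base) {
      for (r in seq_len(n_per_arm)) {
        id <- sprintf("%s_%s_r%d", genotype, treatment, r)
        mu <- 2^(log2mu_base + batch_eff[r, ])
        rows[[id]] <<- nb_draw(mu, cfg$dispersion)
        metas[[id]] <<- data.frame(id = id, genotype = genotype,
                                   age = age, batch = r,
                                   treatment = treatment,
                                   stringsAsFactors = FALSE)
      }
    }
    add_arm(cfg$genotypes[1], "vehicle", lm_wt)
    for (trt in names(arms)) {
      rho <- arms[[trt]]
      lm_arm <- lm_mut
      lm_arm[is_sig] <- lm_mut[is_sig] +
        rho * (lm_wt[is_sig] - lm_mut[is_sig])
      add_arm(cfg$genotypes[2], trt, lm_arm)
    }
    counts <- do.call(rbind, rows)
    colnames(counts) <- genes
    meta <- do.call(rbind, metas)
    study <- expression_study(counts, meta, prm$gene_lengths)
    attr(study, "arms") <- arms
    study
  })
}
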