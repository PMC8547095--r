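# End-to-end pipeline orchestration: simulate -> differential expression ->
# signatures -> proteomics/decoupling -> reversion (-> screening), with all
# result tables and a reproducible run log written to one directory.

#' Default demo pipeline configuration
#'
#' A small, fast configuration exercising every stage: 800 genes, the
#' standard 2 genotypes x 3 ages x 4 mice design, 60 simulated proteins,
#' two drug arms (one strongly reverting, one inert) and a 500-compound
#' screening universe.
#'
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    sim = list(n_genes = 800, frac_up_sig = 0.05, frac_dw_sig = 0.05,
               beta_interaction = 0.15, n_decoupled = 15),
    signatures = list(k = 40),
    proteomics = list(enabled = TRUE, n_proteins = 60),
    reversion = list(arms = list(vehicle = 0, drug_strong = 0.8,
                                 drug_inert = 0),
                     B = 500, alpha = 0.05),
    screening = list(enabled = TRUE, n_compounds = 500,
                     n_planted_reverters = 10)
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> filter/normalize -> differential expression ->
#' signature derivation -> proteomics quantification and decoupling ->
#' treatment simulation and reversion scoring -> compound screening, and
#' writes every result table plus a `run_log.yaml` capturing the seed and
#' the fully resolved configuration. Any stage failure aborts with the
#' stage name.
#'
#' @param config configuration list (see [default_pipeline_config()]) or
#'   path to a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   vector of files written.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("sigrevert_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) config$seed <- 1
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- simulate ------------------------------------------------------------
  sim <- stage("simulate", {
    cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    simulate_expression_study(cfg)
  })
  files <- c(files, write_expression(sim$study,
                                     file.path(out_dir, "expression.tsv")))
  files <- c(files, write_tsv(
    data.frame(gene = names(sim$truth$classes), class = sim$truth$classes,
               half_life = sim$truth$half_life,
               decoupled = names(sim$truth$classes) %in%
                 names(sim$truth$decoupled)),
    file.path(out_dir, "truth.tsv")))
  cfg <- sim$truth$config

  # -- differential expression --------------------------------------------
  de <- stage("diffexp", {
    norm <- quantile_normalize(log2(rpkm(sim$study)$values + 1))
    norm_study <- expression_study(norm, sim$study$sample_meta)
    final_age <- max(cfg$ages)
    at_final <- subset_samples(norm_study,
                               norm_study$sample_meta$age == final_age)
    diff <- fit_moderated(at_final, ~ genotype + batch,
                          coef = paste0("genotype", cfg$genotypes[2]))
    list(norm_study = norm_study, diff = diff)
  })
  files <- c(files, write_tsv(de$diff$table,
                              file.path(out_dir, "diff_genotype.tsv")))
  files <- c(files, write_rnk(rank_metric(de$diff),
                              file.path(out_dir, "diff_genotype.rnk")))

  # -- signatures ----------------------------------------------------------
  sig <- stage("signatures", {
    ir <- fit_age_interaction(de$norm_study)
    k <- config$signatures$k %||% 250
    list(ir = ir, pair = derive_signatures(ir, k = k))
  })
  files <- c(files, write_tsv(sig$ir$table,
                              file.path(out_dir, "interaction.tsv")))
  files <- c(files, write_gmt(sig$pair,
                              file.path(out_dir, "signatures.gmt")))

  # -- proteomics + decoupling --------------------------------------------
  dec <- NULL
  if (isTRUE(config$proteomics$enabled)) {
    dec <- stage("proteomics", {
      psm <- simulate_proteomics(cfg, sim$truth,
                                 n_proteins =
                                   config$proteomics$n_proteins %||% 200,
                                 seed = config$seed + 1)
      psm <- assign_master_protein(suppressMessages(filter_psms(psm)))
      norm <- size_factor_normalize(psm)
      g2 <- paste(cfg$genotypes[2], max(cfg$ages), sep = ".")
      g1 <- paste(cfg$genotypes[1], max(cfg$ages), sep = ".")
      pd <- protein_diffexp(norm, sim$study$sample_meta, g2, g1)
      pairs <- suppressMessages(
        decoupling_classes(match_features(de$diff, pd)))
      conc <- tryCatch(concordance(pairs), error = function(e) NULL)
      hl <- halflife_summary(pairs, data.frame(
        protein = names(sim$truth$half_life),
        half_life = sim$truth$half_life))
      list(protein_diff = pd, pairs = pairs, concordance = conc,
           half_life = hl, size_factors = norm$size_factors)
    })
    files <- c(files, write_tsv(dec$protein_diff,
                                file.path(out_dir, "protein_diff.tsv")))
    files <- c(files, write_tsv(dec$pairs,
                                file.path(out_dir, "decoupling.tsv")))
  }

  # -- treatment + reversion ----------------------------------------------
  rev <- stage("reversion", {
    arms <- unlist(config$reversion$arms %||%
                     list(vehicle = 0, drug = 0.8))
    trt <- simulate_treatment_study(sim$truth, arms,
                                    n_per_arm = cfg$n_per_cell,
                                    seed = config$seed + 2)
    norm <- quantile_normalize(log2(rpkm(trt)$values + 1))
    nstudy <- expression_study(norm, trt$sample_meta)
    drugs <- setdiff(names(arms), "vehicle")
    res <- lapply(drugs, function(dg) {
      sel <- nstudy$sample_meta$genotype == cfg$genotypes[2] &
        nstudy$sample_meta$treatment %in% c(dg, "vehicle")
      diff <- fit_moderated(subset_samples(nstudy, sel),
                            ~ treatment + batch,
                            coef = paste0("treatment", dg))
      reversion_test(diff, sig$pair, B = config$reversion$B %||% 1000,
                     seed = config$seed + 3,
                     alpha = config$reversion$alpha %||% 0.05,
                     treatment = dg)
    })
    names(res) <- drugs
    res
  })
  rev_summary <- do.call(rbind, lapply(names(rev), function(dg) {
    data.frame(treatment = dg,
               signature = c("UP", "DW"),
               es = c(rev[[dg]]$up$es, rev[[dg]]$dw$es),
               p = c(rev[[dg]]$up$p, rev[[dg]]$dw$p),
               reverted = c(rev[[dg]]$up$reverted,
                            rev[[dg]]$dw$reverted),
               n_leading_edge = c(length(rev[[dg]]$up$leading_edge),
                                  length(rev[[dg]]$dw$leading_edge)))
  }))
  files <- c(files, write_tsv(rev_summary,
                              file.path(out_dir, "reversion_summary.tsv")))
  if (length(rev) >= 2) {
    rt <- reversion_rank_table(rev, "up", top_n = 40)
    if (nrow(rt))
      files <- c(files, write_tsv(
        data.frame(gene = rownames(rt), rt, check.names = FALSE),
        file.path(out_dir, "reversion_rank_up.tsv")))
  }

  # -- screening -----------------------------------------------------------
  scr <- NULL
  if (isTRUE(config$screening$enabled)) {
    scr <- stage("screening", {
      sig_vec <- c(stats::setNames(rep(1, length(sig$pair$up_genes)),
                                   sig$pair$up_genes),
                   stats::setNames(rep(-1, length(sig$pair$dw_genes)),
                                   sig$pair$dw_genes))
      uni <- simulate_compound_universe(
        n_compounds = config$screening$n_compounds %||% 1000,
        signature = sig_vec,
        n_planted_reverters =
          config$screening$n_planted_reverters %||% 10,
        seed = config$seed + 4)
      res <- screen_compounds(uni)
      list(universe = uni, result = res, shortlist = shortlist(res))
    })
    files <- c(files, write_tsv(scr$result,
                                file.path(out_dir, "screen.tsv")))
  }

  # -- run log -------------------------------------------------------------
  log <- list(seed = config$seed,
              package_version = as.character(
                utils::packageVersion("sigrevert")),
              config = config)
  log_path <- file.path(out_dir, "run_log.yaml")
  yaml::write_yaml(log, log_path)
  files <- c(files, log_path)

  invisible(list(sim = sim, diffexp = de, signatures = sig,
                 decoupling = dec, reversion = rev, screening = scr,
                 files = files, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
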