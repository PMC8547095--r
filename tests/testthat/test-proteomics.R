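test_that("PSM filter applies the four rules with strict boundaries", {
  psm <- tiny_psm()
  psm$avg_sn[1] <- 3.0        # exactly 3: removed (strictly larger than)
  psm$intensity[2] <- 1000    # exactly 1000: removed
  psm$intensity[3] <- 1001    # kept
  psm$contaminant[4] <- "True"
  psm$quan_usage[5] <- "NotUsed"
  out <- suppressMessages(filter_psms(psm))
  expect_setequal(out$psm_id, c("p03", "p06", "p07", "p08"))
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts["contaminant"]), 1)
  expect_equal(unname(counts["low_sn"]), 1)
  # subset of input and idempotent
  expect_true(all(out$psm_id %in% psm$psm_id))
  again <- suppressMessages(filter_psms(out))
  expect_equal(again$psm_id, out$psm_id)
  expect_error(filter_psms(psm[, -7]), "missing column")
})

test_that("master proteins maximize total intensity with deterministic
           ties", {
  psm <- tiny_psm()
  # totals: P1 rows 4000+8000+2000+4000 (+shared 1500+3000) = 22500
  #         P2 rows 3000+6000 (+shared) = 13500 -> shared peptide -> P1
  out <- assign_master_protein(psm)
  expect_equal(out$master_protein[out$peptide == "pepD"],
               c("P1", "P1"))
  expect_equal(out$master_protein[out$peptide == "pepC"],
               c("P2", "P2"))
  # exact tie: smaller accession wins, with a warning
  tie <- data.frame(psm_id = c("t1", "t2", "t3"),
                    peptide = c("pep1", "pep2", "pep3"),
                    proteins = c("P1", "P2", "P1;P2"),
                    fraction = 1L, batch = 1L, sample = "s1",
                    intensity = c(500, 500, 800), avg_sn = 10,
                    contaminant = "False", quan_usage = "Use",
                    stringsAsFactors = FALSE)
  expect_warning(tie_out <- assign_master_protein(tie), "tie")
  expect_equal(tie_out$master_protein, c("P1", "P2", "P1"))
})

test_that("size factors follow the median-ratio construction", {
  # sample2 = 2 x sample1 for every protein -> reference = 1.5 x sample1,
  # size factors (2/3, 4/3)
  psm <- tiny_psm()
  psm <- assign_master_protein(psm)
  norm <- size_factor_normalize(psm)
  sf <- setNames(norm$size_factors$sf, norm$size_factors$sample)
  expect_equal(unname(sf[c("s1", "s2")]), c(2 / 3, 4 / 3),
               tolerance = 1e-12)
  # identical samples give unit factors
  psm2 <- tiny_psm()
  psm2$intensity <- rep(c(4000, 4000), 4)
  psm2 <- assign_master_protein(psm2)
  sf2 <- size_factor_normalize(psm2)$size_factors$sf
  expect_equal(sf2, c(1, 1))
  # after normalization the median ratio to the reference is 1
  med <- tapply(norm$psm$norm_intensity,
                list(norm$psm$master_protein, norm$psm$sample), median)
  ref <- rowMeans(med)
  expect_equal(unname(apply(med / ref, 2, median)), c(1, 1),
               tolerance = 1e-12)
  # within-sample protein rank order is unchanged
  before <- tapply(psm$intensity[psm$sample == "s1"],
                   psm$master_protein[psm$sample == "s1"], median)
  after <- tapply(norm$psm$norm_intensity[norm$psm$sample == "s1"],
                  norm$psm$master_protein[norm$psm$sample == "s1"],
                  median)
  expect_equal(order(before), order(after))
})

test_that("single-peptide single-fraction proteins reduce to OLS", {
  cfg <- sim_config(n_genes = 100, n_decoupled = 5, seed = 51)
  sim <- simulate_expression_study(cfg)
  psm <- simulate_proteomics(cfg, sim$truth, n_proteins = 12,
                             peptides_lambda = 0, max_fractions = 1,
                             contaminant_rate = 0, low_sn_rate = 0,
                             low_intensity_rate = 0,
                             quan_unused_rate = 0,
                             shared_peptide_rate = 0, seed = 52)
  psm <- assign_master_protein(psm)
  norm <- size_factor_normalize(psm)
  pd <- suppressWarnings(
    protein_diffexp(norm, sim$study$sample_meta, "mut.9", "wt.9"))
  expect_true(all(pd$model == "simple"))
  # oracle: direct least squares on the same cell-means design
  one <- norm$psm[norm$psm$master_protein == pd$protein[1], ]
  meta <- sim$study$sample_meta[match(one$sample,
                                      sim$study$sample_meta$id), ]
  d <- data.frame(y = one$log2_intensity,
                  group = factor(paste(meta$genotype, meta$age,
                                       sep = ".")),
                  batch = factor(meta$batch))
  f <- lm(y ~ 0 + group + batch, d)
  est <- coef(f)["groupmut.9"] - coef(f)["groupwt.9"]
  expect_equal(pd$logFC[1], unname(est), tolerance = 1e-8)
  # the single-protein fitter gives the same answer directly
  d2 <- data.frame(log2_intensity = one$log2_intensity,
                   peptide = one$peptide, fraction = one$fraction,
                   sample = one$sample, batch = meta$batch,
                   group = paste(meta$genotype, meta$age, sep = "."))
  single <- fit_protein_model(d2, c("mut.9", "wt.9"))
  expect_equal(unname(single["estimate"]), unname(est),
               tolerance = 1e-8)
  expect_equal(attr(single, "model_type"), "simple")
  expect_error(fit_protein_model(d2[, -1], c("mut.9", "wt.9")),
               "missing column")
})

test_that("multi-peptide proteins use mixed models and recover planted
           effects", {
  cfg <- sim_config(n_genes = 150, n_decoupled = 10,
                    decoupled_effect = 0.8, seed = 53)
  sim <- simulate_expression_study(cfg)
  psm <- simulate_proteomics(cfg, sim$truth, n_proteins = 40,
                             peptides_lambda = 2, seed = 54)
  psm <- assign_master_protein(suppressMessages(filter_psms(psm)))
  norm <- size_factor_normalize(psm)
  pd <- suppressWarnings(
    protein_diffexp(norm, sim$study$sample_meta, "mut.9", "wt.9"))
  expect_true(any(pd$model == "mixed"))
  # decoupled proteins carry the planted protein-level logFC at final age
  dec <- intersect(pd$protein, names(sim$truth$decoupled))
  expect_gt(length(dec), 3)
  idx <- match(dec, pd$protein)
  prm <- sim$truth$params
  gidx <- match(dec, names(sim$truth$classes))
  expected <- prm$beta_geno[gidx] + prm$beta3[gidx] * 9 + 0.8
  expect_lt(mean(abs(pd$logFC[idx] - expected)), 0.25)
})

test_that("an all-constant protein yields a zero estimate and p = 1", {
  meta <- data.frame(id = sprintf("s%d", 1:8),
                     genotype = rep(c("wt", "mut"), each = 4),
                     age = 9, batch = rep(1:4, 2))
  psm <- data.frame(psm_id = sprintf("q%d", 1:8),
                    peptide = "pep1", proteins = "P9", fraction = 1L,
                    batch = rep(1:4, 2), sample = meta$id,
                    intensity = 4095, avg_sn = 10,
                    contaminant = "False", quan_usage = "Use",
                    master_protein = "P9",
                    log2_intensity = 12, norm_intensity = 4095)
  pd <- suppressWarnings(
    protein_diffexp(psm, meta, "mut.9", "wt.9", min_psms = 4))
  expect_equal(pd$logFC, 0, tolerance = 1e-10)
  expect_equal(pd$p, 1)
})

test_that("balanced data with no random variance matches the fixed-effects
           answer", {
  meta <- data.frame(id = sprintf("s%d", 1:8),
                     genotype = rep(c("wt", "mut"), each = 4),
                     age = 9, batch = rep(1:4, 2))
  set.seed(8)
  base <- rnorm(8, 12, 0.3) + ifelse(meta$genotype == "mut", 0.5, 0)
  # two peptides with identical offsets (zero between-peptide variance);
  # independent residual noise keeps the likelihood non-degenerate
  y <- rep(base, 2) + rnorm(16, 0, 0.1)
  psm <- data.frame(psm_id = sprintf("r%d", 1:16),
                    peptide = rep(c("pepA", "pepB"), each = 8),
                    proteins = "P1", fraction = 1L,
                    batch = rep(meta$batch, 2),
                    sample = rep(meta$id, 2),
                    intensity = 2^y, avg_sn = 10,
                    contaminant = "False", quan_usage = "Use",
                    master_protein = "P1",
                    norm_intensity = 2^y,
                    log2_intensity = y)
  pd <- suppressWarnings(
    protein_diffexp(psm, meta, "mut.9", "wt.9", min_psms = 4))
  d <- data.frame(y = y,
                  group = factor(rep(paste(meta$genotype, meta$age,
                                           sep = "."), 2)),
                  batch = factor(rep(meta$batch, 2)))
  f <- lm(y ~ 0 + group + batch, d)
  fixed_est <- unname(coef(f)["groupmut.9"] - coef(f)["groupwt.9"])
  expect_equal(pd$logFC, fixed_est, tolerance = 1e-6)
})
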