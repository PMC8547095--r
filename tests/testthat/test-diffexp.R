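test_that("expression filter applies inclusive boundaries", {
  meta <- data.frame(id = sprintf("s%d", 1:10), genotype = "wt",
                     age = 3, batch = 1)
  v <- matrix(1, 10, 4,
              dimnames = list(meta$id, c("at_thr", "zero", "nine_of_ten",
                                         "eight_of_ten")))
  v[, "at_thr"] <- 0.2          # exactly at threshold in all samples
  v[, "zero"] <- 0
  v[, "nine_of_ten"] <- c(rep(0.5, 9), 0.1)   # 9/10 = 0.9 inclusive
  v[, "eight_of_ten"] <- c(rep(0.5, 8), 0.1, 0.1)
  st <- expression_study(v, meta)
  kept <- suppressMessages(filter_expressed(st))$gene_ids
  expect_setequal(kept, c("at_thr", "nine_of_ten"))
  # empty result warns rather than errors
  v2 <- v; v2[] <- 0
  expect_warning(suppressMessages(
    filter_expressed(expression_study(v2, meta))), "no genes")
})

test_that("quantile normalization equalizes samples and is idempotent", {
  m <- rbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  colnames(m) <- c("g1", "g2", "g3")
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), rbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  # identical samples unchanged
  m2 <- rbind(s1 = c(1, 5, 2), s2 = c(1, 5, 2))
  colnames(m2) <- c("g1", "g2", "g3")
  expect_equal(quantile_normalize(m2), m2)
  # column-sorted vectors equal across samples; idempotent
  set.seed(1)
  m3 <- matrix(rnorm(60), 6, 10,
               dimnames = list(sprintf("s%d", 1:6), sprintf("g%d", 1:10)))
  q3 <- quantile_normalize(m3)
  sorted <- apply(q3, 1, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_equal(quantile_normalize(q3), q3)
})

test_that("moderated t matches the direct-formula oracle", {
  st <- tiny_study(n_genes = 20, ages = 3, n_rep = 4, seed = 9,
                   effect = c(2, -1))
  fit <- fit_moderated(st, ~ genotype + batch, coef = "genotypemut")
  orc <- oracle_moderated(st$values, design_df(st),
                          ~ genotype + batch, "genotypemut")
  expect_equal(fit$eb$d0, orc$d0, tolerance = 1e-10)
  expect_equal(fit$eb$s02, orc$s02, tolerance = 1e-10)
  expect_equal(fit$table$t, unname(orc$t), tolerance = 1e-10)
  expect_equal(fit$table$p, unname(orc$p), tolerance = 1e-10)
  expect_equal(fit$table$logFC, unname(orc$logFC), tolerance = 1e-10)
})

test_that("moderated fit agrees with the reference empirical-Bayes
           pipeline", {
  st <- tiny_study(n_genes = 50, ages = 3, n_rep = 4, seed = 10,
                   effect = c(1.5, -1.5, 0.8))
  fit <- fit_moderated(st, ~ genotype + batch, coef = "genotypemut")
  X <- model.matrix(~ genotype + batch, design_df(st))
  lf <- limma::eBayes(limma::lmFit(t(st$values), X))
  expect_equal(fit$table$logFC, unname(lf$coefficients[, "genotypemut"]),
               tolerance = 1e-10)
  expect_equal(fit$table$t, unname(lf$t[, "genotypemut"]),
               tolerance = 1e-8)
  expect_equal(fit$table$p, unname(lf$p.value[, "genotypemut"]),
               tolerance = 1e-8)
})

test_that("moderated t interpolates between ordinary t and z", {
  st <- tiny_study(n_genes = 30, ages = 3, n_rep = 4, seed = 11)
  f0 <- fit_moderated(st, ~ genotype + batch, coef = "genotypemut",
                      d0_override = 0)
  # d0 = 0: ordinary t from per-gene lm
  X <- model.matrix(~ genotype + batch, design_df(st))
  tt <- apply(st$values, 2, function(y) {
    f <- summary(lm(y ~ 0 + X))
    f$coefficients["Xgenotypemut", "t value"]
  })
  expect_equal(f0$table$t, unname(tt), tolerance = 1e-8)
  # d0 = Inf: pooled variance, identical s2_post everywhere
  fInf <- fit_moderated(st, ~ genotype + batch, coef = "genotypemut",
                        d0_override = Inf)
  expect_equal(length(unique(fInf$eb$s2_post)), 1L)
})

test_that("degenerate genes get t = 0, p = 1", {
  st <- tiny_study(n_genes = 5, ages = 3, n_rep = 4, seed = 12)
  st$values[, 1] <- 7   # identical in both groups
  fit <- fit_moderated(st, ~ genotype, coef = "genotypemut")
  expect_equal(fit$table$t[1], 0)
  expect_equal(fit$table$p[1], 1)
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(50)^2
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_warning(q <- bh_adjust(c(0.1, NaN)), "NaN")
  expect_true(is.nan(q[2]))
})

test_that("ranking metric is signed -log10 p with deterministic ties", {
  tab <- data.frame(gene = c("g1", "g2", "g4", "g3"),
                    logFC = c(-2, 0.5, 1, 1),
                    ave_expr = 0, t = 0,
                    p = c(0.01, 0.001, 0.05, 0.05), q = 1)
  diff <- structure(list(table = tab), class = "diff_result")
  rl <- rank_metric(diff)
  m <- setNames(rl$metric, rl$ids)
  expect_equal(unname(m["g1"]), -2)
  expect_equal(unname(m["g2"]), 3)
  # ties ordered by gene id ascending
  expect_equal(rl$ids[2:3], c("g3", "g4"))
  # p = 0 floored, metric finite
  tab$p[1] <- 0
  diff0 <- structure(list(table = tab), class = "diff_result")
  expect_true(all(is.finite(rank_metric(diff0)$metric)))
})

test_that("significant counts follow the strict thresholds", {
  tab <- data.frame(gene = sprintf("g%d", 1:5),
                    logFC = c(0.6, -0.6, 0.9, 0.4, -0.51),
                    ave_expr = 0, t = 0, p = 0.01,
                    q = c(0.01, 0.01, 0.2, 0.01, 0.01))
  diff <- structure(list(table = tab), class = "diff_result")
  expect_equal(count_significant(diff, fdr = 0.05, min_abs_lfc = 0.5),
               c(n_up = 1L, n_down = 2L))
  expect_equal(count_significant(diff, min_abs_lfc = Inf),
               c(n_up = 0L, n_down = 0L))
  empty <- structure(list(table = tab[0, ]), class = "diff_result")
  expect_equal(count_significant(empty), c(n_up = 0L, n_down = 0L))
  expect_lte(sum(count_significant(diff)), nrow(tab))
})

test_that("p-values are calibrated under a global null", {
  cfg <- sim_config(n_genes = 2000, frac_up_sig = 0, frac_dw_sig = 0,
                    beta_age_sd = 0, beta_genotype_sd = 0, batch_sd = 0,
                    seed = 21)
  sim <- simulate_expression_study(cfg)
  norm <- quantile_normalize(log2(rpkm(sim$study)$values + 1))
  fit <- fit_moderated(expression_study(norm, sim$study$sample_meta),
                       ~ genotype + batch, coef = "genotypemut")
  frac <- mean(fit$table$q < 0.05)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lte(frac, 0.05 + 3 * se)
  # raw p uniform
  expect_gt(suppressWarnings(
    ks.test(fit$table$p, "punif")$p.value), 0.01)
})
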