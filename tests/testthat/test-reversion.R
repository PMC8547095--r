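rl_of <- function(metric, ids = sprintf("g%02d", seq_along(metric)))
  ranked_list(ids, metric)

test_that("running ES hits its extremes at the top and bottom", {
  rl <- rl_of(10:1)
  top <- running_es(rl, rl$ids[1:3])
  expect_equal(top$es, 1)
  expect_setequal(top$leading_edge, rl$ids[1:3])
  bottom <- running_es(rl, rl$ids[8:10])
  expect_equal(bottom$es, -1)
  expect_setequal(bottom$leading_edge, rl$ids[8:10])
  expect_error(running_es(rl, "absent"), "intersect")
  expect_error(running_es(rl, rl$ids), "whole universe")
})

test_that("running ES matches the step-by-step oracle on the worked
           example", {
  rl <- rl_of(c(5, 4, 3, 2, 1))
  set <- rl$ids[c(2, 4)]
  es <- running_es(rl, set, weight = 1)
  orc <- oracle_running_es(rl$ids, rl$metric, set, weight = 1)
  expect_equal(es$es, orc$es)
  expect_equal(es$profile, orc$profile)
  # hand arithmetic: profile is (-1/3, 1/3, 0, 1/3, 0), ES = +1/3
  expect_equal(es$profile,
               c(-1/3, 1/3, 0, 1/3, 0), tolerance = 1e-12)
  expect_equal(es$es, 1/3, tolerance = 1e-12)
})

test_that("running ES matches the oracle across random instances and
           stays in [-1, 1]", {
  set.seed(99)
  for (i in 1:60) {
    N <- sample(10:50, 1)
    k <- sample(2:min(10, N - 1), 1)
    metric <- round(rnorm(N, 0, 2), 2)
    rl <- rl_of(metric, sprintf("G%03d", sample.int(999, N)))
    set <- sample(rl$ids, k)
    w <- sample(c(0, 1), 1)
    es <- running_es(rl, set, weight = w)
    orc <- oracle_running_es(rl$ids, rl$metric, set, weight = w)
    expect_equal(es$es, orc$es, tolerance = 1e-12)
    expect_true(abs(es$es) <= 1 + 1e-12)
  }
})

test_that("weight 0 reduces to the classical KS statistic", {
  set.seed(7)
  for (i in 1:100) {
    N <- sample(8:40, 1)
    rl <- rl_of(rnorm(N))
    set <- sample(rl$ids, sample(2:(N - 2), 1))
    expect_equal(running_es(rl, set, weight = 0)$es,
                 oracle_ks_es(rl$ids, set), tolerance = 1e-12)
  }
})

test_that("ES agrees with the reference pre-ranked GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(13)
  metric <- rnorm(200)
  rl <- rl_of(metric, sprintf("G%03d", 1:200))
  set <- sample(rl$ids, 20)
  es <- running_es(rl, set, weight = 1)
  stats <- setNames(rl$metric, rl$ids)
  ref <- fgsea::calcGseaStat(stats, selectedStats = match(set, rl$ids),
                             gseaParam = 1)
  expect_equal(es$es, ref, tolerance = 1e-8)
})

test_that("randomized null reproduces exhaustive enumeration on a tiny
           universe", {
  rl <- rl_of(c(3, 2.5, 1, 0.5, -1, -2))
  combos <- combn(6, 2)
  exact_es <- apply(combos, 2, function(ix)
    oracle_running_es(rl$ids, rl$metric, rl$ids[ix])$es)
  obs <- running_es(rl, rl$ids[c(1, 2)])$es
  exact_p <- (1 + sum(abs(exact_es) >= abs(obs))) / (ncol(combos) + 1)
  # every sampled null ES belongs to the enumerated support
  nul <- randomized_null(rl, 2, B = 3000, seed = 5, observed_es = obs)
  dist_to_support <- vapply(nul$null_es, function(e)
    min(abs(e - exact_es)), 0)
  expect_lt(max(dist_to_support), 1e-12)
  # exact-tail p from the full enumeration equals the oracle computation
  expect_equal(empirical_p(exact_es, obs), exact_p)
  # the sampled tail fraction converges on the enumerated one
  expect_lt(abs(mean(abs(nul$null_es) >= abs(obs)) -
                  mean(abs(exact_es) >= abs(obs))), 0.02)
})

test_that("empirical p uses add-one smoothing and is never zero", {
  expect_equal(empirical_p(c(0.1, 0.2, 0.3), 0.9), 1 / 4)
  expect_equal(empirical_p(c(0.1, 0.2, 0.3), 0), 1)
  expect_gt(empirical_p(rnorm(100), 50), 0)
  rl <- rl_of(rnorm(30, sd = 2))
  nul <- randomized_null(rl, 5, B = 200, seed = 1)
  expect_equal(length(nul$null_es), 200)
  n2 <- randomized_null(rl, 5, B = 200, seed = 1)
  expect_identical(nul$null_es, n2$null_es)
  expect_warning(randomized_null(rl_of(rnorm(20)), 3, B = 50, seed = 1),
                 "coarse")
})

test_that("empirical p is uniform under a random set and metric", {
  set.seed(123)
  ps <- replicate(400, {
    rl <- rl_of(rnorm(60))
    es <- running_es(rl, sample(rl$ids, 8))$es
    nul <- randomized_null(rl, 8, B = 200,
                           seed = sample.int(1e6, 1),
                           observed_es = es)
    nul$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("sign-flipping the metric swaps UP and DW verdicts", {
  set.seed(31)
  cfg <- sim_config(n_genes = 500, frac_up_sig = 0.1, frac_dw_sig = 0.1,
                    beta_interaction = 0.3, dispersion = 0.05, seed = 17)
  sim <- simulate_expression_study(cfg)
  sig <- signature_pair(
    names(sim$truth$classes)[sim$truth$classes == "up-signature"],
    names(sim$truth$classes)[sim$truth$classes == "dw-signature"])
  metric <- rnorm(500)
  names(metric) <- names(sim$truth$classes)
  rl <- ranked_list(names(metric), metric)
  rl_flip <- ranked_list(names(metric), -metric)
  a <- reversion_test(rl, sig, B = 300, seed = 3)
  b <- reversion_test(rl_flip, sig, B = 300, seed = 3)
  expect_equal(a$up$es, -b$up$es, tolerance = 1e-10)
  expect_equal(a$dw$es, -b$dw$es, tolerance = 1e-10)
})

test_that("a strongly reverting arm is detected and the vehicle is not", {
  cfg <- sim_config(n_genes = 1000, frac_up_sig = 0.1, frac_dw_sig = 0.1,
                    beta_interaction = 0.15, seed = 23)
  sim <- simulate_expression_study(cfg)
  norm <- quantile_normalize(log2(rpkm(sim$study)$values + 1))
  ir <- fit_age_interaction(expression_study(norm,
                                             sim$study$sample_meta))
  sig <- derive_signatures(ir, k = 100)
  trt <- simulate_treatment_study(sim$truth,
                                  c(vehicle = 0, strong = 0.8,
                                    inert = 0),
                                  seed = 29)
  tn <- expression_study(quantile_normalize(log2(rpkm(trt)$values + 1)),
                         trt$sample_meta)
  fit_arm <- function(arm) {
    sel <- tn$sample_meta$genotype == "mut" &
      tn$sample_meta$treatment %in% c(arm, "vehicle")
    fit_moderated(subset_samples(tn, sel), ~ treatment + batch,
                  coef = paste0("treatment", arm))
  }
  strong <- reversion_test(fit_arm("strong"), sig, B = 500, seed = 7,
                           treatment = "strong")
  expect_true(strong$up$reverted)
  expect_true(strong$dw$reverted)
  expect_lt(strong$up$es, 0)
  expect_gt(strong$dw$es, 0)
  inert <- reversion_test(fit_arm("inert"), sig, B = 500, seed = 7,
                          treatment = "inert")
  expect_false(inert$up$reverted && inert$dw$reverted)
})

test_that("reversion rank tables aggregate leading edges across
           treatments", {
  rl <- rl_of(c(6, 5, 4, 3, 2, 1), sprintf("g%d", 1:6))
  sig <- signature_pair(c("g5", "g6"), c("g1", "g2"))
  r1 <- reversion_test(rl, sig, B = 100, seed = 1, treatment = "t1")
  r2 <- reversion_test(rl, sig, B = 100, seed = 2, treatment = "t2")
  # single treatment: nothing qualifies at min_treatments = 2
  expect_equal(nrow(reversion_rank_table(list(t1 = r1), "up")), 0)
  # identical treatments: shared leading edge, rank from the bottom
  rt <- reversion_rank_table(list(t1 = r1, t2 = r2), "up")
  expect_true(all(rt[, "t1"] == rt[, "t2"]))
  expect_equal(unname(rt[order(rownames(rt)), "t1"][c("g5", "g6")] -
                        c(2, 1)), c(0, 0),
               ignore_attr = TRUE)
})

test_that("restoration follows the reversion strength", {
  cfg <- sim_config(n_genes = 600, frac_up_sig = 0.1, frac_dw_sig = 0.1,
                    beta_interaction = 0.2, dispersion = 0.05, seed = 41)
  sim <- simulate_expression_study(cfg)
  norm <- quantile_normalize(log2(rpkm(sim$study)$values + 1))
  ir <- fit_age_interaction(expression_study(norm,
                                             sim$study$sample_meta))
  sig <- derive_signatures(ir, k = 60)
  trt <- simulate_treatment_study(sim$truth,
                                  c(vehicle = 0, full = 1, none = 0),
                                  n_per_arm = 4, seed = 43)
  tn <- expression_study(quantile_normalize(log2(rpkm(trt)$values + 1)),
                         trt$sample_meta)
  vs_wt <- function(arm) {
    sel <- (tn$sample_meta$genotype == "wt" &
              tn$sample_meta$treatment == "vehicle") |
      (tn$sample_meta$genotype == "mut" &
         tn$sample_meta$treatment == arm)
    fit_moderated(subset_samples(tn, sel), ~ genotype + batch,
                  coef = "genotypemut")
  }
  veh <- vs_wt("vehicle")
  # rho = 1: drug arm looks wild-type, signature t-scores collapse
  full <- restoration_check(vs_wt("full"), veh, sig)
  expect_lt(mean(abs(full$t_drug)), 1)
  # rho = 0: t-scores track the vehicle contrast
  none <- restoration_check(vs_wt("none"), veh, sig)
  expect_gt(cor(none$t_drug, none$t_vehicle), 0.9)
  expect_gt(mean(full$restored), mean(none$restored))
})
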