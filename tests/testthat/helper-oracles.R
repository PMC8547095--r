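# Independent oracles: deliberately naive step-by-step implementations,
# kept separate from the package's code paths.

# Literal running-sum ES: walk the ranked list one gene at a time.
oracle_running_es <- function(ids, metric, set, weight = 1) {
  N <- length(ids)
  hit <- ids %in% set
  w <- abs(metric[hit])^weight
  if (sum(w) == 0) w <- rep(1, sum(hit))
  w <- w / sum(w)
  miss_step <- 1 / (N - sum(hit))
  running <- numeric(N)
  s <- 0; j <- 0
  for (i in seq_len(N)) {
    if (hit[i]) { j <- j + 1; s <- s + w[j] } else s <- s - miss_step
    running[i] <- s
  }
  mx <- max(0, running); mn <- min(0, running)
  list(es = if (mx >= -mn - 1e-12) mx else mn, profile = running)
}

# Classical unweighted two-sample KS statistic between hit positions and
# miss positions, computed from first principles (signed by the direction
# of maximal deviation).
oracle_ks_es <- function(ids, set) {
  N <- length(ids)
  hit <- ids %in% set
  k <- sum(hit)
  F_hit <- cumsum(hit) / k
  F_miss <- cumsum(!hit) / (N - k)
  d <- F_hit - F_miss
  mx <- max(0, d); mn <- min(0, d)
  if (mx >= -mn - 1e-12) mx else mn
}

# Exact Fisher two-sided p by enumerating the hypergeometric support and
# summing probabilities not exceeding the observed table's.
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up from the published formula: q_i = min_{j >= i} p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Moderated t pipeline evaluated directly: per-gene lm(), limma's
# moment-based prior (fitFDist), closed-form posterior variance.
oracle_moderated <- function(values, design_df, formula, coef) {
  X <- model.matrix(formula, design_df)
  fits <- apply(values, 2, function(y) {
    f <- lm.fit(X, y)
    s2 <- sum(f$residuals^2) / f$df.residual
    c(b = f$coefficients[coef], s2 = s2, df = f$df.residual)
  })
  b <- fits[1, ]; s2 <- fits[2, ]; dfr <- fits[3, 1]
  pr <- limma::fitFDist(s2, df1 = dfr)
  d0 <- pr$df2; s02 <- pr$scale
  s2_post <- if (is.finite(d0)) (d0 * s02 + dfr * s2) / (d0 + dfr)
             else rep(s02, length(s2))
  XtXi <- solve(crossprod(X))
  se_u <- sqrt(XtXi[coef, coef])
  t <- b / (sqrt(s2_post) * se_u)
  list(t = t, p = 2 * pt(-abs(t), dfr + d0), d0 = d0, s02 = s02,
       logFC = b)
}
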