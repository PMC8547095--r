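# Small fixtures built in code, shared across test files.

# A tiny normalized study: 2 genotypes x n ages x n_rep, deterministic
# batch layout, values drawn under a fixed seed.
tiny_study <- function(n_genes = 20, ages = c(3, 9), n_rep = 4,
                       seed = 42, effect = NULL) {
  set.seed(seed)
  meta <- expand.grid(rep = seq_len(n_rep), age = ages,
                      genotype = c("wt", "mut"),
                      stringsAsFactors = FALSE)
  meta$batch <- meta$rep
  meta$id <- sprintf("%s_%g_r%d", meta$genotype, meta$age, meta$rep)
  meta$treatment <- "none"
  genes <- sprintf("g%03d", seq_len(n_genes))
  v <- matrix(rnorm(nrow(meta) * n_genes, 5, 1), nrow(meta), n_genes,
              dimnames = list(meta$id, genes))
  if (!is.null(effect))
    v[meta$genotype == "mut", seq_along(effect)] <-
      v[meta$genotype == "mut", seq_along(effect)] + rep(effect,
                                                         each = sum(meta$genotype == "mut"))
  expression_study(v, meta[, c("id", "genotype", "age", "batch",
                               "treatment")])
}

# Minimal valid PSM table for the filter/normalization unit tests.
tiny_psm <- function() {
  data.frame(
    psm_id = sprintf("p%02d", 1:8),
    peptide = c("pepA", "pepA", "pepB", "pepB", "pepC", "pepC",
                "pepD", "pepD"),
    proteins = c("P1", "P1", "P1", "P1", "P2", "P2", "P1;P2", "P1;P2"),
    fraction = 1L,
    batch = 1L,
    sample = rep(c("s1", "s2"), 4),
    intensity = c(4000, 8000, 2000, 4000, 3000, 6000, 1500, 3000),
    avg_sn = 10,
    contaminant = "False",
    quan_usage = "Use",
    stringsAsFactors = FALSE)
}

# Model frame matching the package's design conventions (wt reference,
# batch as factor), rebuilt here so oracles do not share package code.
design_df <- function(st) {
  df <- st$sample_meta
  gl <- unique(df$genotype)
  df$genotype <- factor(df$genotype, levels = c("wt", setdiff(gl, "wt")))
  df$batch <- factor(df$batch)
  df
}
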