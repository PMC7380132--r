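# Shared fixtures and independent oracles.  Oracles are deliberately naive
# (loops, full enumeration) and never call the code paths they check.

# small deterministic expression matrix, genes x samples
toy_matrix <- function(n_genes = 5L, n_samples = 7L, seed = 11L) {
  withr::with_seed(seed, {
    m <- matrix(round(stats::runif(n_genes * n_samples, 1, 100), 3),
                nrow = n_genes,
                dimnames = list(paste0("G", seq_len(n_genes)),
                                paste0("S", seq_len(n_samples))))
    m
  })
}

write_tsv_matrix <- function(mat, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# full-enumeration two-sided Fisher oracle (point-probability rule)
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ]); c1 <- sum(tab[, 1L])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1L, 1L], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# kappa recomputed from raw label vectors, bypassing the confusion table
kappa_oracle <- function(a, b) {
  labs <- union(a, b)
  p_o <- mean(a == b)
  p_e <- sum(vapply(labs, function(l) mean(a == l) * mean(b == l), 0))
  (p_o - p_e) / (1 - p_e)
}

# naive double-loop Mes classifier: medians over reference, strict threshold
naive_mes_calls <- function(mat, genes, ref_ids) {
  vapply(colnames(mat), function(s) {
    ones <- 0L
    for (g in genes) {
      thr <- stats::median(sort(mat[g, ref_ids]))
      if (mat[g, s] > thr) ones <- ones + 1L
    }
    ones / length(genes)
  }, 0)
}

# small synthetic cohort used by several module tests (kept deliberately
# smaller than the default design to keep the suite fast)
small_cohort <- function(seed = 5L, n_total = 80L) {
  arch <- generate_archetypes(
    gene_universe = default_gene_universe(n_genes = 180L), seed = seed)
  generate_cohort(arch, default_cohort_design(n_total = n_total), seed = seed + 1L)
}
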