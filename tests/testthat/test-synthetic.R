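test_that("archetype generation is deterministic and encodes the fold structure", {
  arch1 <- generate_archetypes(seed = 81L)
  arch2 <- generate_archetypes(seed = 81L)
  expect_identical(arch1$means, arch2$means)   # same seed, bit-identical
  expect_false(identical(arch1$means, generate_archetypes(seed = 82L)$means))
  # fold structure: every Mes-panel gene elevated >= fold in metastatic stroma
  mes <- arch1$signatures$mes15$genes
  ratio <- arch1$means[mes, "metastatic_stroma"] /
    arch1$means[mes, "cancer_epithelium"]
  expect_true(all(ratio >= arch1$folds["mes"]))
  om <- arch1$signatures$omental_stroma$genes
  expect_true(all(arch1$means[om, "metastatic_stroma"] /
                    arch1$means[om, "cancer_epithelium"] >=
                    arch1$folds["omental"]))
  pr <- arch1$signatures$primary_stroma$genes
  expect_true(all(arch1$means[pr, "primary_stroma"] /
                    arch1$means[pr, "cancer_epithelium"] >=
                    arch1$folds["primary"]))
  # null effects make signature-gene archetypes exchangeable (identical here)
  null <- generate_archetypes(fold_mes = 1, fold_omental = 1, fold_primary = 1,
                              class_jitter_sd = 0, seed = 81L)
  expect_true(all(null$means[, "metastatic_stroma"] == null$means[, "immune"]))
  expect_error(generate_archetypes(gene_universe = c("A", "B"), seed = 1L),
               "absent")
})

test_that("cohort mixtures follow fractions, archetypes and noise model", {
  arch <- generate_archetypes(
    gene_universe = default_gene_universe(n_genes = 100L), seed = 83L)
  # degenerate design: one pure-cancer sample, no noise
  des <- default_cohort_design(noise_sigma = 0)
  des$groups <- des$groups[3L, ]   # single metastatic stratum
  des$groups$n <- 2L
  des$groups$a_fib <- 1e-8; des$groups$a_can <- 1e8; des$groups$a_imm <- 1e-8
  coh <- generate_cohort(arch, des, seed = 84L)
  expect_equal(coh$matrix[, 1L], arch$means[, "cancer_epithelium"],
               tolerance = 1e-6, ignore_attr = TRUE)
  # identical fractions + zero noise => identical columns
  expect_equal(unname(coh$matrix[, 1L]), unname(coh$matrix[, 2L]),
               tolerance = 1e-6)
  # truth invariants
  frac <- coh$truth[, c("frac_fibroblast", "frac_cancer", "frac_immune")]
  expect_equal(rowSums(frac), rep(1, nrow(frac)), tolerance = 1e-12,
               ignore_attr = TRUE)
  des0 <- des; des0$groups$n <- 0L
  expect_error(generate_cohort(arch, des0), "zero samples")
})

test_that("cohort generation is deterministic and truth matches the design", {
  coh1 <- small_cohort(seed = 85L)
  coh2 <- small_cohort(seed = 85L)
  expect_identical(coh1$matrix, coh2$matrix)
  expect_identical(coh1$truth, coh2$truth)
  # intended Mes couples metastatic stroma with the fibroblast floor
  tr <- coh1$truth
  expect_identical(tr$intended_mes,
                   tr$stroma_identity == "metastatic_stroma" &
                     tr$frac_fibroblast >= coh1$design$fib_floor)
  # early-stage ov-ov strata carry only primary stroma
  ann <- coh1$annotations
  early <- ann$sample_id[ann$route == "ov-ov" & ann$stage_group == "I-II"]
  expect_true(all(tr$stroma_identity[tr$sample_id %in% early] == "primary_stroma"))
  # annotations carry consistent derived columns
  expect_identical(ann$route, route_label(ann$primary_site, ann$collection_site))
  expect_identical(ann$stage_group, stage_group(ann$stage))
})

test_that("fixture bundles round-trip, are byte-identical per seed, and hash the config", {
  coh <- small_cohort(seed = 86L, n_total = 40L)
  d1 <- file.path(tempfile(), "b1"); d2 <- file.path(tempfile(), "b2")
  write_fixture_bundle(coh, d1)
  expect_error(write_fixture_bundle(coh, d1), "force")
  write_fixture_bundle(coh, d2)
  files <- c("matrix.tsv", "annotations.tsv", "content.tsv", "truth.tsv",
             "signatures.gmt", "manifest.json")
  expect_setequal(list.files(d1), files)
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  # round trip of the matrix
  back <- read_expression(file.path(d1, "matrix.tsv"))
  expect_equal(unname(back[, ]), unname(coh$matrix[, ]))
  # manifest hash changes iff the configuration changes
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  coh_b <- generate_cohort(coh$archetypes,
                           default_cohort_design(n_total = 40L,
                                                 noise_sigma = 0.3),
                           seed = 86L + 1L)
  d3 <- tempfile()
  write_fixture_bundle(coh_b, d3)
  m3 <- jsonlite::read_json(file.path(d3, "manifest.json"))
  expect_false(identical(m1$config_md5, m3$config_md5))
  coh_c <- small_cohort(seed = 86L, n_total = 40L)
  d4 <- tempfile()
  write_fixture_bundle(coh_c, d4)
  expect_identical(jsonlite::read_json(file.path(d4, "manifest.json"))$config_md5,
                   m1$config_md5)
  # annotations re-read cleanly through the validating loader
  ann <- read_annotations(file.path(d1, "annotations.tsv"))
  expect_identical(ann$sample_id, coh$annotations$sample_id)
})

test_that("log-expression of a Mes gene regresses positively on fibroblast fraction", {
  # parameter recovery: within metastatic-stroma samples, 50 replicates
  arch <- generate_archetypes(
    gene_universe = default_gene_universe(n_genes = 80L), seed = 87L)
  gene <- arch$signatures$mes15$genes[1L]
  des <- default_cohort_design(n_total = 100L)
  hits <- vapply(seq_len(50L), function(i) {
    coh <- generate_cohort(arch, des, seed = 870L + i)
    met <- coh$truth$stroma_identity == "metastatic_stroma"
    fit <- stats::lm(log(coh$matrix[gene, met]) ~ coh$truth$frac_fibroblast[met])
    unname(stats::coef(fit)[2L]) > 0
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})

test_that("null effects calibrate the classifier and the stage-group Fisher test", {
  # fold = 1 everywhere: Mes-call rate bounded by the exchangeable
  # all-genes-above-median rate, and stage-group Fisher rejects <= 5%
  arch <- generate_archetypes(
    gene_universe = default_gene_universe(n_genes = 60L),
    fold_mes = 1, fold_omental = 1, fold_primary = 1, seed = 88L)
  des <- default_cohort_design(n_total = 50L)
  sig <- arch$signatures$mes15
  n_cohorts <- 200L
  mes_calls <- 0L; n_samples <- 0L; rejections <- 0L; n_tests <- 0L
  for (i in seq_len(n_cohorts)) {
    coh <- generate_cohort(arch, des, seed = 8800L + i)
    res <- classify_cohort(coh$matrix, sig, "all", coh$annotations)
    mes_calls <- mes_calls + sum(res$calls$is_mes)
    n_samples <- n_samples + nrow(res$calls)
    gt <- subtype_by_group_test(res$calls, coh$annotations, "stage_group")
    if (is.data.frame(gt) && "p" %in% names(gt)) {
      rejections <- rejections + sum(gt$p < 0.05)
      n_tests <- n_tests + nrow(gt)
    }
  }
  k <- length(sig$genes)
  # 99.9% binomial envelope around the exchangeable rate 2^-k
  expect_lte(mes_calls, stats::qbinom(0.999, n_samples, 2^-k))
  expect_lte(rejections / n_tests, 0.05)
})

test_that("increasing the Mes fold strictly increases the Mes z-score in metastatic stroma", {
  des <- default_cohort_design(n_total = 80L)
  means <- vapply(c(2, 5, 10), function(fold) {
    arch <- generate_archetypes(
      gene_universe = default_gene_universe(n_genes = 80L),
      fold_mes = fold, seed = 89L)
    coh <- generate_cohort(arch, des, seed = 890L)
    z <- ztransform(coh$matrix)
    m15 <- mes15_zscore(z, arch$signatures$mes15)
    mean(m15[coh$truth$sample_id[coh$truth$stroma_identity == "metastatic_stroma"]])
  }, 0)
  expect_true(all(diff(means) > 0))
})
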