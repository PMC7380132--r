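#!/usr/bin/env Rscript
# Concordance statistics.  Part 1: Cohen's kappa and per-class accuracy of
# the 15-gene classifier against the original molecular-subtype labels,
# rebuilt from the published confusion counts.  Part 2: the same machinery
# on the simulated cohort (15-gene calls vs the generator's subtype labels),
# plus two-sided Fisher exact tests of Mes-by-stage-group contingency.

library(mesoscore)

pc <- read.table(system.file("extdata", "published_concordance.tsv",
                             package = "mesoscore"),
                 sep = "\t", header = TRUE)
for (ds in unique(pc$dataset)) {
  sub <- pc[pc$dataset == ds, ]
  tab <- confusion_from_counts(sub$n_correct[sub$class == "Mes"],
                               sub$n_total[sub$class == "Mes"],
                               sub$n_correct[sub$class == "non-Mes"],
                               sub$n_total[sub$class == "non-Mes"])
  acc <- per_class_accuracy(tab)
  message(sprintf("%s: kappa = %.3f; Mes accuracy %.0f%%, non-Mes accuracy %.0f%% (n = %d)",
                  ds, cohens_kappa(tab), 100 * acc["Mes"], 100 * acc["non-Mes"],
                  sum(tab)))
}

calls <- read.table("results/mes_calls.tsv", sep = "\t", header = TRUE)
ann <- read_annotations("results/fixtures/annotations.tsv")
called <- setNames(ifelse(calls$is_mes, "Mes", "non-Mes"), calls$sample_id)
orig <- setNames(ifelse(ann$original_subtype == "Mesenchymal",
                        "Mes", "non-Mes"), ann$sample_id)
tab_syn <- cross_tabulate(orig, called)
message(sprintf("synthetic cohort: kappa vs generated subtype labels = %.3f",
                cohens_kappa(tab_syn)))

gt <- subtype_by_group_test(calls, ann, "stage_group")
write.table(gt, "results/stage_group_fisher.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("Mes-by-stage-group Fisher test:")
print(gt)
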