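#!/usr/bin/env Rscript
# Associate the Mes 15-gene z-score with annotated cell-type content.  In
# metastatic-site samples the score should track fibroblast content
# (positive r) and run against cancer-cell content (negative r); in
# early-stage primary-site samples, whose stroma lacks the metastatic
# archetype, the association should be null.

library(mesoscore)

mat <- read_expression("results/fixtures/matrix.tsv")
ann <- read_annotations("results/fixtures/annotations.tsv")
sigs <- read_gmt("results/fixtures/signatures.gmt")
content <- read.table("results/fixtures/content.tsv", sep = "\t", header = TRUE)

z <- ztransform(mat)
m15 <- mes15_zscore(z, sigs$mes15)
pct <- cell_percents(content)
fib <- setNames(pct$fibroblast, pct$sample_id)
can <- setNames(pct$cancer, pct$sample_id)

met <- ann$sample_id[ann$route %in% c("ov-per", "per-ov", "per-per")]
pri <- ann$sample_id[ann$route == "ov-ov" & ann$stage_group == "I-II"]
r_fib <- correlate_score_content(m15[met], fib[met])
r_can <- correlate_score_content(m15[met], can[met])
r_pri <- correlate_score_content(m15[pri], fib[pri])
message(sprintf("metastatic sites: r(mes15, fibroblast%%) = %.3f (p = %.2e, n = %d)",
                r_fib$r, r_fib$p, r_fib$n))
message(sprintf("metastatic sites: r(mes15, cancer%%)     = %.3f (p = %.2e)",
                r_can$r, r_can$p))
message(sprintf("stage I-II ov-ov: r(mes15, fibroblast%%) = %.3f (p = %.2f) -- null expected",
                r_pri$r, r_pri$p))

strat <- stratified_association(m15, fib, ann, "route")
write.table(strat, "results/content_association_by_route.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("association by route:")
print(strat)
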