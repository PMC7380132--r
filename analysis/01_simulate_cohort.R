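#!/usr/bin/env Rscript
# Simulate the default synthetic HGSC cohort (n = 200): bulk expression as
# fibroblast/cancer/immune mixtures in which the stromal archetype depends on
# tumor location, structured by dissemination route and FIGO stage group.
# Writes a plain-text fixture bundle consumed by the downstream scripts.

library(mesoscore)

seed <- 1L
arch <- generate_archetypes(seed = seed)
coh <- generate_cohort(arch, default_cohort_design(), seed = seed + 1L)

out <- "results/fixtures"
write_fixture_bundle(coh, out, force = TRUE)

message(sprintf("cohort: %d genes x %d samples; %d intended Mes samples",
                nrow(coh$matrix), ncol(coh$matrix),
                sum(coh$truth$intended_mes)))
message("strata:")
print(table(route = coh$annotations$route,
            stage = coh$annotations$stage_group))
message("bundle written to ", out)
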