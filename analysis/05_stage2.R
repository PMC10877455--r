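#!/usr/bin/env Rscript
# Stage 5: mask-based effect sizes.
# Binary masks from the surviving stage-1 clusters (strategy 1) define
# regions of interest; per-subject mask means yield Cohen's d (with
# seeded bootstrap CIs) for each exact-k stratum and each criteria
# constellation with >= min_n members, always against the single control
# pool.

source("analysis/_common.R")

cfg <- demo_config()
cache <- readRDS(file.path(SCRATCH, "measure_stacks.rds"))
s1 <- readRDS(file.path(SCRATCH, "stage1.rds"))

masks <- s1$pool$masks
stopifnot(length(masks) > 0)
mm <- mask_means_by_modality(cache$stacks, masks)

eff_k <- effect_table(cache$subjects, mm, "strata", min_n = cfg$min_n,
                      ci = TRUE, n_boot = cfg$n_boot, seed = cfg$seed)
eff_c <- effect_table(cache$subjects, mm, "constellations",
                      min_n = cfg$min_n, ci = TRUE, n_boot = cfg$n_boot,
                      seed = cfg$seed)
write_tsv(eff_k, "effects_strata.tsv")
write_tsv(eff_c, "effects_constellations.tsv")
saveRDS(list(eff_k = eff_k, eff_c = eff_c),
        file.path(SCRATCH, "stage2.rds"))

cat(sprintf("%d masks, %d stratum records, %d constellation records\n",
            length(masks), nrow(eff_k), nrow(eff_c)))
dec <- eff_k[grepl("decrease", eff_k$mask_id), ]
if (nrow(dec)) {
  cat("stratum effect sizes on decrease masks (d by k):\n")
  print(tapply(dec$d, list(dec$k, dec$mask_id), mean), digits = 2)
}
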