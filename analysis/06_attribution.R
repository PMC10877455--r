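#!/usr/bin/env Rscript
# Stage 6: criterion attribution.
# For every mask and criterion: mean Cohen's d over retained
# constellations containing the criterion minus the mean over those
# lacking it; summarised per modality as median [IQR] over masks. In the
# demo cohort only antidepressant use and ICD-10 carry planted functional
# decreases, so they should sit in the negative tail. At this small demo
# scale only a handful of constellations clear min_n, so strongly
# correlated criteria can share a retained-membership pattern and tie
# exactly; the properly sized recovery experiment (see 07 and
# ?recovery_config) separates them.

source("analysis/_common.R")

cfg <- demo_config()
s2 <- readRDS(file.path(SCRATCH, "stage2.rds"))

at <- attribute_criteria(s2$eff_c)
write_tsv(at, "attribution.tsv")

summ <- do.call(rbind, lapply(cfg$modalities, function(m) {
  ids <- grep(paste0("^", m, "\\."), unique(at$mask_id), value = TRUE)
  ok <- at$mask_id %in% ids & !is.na(at$delta_es)
  if (!any(ok)) return(NULL)
  cbind(modality = m, summarize_attribution(at[ok, ], ids))
}))
write_tsv(summ, "attribution_summary.tsv")
print(summ, digits = 2)

func_dec <- at[grepl("^(falff|lcor|gcor)\\..*decrease", at$mask_id) &
                 !is.na(at$delta_es), ]
if (nrow(func_dec)) {
  rank2 <- vapply(split(func_dec, func_dec$mask_id), function(s)
    paste(s$criterion[order(s$delta_es)][1:2], collapse = "+"), "")
  cat("two most negative criteria per functional decrease mask:\n")
  print(rank2)
}
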