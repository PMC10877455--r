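#!/usr/bin/env Rscript
# Stage 2: per-subject measure maps.
# Simulates each subject's 4D functional and 3D structural volumes and
# derives smoothed voxel-wise fALFF, LCOR, GCOR and GMV maps (8-mm FWHM,
# fALFF band 0.008-0.09 Hz). The voxel-by-subject stacks feed every later
# stage; they are cached under scratch/ as a binary intermediate.

source("analysis/_common.R")

cfg <- demo_config()
scfg <- depstrat:::.build_sim_config(cfg)
subjects <- simulate_cohort(scfg)

t0 <- proc.time()
stacks <- simulate_measure_stack(
  scfg, subjects, modalities = cfg$modalities,
  band = band_spec(cfg$band_low, cfg$band_high),
  smooth_fwhm_mm = cfg$smooth_fwhm_mm, lcor_fwhm_mm = cfg$lcor_fwhm_mm)
cat(sprintf("computed %d x %d maps for %d subjects in %.0f s\n",
            length(stacks), nrow(stacks[[1]]), ncol(stacks[[1]]),
            (proc.time() - t0)[3]))
saveRDS(list(stacks = stacks, subjects = subjects),
        file.path(SCRATCH, "measure_stacks.rds"))

summ <- do.call(rbind, lapply(names(stacks), function(m) {
  v <- stacks[[m]]
  data.frame(modality = m, mean = mean(v), sd = sd(v),
             min = min(v), max = max(v))
}))
write_tsv(summ, "measure_summary.tsv")
print(summ, digits = 3)
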