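# Shared setup for the numbered analysis scripts. Each script can be run
# from the repository root after installing the package:
#     Rscript analysis/01_simulate.R
# Intermediate binary objects live under scratch/ (not part of the
# deliverable); tables land under results/.

suppressPackageStartupMessages(library(depstrat))

RESULTS <- "results"
SCRATCH <- "scratch"
dir.create(RESULTS, showWarnings = FALSE)
dir.create(SCRATCH, showWarnings = FALSE)

# The demo study: 24^3 grid at 4 mm, 60 cases / 60 controls, all four
# modalities. A single spherical region carries an in-band functional
# decrease for the antidepressant-use and ICD-10 criteria and weak
# bidirectional structural offsets, mimicking the qualitative pattern the
# analysis is designed to detect (consistent functional decreases, weak
# mixed structural effects).
demo_config <- function(seed = 20260925) {
  run_config(
    seed = seed,
    sim = list(
      shape = c(24, 24, 24), n_timepoints = 120,
      n_cases = 60, n_controls = 60,
      prevalence = c(.5, .4, .35, .3, .25, .25),
      criteria_loading = 0.7,
      effect_regions = list(list(
        center = c(12, 12, 12), radius = 4, baseline_amp = 1,
        func_amp = c(0, 0, -0.25, 0, -0.25, 0),
        struct_amp = c(0, 0.01, -0.02, 0, -0.03, 0.01)))),
    modalities = c("falff", "lcor", "gcor", "gmv"),
    strategies = c("pool", "matched"),
    n_perm = 500, min_n = 5, n_boot = 500)
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("  wrote", path, "\n")
  invisible(path)
}
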