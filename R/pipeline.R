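#' Build a full run configuration
#'
#' One flat, YAML-serialisable list controlling every pipeline stage. All
#' stochastic steps derive their streams from the single `seed`. Defaults
#' follow the analysis design: band 0.008-0.09 Hz, 8 mm smoothing, voxel
#' p < .001 with cluster-level FWE at p < .05, minimum constellation size
#' 10.
#'
#' @param seed Global integer seed (mandatory).
#' @param sim Named list of overrides passed to [sim_config()] (e.g.
#'   `shape`, `voxel_size_mm`, `n_cases`, `prevalence`, `effect_regions` as
#'   plain lists).
#' @param modalities Measures to compute.
#' @param band_low,band_high fALFF band edges in Hz.
#' @param smooth_fwhm_mm Measure-map smoothing FWHM.
#' @param lcor_fwhm_mm LCOR neighbourhood FWHM.
#' @param strategies Control strategies to run in stage 1.
#' @param n_perm,p_voxel,alpha_cluster,connectivity Stage-1 parameters.
#' @param min_n Minimum constellation size in stage 2.
#' @param n_boot Bootstrap resamples for effect-size CIs (0 = none).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed, sim = list(),
                       modalities = c("falff", "lcor", "gcor", "gmv"),
                       band_low = 0.008, band_high = 0.09,
                       smooth_fwhm_mm = 8, lcor_fwhm_mm = 25,
                       strategies = "pool",
                       n_perm = 500, p_voxel = 0.001, alpha_cluster = 0.05,
                       connectivity = 26, min_n = 10, n_boot = 1000) {
  if (missing(seed)) stop("a seed is mandatory")
  structure(list(seed = as.integer(seed), sim = sim,
                 modalities = modalities,
                 band_low = band_low, band_high = band_high,
                 smooth_fwhm_mm = smooth_fwhm_mm, lcor_fwhm_mm = lcor_fwhm_mm,
                 strategies = strategies, n_perm = n_perm, p_voxel = p_voxel,
                 alpha_cluster = alpha_cluster, connectivity = connectivity,
                 min_n = min_n, n_boot = n_boot),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The YAML round trip is lossless for every field the pipeline consumes.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, c(list(seed = x$seed, sim = x$sim),
                        x[setdiff(names(x), c("seed", "sim"))]))
}

# Materialise the sim_config of a run_config. The `sim` overrides use plain
# lists for grid and effect regions so the whole config stays YAML-safe.
.build_sim_config <- function(cfg) {
  sim <- cfg$sim
  shape <- sim$shape %||% c(24, 24, 24)
  grid <- volume_grid(shape, sim$voxel_size_mm %||% 4)
  regions <- if (is.null(sim$effect_regions)) {
    list(effect_region(center = shape / 2, radius = 4))
  } else {
    lapply(sim$effect_regions, function(r)
      effect_region(r$center, r$radius,
                    baseline_amp = r$baseline_amp %||% 1,
                    func_amp = as.numeric(r$func_amp %||% numeric(6)),
                    struct_amp = as.numeric(r$struct_amp %||% numeric(6))))
  }
  args <- sim[setdiff(names(sim), c("shape", "voxel_size_mm", "effect_regions"))]
  if (!is.null(args$prevalence)) args$prevalence <- unlist(args$prevalence)
  do.call(sim_config, c(list(seed = cfg$seed, grid = grid,
                             effect_regions = regions), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a data frame as TSV (the pipeline's tabular interchange format).
.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Execute the full pipeline
#'
#' simulate -> measures -> stratify -> stage 1 -> stage 2 -> attribution,
#' writing all tabular outputs plus a manifest (config, per-file MD5
#' checksums) under `out_dir`. Re-running with the same config reproduces
#' identical TSV outputs and manifest checksums.
#'
#' @param config A [run_config()] (or path to its YAML file).
#' @param out_dir Output directory.
#' @param write_masks Also write significance masks as NIfTI volumes.
#' @return Invisibly, a list with the in-memory stage outputs
#'   (`subjects`, `stage1`, `effects_constellations`, `effects_strata`,
#'   `attribution`, `attribution_summary`, `manifest`).
#' @export
run_all <- function(config, out_dir, write_masks = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- .build_sim_config(config)
  stage <- "simulate"
  out <- list()
  tryCatch({
    subjects <- simulate_cohort(scfg)
    tab <- subjects
    for (cn in paste0("crit_", .criteria)) tab[[cn]] <- as.integer(tab[[cn]])
    files <- .write_tsv(tab, file.path(out_dir, "subjects.tsv"))
    out$subjects <- subjects

    stage <- "measures"
    stacks <- simulate_measure_stack(
      scfg, subjects, modalities = config$modalities,
      band = band_spec(config$band_low, config$band_high),
      smooth_fwhm_mm = config$smooth_fwhm_mm,
      lcor_fwhm_mm = config$lcor_fwhm_mm)

    stage <- "stratify"
    strata <- assign_strata(subjects)
    files <- c(files, .write_tsv(strata, file.path(out_dir, "strata.tsv")))

    stage <- "stage1"
    s1 <- list()
    for (strat in config$strategies) {
      s1[[strat]] <- run_stage1(
        stacks, subjects, scfg$grid, strategy = strat,
        n_perm = config$n_perm, p_voxel = config$p_voxel,
        alpha_cluster = config$alpha_cluster,
        connectivity = config$connectivity, seed = config$seed)
      ct <- do.call(rbind, lapply(names(s1[[strat]]$results), function(key) {
        r <- s1[[strat]]$results[[key]]
        if (is.null(r) || !nrow(r$cluster_table)) return(NULL)
        cbind(contrast = key, r$cluster_table)
      }))
      if (is.null(ct))
        ct <- data.frame(contrast = character(), cluster_id = integer(),
                         size = integer(), max_abs_t = numeric(),
                         peak_index = integer(), p_corrected = numeric())
      files <- c(files, .write_tsv(
        ct, file.path(out_dir, sprintf("stage1_clusters_%s.tsv", strat))))
      if (write_masks) {
        for (key in names(s1[[strat]]$masks)) {
          ni <- RNifti::asNifti(s1[[strat]]$masks[[key]] + 0)
          RNifti::pixdim(ni) <- scfg$grid$voxel_size_mm
          RNifti::writeNifti(ni, file.path(out_dir,
            sprintf("mask_%s_%s.nii.gz", strat, key)))
        }
      }
    }
    out$stage1 <- s1

    stage <- "stage2"
    masks <- s1[["pool"]]$masks %||% s1[[1]]$masks
    if (length(masks)) {
      mm <- mask_means_by_modality(stacks, masks)
      eff_c <- effect_table(subjects, mm, "constellations",
                            min_n = config$min_n, ci = config$n_boot > 0,
                            n_boot = max(config$n_boot, 1), seed = config$seed)
      eff_k <- effect_table(subjects, mm, "strata",
                            min_n = config$min_n, ci = config$n_boot > 0,
                            n_boot = max(config$n_boot, 1), seed = config$seed)
      files <- c(files,
                 .write_tsv(eff_c, file.path(out_dir, "effects_constellations.tsv")),
                 .write_tsv(eff_k, file.path(out_dir, "effects_strata.tsv")))
      out$effects_constellations <- eff_c
      out$effects_strata <- eff_k

      stage <- "attribution"
      attr_tab <- attribute_criteria(eff_c)
      files <- c(files, .write_tsv(attr_tab, file.path(out_dir, "attribution.tsv")))
      summ <- do.call(rbind, lapply(config$modalities, function(m) {
        ids <- grep(paste0("^", m, "\\."), unique(attr_tab$mask_id), value = TRUE)
        ok <- attr_tab$mask_id %in% ids & !is.na(attr_tab$delta_es)
        if (!any(ok)) return(NULL)
        cbind(modality = m, summarize_attribution(attr_tab, ids))
      }))
      if (!is.null(summ))
        files <- c(files, .write_tsv(summ, file.path(out_dir, "attribution_summary.tsv")))
      out$attribution <- attr_tab
      out$attribution_summary <- summ
    } else {
      message("no significant masks; stage 2 and attribution skipped")
    }

    stage <- "manifest"
    cfg_path <- file.path(out_dir, "run_config.yaml")
    write_run_config(config, cfg_path)
    files <- c(files, cfg_path)
    manifest <- list(
      package_version = as.character(utils::packageVersion("depstrat")),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      outputs = as.list(tools::md5sum(sort(unique(files)))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out$manifest <- manifest
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(out)
}

#' Per-subject mask means across modalities
#'
#' Applies each mask to the measure stack of its own modality (mask ids are
#' `<modality>.k<k>.<direction>`).
#'
#' @param stacks Named list of V x N measure matrices.
#' @param masks Named list of logical arrays keyed by mask id.
#' @return N x length(masks) matrix of mask means.
#' @export
mask_means_by_modality <- function(stacks, masks) {
  cols <- lapply(names(masks), function(key) {
    mod <- strsplit(key, ".", fixed = TRUE)[[1]][1]
    if (is.null(stacks[[mod]])) stop("no measure stack for mask ", key)
    colMeans(stacks[[mod]][as.logical(masks[[key]]), , drop = FALSE])
  })
  out <- do.call(cbind, cols)
  colnames(out) <- names(masks)
  out
}
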