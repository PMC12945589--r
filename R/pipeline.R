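# Configuration, provenance and end-to-end orchestration.

config_defaults <- function() {
  list(
    mode = "simulate",
    grid_shape = c(48L, 56L, 48L),
    voxel_size = c(2, 2, 2),
    seed = 1L,
    n_mre_subjects = 20L,
    actuation = "occipital",
    preset = "subacute_chronic",
    n_control = 31L,
    n_mtbi = 31L,
    q_thr = 0.05,
    t_thr = 4,
    bin_width = 0.25,
    min_voxels_per_bin = 10L,
    fa_threshold = 0.7,
    lmax = 8L,
    tau = 0.1,
    lambda = 1,
    run_loo = FALSE,
    zscore_order = "zscore_then_average",
    logging = "info"
  )
}

config_ranges <- list(
  q_thr = c(0, 1), t_thr = c(0, Inf), bin_width = c(1e-6, Inf),
  min_voxels_per_bin = c(1, Inf), fa_threshold = c(0, 1),
  lmax = c(2, 16), tau = c(0, 1), lambda = c(0, Inf),
  n_mre_subjects = c(3, Inf), n_control = c(2, Inf), n_mtbi = c(2, Inf)
)

#' Build and validate a pipeline configuration
#'
#' Starts from documented defaults and overrides with named arguments.
#' Unknown keys are rejected; threshold-type values are checked against their
#' documented ranges.
#'
#' @param ... Named overrides of the default configuration (see
#'   [run_pipeline()] for the meaning of each key).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  if (length(over) && is.null(names(over))) {
    stop("Configuration overrides must be named.", call. = FALSE)
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("Unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  for (k in names(config_ranges)) {
    r <- config_ranges[[k]]
    v <- cfg[[k]]
    if (!is.numeric(v) || any(v < r[1]) || any(v > r[2])) {
      stop("Configuration key '", k, "' out of range [", r[1], ", ", r[2],
           "].", call. = FALSE)
    }
  }
  if (!cfg$mode %in% c("simulate")) {
    stop("Unsupported mode '", cfg$mode, "' (only 'simulate' is built in; ",
         "ingest precomputed maps with read_volume() and call the stage ",
         "functions directly).", call. = FALSE)
  }
  if (!cfg$zscore_order %in% c("zscore_then_average", "average_then_zscore")) {
    stop("zscore_order must be 'zscore_then_average' or ",
         "'average_then_zscore'.", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are configuration overrides.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# order-independent hash of a config (canonicalize by sorting keys)
config_hash <- function(cfg) {
  canon <- cfg[order(names(cfg))]
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(canon, tf)
  unname(tools::md5sum(tf))
}

provenance_record <- function(cfg, stage, inputs = character(0)) {
  list(
    tool = paste0("strainmap ", as.character(utils::packageVersion("strainmap"))),
    stage = stage,
    config_hash = config_hash(unclass(cfg)),
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_hashes = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else list(),
    parameters = unclass(cfg)
  )
}

write_provenance <- function(prov, path) {
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the full strain-vulnerability pipeline
#'
#' Orchestrates, in simulate mode: ground-truth field construction, MRE
#' cohort simulation, OSS computation and within-subject z-scoring, the
#' normative mean map, voxelwise statistics and high/low-strain mask
#' definition (optionally with leave-one-out cross-validation), AFD cohort
#' simulation, OSS binning and the binned AFD table, and the group statistics
#' (mixed model, delta-AFD curve, 2x2 ANOVA, ratio test). Every output
#' carries a provenance record; reruns with the same configuration reproduce
#' all numbers exactly.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for the output tree (created if needed).
#' @param resume If `TRUE`, volumes already present in `output_dir` are not
#'   rewritten (stage results are still recomputed in memory as needed by
#'   downstream stages).
#' @return Invisibly, a list with the in-memory stage results: `spec`,
#'   `mre`, `roi`, `stats_map`, `loo` (or NULL), `afd_cohort`, `table`,
#'   `lme`, `delta`, `anova`, `ratio`, and `manifest` (paths written).
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir,
                         resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  info <- function(...) {
    if (identical(config$logging, "info")) message("[strainmap] ", ...)
  }
  emit <- function(writer, path) {
    path <- file.path(output_dir, path)
    if (!(resume && file.exists(path))) writer(path)
    manifest <<- c(manifest, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("Pipeline stage '", name, "' failed: ", conditionMessage(e),
           "\nPartial outputs: ",
           paste(basename(manifest), collapse = ", "), call. = FALSE)
    })
  }

  info("stage simulate: ground truth + MRE cohort")
  spec <- stage("simulate", {
    grid <- voxel_grid(config$grid_shape, config$voxel_size)
    make_normative_field(grid, seed = config$seed)
  })
  mre <- stage("simulate", {
    simulate_mre_cohort(spec, n_subjects = config$n_mre_subjects,
                        actuation = config$actuation, seed = config$seed,
                        tensors = FALSE)
  })

  info("stage oss: z-scored strain maps")
  zmaps <- stage("oss", {
    lapply(mre$subjects, function(s) zscore_within_subject(s$oss))
  })
  normative <- stage("oss", {
    if (config$zscore_order == "zscore_then_average") {
      normative_mean_map(zmaps)
    } else {
      zscore_within_subject(
        normative_mean_map(lapply(mre$subjects, `[[`, "oss")))
    }
  })
  emit(function(p) write_volume(normative, p), "normative_oss_z.nii.gz")

  info("stage mask: voxelwise statistics and HS/LS partition")
  stats_map <- stage("mask", voxelwise_one_sample_t(zmaps))
  roi <- stage("mask", {
    define_hs_mask(stats_map, spec$mask, q_thr = config$q_thr,
                   t_thr = config$t_thr)
  })
  emit(function(p) write_volume(roi, p), "strain_roi.nii.gz")

  loo <- NULL
  if (isTRUE(config$run_loo)) {
    info("stage loo: leave-one-out cross-validation")
    loo <- stage("loo", {
      loo_cross_validation(zmaps, q_thr = config$q_thr, t_thr = config$t_thr,
                           subject_ids = mre$cohort$subject_id)
    })
    emit(function(p) utils::write.table(loo$folds, p, sep = "\t",
                                        row.names = FALSE, quote = FALSE),
         "loo_folds.tsv")
  }

  info("stage afd: simulated AFD cohort")
  afd <- stage("afd", {
    simulate_afd_cohort(spec, preset = config$preset,
                        n_control = config$n_control,
                        n_mtbi = config$n_mtbi,
                        seed = config$seed + 1L)
  })
  emit(function(p) write_cohort_table(afd$cohort, p), "cohort.tsv")

  info("stage stats: binning and group statistics")
  tab <- stage("stats", {
    bin_afd_cohort(afd, width = config$bin_width,
                   min_voxels = config$min_voxels_per_bin)
  })
  emit(function(p) utils::write.table(tab, p, sep = "\t", row.names = FALSE,
                                      quote = FALSE),
       "binned_afd.tsv")
  lme <- stage("stats", fit_lme(tab))
  delta <- stage("stats", delta_afd_curve(tab))
  rois <- stage("stats", roi_afd_summary(afd, roi))
  anova <- stage("stats", mixed_anova_2x2(rois))
  ratio <- stage("stats", ratio_ttest(rois))
  emit(function(p) {
    jsonlite::write_json(
      list(
        lme = tidy(lme),
        anova = anova,
        ratio = ratio[c("t", "df", "p", "mean_control", "mean_mtbi",
                        "direction")],
        loo = if (!is.null(loo)) {
          list(wilcoxon = loo$wilcoxon,
               folds_hs_greater = sum(loo$folds$hs_mean > loo$folds$ls_mean),
               n_folds = nrow(loo$folds))
        },
        hs_frac_brain = sum(roi$hs) / sum(roi$brain_mask)
      ),
      p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }, "statistics.json")

  prov <- provenance_record(config, stage = "run_pipeline")
  prov$outputs <- basename(manifest)
  write_provenance(prov, file.path(output_dir, "provenance.json"))
  manifest <- c(manifest, file.path(output_dir, "provenance.json"))

  invisible(list(spec = spec, mre = mre, roi = roi, stats_map = stats_map,
                 loo = loo, afd_cohort = afd, table = tab, lme = lme,
                 delta = delta, anova = anova, ratio = ratio,
                 manifest = manifest))
}
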