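#' Assemble a pipeline configuration
#'
#' Bundles the stage specifications and per-stage seeds for an end-to-end
#' run: simulate a cohort, estimate single-trial betas, decode speaker
#' identity (ROI and/or searchlight), run group inference, and summarize
#' behaviour. Every stochastic stage has an explicit seed; the configuration
#' round-trips losslessly through JSON.
#'
#' @param out_dir output directory.
#' @param design a [design_spec()].
#' @param phantom a [phantom_spec()].
#' @param cohort a [cohort_spec()].
#' @param classifier a [classifier_spec()].
#' @param scheme a [cv_scheme()].
#' @param radius_mm searchlight radius (mm).
#' @param searchlight if FALSE, only ROI decoding is run (the informative
#'   ROI union is the ROI), which is much faster.
#' @param n_permutations,alpha,fwhm_mm,chance group-inference parameters.
#' @param seed master seed; stage seeds derive from it deterministically.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, design = design_spec(),
                            phantom = phantom_spec(),
                            cohort = cohort_spec(),
                            classifier = classifier_spec(),
                            scheme = cv_scheme("loro"),
                            radius_mm = 12, searchlight = TRUE,
                            n_permutations = 5000, alpha = 0.05,
                            fwhm_mm = 8, chance = 1 / 3, seed = 1L) {
  structure(list(out_dir = out_dir, design = design, phantom = phantom,
                 cohort = cohort, classifier = classifier, scheme = scheme,
                 radius_mm = radius_mm, searchlight = searchlight,
                 n_permutations = n_permutations, alpha = alpha,
                 fwhm_mm = fwhm_mm, chance = chance,
                 seeds = list(cohort = seed, group = seed + 1L)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> GLM -> decoding -> group inference -> behaviour -> report.
#' The cohort is generated on disk, re-read through the package's own I/O,
#' then analysed exactly as scanner data would be: per-subject single-trial
#' betas, cross-validated decoding restricted to the sound-responsive mask,
#' chance subtraction, smoothing, sign-flip group test, covariate regression
#' of accuracy on behavioural percent correct, and cluster/peak extraction.
#'
#' @param config a [pipeline_config()].
#' @param keep_maps if TRUE the per-subject maps are returned in the report.
#' @return A `pipeline_report` list (also written as JSON to `out_dir`).
#' @export
run_pipeline <- function(config, keep_maps = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out_dir, "rawdata")
  deriv_dir <- file.path(out_dir, "derivatives")
  dir.create(deriv_dir, recursive = TRUE, showWarnings = FALSE)

  prov <- generate_cohort(config$cohort, config$design, config$phantom,
                          data_dir, seed = config$seeds$cohort)
  truth <- prov$truth
  phantom <- config$phantom
  roi_union <- Reduce(`|`, lapply(phantom$informative_rois, `[[`, "mask"))
  sound_mask <- phantom$sound_responsive_mask

  n_sub <- config$cohort$n_subjects
  subj_maps <- vector("list", n_sub)
  roi_acc <- numeric(n_sub)
  pc <- numeric(n_sub)
  missing_rate <- numeric(n_sub)
  confusions <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    sub <- truth$subject[i]
    func_dir <- file.path(data_dir, sub, "func")
    ev_files <- sort(list.files(func_dir, "_events\\.tsv$", full.names = TRUE))
    events <- do.call(rbind, lapply(ev_files, function(f) {
      as.data.frame(read_events(f))
    }))
    events <- structure(events, class = c("event_table", "data.frame"),
                        speakers = config$design$speakers,
                        words = config$design$words,
                        tr = config$design$tr)
    runs <- lapply(sort(list.files(func_dir, "_bold\\.nii", full.names = TRUE)),
                   read_volume)
    check_coregistered(runs)
    betas <- fit_beta_series(runs, events, mask = sound_mask,
                             tr = config$design$tr)
    cv <- roi_accuracy(betas, roi_union, config$scheme, config$classifier)
    roi_acc[i] <- cv$accuracy
    confusions[[i]] <- cv$confusion
    if (config$searchlight) {
      am <- run_searchlight(betas, mask = sound_mask,
                            radius_mm = config$radius_mm,
                            voxel_size_mm = phantom$voxel_size_mm,
                            scheme = config$scheme, spec = config$classifier)
      sm <- gaussian_smooth(subtract_chance(am, config$chance),
                            fwhm_mm = config$fwhm_mm,
                            voxel_size_mm = phantom$voxel_size_mm)
      subj_maps[[i]] <- sm
      map_path <- file.path(deriv_dir,
                            sprintf("%s_accuracy.nii.gz", sub))
      write_volume(replace(unclass(am), is.na(am), 0), map_path,
                   phantom$voxel_size_mm)
      write_sidecar(map_path,
                    list(stage = "searchlight", subject = sub,
                         scheme = config$scheme$kind,
                         radius_mm = config$radius_mm,
                         chance = config$chance, fwhm_mm = config$fwhm_mm,
                         cohort_seed = config$seeds$cohort))
    }
    bs <- percent_correct(events)
    pc[i] <- bs$pc_overall
    missing_rate[i] <- bs$missing_rate
  }

  group <- NULL
  regression <- NULL
  peaks <- NULL
  if (config$searchlight) {
    group <- signflip_onesample(subj_maps,
                                n_permutations = config$n_permutations,
                                seed = config$seeds$group, mask = sound_mask)
    regression <- permutation_regression(subj_maps, pc,
                                         n_permutations = config$n_permutations,
                                         seed = config$seeds$group + 1L,
                                         mask = sound_mask)
    crit <- stats::quantile(group$max_null, 1 - config$alpha, names = FALSE)
    peaks <- cluster_peaks(group, voxel_threshold = crit,
                           min_cluster_mm3 = 20,
                           voxel_size_mm = phantom$voxel_size_mm)
    write_volume(replace(group$stat, is.na(group$stat), 0),
                 file.path(deriv_dir, "group_tstat.nii.gz"),
                 phantom$voxel_size_mm)
    write_volume(replace(group$p_fwe, is.na(group$p_fwe), 1),
                 file.path(deriv_dir, "group_pfwe.nii.gz"),
                 phantom$voxel_size_mm)
    utils::write.table(peaks, file.path(deriv_dir, "group_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    group_prov <- list(stage = "group_inference",
                       n_permutations = config$n_permutations,
                       alpha = config$alpha, seed = config$seeds$group,
                       n_subjects = n_sub)
    write_sidecar(file.path(deriv_dir, "group_tstat.nii.gz"), group_prov)
    write_sidecar(file.path(deriv_dir, "group_pfwe.nii.gz"), group_prov)
    write_sidecar(file.path(deriv_dir, "group_peaks.tsv"),
                  c(group_prov, list(min_peak_separation_mm = 8,
                                     min_cluster_mm3 = 20)))
  }

  mean_confusion <- Reduce(`+`, lapply(confusions, unclass)) / n_sub
  rho_roi <- suppressWarnings(stats::cor(roi_acc, pc, method = "spearman"))
  report <- structure(
    list(n_subjects = n_sub,
         behaviour = list(pc_mean = mean(pc), pc_sd = stats::sd(pc),
                          missing_rate_mean = mean(missing_rate)),
         roi = list(accuracy = roi_acc, accuracy_mean = mean(roi_acc),
                    vs_chance = one_sample_vs_chance(roi_acc, chance = config$chance),
                    spearman_rho_vs_pc = rho_roi),
         mean_confusion = mean_confusion,
         group = if (!is.null(group)) {
           list(min_p_fwe = min(group$p_fwe, na.rm = TRUE),
                n_significant = sum(group$p_fwe <= config$alpha, na.rm = TRUE))
         },
         regression = if (!is.null(regression)) {
           list(min_p_fwe = min(regression$p_fwe, na.rm = TRUE),
                n_significant = sum(regression$p_fwe <= config$alpha,
                                    na.rm = TRUE))
         },
         peaks = peaks,
         truth = truth,
         seeds = config$seeds),
    class = "pipeline_report")
  report_json <- report
  report_json$peaks <- if (!is.null(peaks)) as.data.frame(peaks)
  jsonlite::write_json(
    lapply(report_json, function(x) if (is.matrix(x)) as.data.frame(x) else x),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report:", x$n_subjects, "subjects\n")
  cat("  behaviour: mean PC", round(x$behaviour$pc_mean, 1), "% (sd",
      round(x$behaviour$pc_sd, 1), ")\n")
  cat("  ROI decoding: mean accuracy", round(x$roi$accuracy_mean, 3),
      "; vs chance t =", round(x$roi$vs_chance$t, 2),
      ", p =", format(x$roi$vs_chance$p, digits = 3), "\n")
  cat("  accuracy-PC Spearman rho:", round(x$roi$spearman_rho_vs_pc, 3), "\n")
  if (!is.null(x$group)) {
    cat("  group sign-flip: min FWE p =", format(x$group$min_p_fwe, digits = 3),
        ";", x$group$n_significant, "significant voxels\n")
  }
  invisible(x)
}
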