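# End-to-end orchestration: per-sample quantification (shading correction ->
# baseline subtraction -> reference-channel auto-threshold masking -> masked
# intensity density), in memory or from a cohort manifest on disk, plus
# cohort statistics and artifact output.

#' Pipeline configuration
#'
#' @param referenceChannel,targetChannel,punctaChannel channel roles.
#' @param maskConfig a \code{\link{maskingConfig}}.
#' @param spotParams a \code{\link{spotDetectParams}}.
#' @param baselineTolerance exceedance tolerance for baseline calibration.
#' @param runSpots,runPhase include spot modeling / phase classification
#'   stages when running from a manifest.
#' @param seed global seed recorded in outputs.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(referenceChannel = "reference",
                           targetChannel = "target",
                           punctaChannel = "intron_puncta",
                           maskConfig = maskingConfig(),
                           spotParams = spotDetectParams(),
                           baselineTolerance = 1e-4,
                           runSpots = FALSE, runPhase = TRUE, seed = 0L) {
  structure(list(referenceChannel = referenceChannel,
                 targetChannel = targetChannel,
                 punctaChannel = punctaChannel, maskConfig = maskConfig,
                 spotParams = spotParams,
                 baselineTolerance = baselineTolerance,
                 runSpots = runSpots, runPhase = runPhase,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Quantify one sample: correct, subtract, mask, measure
#'
#' The core per-embryo measurement: shading-correct the reference and target
#' channels, subtract the target baseline cutoff, auto-threshold the
#' corrected reference channel to the configured volume window, and return
#' the masked target intensity density.
#'
#' @param image an \linkS4class{EmbryoImage} (or named list of
#'   \linkS4class{VoxelGrid}s).
#' @param flatfields named list of flat-field \linkS4class{VoxelGrid}s, one
#'   per channel role used.
#' @param targetCutoff a \linkS4class{BaselineCutoff} (or number) for the
#'   target channel.
#' @param config a \code{\link{pipelineConfig}}.
#' @return list with \code{measure} (\code{ExpressionMeasure} row),
#'   \code{mask}, \code{threshold}, and the corrected \code{target} grid.
#' @export
quantifySample <- function(image, flatfields, targetCutoff,
                           config = pipelineConfig()) {
  ch <- if (is(image, "EmbryoImage")) image@channels else image
  sid <- if (is(image, "EmbryoImage")) image@sampleId else "sample"
  ref <- shadingCorrect(ch[[config$referenceChannel]],
                        flatfields[[config$referenceChannel]])
  tgt <- shadingCorrect(ch[[config$targetChannel]],
                        flatfields[[config$targetChannel]])
  tgt <- subtractBaseline(tgt, targetCutoff)
  at <- autoThresholdToVolume(ref, config$maskConfig)
  meas <- maskedIntensityDensity(tgt, at$mask, sampleId = sid,
                                 maskGene = config$referenceChannel)
  list(measure = meas, mask = at$mask, threshold = at$threshold, target = tgt)
}

#' Calibrate the target baseline cutoff from null-embryo phantoms
#'
#' Generates \code{n} probe-null phantoms (target signal zeroed) from a
#' spec, applies shading correction with the supplied flat field, and
#' calibrates the whole-stack exceedance cutoff.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param flatfield target-channel flat field.
#' @param n number of null embryos (default 2).
#' @param baseSeed seed for the null embryos.
#' @param tolerance exceedance tolerance.
#' @return A \linkS4class{BaselineCutoff}.
#' @export
calibrateNullEmbryoCutoff <- function(spec, flatfield, n = 2L,
                                      baseSeed = 990000L, tolerance = 1e-4) {
  grids <- lapply(seq_len(n), function(i) {
    e <- generateEmbryo(nullTargetSpec(spec, seed = baseSeed + i))
    shadingCorrect(getChannel(e$image, "target"), flatfield)
  })
  calibrateBaseline(grids, tolerance = tolerance, channel = "target")
}

#' Quantify a generated cohort in memory
#'
#' Runs \code{\link{quantifySample}} over every sample of a
#' \code{\link{generateCohort}} result, using cohort-wide flat fields
#' (generated once per channel from the spec) and a null-embryo-calibrated
#' target baseline cutoff.
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param spec the \linkS4class{SyntheticSpec} the cohort was generated
#'   from (provides the flat-field and null-embryo models).
#' @param config a \code{\link{pipelineConfig}}.
#' @return data.frame: manifest columns plus \code{intensity_sum,
#'   volume_um3, density}.
#' @export
quantifyCohort <- function(cohort, spec, config = pipelineConfig()) {
  ffs <- list()
  for (chn in c(config$referenceChannel, config$targetChannel)) {
    ffs[[chn]] <- generateFlatfield(spec, chn)
  }
  cut <- calibrateNullEmbryoCutoff(spec, ffs[[config$targetChannel]],
                                   tolerance = config$baselineTolerance)
  rows <- lapply(cohort$samples, function(s) {
    quantifySample(s$image, ffs, cut, config)$measure
  })
  meas <- do.call(rbind, rows)
  cbind(cohort$manifest,
        meas[, c("intensity_sum", "volume_um3", "density")])
}

#' Run the full pipeline from a cohort manifest on disk
#'
#' Reads the manifest CSV (columns \code{sample_id, genotype, phase, seed}
#' plus per-channel \code{path_*} columns), processes every sample
#' (correct -> subtract baseline -> mask -> quantify, optionally spot
#' modeling and phase classification), writes a per-sample results CSV, a
#' cohort JSON with group statistics, and per-sample JSON sidecars, and
#' returns the cohort result. Reruns with identical inputs are
#' byte-identical.
#'
#' @param manifestPath path to the manifest CSV.
#' @param flatfieldPaths named list/vector of flat-field TIFF paths per
#'   channel role.
#' @param targetCutoff a \linkS4class{BaselineCutoff}, a number, or a path
#'   to a cutoff JSON.
#' @param outputDir directory for artifacts.
#' @param config a \code{\link{pipelineConfig}}.
#' @param controlGenotype genotype treated as control in pairwise
#'   comparisons.
#' @return list with \code{results} (per-sample data.frame) and
#'   \code{comparisons} (per-genotype statistics vs control).
#' @export
runPipeline <- function(manifestPath, flatfieldPaths, targetCutoff, outputDir,
                        config = pipelineConfig(),
                        controlGenotype = "control") {
  if (!file.exists(manifestPath)) stop("manifest not found: ", manifestPath)
  man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  if (nrow(man) == 0L) stop("manifest is empty")
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  ffs <- lapply(flatfieldPaths, readStack)
  if (is.character(targetCutoff) && file.exists(targetCutoff)) {
    targetCutoff <- readBaselineCutoff(targetCutoff)
  }
  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sid <- man$sample_id[i]
    chans <- list()
    for (chn in c(config$referenceChannel, config$targetChannel,
                  if (config$runSpots || config$runPhase) config$punctaChannel)) {
      col <- paste0("path_", chn)
      if (!col %in% names(man)) stop("stage read: manifest lacks ", col,
                                     " (sample ", sid, ")")
      chans[[chn]] <- readStack(man[[col]][i])
    }
    res <- tryCatch(
      quantifySample(chans, ffs, targetCutoff, config),
      error = function(e) stop("stage quantify failed for sample ", sid, ": ",
                               conditionMessage(e)))
    row <- cbind(man[i, c("sample_id", "genotype", "phase")],
                 res$measure[, c("intensity_sum", "volume_um3", "density")],
                 mask_threshold = res$threshold)
    sidecar <- list(sample_id = sid, genotype = man$genotype[i],
                    density = res$measure$density,
                    mask_volume_um3 = res$measure$volume_um3,
                    mask_threshold = res$threshold)
    if (config$runPhase) {
      pc <- tryCatch({
        ss <- detectStripes(chans[[config$targetChannel]], res$mask)
        classifyPhase(ss)
      }, error = function(e) stop("stage phase failed for sample ", sid, ": ",
                                  conditionMessage(e)))
      row$phase_call <- phaseLabel(pc)
      sidecar$phase_call <- phaseLabel(pc)
      sidecar$criteria_trace <- pc@criteriaTrace
    }
    if (config$runSpots) {
      sp <- tryCatch(
        binSpots(detectSpots(chans[[config$punctaChannel]],
                             config$spotParams, mask = res$mask)),
        error = function(e) stop("stage spots failed for sample ", sid, ": ",
                                 conditionMessage(e)))
      row$n_spots <- nSpots(sp)
      writeSpots(sp, file.path(outputDir, paste0(sid, "_spots.csv")))
    }
    jsonlite::write_json(sidecar,
                         file.path(outputDir, paste0(sid, ".json")),
                         auto_unbox = TRUE, digits = NA)
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)
  utils::write.csv(results, file.path(outputDir, "results.csv"),
                   row.names = FALSE)
  comparisons <- list()
  ctl <- results$density[results$genotype == controlGenotype]
  for (g in setdiff(unique(results$genotype), controlGenotype)) {
    tst <- results$density[results$genotype == g]
    if (length(tst) >= 2L && length(ctl) >= 2L) {
      comparisons[[g]] <- compareGroups(tst, ctl)
    }
  }
  jsonlite::write_json(list(config = list(seed = config$seed,
                              volume_window_um3 = config$maskConfig$volumeWindow,
                              smoothing_scale_um = config$maskConfig$smoothingScale,
                              baseline_tolerance = config$baselineTolerance),
                            control_genotype = controlGenotype,
                            comparisons = comparisons),
                       file.path(outputDir, "cohort_result.json"),
                       auto_unbox = TRUE, digits = NA)
  list(results = results, comparisons = comparisons)
}
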