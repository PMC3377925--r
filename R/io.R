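# Serialization (plans as JSON, phantoms as NIfTI or raw + sidecar, configs
# as YAML) and the end-to-end experiment runner.

PLAN_SCHEMA <- "twostep-plan-1"

#' Save a treatment plan as JSON
#'
#' Round-trip safe: \code{\link{loadPlan}} reproduces every field, including
#' gaps left by discarded beams and the discard log.
#'
#' @param plan a \code{\link{TreatmentPlan}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
savePlan <- function(plan, path) {
  segs <- lapply(planSegments(plan), function(s) list(
    gantryAngle = s@beam@gantryAngle, isocenter = s@beam@isocenter,
    sad = s@beam@sad, order = s@order, weight = s@weight,
    leafWidth = s@aperture@leafWidth, rowEdges = s@aperture@rowEdges,
    x1 = s@aperture@intervals[, 1L], x2 = s@aperture@intervals[, 2L],
    valid = s@aperture@valid))
  obj <- list(schema = PLAN_SCHEMA, name = plan@name,
              caseName = plan@caseName, arcDeg = plan@arcDeg,
              plannedAngles = plan@plannedAngles,
              discardLog = plan@discardLog, segments = segs)
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              null = "null", na = "null"), path)
  invisible(path)
}

#' Load a treatment plan from JSON
#'
#' @param path file written by \code{\link{savePlan}}.
#' @return a \code{\link{TreatmentPlan}}.
#' @export
loadPlan <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e)
                    stop("cannot parse plan file '", path, "': ",
                         conditionMessage(e)))
  if (is.null(obj$schema) || !identical(obj$schema, PLAN_SCHEMA))
    stop("schema-version mismatch: expected '", PLAN_SCHEMA, "', found '",
         if (is.null(obj$schema)) "<none>" else obj$schema, "'")
  segRows <- obj$segments
  segs <- lapply(seq_len(NROW(segRows)), function(i) {
    s <- if (is.data.frame(segRows)) lapply(segRows, `[[`, i) else segRows[[i]]
    iv <- cbind(x1 = as.numeric(unlist(s$x1)), x2 = as.numeric(unlist(s$x2)))
    ap <- new("Aperture", intervals = iv,
              rowEdges = as.numeric(unlist(s$rowEdges)),
              leafWidth = s$leafWidth, valid = s$valid)
    new("Segment", beam = Beam(s$gantryAngle, as.numeric(unlist(s$isocenter)),
                               s$sad),
        aperture = ap, order = s$order, weight = s$weight)
  })
  log <- as.data.frame(obj$discardLog)
  if (!nrow(log)) log <- data.frame(angle = numeric(), order = character(),
                                    reason = character())
  new("TreatmentPlan", segments = segs, caseName = obj$caseName,
      plannedAngles = as.numeric(obj$plannedAngles), arcDeg = obj$arcDeg,
      name = obj$name, discardLog = log)
}

#' Export structure masks
#'
#' Writes each structure as a NIfTI volume when the RNifti package is
#' available, otherwise as raw uint8 volumes, plus a plain-text YAML sidecar
#' with the grid specification.
#'
#' @param case a \code{\link{CaseGeometry}}.
#' @param dir output directory (created if missing).
#' @return the sidecar path, invisibly.
#' @export
exportStructures <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  useNifti <- requireNamespace("RNifti", quietly = TRUE)
  files <- character()
  for (nm in structureNames(case)) {
    m <- structureMask(case, nm)
    if (useNifti) {
      f <- file.path(dir, paste0(nm, ".nii.gz"))
      img <- RNifti::asNifti(array(as.integer(m), dim = dim(m)),
                             pixdim = case@voxelSize)
      RNifti::writeNifti(img, f)
    } else {
      f <- file.path(dir, paste0(nm, ".bin"))
      writeBin(as.raw(as.integer(m)), f)
    }
    files[nm] <- basename(f)
  }
  sidecar <- file.path(dir, "grid.yaml")
  yaml::write_yaml(list(case = caseName(case),
                        grid_dim = as.integer(gridDim(case)),
                        voxel_mm = as.numeric(voxelSize(case)),
                        format = if (useNifti) "nifti" else "raw-uint8",
                        prescription_gy = as.list(case@prescription),
                        structures = as.list(files)), sidecar)
  invisible(sidecar)
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file with fields \code{case}, \code{recipes} (each with
#'   name/type/n and either \code{pattern} or \code{orders}; exactly one
#'   marked \code{reference: true}), and optional \code{optimizer},
#'   \code{influence} and \code{seed} blocks.
#' @return the validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
  if (is.null(cfg$recipes) || !length(cfg$recipes))
    stop("config must define at least one plan recipe")
  refs <- vapply(cfg$recipes, function(r) isTRUE(r$reference), logical(1))
  if (sum(refs) != 1L)
    stop("exactly one recipe must be marked reference: true")
  cfg
}

#' Run a planning experiment on a synthetic case
#'
#' End-to-end study runner: builds the phantom and objective set, constructs
#' every plan recipe (Fast single-segment or multi-segment reference),
#' optimizes each with the same engine and objectives, and reports a summary
#' table per plan: total MU_eff, field and segment counts, COV normalized to
#' the reference recipe, S_D/n, and modelled delivery times on the old and
#' new machine presets. Deterministic for a fixed seed. A recipe that fails
#' is logged and skipped; the others proceed.
#'
#' @param config configuration list (see \code{\link{readRunConfig}}) or
#'   path to a YAML file.
#' @param outDir optional output directory: writes summary.csv, per-plan
#'   JSON plans and the structure export.
#' @return list with \code{summary} (data.frame), \code{plans},
#'   \code{reports}, \code{case}, \code{objectives} and \code{errors}.
#' @export
runExperiment <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- validateRunConfig(config)
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  set.seed(seed)

  cs <- config$case
  case <- makePhantom(preset = if (is.null(cs$preset)) "quasimodo" else cs$preset,
                      gridDim = if (is.null(cs$gridDim)) c(256L, 256L, 16L)
                                else as.integer(cs$gridDim),
                      voxel = if (is.null(cs$voxel)) 2 else cs$voxel,
                      params = if (is.null(cs$params)) list() else cs$params)
  objectives <- makeObjectiveTemplate(case,
    preset = if (is.null(config$objective_preset)) "auto"
             else config$objective_preset)
  calib <- calibrate()
  mlc <- mlcPreset(if (is.null(config$mlc)) "s4" else config$mlc)
  sparams <- do.call(segmentationParams,
                     if (is.null(config$segmentation)) list()
                     else config$segmentation)
  optCfg <- do.call(optimizerConfig,
                    c(if (is.null(config$optimizer)) list()
                      else config$optimizer, list(seed = seed)))
  infl <- config$influence
  resolution <- if (is.null(infl$resolution)) 2 else infl$resolution

  plans <- list(); errors <- list()
  for (r in config$recipes) {
    res <- tryCatch({
      if (identical(r$type, "multiseg"))
        buildMultisegmentPlan(case, n = r$n,
          arcDeg = if (is.null(r$arc)) 360 else r$arc,
          orders = if (is.null(r$orders)) c("S0", "S1", "S2") else r$orders,
          bothSides = isTRUE(r$bothSides), params = sparams, mlc = mlc,
          resolution = resolution,
          startDeg = if (is.null(r$start)) 0 else r$start, name = r$name)
      else
        buildFastPlan(case, n = r$n,
          arcDeg = if (is.null(r$arc)) 360 else r$arc,
          pattern = if (is.null(r$pattern)) c("S1", "S2") else r$pattern,
          params = sparams, mlc = mlc, resolution = resolution,
          startDeg = if (is.null(r$start)) 0 else r$start, name = r$name)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[r$name]] <- conditionMessage(res)
      warning("recipe '", r$name, "' failed: ", conditionMessage(res))
    } else plans[[r$name]] <- res
  }
  if (!length(plans)) stop("every recipe failed")

  influence <- buildInfluence(case, plans, calib, resolution = resolution,
    scoringStructures = infl$scoringStructures,
    bodySubsample = if (is.null(infl$bodySubsample)) 1L
                    else infl$bodySubsample,
    maxVoxelsPerStructure = if (is.null(infl$maxVoxelsPerStructure)) Inf
                            else infl$maxVoxelsPerStructure,
    padMM = if (is.null(infl$padMM)) 12 else infl$padMM)

  results <- list()
  for (nm in names(plans)) {
    res <- tryCatch(
      fineTunePlan(plans[[nm]], influence, objectives, case, optCfg),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
      warning("optimization of '", nm, "' failed: ", conditionMessage(res))
      plans[[nm]] <- NULL
    } else results[[nm]] <- res
  }
  if (!length(results)) stop("every recipe failed during optimization")

  refIdx <- which(vapply(config$recipes, function(r)
    isTRUE(r$reference) && !is.null(results[[r$name]]), logical(1)))
  if (!length(refIdx)) stop("the reference recipe failed; cannot normalize")
  refName <- config$recipes[[refIdx[1L]]]$name
  doses <- lapply(results, function(r)
    as.numeric(r$segDose %*% planWeights(r$plan)))
  # normalization uses the reported (DVH-statistic) COV of the reference
  refCov <- compositeObjectiveValue(doses[[refName]], case, objectives,
                                    influence@voxelIndex)

  reports <- list(); stats <- list()
  for (nm in names(results)) {
    reports[[nm]] <- qualityReport(doses[[nm]], case, objectives,
                                   referenceCov = refCov,
                                   voxelIndex = influence@voxelIndex)
    stats[[nm]] <- planDeliveryStats(results[[nm]]$plan)
  }
  tt <- timeReport(stats, reference = refName)
  summary <- data.frame(
    plan = names(results),
    mu_eff = round(vapply(stats, `[[`, numeric(1), "mu")),
    fields = vapply(stats, `[[`, numeric(1), "n"),
    segments = vapply(stats, `[[`, numeric(1), "N"),
    norm_cov = round(vapply(reports, `[[`, numeric(1), "normalized_cov"), 2),
    s_d_per_n = round(vapply(reports, `[[`, numeric(1), "s_d_per_n"), 1),
    T_old_min = tt$T_old, T_new_min = tt$T_new,
    row.names = NULL)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(outDir, "summary.csv"),
                     row.names = FALSE)
    for (nm in names(results))
      savePlan(results[[nm]]$plan, file.path(outDir, paste0(nm, ".plan.json")))
    exportStructures(case, file.path(outDir, "structures"))
    utils::write.csv(
      data.frame(plan = rep(names(results),
                            vapply(results, function(r) length(r$trace),
                                   integer(1))),
                 iteration = unlist(lapply(results, function(r)
                   seq_along(r$trace) - 1L)),
                 cov = unlist(lapply(results, `[[`, "trace"))),
      file.path(outDir, "cov_trace.csv"), row.names = FALSE)
  }
  list(summary = summary, plans = lapply(results, `[[`, "plan"),
       reports = reports, results = results, case = case,
       objectives = objectives, influence = influence, errors = errors)
}
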