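## Orchestration and I/O.
##
## The ingestion boundary is a documented columnar interchange format
## (proprietary acquisition files are converted outside this package):
##   sweep file   — whitespace/CSV text, columns time_s, current_pA
##   manifest.csv — sweep_id (file name), stimulus_value, onset, offset,
##                  plus recording metadata columns
##   domes.csv    — pressure_mmHg, r_um, sigma_r, rel_sd, qc_keep
##   peaks.csv    — sweep, stimulus, Ip (peak-level interchange)
##   meta.json    — seal_GOhm, leak_pA, holding_mV (or whole-cell fields)
## Every run writes its resolved configuration next to its outputs and a
## structured exclusion log naming each excluded patch/sweep/image and
## the rule that excluded it.

#' Read a columnar sweep file
#'
#' @param path text file with columns \code{time_s}, \code{current_pA}
#'   (header optional; whitespace or comma separated).
#' @param stimulusValue,stimulusType,onset,offset sweep metadata from the
#'   manifest.
#' @return A \linkS4class{SweepTrace}.
#' @export
readSweepFile <- function(path, stimulusValue, stimulusType,
                          onset, offset) {
  if (!file.exists(path)) stopf("sweep file not found: %s", path)
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("[A-Za-z]", first)
  sep <- if (grepl(",", first)) "," else ""
  d <- utils::read.table(path, header = hasHeader, sep = sep)
  if (ncol(d) < 2L) stopf("sweep file %s needs 2 columns", path)
  SweepTrace(d[[1]], d[[2]], stimulusValue, stimulusType, onset, offset)
}

#' Read a grayscale TIFF micrograph as a matrix
#'
#' @param path single-frame 8/16-bit grayscale TIFF.
#' @return numeric matrix (rows x cols), values as stored (not
#'   rescaled to [0, 1]).
#' @export
readDomeTiff <- function(path) {
  if (!file.exists(path)) stopf("image not found: %s", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Write a matrix as a grayscale TIFF
#'
#' @param image numeric matrix; rescaled to [0, 1] for storage.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDomeTiff <- function(image, path) {
  rng <- range(image)
  scl <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  tiff::writeTIFF(scl, path, bits.per.sample = 16L)
  invisible(path)
}

#' Load one patch directory
#'
#' A patch directory holds \code{meta.json}, \code{domes.csv} (optional)
#' and either \code{manifest.csv} plus the sweep files it names, or
#' \code{peaks.csv}.
#'
#' @param dir patch directory.
#' @param stimulusType stimulus type of the sweeps.
#' @return A \linkS4class{PatchRecord}.
#' @export
readPatchDir <- function(dir, stimulusType = "pressure") {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath)) stopf("missing %s", metaPath)
  meta <- jsonlite::fromJSON(metaPath)
  domes <- data.frame()
  dp <- file.path(dir, "domes.csv")
  if (file.exists(dp)) domes <- utils::read.csv(dp)
  mf <- file.path(dir, "manifest.csv")
  pf <- file.path(dir, "peaks.csv")
  sweeps <- list(); peaks <- data.frame()
  if (file.exists(mf)) {
    man <- utils::read.csv(mf)
    need <- c("sweep_id", "stimulus_value", "onset", "offset")
    miss <- setdiff(need, names(man))
    if (length(miss))
      stopf("manifest %s lacks column(s): %s", mf,
            paste(miss, collapse = ", "))
    sweeps <- lapply(seq_len(nrow(man)), function(i) {
      row <- man[i, ]
      if (any(is.na(row[need])))
        stopf("manifest %s row %d has missing values", mf, i)
      readSweepFile(file.path(dir, row$sweep_id), row$stimulus_value,
                    stimulusType, row$onset, row$offset)
    })
  } else if (file.exists(pf)) {
    peaks <- utils::read.csv(pf)
  } else {
    stopf("patch dir %s has neither manifest.csv nor peaks.csv", dir)
  }
  p <- PatchRecord(basename(dir), sweeps, domes = domes,
                   metadata = as.list(meta),
                   construct = if (!is.null(meta$construct))
                     meta$construct else NA_character_)
  p@peaks <- peaks
  p
}

#' Write a synthetic stretch patch as a patch directory
#'
#' @param res one element of \code{\link{genStretchCohort}}'s output.
#' @param dir target directory (created).
#' @return \code{dir}, invisibly.
#' @export
writeStretchPatch <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pk <- res$patch@peaks
  if (!nrow(pk))
    pk <- data.frame(sweep = seq_len(nrow(res$peaks)),
                     stimulus = res$peaks$pressure_mmHg,
                     Ip = res$peaks$Ip)
  utils::write.csv(pk, file.path(dir, "peaks.csv"), row.names = FALSE)
  utils::write.csv(res$patch@domes, file.path(dir, "domes.csv"),
                   row.names = FALSE)
  meta <- res$patch@metadata
  meta$construct <- res$patch@construct
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(truthToJSON(res$truth), file.path(dir, "truth.json"))
  invisible(dir)
}

#' Run the pipeline
#'
#' Modes: \code{"simulate"} generates a synthetic stretch cohort and
#' writes one patch directory per patch; \code{"analyze-stretch"} loads
#' patch directories, runs per-patch tension-response fits with all QC
#' and exclusion rules, the binned cohort curve, tuning curve and
#' thermodynamics, and writes result CSVs; \code{"report"} summarises a
#' per-patch table by construct. Every run writes its resolved config
#' and an exclusion log next to its outputs; identical config and seed
#' give byte-identical result CSVs.
#'
#' @param config named list (or path to a JSON/YAML file):
#'   \code{mode}, \code{out} (output directory), \code{seed}; simulate
#'   adds any \code{\link{stretchCohortSpec}} argument; analyze-stretch
#'   adds \code{input} (directory of patch directories).
#' @return Invisibly, a list of result tables (mode-dependent).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(config$mode) || is.null(config$out))
    stopf("config must name 'mode' and 'out'")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(config$out, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  res <- switch(config$mode,
    "simulate" = pipelineSimulate(config),
    "analyze-stretch" = pipelineAnalyzeStretch(config),
    "report" = pipelineReport(config),
    stopf("unknown mode '%s'", config$mode))
  invisible(res)
}

#' Read a run configuration file
#' @param path JSON (or YAML, if the yaml package is installed) file.
#' @return Named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("YAML config requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path)
}

pipelineSimulate <- function(config) {
  specArgs <- config[intersect(names(config),
                               names(formals(stretchCohortSpec)))]
  if (!is.null(config$seed)) specArgs$seed <- config$seed
  spec <- do.call(stretchCohortSpec, specArgs)
  cohort <- genStretchCohort(spec)
  for (i in seq_along(cohort))
    writeStretchPatch(cohort[[i]],
                      file.path(config$out, sprintf("patch-%03d", i)))
  invisible(cohort)
}

pipelineAnalyzeStretch <- function(config) {
  if (is.null(config$input)) stopf("analyze-stretch needs 'input'")
  dirs <- list.dirs(config$input, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "meta.json"))]
  if (!length(dirs)) stopf("no patch directories under %s", config$input)
  exclusions <- list()
  perPatch <- list(); pointsList <- list()
  for (d in dirs) {
    patch <- readPatchDir(d)
    res <- tryCatch(patchTensionResponse(patch), error = function(e) e)
    if (inherits(res, "error")) {
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(unit = "patch", id = patch@patchId,
                   rule = conditionMessage(res))
      next
    }
    rd <- res$points[res$points$rundown, , drop = FALSE]
    if (nrow(rd))
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(unit = "sweep",
                   id = paste0(patch@patchId, "/sweep-", rd$sweep),
                   rule = "rundown: peak < 70% of running maximum")
    perPatch[[length(perPatch) + 1L]] <- data.frame(
      patch_id = patch@patchId, construct = patch@construct,
      T50 = halfMax(res$fit), k = slopeK(res$fit),
      A = plateau(res$fit),
      P50 = halfMax(res$pressureFit), A_pA = plateau(res$pressureFit),
      n_points = res$fit@nPoints,
      low_confidence = res$fit@lowConfidence,
      deltaG_kBT = gibbsEnergy(halfMax(res$fit), slopeK(res$fit)),
      deltaA_nm2 = areaExpansion(slopeK(res$fit)))
    if (!res$fit@lowConfidence)
      pointsList[[length(pointsList) + 1L]] <-
        res$points[res$points$included, c("tension", "I_norm")]
  }
  if (!length(perPatch)) stopf("no patch qualified for analysis")
  patchTab <- do.call(rbind, perPatch)
  cohort <- if (length(pointsList) >= 3L)
    cohortTensionCurve(pointsList) else NULL
  excl <- if (length(exclusions)) do.call(rbind, exclusions)
          else data.frame(unit = character(), id = character(),
                          rule = character())
  utils::write.csv(patchTab, file.path(config$out, "patches.csv"),
                   row.names = FALSE)
  utils::write.csv(excl, file.path(config$out, "exclusions.csv"),
                   row.names = FALSE)
  if (!is.null(cohort)) {
    utils::write.csv(cohort$bins, file.path(config$out, "cohort_bins.csv"),
                     row.names = FALSE)
    tc <- tuningCurve(cohort$fit)
    jsonlite::write_json(
      list(A = plateau(cohort$fit), k = slopeK(cohort$fit),
           T50 = halfMax(cohort$fit),
           tuning_peak_height = tc$peakHeight,
           tuning_peak_location = tc$peakLocation),
      file.path(config$out, "cohort_fit.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(list(patches = patchTab, cohort = cohort, exclusions = excl))
}

pipelineReport <- function(config) {
  if (is.null(config$input)) stopf("report needs 'input' (patches.csv)")
  tab <- utils::read.csv(config$input)
  summ <- summarizeGroups(tab, "construct")
  utils::write.csv(summ, file.path(config$out, "summary.csv"),
                   row.names = FALSE)
  invisible(summ)
}

#' Group-wise mean, SEM and n
#'
#' Summarises every numeric column of a per-patch table by group:
#' mean, SEM (SD/sqrt(n)) and n. Groups of one report an absent (NA)
#' SEM; empty groups are omitted with a warning. No significance testing
#' is performed here — the output shape is consumable by any standard
#' statistics tool.
#'
#' @param table data.frame of per-patch metrics.
#' @param group name of the grouping column.
#' @return data.frame: \code{group}, \code{metric}, \code{mean},
#'   \code{sem}, \code{n}.
#' @export
summarizeGroups <- function(table, group = "construct") {
  if (!group %in% names(table)) stopf("no grouping column '%s'", group)
  numCols <- names(table)[vapply(table, is.numeric, logical(1))]
  g <- table[[group]]
  if (anyNA(g)) {
    warning("dropping rows with missing group label")
    table <- table[!is.na(g), , drop = FALSE]
    g <- table[[group]]
  }
  out <- list()
  for (lev in unique(g)) {
    sub <- table[g == lev, , drop = FALSE]
    if (!nrow(sub)) { warning(sprintf("empty group '%s' omitted", lev)); next }
    for (m in numCols) {
      v <- sub[[m]][is.finite(sub[[m]])]
      if (!length(v)) next
      out[[length(out) + 1L]] <- data.frame(
        group = lev, metric = m, mean = mean(v),
        sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
              else NA_real_,
        n = length(v))
    }
  }
  do.call(rbind, out)
}
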