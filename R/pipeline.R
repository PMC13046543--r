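# End-to-end pipeline: simulate (optional) -> group ICA -> temporal dynamic
# FNC -> windowed IVA-GL -> normalized-MI spatial dynamics -> group statistics.
# Every stage persists its outputs under the output directory so stages can be
# run separately and compose; a manifest records config, seed and version.

#' Default pipeline configuration
#'
#' Returns the pipeline configuration pre-filled with the study-scale
#' settings: 100 ICA components with 100 ICASSO runs and minimum cluster size
#' 80, template-correlation artifact threshold 0.2, 18-TR/1-TR sliding
#' windows with automatic k and the 10-window state-membership rule, 48-TR
#' IVA windows at 50\% overlap with 20 components of which 9 are kept, and
#' FDR control at alpha = 0.05. Override any entry via \code{...} (nested
#' lists are replaced whole).
#'
#' @param ... named overrides, e.g. \code{gica = list(nComponents = 4, ...)}.
#' @return nested named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    paths = list(volumes = NULL, mask = NULL, clinical = NULL,
                 templates = NULL),
    simulate = NULL,   # list of generateDataset() arguments, or NULL
    gica = list(nComponents = 100L, icassoRuns = 100L, minClusterSize = 80L,
                artifactR = 0.2, nSubjectPCs = 120L, nGroupPCs = 100L),
    tdfnc = list(widthTrs = 18L, stepTrs = 1L, k = "auto", minWindows = 10L),
    iva = list(windowTrs = 48L, overlap = 0.5, nComponents = 20L,
               keepSdcs = 9L, maxIter = 1024L),
    stats = list(alpha = 0.05, fdrFamily = "state"),
    seed = 1L
  )
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file path (.yaml/.yml or .json).
#' @return configuration list (defaults filled in via [pipelineConfig()]).
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, raw)
}

writeStageCsv <- function(df, outDir, name) {
  p <- file.path(outDir, name)
  utils::write.csv(df, p, row.names = FALSE)
  p
}

stageState <- function(outDir, name, value = NULL) {
  p <- file.path(outDir, "state", paste0(name, ".rds"))
  if (is.null(value)) {
    if (!file.exists(p)) stop(sprintf("stage input '%s' not found; run the earlier stages first", name))
    readRDS(p)
  } else {
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    saveRDS(value, p)
    invisible(p)
  }
}

#' Run the dynamic-FNC pipeline
#'
#' Executes the requested stages in order, persisting every intermediate and
#' all CSV outputs under \code{outDir}. A rerun with the same configuration
#' and seed reproduces all CSV outputs bit-identically.
#'
#' Stages and their CSV outputs:
#' \describe{
#'   \item{simulate}{synthetic NIfTI volumes, mask, \code{clinical.csv}.}
#'   \item{gica}{\code{gica_components.csv} (component,label,template_r,iq).}
#'   \item{tdfnc}{\code{state_assignments.csv}
#'     (subject_id,window_index,state), \code{state_metrics.csv}.}
#'   \item{iva}{\code{sdc_screening.csv} (component,template,r,kept).}
#'   \item{sdfnc}{\code{mi_connectivity.csv} (long format),
#'     \code{mi_std.csv}.}
#'   \item{stats}{\code{stats_static_fnc.csv}, \code{stats_state_fnc.csv},
#'     \code{stats_mi_std.csv}, \code{stats_clinical.csv}.}
#' }
#'
#' @param config configuration from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param stages character vector of stages, or "all".
#' @param seed overrides \code{config$seed} when given.
#' @return invisibly, a list with the final stage objects.
#' @export
runPipeline <- function(config, outDir, stages = "all", seed = NULL) {
  allStages <- c("simulate", "gica", "tdfnc", "iva", "sdfnc", "stats")
  if (identical(stages, "all"))
    stages <- if (is.null(config$simulate)) allStages[-1] else allStages
  stopifnot(all(stages %in% allStages))
  if (!is.null(seed)) config$seed <- seed
  seed <- as.integer(config$seed)
  if (is.null(config$simulate)) {
    if (is.null(config$paths$volumes) || is.null(config$paths$mask))
      stop("config validation: paths$volumes and paths$mask are required when simulate is NULL")
    if (!all(file.exists(unlist(config$paths$volumes))))
      stop("config validation: a volume path does not exist")
    if (!file.exists(config$paths$mask))
      stop("config validation: mask path does not exist")
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ret <- list()
  runStage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[%s] starting", name))
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    ret[[name]] <<- res
    invisible(res)
  }

  runStage("simulate", function() {
    args <- config$simulate
    args$seed <- childSeed(seed, 11L)
    ds <- do.call(generateDataset, args)
    writeDataset(ds, file.path(outDir, "simulated"))
    stageState(outDir, "dataset", ds)
    ds
  })

  loadInputs <- function() {
    if (!is.null(config$simulate)) {
      ds <- stageState(outDir, "dataset")
      templates <- ds$truth@spatialSources
      clinical <- ds$truth@clinicalTable
      series <- lapply(ds$series, function(s) {
        s@data <- scale(s@data)
        attr(s@data, "scaled:center") <- NULL
        attr(s@data, "scaled:scale") <- NULL
        methods::validObject(s)
        s
      })
      list(series = series, templates = templates, clinical = clinical)
    } else {
      series <- lapply(unlist(config$paths$volumes), function(v)
        loadMaskedSeries(v, config$paths$mask))
      clinical <- if (!is.null(config$paths$clinical))
        readClinicalTable(config$paths$clinical) else NULL
      templates <- if (!is.null(config$paths$templates)) {
        msk <- RNifti::readNifti(config$paths$mask)
        loadComponentMaps(config$paths$templates, as.array(msk))
      } else NULL
      list(series = series, templates = templates, clinical = clinical)
    }
  }

  runStage("gica", function() {
    inp <- loadInputs()
    g <- config$gica
    red <- reduceAndConcat(inp$series, g$nSubjectPCs, g$nGroupPCs)
    ic <- icassoSelect(red$groupData, g$nComponents, nRuns = g$icassoRuns,
                       minClusterSize = g$minClusterSize,
                       seed = childSeed(seed, 21L))
    comps <- ic$components
    if (!is.null(inp$templates))
      comps <- labelComponents(comps, inp$templates,
                               artifactRThreshold = g$artifactR)
    subj <- backReconstruct(comps, red, inp$series)
    lab <- comps@labels
    writeStageCsv(data.frame(component = seq_along(lab),
                             label = ifelse(is.na(lab), "unlabeled", lab),
                             template_r = if (nrow(comps@templateCorrelations))
                               comps@templateCorrelations$r else NA_real_,
                             iq = comps@stabilityIq),
                  outDir, "gica_components.csv")
    out <- list(group = comps, subject = subj, clusterInfo = ic$clusterInfo)
    stageState(outDir, "gica", out)
    out
  })

  runStage("tdfnc", function() {
    gica <- stageState(outDir, "gica")
    td <- config$tdfnc
    lab <- gica$group@labels
    keep <- which(is.na(lab) | lab != "artifact")
    if (length(keep) < 2L) {
      warning("fewer than 2 non-artifact components; keeping all for dynamic FNC")
      keep <- seq_along(lab)
    }
    wfnc <- lapply(gica$subject, function(cs) {
      tc <- cs@timeCourses[[1]][, keep, drop = FALSE]
      slidingWindowFNC(tc, widthTrs = td$widthTrs, stepTrs = td$stepTrs)
    })
    ids <- vapply(gica$subject, function(cs) names(cs@timeCourses)[1],
                  character(1))
    sm <- clusterStates(wfnc, k = td$k, seed = childSeed(seed, 31L))
    asg <- do.call(rbind, lapply(seq_along(ids), function(m)
      data.frame(subject_id = ids[m],
                 window_index = seq_along(sm@assignments[[m]]),
                 state = sm@assignments[[m]])))
    writeStageCsv(asg, outDir, "state_assignments.csv")
    writeStageCsv(stateMetrics(sm, minWindows = td$minWindows,
                               subjectIds = ids),
                  outDir, "state_metrics.csv")
    out <- list(wfnc = wfnc, stateModel = sm, components = keep,
                subjectIds = ids)
    stageState(outDir, "tdfnc", out)
    out
  })

  runStage("iva", function() {
    inp <- loadInputs()
    iv <- config$iva
    segs <- lapply(inp$series, segmentWindows, windowTrs = iv$windowTrs,
                   overlapFraction = iv$overlap)
    scv <- ivaGL(segs, nComponents = iv$nComponents,
                 seed = childSeed(seed, 41L),
                 maxIter = if (is.null(iv$maxIter)) 1024L else iv$maxIter)
    if (!is.null(inp$templates)) {
      keep <- min(iv$keepSdcs, iv$nComponents)
      scr <- screenSDCs(scv, inp$templates, keep = keep)
      writeStageCsv(cbind(scr$ranking,
                          kept = scr$ranking$component %in% scr$kept),
                    outDir, "sdc_screening.csv")
      scv <- scr$scvset
    }
    stageState(outDir, "iva", scv)
    scv
  })

  runStage("sdfnc", function() {
    scv <- stageState(outDir, "iva")
    mi <- miConnectivity(scv)
    inp <- loadInputs()
    ids <- vapply(inp$series, function(s) s@subjectId, character(1))
    writeStageCsv(miLongFormat(mi, subjectIds = ids), outDir,
                  "mi_connectivity.csv")
    ev <- edgeVariability(mi)
    P <- dim(mi$values)[3]
    ep <- edgePairs(P)
    stdLong <- do.call(rbind, lapply(seq_along(ids), function(m)
      data.frame(subject_id = ids[m], component_i = ep$i,
                 component_j = ep$j,
                 std = ev$stdPerSubject[m, , ][cbind(ep$i, ep$j)])))
    writeStageCsv(stdLong, outDir, "mi_std.csv")
    out <- list(mi = mi, variability = ev, subjectIds = ids)
    stageState(outDir, "sdfnc", out)
    out
  })

  runStage("stats", function() {
    inp <- loadInputs()
    if (is.null(inp$clinical)) stop("stats stage requires a clinical table")
    td <- stageState(outDir, "tdfnc")
    sd <- stageState(outDir, "sdfnc")
    stp <- config$stats
    clin <- inp$clinical[match(td$subjectIds, inp$clinical$subject_id), ]
    groups <- clin$group

    # static FNC: Fisher-z whole-series correlations, pooled t per edge
    gica <- stageState(outDir, "gica")
    N <- length(td$components)
    ep <- edgePairs(N)
    statFeat <- t(vapply(gica$subject, function(cs) {
      tc <- cs@timeCourses[[1]][, td$components, drop = FALSE]
      fisherZ(upperTriVec(staticFNC(tc)))
    }, numeric(nrow(ep))))
    statRes <- compareEdgeFeatures(statFeat, groups, test = "t",
                                   alpha = stp$alpha, edgeInfo = ep)
    writeStageCsv(statRes, outDir, "stats_static_fnc.csv")

    stateRes <- compareStateFNC(td$stateModel, td$wfnc, groups,
                                minWindows = config$tdfnc$minWindows,
                                alpha = stp$alpha,
                                fdrFamily = stp$fdrFamily)
    writeStageCsv(stateRes$results, outDir, "stats_state_fnc.csv")

    # STD of spatial connectivity: Mann-Whitney per edge
    P <- dim(sd$mi$values)[3]
    epP <- edgePairs(P)
    stdFeat <- t(vapply(seq_along(td$subjectIds), function(m)
      sd$variability$stdPerSubject[m, , ][cbind(epP$i, epP$j)],
      numeric(nrow(epP))))
    stdRes <- compareEdgeFeatures(stdFeat, groups, test = "u",
                                  alpha = stp$alpha, edgeInfo = epP)
    writeStageCsv(stdRes, outDir, "stats_mi_std.csv")

    # clinical correlation for features with significant group differences
    feats <- list()
    sig <- which(statRes$significant)
    for (e in sig)
      feats[[sprintf("static_%d_%d", ep$i[e], ep$j[e])]] <- statFeat[, e]
    sres <- stateRes$results
    for (r in which(sres$significant)) {
      st <- sres$state[r]
      i <- sres$component_i[r]; j <- sres$component_j[r]
      eIdx <- which(ep$i == i & ep$j == j)
      vals <- vapply(seq_along(td$wfnc), function(m) {
        w <- which(td$stateModel@assignments[[m]] == st)
        if (length(w) < config$tdfnc$minWindows) return(NA_real_)
        mean(windowVectors(td$wfnc[[m]])[w, eIdx])
      }, numeric(1))
      feats[[sprintf("state%d_%d_%d", st, i, j)]] <- vals
    }
    for (e in which(stdRes$significant))
      feats[[sprintf("mistd_%d_%d", epP$i[e], epP$j[e])]] <- stdFeat[, e]
    usable <- vapply(feats, function(x)
      sum(is.finite(x)) >= 3L && stats::sd(x[is.finite(x)]) > 0, logical(1))
    feats <- feats[usable]
    corRes <- if (length(feats)) {
      correlateClinical(feats, clin[, c("score", "duration_months")])
    } else data.frame(feature = character(), score = character(),
                      r = numeric(), p = numeric(), n = integer())
    writeStageCsv(corRes, outDir, "stats_clinical.csv")
    out <- list(static = statRes, state = stateRes, std = stdRes,
                clinical = corRes)
    stageState(outDir, "stats", out)
    out
  })

  manifest <- list(config = config, seed = seed,
                   package = "dynetfnc",
                   version = as.character(utils::packageVersion("dynetfnc")),
                   stages = stages)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(ret)
}
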