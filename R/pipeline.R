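## TSV with "# key: value" provenance header lines
writeTaggedTsv <- function(df, file, meta = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# package: surpriseERP %s",
                     as.character(packageVersion("surpriseERP"))), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a pipeline configuration
#'
#' YAML configuration with top-level keys \code{nParticipants}, \code{seed},
#' \code{task} (arguments of [taskConfig()]), \code{behaviour} (overrides of
#' [behaviourModel()]), \code{erp} (\code{nPerCondition}), \code{cluster}
#' (\code{nPermutations}, \code{channels}, \code{window}, \code{sidedness})
#' and \code{microstates} (\code{kRange}). Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("nParticipants", "seed", "task", "behaviour", "erp", "cluster",
             "microstates")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' Run the full simulation and analysis pipeline
#'
#' End-to-end orchestration on synthetic participants: cohort simulation
#' (sessions, responses, surprise), behavioural statistics (repeated-measures
#' ANOVA of offset latency, FDR-corrected pairwise tests, post-session median
#' split, surprise-latency correlations), ERP simulation and preprocessing
#' (artifact rejection, average reference, condition averages, grand
#' average), a cluster-mass permutation test (prediction errors vs
#' standards), and microstate segmentation of the grand-average ERPs with
#' map-count selection and back-fitting. All tables are written as TSV, the
#' collected statistics as a machine-readable JSON summary; every file
#' carries the package version and config hash.
#'
#' @param config path to a YAML config, or a config list
#'   (see [readPipelineConfig()]).
#' @param outputDir directory for outputs (created if needed).
#' @param seed overrides the config seed if not NULL.
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(config, outputDir, seed = NULL) {
  if (is.character(config)) {
    configHash <- unname(tools::md5sum(config))
    config <- readPipelineConfig(config)
  } else {
    configHash <- unname(tools::md5sum(
      textConnection2file(yaml::as.yaml(config))))
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed)) config$seed <- 1L
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  meta <- c(config_hash = configHash, seed = as.character(config$seed))
  summary <- list(package = "surpriseERP",
                  version = as.character(packageVersion("surpriseERP")),
                  configHash = configHash, seed = config$seed,
                  stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  ## -- simulate ------------------------------------------------------------
  cohort <- stage("simulate", {
    tc <- do.call(taskConfig, config$task %||% list())
    bm <- do.call(behaviourModel, config$behaviour %||% list())
    simulateCohort(config$nParticipants %||% 12L, config = tc, model = bm,
                   seed = config$seed)
  })
  lat <- do.call(rbind, lapply(cohort$participants, `[[`, "latencies"))
  postLat <- do.call(rbind, lapply(cohort$participants, `[[`,
                                   "postLatencies"))
  sur <- do.call(rbind, lapply(seq_along(cohort$participants), function(i) {
    s <- cohort$participants[[i]]$surprise
    s$participant <- cohort$participants[[i]]$id
    s
  }))
  writeTaggedTsv(lat, file.path(outputDir, "latencies.tsv"), meta)
  writeTaggedTsv(sur, file.path(outputDir, "surprise.tsv"), meta)
  writeSessionTsv(cohort$participants[[1]]$session,
                  file.path(outputDir, "session-p01"), meta)

  ## -- behaviour -----------------------------------------------------------
  behaviourStats <- stage("behaviour", {
    anova <- rmAnova2x3(lat[!lat$excluded, ])
    cm <- aggregate(offsetLatency ~ participant + compliance,
                    data = lat[!lat$excluded, ], FUN = mean)
    pw <- combn(COMPLIANCE_LEVELS, 2, simplify = FALSE)
    pairwise <- do.call(rbind, lapply(pw, function(pair) {
      w <- merge(cm[cm$compliance == pair[1], c("participant",
                                                "offsetLatency")],
                 cm[cm$compliance == pair[2], c("participant",
                                                "offsetLatency")],
                 by = "participant")
      tt <- t.test(w[[2]], w[[3]], paired = TRUE)
      data.frame(effect = paste(pair, collapse = " vs "),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }))
    pairwise$pAdjusted <- fdrBH(pairwise$p)
    split <- medianSplitGain(postLat)
    grp <- split$assignment$group[match(lat$participant,
                                        split$assignment$participant)]
    ## subgroup correlations need enough extended-sequence pairs; small
    ## cohorts report NA instead of aborting
    tryCor <- function(d) tryCatch(correlateSurpriseLatency(d),
                                   error = function(e)
                                     list(r = NA_real_, n = 0L,
                                          df = NA_integer_, p = NA_real_))
    corGain <- tryCor(lat[grp == "gain", ])
    corNoGain <- tryCor(lat[grp == "no_gain", ])
    zcmp <- if (is.na(corGain$r) || is.na(corNoGain$r))
      list(Z = NA_real_, p = NA_real_) else
        compareCorrelations(corGain$r, corGain$n, corNoGain$r, corNoGain$n)
    list(anova = anova, pairwise = pairwise, split = split,
         correlations = list(gain = corGain, noGain = corNoGain,
                             fisher = zcmp))
  })
  writeTaggedTsv(behaviourStats$anova, file.path(outputDir, "anova.tsv"),
                 meta)
  writeTaggedTsv(behaviourStats$pairwise,
                 file.path(outputDir, "pairwise.tsv"), meta)
  writeTaggedTsv(behaviourStats$split$assignment,
                 file.path(outputDir, "groups.tsv"), meta)

  ## -- erp -----------------------------------------------------------------
  erpCfg <- config$erp %||% list()
  erpBits <- stage("erp", {
    model <- erpModel()
    nPer <- erpCfg$nPerCondition %||% 12L
    erpSets <- lapply(seq_along(cohort$participants), function(i) {
      ep <- simulateEpochs(cohort$participants[[i]]$session@events, model,
                           nPerCondition = nPer,
                           participant = cohort$participants[[i]]$id,
                           seed = config$seed + 1000L + i)
      ep <- rejectArtifacts(ep)
      ep <- rereferenceAverage(ep)
      averageErp(ep)
    })
    list(model = model, erpSets = erpSets, grand = grandAverage(erpSets))
  })

  ## -- cluster test --------------------------------------------------------
  clCfg <- config$cluster %||% list()
  clusterRes <- stage("cluster", {
    roi <- clCfg$channels %||% c("CP1", "CPz", "CP2", "P1", "Pz", "P2")
    win <- as.numeric(clCfg$window %||% c(300, 600))
    model <- erpBits$model
    sel <- match(roi, model@channels$name)
    times <- erpBits$grand@times
    tsel <- which(times >= win[1] & times < win[2])
    erpA <- lapply(erpBits$erpSets, function(e) e@erps$PE[sel, tsel])
    erpB <- lapply(erpBits$erpSets, function(e) e@erps$STD[sel, tsel])
    clusterMassTest(erpA, erpB,
                    channels = model@channels[sel, ],
                    nPermutations = clCfg$nPermutations %||% 500L,
                    sidedness = clCfg$sidedness %||% "two",
                    seed = config$seed + 77L)
  })
  writeTaggedTsv(clusterRes@clusters, file.path(outputDir, "clusters.tsv"),
                 meta)
  tmapDf <- as.data.frame(clusterRes@tMap)
  tmapDf <- cbind(channel = rownames(clusterRes@tMap), tmapDf)
  writeTaggedTsv(tmapDf, file.path(outputDir, "tmap.tsv"), meta)

  ## -- microstates ---------------------------------------------------------
  msCfg <- config$microstates %||% list()
  micro <- stage("microstates", {
    conds <- names(erpBits$grand@erps)
    kRange <- msCfg$kRange %||% 2:15
    fit <- aahc(erpBits$grand@erps, kRange = kRange)
    kStar <- selectNMaps(fit, method = msCfg$method %||% "cv")
    templ <- templateMaps(fit, kStar)
    segs <- lapply(conds, function(cn)
      backfit(templ, erpBits$grand@erps[[cn]], condition = cn,
              times = erpBits$grand@times))
    stats <- do.call(rbind, lapply(segs, segmentStats))
    list(kStar = kStar, fit = fit, stats = stats)
  })
  writeTaggedTsv(micro$stats, file.path(outputDir, "microstates.tsv"), meta)

  ## -- summary -------------------------------------------------------------
  mainEffect <- behaviourStats$anova[
    behaviourStats$anova$effect == "compliance", ]
  summary$stages <- list(
    simulate = list(nParticipants = length(cohort$participants),
                    nSequences = nrow(lat)),
    behaviour = list(
      complianceF = mainEffect$F, complianceDf = c(mainEffect$df1,
                                                   mainEffect$df2),
      complianceP = mainEffect$p,
      gainCorrelation = behaviourStats$correlations$gain$r,
      noGainCorrelation = behaviourStats$correlations$noGain$r,
      fisherZ = behaviourStats$correlations$fisher$Z),
    cluster = list(mode = clusterRes@mode,
                   nComparisons = clusterRes@nComparisons,
                   nClusters = nrow(clusterRes@clusters),
                   minP = if (nrow(clusterRes@clusters))
                     min(clusterRes@clusters$pCorrected) else NA),
    microstates = list(kStar = micro$kStar,
                       explainedVariance =
                         unname(explainedVariance(micro$fit, micro$kStar))))
  jsonlite::write_json(summary, file.path(outputDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## write a string to a temp file (for hashing in-memory configs)
textConnection2file <- function(text) {
  f <- tempfile(fileext = ".yaml")
  writeLines(text, f)
  f
}
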