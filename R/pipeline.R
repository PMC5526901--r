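## Config-driven orchestration: simulate -> prefilter -> cluster ->
## annotate -> evaluate, with per-stage logging and reproducible seeding.
##
## Three analysis modes mirror the common automated-gating workflows:
##   single-stage : DAG prefilter each sample, cluster its markers, apply
##                  the annotation rule per sample.
##   template     : DAG prefilter all samples, build a consensus by
##                  subsampling, fit one template model, assign every
##                  sample to the shared cluster set.
##   two-stage    : no DAG; stage-1 clustering on scatter + viability with
##                  rule-based lymphocyte cluster selection, stage-2
##                  clustering of CD8 x multimer within the selection.

.PIPELINE_MODES <- c("single-stage", "template", "two-stage")

#' Read and validate a pipeline configuration
#'
#' Reads a YAML pipeline configuration and validates it against the
#' schema before any computation (unknown modes, roles referenced but
#' absent from the panel, and malformed sample entries are schema errors).
#'
#' @param path YAML file path.
#' @return A validated, default-filled config list.
#' @seealso [runPipeline()] for the config fields.
#' @export
readPipelineConfig <- function(path) {
  validatePipelineConfig(yaml::read_yaml(path))
}

#' @rdname readPipelineConfig
#' @param config a config list (as from [runPipeline()]'s `config`
#'   argument).
#' @export
validatePipelineConfig <- function(config) {
  stopifnot(is.list(config))
  config$mode <- config$mode %||% "single-stage"
  if (!config$mode %in% .PIPELINE_MODES)
    stop(sprintf("schema error: unknown mode '%s' (expected %s)",
                 config$mode, paste(.PIPELINE_MODES, collapse = "/")),
         call. = FALSE)
  config$panel <- unlist(config$panel) %||%
    c("FSC-A", "FSC-H", "SSC-A", "viability", "dump", "CD3", "CD8",
      "multimer-PE")
  bad <- setdiff(config$panel, .ALL_ROLES)
  if (length(bad))
    stop(sprintf("schema error: unknown panel role '%s'", bad[1]),
         call. = FALSE)
  config$cluster <- config$cluster %||% list()
  config$cluster$bins <- config$cluster$bins %||% 12
  config$cluster$maxClusters <- config$cluster$maxClusters %||% 100
  config$annotate <- config$annotate %||% list()
  config$annotate$thresholdEvents <- config$annotate$thresholdEvents %||% 10
  mmr <- unlist(config$annotate$multimerRoles) %||%
    intersect(.MULTIMER_ROLES, config$panel)
  config$annotate$multimerRoles <- mmr
  roles <- unlist(config$cluster$roles) %||%
    c(intersect(if ("CD3" %in% config$panel) "CD3" else "dump",
                config$panel),
      "CD8", mmr)
  for (r in c(roles, mmr)) {
    if (!r %in% .ALL_ROLES)
      stop(sprintf("schema error: unknown channel role '%s'", r),
           call. = FALSE)
    if (!r %in% config$panel)
      stop(sprintf(
        "schema error: role '%s' referenced but absent from the panel", r),
        call. = FALSE)
  }
  config$cluster$roles <- roles
  if (is.null(config$samples) && is.null(config$design))
    stop("schema error: config needs 'samples' and/or 'design'",
         call. = FALSE)
  for (s in config$samples) {
    if (is.null(s$name) || (is.null(s$preset) && is.null(s$fcs)))
      stop("schema error: each sample needs 'name' and 'preset' or 'fcs'",
           call. = FALSE)
  }
  config$seed <- config$seed %||% 1L
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Build the gate sequence for a config/panel.
.configGates <- function(config) {
  if (!is.null(config$gates) && is.list(config$gates)) {
    steps <- lapply(config$gates, function(g)
      gateStep(g$x, g$y, unlist(g$rect)))
    gateSequence(steps)
  } else {
    defaultGateSequence(viability = "viability" %in% config$panel)
  }
}

## Analyze one prefiltered+transformed sample with a fitted or template
## model; returns the PopulationCall plus bookkeeping.
.annotateSample <- function(model, counts, liveSingleCount, config,
                            cd8Count = NA) {
  categories <- categorizeExpression(model)
  ids <- callMultimerPopulation(
    categories, multimerRoles = config$annotate$multimerRoles)
  computeFrequencies(ids, counts, liveSingleCount, cd8Count = cd8Count,
                     thresholdEvents = config$annotate$thresholdEvents)
}

#' Run the configured analysis pipeline end to end
#'
#' Executes simulate/load -> prefilter -> cluster -> annotate -> evaluate
#' for the configured mode, writing CSV reports, the cluster model (JSON),
#' a structured log and the resolved configuration (with its MD5 hash and
#' seed stamped into every report) into `outdir`. Given the same config
#' and seed, all CSV outputs are byte-identical across runs.
#'
#' Config fields: `mode` (`"single-stage"`, `"template"`, `"two-stage"`),
#' `panel` (roles present), `samples` (list of `name`/`preset`/`nEvents`/
#' `duplicates` entries or `fcs` paths plus a `roleMap`), `design`
#' (spike-in dilution: `f0`, `d`, `nSteps`, `nEventsPerSample`,
#' `duplicates`, `includePureNegative`, plus `positivePreset`/
#' `negativePreset`), `gates` (list of `x`/`y`/`rect` steps, or omitted
#' for the default sequence), `cluster` (`roles`, `bins`, `minDensity`,
#' `maxClusters`), `annotate` (`thresholdEvents`, `multimerRoles`),
#' `seed`, `outdir`.
#'
#' @param config config list or path to a YAML file.
#' @param seed overrides the config seed.
#' @param outdir overrides the config output directory.
#' @return Invisibly, `list(calls, summary, lod, outdir)`: the per-run
#'   population-call table, the duplicate-averaged per-sample summary,
#'   the [lodReport()] (when a dilution design was run) and the output
#'   directory.
#' @export
runPipeline <- function(config, seed = NULL, outdir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  else config <- validatePipelineConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(outdir)) config$outdir <- outdir
  config$outdir <- config$outdir %||% tempfile("flowDAG_run_")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  ## the recorded (and hashed) configuration excludes the output path, so
  ## that identical analyses in different directories share a hash
  cfgRecord <- config[setdiff(sort(names(config)), "outdir")]
  cfgPath <- file.path(config$outdir, "config_used.yaml")
  yaml::write_yaml(cfgRecord, cfgPath)
  cfgHash <- unname(tools::md5sum(cfgPath))

  logLines <- character()
  logIt <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    logLines <<- c(logLines, line)
    invisible(line)
  }
  logIt("pipeline mode=%s seed=%d config=%s", config$mode, config$seed,
        cfgHash)

  ## ---- stage: simulate / load -------------------------------------
  profile <- labProfile(panel = config$panel)
  entries <- list()   # each: name, duplicate, table, theoretical (or NA)
  k <- 0L
  for (s in config$samples) {
    dups <- s$duplicates %||% 1L
    for (dup in seq_len(dups)) {
      k <- k + 1L
      sSeed <- .subSeed(config$seed, k)
      tab <- if (!is.null(s$fcs)) {
        t0 <- readFCS(s$fcs)
        if (!is.null(config$roleMap))
          t0 <- assignChannelRoles(t0, config$roleMap)
        t0
      } else {
        simulateDonor(donorPreset(s$preset,
                                  separation = s$separation %||%
                                    "distinct"),
                      profile, nEvents = s$nEvents %||% 2e5, seed = sSeed)
      }
      entries[[k]] <- list(name = s$name, duplicate = dup, table = tab,
                           theoretical = s$theoretical %||% NA_real_,
                           seed = sSeed)
      logIt("simulated sample=%s dup=%d n=%d seed=%d", s$name, dup,
            nEvents(tab), sSeed)
    }
  }
  if (!is.null(config$design)) {
    dg <- config$design
    design <- spikeInDesign(
      f0 = dg$f0 %||% 1.7, d = dg$d %||% 5, nSteps = dg$nSteps %||% 7,
      nEventsPerSample = dg$nEventsPerSample %||% 2e5,
      duplicates = dg$duplicates %||% 2,
      includePureNegative = isTRUE(dg$includePureNegative),
      seed = .subSeed(config$seed, 1000L))
    pos <- simulateDonor(donorPreset(dg$positivePreset %||%
                                       "spikein1_positive"),
                         profile, nEvents = dg$donorEvents %||% 2e5,
                         seed = .subSeed(config$seed, 1001L))
    neg <- simulateDonor(donorPreset(dg$negativePreset %||%
                                       "spikein1_negative"),
                         profile, nEvents = dg$donorEvents %||% 2e5,
                         seed = .subSeed(config$seed, 1002L))
    series <- makeDilutionSeries(design, pos, neg)
    for (e in series) {
      k <- k + 1L
      entries[[k]] <- list(
        name = if (is.na(e$step)) "negative_control"
               else sprintf("dilution_step%02d", e$step),
        duplicate = e$duplicate, table = e$table,
        theoretical = e$theoretical, seed = e$seed)
      logIt("dilution step=%s dup=%d theoretical=%g seed=%d",
            format(e$step), e$duplicate, e$theoretical, e$seed)
    }
  }

  ## ---- stage: prefilter + transform -------------------------------
  gates <- .configGates(config)
  retention <- NULL
  filtered <- vector("list", length(entries))
  if (config$mode %in% c("single-stage", "template")) {
    for (i in seq_along(entries)) {
      tab <- arcsinhTransform(entries[[i]]$table)
      res <- dagFilter(tab, gates)
      filtered[[i]] <- res$table
      rep_i <- cbind(sample = entries[[i]]$name,
                     duplicate = entries[[i]]$duplicate, res$report)
      retention <- rbind(retention, rep_i)
      logIt("prefilter sample=%s dup=%d kept=%d/%d",
            entries[[i]]$name, entries[[i]]$duplicate,
            nEvents(res$table), nEvents(tab))
    }
  } else {
    for (i in seq_along(entries))
      filtered[[i]] <- arcsinhTransform(entries[[i]]$table)
  }

  ## ---- stage: cluster + annotate ----------------------------------
  calls <- NULL
  addCall <- function(i, call, nClust) {
    e <- entries[[i]]
    calls <<- rbind(calls, data.frame(
      sample = e$name, duplicate = e$duplicate,
      theoretical = e$theoretical,
      event_count = call@eventCount,
      denominator_live_single = call@denominatorLiveSingle,
      denominator_cd8 = call@denominatorCD8,
      freq_of_lymphocytes = call@freqOfLymphocytes,
      freq_of_cd8 = call@freqOfCD8,
      detected = call@detected,
      clusters_selected = paste(call@multimerClusterIds, collapse = ";"),
      n_clusters = nClust,
      sample_seed = e$seed, seed = config$seed, config_hash = cfgHash,
      stringsAsFactors = FALSE))
  }

  if (config$mode == "single-stage") {
    for (i in seq_along(entries)) {
      fit <- gridDensityCluster(filtered[[i]], config$cluster$roles,
                                bins = config$cluster$bins,
                                minDensity = config$cluster$minDensity,
                                maxClusters = config$cluster$maxClusters)
      call <- .annotateSample(fit$model, clusterCounts(fit$model),
                              nEvents(filtered[[i]]), config)
      addCall(i, call, nClusters(fit$model))
      logIt("cluster sample=%s dup=%d clusters=%d multimer_events=%.0f",
            entries[[i]]$name, entries[[i]]$duplicate,
            nClusters(fit$model), call@eventCount)
    }
  } else if (config$mode == "template") {
    nPer <- config$cluster$consensusPerSample %||% 250000
    consensus <- subsampleConcat(filtered, nPer,
                                 seed = .subSeed(config$seed, 2000L))
    logIt("consensus n=%d from %d samples", nEvents(consensus),
          length(filtered))
    template <- buildTemplate(consensus, config$cluster$roles,
                              bins = config$cluster$bins,
                              minDensity = config$cluster$minDensity,
                              maxClusters = config$cluster$maxClusters)
    writeClusterModel(template, file.path(config$outdir,
                                          "template_model.json"))
    for (i in seq_along(entries)) {
      asg <- assignToCentroids(filtered[[i]], template)
      call <- .annotateSample(template, asg$counts,
                              nEvents(filtered[[i]]), config)
      addCall(i, call, nClusters(template))
    }
  } else { # two-stage
    s1roles <- intersect(c("FSC-A", "SSC-A", "viability"), config$panel)
    s1rect <- config$stage1Rect %||%
      list("FSC-A" = c(0.15, 0.60), "SSC-A" = c(0.02, 0.50),
           "viability" = c(0, 0.5))
    for (i in seq_along(entries)) {
      fit1 <- gridDensityCluster(filtered[[i]], s1roles,
                                 bins = config$cluster$bins,
                                 minDensity = config$cluster$minDensity)
      sc <- .scaleTo01(centroids(fit1$model), fit1$model@scaleRange)
      inRect <- rep(TRUE, nClusters(fit1$model))
      for (r in names(s1rect)) {
        j <- match(r, channelRoles(fit1$model))
        if (is.na(j)) next
        inRect <- inRect & sc[, j] >= s1rect[[r]][1] &
          sc[, j] <= s1rect[[r]][2]
      }
      selEvents <- fit1$assignment %in% which(inRect)
      sub <- filtered[[i]][which(selEvents), ]
      logIt("stage1 sample=%s dup=%d lymph_clusters=%d/%d kept=%d",
            entries[[i]]$name, entries[[i]]$duplicate, sum(inRect),
            nClusters(fit1$model), nEvents(sub))
      s2roles <- intersect(c("CD8", config$annotate$multimerRoles),
                           config$panel)
      fit2 <- gridDensityCluster(sub, s2roles,
                                 bins = config$cluster$bins,
                                 minDensity = config$cluster$minDensity)
      call <- .annotateSample(fit2$model, clusterCounts(fit2$model),
                              nEvents(sub), config)
      addCall(i, call, nClusters(fit2$model))
    }
  }

  ## ---- stage: evaluate --------------------------------------------
  summary <- do.call(rbind, lapply(split(calls, calls$sample),
                                   function(g) data.frame(
    sample = g$sample[1],
    n_duplicates = nrow(g),
    mean_freq_of_lymphocytes = meanOfDuplicates(g$freq_of_lymphocytes),
    mean_freq_of_cd8 = if (all(is.na(g$freq_of_cd8))) NA_real_
                       else meanOfDuplicates(g$freq_of_cd8),
    all_detected = all(g$detected),
    theoretical = g$theoretical[1],
    seed = config$seed, config_hash = cfgHash,
    stringsAsFactors = FALSE)))
  rownames(summary) <- NULL

  lod <- NULL
  dil <- calls[!is.na(calls$theoretical), , drop = FALSE]
  if (nrow(dil)) {
    lod <- lodReport(data.frame(theoretical = dil$theoretical,
                                estimated = dil$freq_of_lymphocytes,
                                detected = dil$detected,
                                duplicate = dil$duplicate))
    write.csv(lod$table, file.path(config$outdir, "lod.csv"),
              row.names = FALSE)
  }

  ## negative-control exclusion rule: a 'negative' sample in which the
  ## called population exceeds 20% of live single lymphocytes marks an
  ## extreme outlier run
  outliers <- calls$freq_of_lymphocytes > 20 &
    grepl("negative", calls$sample)
  if (any(outliers))
    logIt("outlier flagged: %s (negative-control frequency > 20%%)",
          paste(unique(calls$sample[outliers]), collapse = ", "))

  write.csv(calls, file.path(config$outdir, "population_calls.csv"),
            row.names = FALSE)
  write.csv(summary, file.path(config$outdir, "summary.csv"),
            row.names = FALSE)
  if (!is.null(retention))
    write.csv(retention, file.path(config$outdir, "retention.csv"),
              row.names = FALSE)
  writeLines(logLines, file.path(config$outdir, "log.txt"))

  invisible(list(calls = calls, summary = summary, lod = lod,
                 outdir = config$outdir))
}
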