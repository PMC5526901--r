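# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# A small EventTable around an explicit matrix, with roles taken from the
# column count: first columns get scatter roles, the rest marker roles.
makeTable <- function(mat, roles = NULL, labels = NULL,
                      transformState = "raw") {
  mat <- as.matrix(mat)
  if (is.null(roles))
    roles <- c("FSC-A", "FSC-H", "SSC-A", "CD3", "CD8",
               "multimer-PE")[seq_len(ncol(mat))]
  EventTable(mat,
             channels = data.frame(shortName = paste0("ch", seq_along(roles)),
                                   stainLabel = NA_character_,
                                   role = roles,
                                   stringsAsFactors = FALSE),
             labels = labels, transformState = transformState)
}

# Labels constituting live single lymphocytes / CD8+ T cells.
LIVE_SINGLE_LABELS <- c("nonT_lymph", "CD3pos_CD8neg",
                        "CD8pos_multimer_neg", "CD8pos_multimer_pos")
CD8_LABELS <- c("CD8pos_multimer_neg", "CD8pos_multimer_pos")

# The standard single-sample analysis chain used across tests: simulate,
# arcsinh, DAG prefilter, cluster the marker channels, annotate.
analyzeDonor <- function(preset, nEvents, seed,
                         roles = c("CD3", "CD8", "multimer-PE"), ...) {
  et <- simulateDonor(donorPreset(preset), labProfile(), nEvents,
                      seed = seed)
  tt <- arcsinhTransform(et)
  filt <- dagFilter(tt, defaultGateSequence())$table
  fit <- gridDensityCluster(filt, roles = roles, ...)
  ids <- callMultimerPopulation(categorizeExpression(fit$model))
  lab <- eventLabels(filt)
  call <- computeFrequencies(
    ids, clusterCounts(fit$model), nEvents(filt),
    cd8Count = max(1, sum(lab %in% CD8_LABELS)))
  list(call = call, filtered = filt, fit = fit, raw = et)
}

# 3-SE binomial tolerance, in percent, for a proportion p (as percent)
# observed on a denominator n.
binomTol3SE <- function(pPercent, n) {
  p <- pPercent / 100
  3 * sqrt(p * (1 - p) / n) * 100
}
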