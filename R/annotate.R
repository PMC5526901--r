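## Cluster annotation and population quantification.
##
## Clusters are turned into population calls by a rule on categorized
## expression levels: each marker's observed range is split into four
## equal-width intervals (1 = negative, 2 = low, 3 = positive, 4 = high)
## and a cluster is called multimer-positive when its levels satisfy
## CD3 > 1 (skipped when the panel has no CD3), CD8 > 1 and multimer > 2;
## panels using a dump channel instead of CD3 additionally require
## dump = 1. The same cutoff is applied to every sample — deliberately: a
## standardized pipeline with no per-sample tuning, whose failure modes on
## poorly separated data are part of what the evaluation layer measures.

#' Categorize cluster expression levels 1-4
#'
#' For each clustering marker, the observed event-value range (the model's
#' frozen normalization range, analysis scale) is split into four
#' equal-width intervals and each cluster receives the level of the
#' interval containing its centroid: 1 = negative, 2 = low, 3 = positive,
#' 4 = high. Deterministic; a degenerate (zero-width) channel range puts
#' all clusters at level 1 with a warning.
#'
#' @param model a [ClusterModel-class].
#' @return Integer matrix, clusters x markers, values in 1..4.
#' @examples
#' et <- simulateDonor(donorPreset("519_EBV"), labProfile(), 20000, seed = 3)
#' fit <- gridDensityCluster(arcsinhTransform(et),
#'                           roles = c("CD3", "CD8", "multimer-PE"))
#' categorizeExpression(fit$model)
#' @export
categorizeExpression <- function(model) {
  cent <- centroids(model)
  rng <- model@scaleRange
  lev <- matrix(1L, nrow(cent), ncol(cent),
                dimnames = list(NULL, channelRoles(model)))
  for (j in seq_len(ncol(cent))) {
    span <- rng[2, j] - rng[1, j]
    if (span <= 0) {
      warning(sprintf(
        "channel '%s' has a degenerate range; all clusters set to level 1",
        channelRoles(model)[j]), call. = FALSE)
      next
    }
    frac <- (cent[, j] - rng[1, j]) / span
    lev[, j] <- as.integer(pmin(pmax(floor(frac * 4) + 1, 1), 4))
  }
  lev
}

#' Call multimer-positive clusters from expression categories
#'
#' Applies the fixed cutoff rule: level > 1 for CD3 (when a CD3 column is
#' present), level > 1 for CD8, and level > 2 for the multimer marker(s)
#' named in `multimerRoles`. When the panel categorizes a dump channel,
#' clusters must additionally be dump-negative (level 1).
#'
#' @param categories integer matrix from [categorizeExpression()].
#' @param multimerRoles which multimer column(s) must exceed level 2;
#'   defaults to every multimer column present.
#' @return Integer vector of selected cluster indices (possibly empty).
#' @export
callMultimerPopulation <- function(categories, multimerRoles = NULL) {
  markers <- colnames(categories)
  if (is.null(multimerRoles))
    multimerRoles <- intersect(.MULTIMER_ROLES, markers)
  if (!length(multimerRoles) || !all(multimerRoles %in% markers))
    stop("no multimer marker among the categorized channels",
         call. = FALSE)
  if (!"CD8" %in% markers)
    stop("the annotation rule requires a CD8 marker", call. = FALSE)
  sel <- categories[, "CD8"] > 1L
  if ("CD3" %in% markers) sel <- sel & categories[, "CD3"] > 1L
  if ("dump" %in% markers) sel <- sel & categories[, "dump"] == 1L
  for (mr in multimerRoles) sel <- sel & categories[, mr] > 2L
  unname(which(sel))
}

#' Compute reported population frequencies
#'
#' @param multimerClusterIds selected cluster indices from
#'   [callMultimerPopulation()].
#' @param counts per-cluster event counts (from the model fit or a
#'   template assignment).
#' @param liveSingleCount events in the live single lymphocyte denominator
#'   (> 0); typically the DAG-prefiltered event count.
#' @param cd8Count optional CD8+ T cell count for the secondary
#'   denominator.
#' @param thresholdEvents detection threshold (default 10 events, the
#'   conventional minimum for calling a positive multimer response).
#' @return A [PopulationCall-class].
#' @examples
#' computeFrequencies(1L, counts = c(10, 990), liveSingleCount = 1e6)
#' @export
computeFrequencies <- function(multimerClusterIds, counts,
                               liveSingleCount, cd8Count = NA,
                               thresholdEvents = 10) {
  if (is.na(liveSingleCount) || liveSingleCount <= 0)
    stop("undefined frequency: live single lymphocyte denominator is zero",
         call. = FALSE)
  if (!is.na(cd8Count) && cd8Count <= 0)
    stop("undefined frequency: CD8 denominator is zero", call. = FALSE)
  eventCount <- if (length(multimerClusterIds))
    sum(counts[multimerClusterIds]) else 0
  new("PopulationCall",
      multimerClusterIds = as.integer(multimerClusterIds),
      eventCount = eventCount,
      denominatorLiveSingle = as.numeric(liveSingleCount),
      denominatorCD8 = as.numeric(cd8Count),
      freqOfLymphocytes = 100 * eventCount / liveSingleCount,
      freqOfCD8 = if (is.na(cd8Count)) NA_real_
                  else 100 * eventCount / cd8Count,
      detected = eventCount >= thresholdEvents,
      thresholdEvents = thresholdEvents)
}

setMethod("show", "PopulationCall", function(object) {
  cat(sprintf(
    "PopulationCall: %.0f events in cluster(s) %s\n",
    object@eventCount,
    if (length(object@multimerClusterIds))
      paste(object@multimerClusterIds, collapse = ",") else "<none>"))
  cat(sprintf("  %% of live single lymphocytes: %.4g (n = %.0f)\n",
              object@freqOfLymphocytes, object@denominatorLiveSingle))
  if (!is.na(object@freqOfCD8))
    cat(sprintf("  %% of CD8+ T cells: %.4g (n = %.0f)\n",
                object@freqOfCD8, object@denominatorCD8))
  cat(sprintf("  detected: %s (threshold %.0f events)\n",
              object@detected, object@thresholdEvents))
})

#' Average duplicate measurements
#'
#' Reported frequencies are the arithmetic mean over duplicate runs; a
#' single value passes through unchanged (the convention when only one
#' run of a sample is available).
#'
#' @param freqs numeric vector of frequencies (length >= 1).
#' @return The mean frequency.
#' @export
meanOfDuplicates <- function(freqs) {
  if (!length(freqs)) stop("no duplicate values given", call. = FALSE)
  mean(freqs)
}
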