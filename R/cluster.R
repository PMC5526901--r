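## Grid-based density clustering with centroid templates.
##
## Channels are min-max scaled to [0, 1], binned into a regular grid, and
## hyper-bins holding at least `minDensity` events are marked dense. Dense
## bins are merged by hill-climbing: each dense bin links to its
## highest-count strictly-greater Chebyshev neighbor (radius 1, then
## radius 2 to absorb fringe fluctuations), so every local density mode
## roots one cluster and adjacent modes separated by a density saddle stay
## apart even when their dense regions touch. Every event (dense or not)
## is then assigned to its nearest mode centroid in the scaled space,
## centroids are re-estimated once from that assignment, and the final
## assignment to the re-estimated centroids defines the reported
## per-cluster counts. Freezing the normalization range inside the model
## makes cross-sample assignment well-defined.

#' @describeIn ClusterModel-class centroid matrix (analysis scale).
#' @param object a `ClusterModel`.
#' @export
setMethod("centroids", "ClusterModel", function(object) object@centroids)

#' @describeIn ClusterModel-class events per cluster.
#' @export
setMethod("clusterCounts", "ClusterModel", function(object) object@counts)

#' @describeIn ClusterModel-class number of clusters.
#' @export
setMethod("nClusters", "ClusterModel",
          function(object) nrow(object@centroids))

#' @describeIn ClusterModel-class clustering channel roles.
#' @export
setMethod("channelRoles", "ClusterModel",
          function(object) object@channelRoles)

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: %d clusters on %s (%d events)\n",
              nClusters(object),
              paste(object@channelRoles, collapse = ", "),
              sum(object@counts)))
  cat(sprintf("  params: bins=%s, minDensity=%s\n",
              object@params$bins, object@params$minDensity))
})

## Scale a role matrix into [0,1] given a 2 x k (min,max) range matrix.
.scaleTo01 <- function(mat, rng) {
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  sweep(sweep(mat, 2, rng[1, ]), 2, span, "/")
}

## Nearest-centroid assignment in scaled space; ties go to the lowest
## cluster index (strict improvement required to switch).
.assignNearest <- function(scaled, cent) {
  n <- nrow(scaled)
  best <- rep.int(1L, n)
  bestD <- rowSums(sweep(scaled, 2, cent[1, ])^2)
  k <- nrow(cent)
  if (k > 1) for (c in 2:k) {
    d <- rowSums(sweep(scaled, 2, cent[c, ])^2)
    hit <- d < bestD
    best[hit] <- c
    bestD[hit] <- d[hit]
  }
  best
}

#' Grid-based density clustering
#'
#' @param table an [EventTable-class] (typically DAG-prefiltered and
#'   arcsinh-transformed).
#' @param roles two or more channel roles to cluster on.
#' @param bins grid bins per channel (default 12).
#' @param minDensity minimum events for a hyper-bin to count as dense;
#'   default `max(5, round(n / 1e5))` (see the methods vignette for the
#'   rationale: low enough to seed populations of ~100 events at n = 1e6
#'   without bridging well-separated modes).
#' @param maxClusters cap on the number of seed components; when exceeded,
#'   the largest components (by dense-bin event count) are kept (default
#'   100).
#' @return `list(model = <ClusterModel>, assignment = <integer vector>)`;
#'   the assignment is a total partition (counts sum to `nEvents`).
#' @examples
#' et <- simulateDonor(donorPreset("519_EBV"), labProfile(), 20000, seed = 2)
#' et <- arcsinhTransform(et)
#' fit <- gridDensityCluster(et, roles = c("CD3", "CD8", "multimer-PE"))
#' nClusters(fit$model)
#' @export
gridDensityCluster <- function(table, roles, bins = 12, minDensity = NULL,
                               maxClusters = 100) {
  stopifnot(length(roles) >= 2)
  if (nEvents(table) == 0) stop("empty table", call. = FALSE)
  cols <- vapply(roles, function(r) .roleCol(table, r), integer(1))
  mat <- exprs(table)[, cols, drop = FALSE]
  n <- nrow(mat)
  if (is.null(minDensity)) minDensity <- max(5, round(n / 1e5))
  rng <- apply(mat, 2, range)
  scaled <- .scaleTo01(mat, rng)
  d <- ncol(scaled)

  binIdx <- pmin(pmax(floor(scaled * bins) + 1L, 1L), as.integer(bins))
  storage.mode(binIdx) <- "integer"
  radix <- as.integer(bins)^(seq_len(d) - 1)
  key <- as.integer(binIdx %*% radix) - as.integer(sum(radix)) + 1L

  counts <- tabulate(key, nbins = as.integer(bins)^d)
  denseKeys <- which(counts >= minDensity)

  if (!length(denseKeys)) {
    warning("no hyper-bin reaches the density threshold; ",
            "falling back to a single cluster", call. = FALSE)
    cent <- matrix(colMeans(scaled), nrow = 1)
    assignment <- rep.int(1L, n)
  } else {
    ## group dense bins by the density mode they hill-climb to
    comp <- .modeSeeds(denseKeys, counts[denseKeys], as.integer(bins), d)
    ## seed centroids: mean of events lying in each component's dense bins
    inDense <- match(key, denseKeys)
    evComp <- comp[inDense]                 # NA for events in sparse bins
    nc <- max(comp)
    seedCounts <- tabulate(evComp, nbins = nc)
    if (nc > maxClusters) {
      keep <- order(seedCounts, decreasing = TRUE)[seq_len(maxClusters)]
      remap <- rep(NA_integer_, nc)
      remap[keep] <- seq_along(keep)
      evComp <- remap[evComp]
      nc <- maxClusters
    }
    cent <- matrix(0, nc, d)
    for (j in seq_len(d))
      cent[, j] <- tapply(scaled[, j], factor(evComp, levels = seq_len(nc)),
                          mean)
    cent[!is.finite(cent)] <- 0.5
    assignment <- .assignNearest(scaled, cent)
    ## one re-estimation pass, then the final assignment
    for (c in seq_len(nc)) {
      sel <- assignment == c
      if (any(sel)) cent[c, ] <- colMeans(scaled[sel, , drop = FALSE])
    }
    assignment <- .assignNearest(scaled, cent)
  }

  span <- rng[2, ] - rng[1, ]; span[span == 0] <- 1
  centData <- sweep(sweep(cent, 2, span, "*"), 2, rng[1, ], "+")
  colnames(centData) <- roles
  colnames(rng) <- roles
  model <- new("ClusterModel", centroids = centData,
               counts = as.numeric(tabulate(assignment, nbins = nrow(cent))),
               channelRoles = roles, scaleRange = rng,
               params = list(bins = bins, minDensity = minDensity))
  list(model = model, assignment = assignment)
}

## Group dense hyper-bins by density mode. Each dense bin links to the
## dense Chebyshev-radius-1 neighbor with the highest, strictly greater
## event count; bins without such a neighbor look one shell further
## (radius 2), which absorbs isolated fringe fluctuations of a population
## tail without bridging modes separated by an empty gap. Bins with no
## strictly greater neighbor within radius 2 are mode roots. Returns the
## root (cluster) index of every dense key, numbered 1..k in decreasing
## root-count order.
.modeSeeds <- function(denseKeys, denseCounts, bins, d) {
  nd <- length(denseKeys)
  coords <- matrix(0L, nd, d)
  rem <- denseKeys - 1L
  for (j in seq_len(d)) {
    coords[, j] <- rem %% bins
    rem <- rem %/% bins
  }
  radix <- bins^(seq_len(d) - 1)
  bestCount <- denseCounts     # strictly greater required to link
  parent <- seq_len(nd)
  linkShell <- function(radius, parent, bestCount) {
    offs <- as.matrix(expand.grid(rep(list(-radius:radius), d)))
    offs <- offs[apply(abs(offs), 1, max) == radius, , drop = FALSE]
    for (oi in seq_len(nrow(offs))) {
      nb <- sweep(coords, 2, offs[oi, ], "+")
      ok <- rowSums(nb < 0 | nb >= bins) == 0
      if (!any(ok)) next
      nbKey <- as.integer(nb[ok, , drop = FALSE] %*% radix) + 1L
      hit <- match(nbKey, denseKeys)
      src <- which(ok)[!is.na(hit)]
      dst <- hit[!is.na(hit)]
      gain <- denseCounts[dst] > bestCount[src]
      parent[src[gain]] <- dst[gain]
      bestCount[src[gain]] <- denseCounts[dst[gain]]
    }
    list(parent = parent, bestCount = bestCount)
  }
  r1 <- linkShell(1L, parent, bestCount)
  unlinked <- r1$parent == seq_len(nd)
  r2 <- linkShell(2L, r1$parent, r1$bestCount)
  parent <- r1$parent
  parent[unlinked] <- r2$parent[unlinked]
  ## follow links to the roots (counts strictly increase along links, so
  ## this terminates)
  root <- parent
  repeat {
    nxt <- parent[root]
    if (all(nxt == root)) break
    root <- nxt
  }
  roots <- unique(root)
  ## order clusters by total dense-bin events at the root's basin
  basin <- vapply(roots, function(r) sum(denseCounts[root == r]),
                  numeric(1))
  roots <- roots[order(basin, decreasing = TRUE)]
  match(root, roots)
}

#' Fit a clustering template on a consensus table
#'
#' Fits [gridDensityCluster()] on a consensus table (built with
#' [subsampleConcat()] from all samples of a batch) and returns the model
#' for reuse as a reference: assigning each individual sample's events to
#' the template's centroids maps all samples onto one shared cluster set.
#'
#' @inheritParams gridDensityCluster
#' @param consensus the consensus [EventTable-class].
#' @return A [ClusterModel-class].
#' @export
buildTemplate <- function(consensus, roles, bins = 12, minDensity = NULL,
                          maxClusters = 100) {
  gridDensityCluster(consensus, roles, bins = bins,
                     minDensity = minDensity,
                     maxClusters = maxClusters)$model
}

#' Assign events to a model's centroids
#'
#' Scales the table's clustering channels with the model's frozen
#' normalization range and assigns every event to the nearest centroid
#' (Euclidean distance in the scaled space; ties go to the lowest cluster
#' index). Deterministic and independent of event order.
#'
#' @param table an [EventTable-class] carrying all model roles.
#' @param model a [ClusterModel-class].
#' @return `list(assignment = <integer>, counts = <numeric>)`.
#' @export
assignToCentroids <- function(table, model) {
  cols <- vapply(channelRoles(model), function(r) .roleCol(table, r),
                 integer(1))
  mat <- exprs(table)[, cols, drop = FALSE]
  scaled <- .scaleTo01(mat, model@scaleRange)
  centScaled <- .scaleTo01(model@centroids, model@scaleRange)
  assignment <- .assignNearest(scaled, centScaled)
  list(assignment = assignment,
       counts = as.numeric(tabulate(assignment, nbins = nClusters(model))))
}

#' Serialize a ClusterModel to JSON
#'
#' @param model a [ClusterModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClusterModel <- function(model, path) {
  obj <- list(centroids = unclass(model@centroids),
              counts = model@counts,
              channelRoles = model@channelRoles,
              scaleRange = unclass(model@scaleRange),
              params = model@params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a ClusterModel from JSON
#'
#' @param path path written by [writeClusterModel()].
#' @return A [ClusterModel-class].
#' @export
readClusterModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- as.matrix(obj$centroids)
  rng <- as.matrix(obj$scaleRange)
  colnames(cent) <- obj$channelRoles
  colnames(rng) <- obj$channelRoles
  new("ClusterModel", centroids = cent, counts = as.numeric(obj$counts),
      channelRoles = obj$channelRoles, scaleRange = rng,
      params = as.list(obj$params))
}
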