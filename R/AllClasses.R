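#' EventTable: per-event cytometry measurements
#'
#' The central container of the package: an `n_events x n_channels` matrix
#' of (compensated) fluorescence and scatter intensities together with
#' channel metadata, stable event identifiers, optional ground-truth
#' population labels (carried by synthetic data), and the current transform
#' state of the fluorescence channels.
#'
#' @slot exprs numeric matrix, events in rows, channels in columns. All
#'   values must be finite.
#' @slot channels `data.frame` with one row per channel and columns
#'   `shortName` (FCS `$PnN`, non-empty, unique), `stainLabel` (FCS `$PnS`,
#'   may be `NA`) and `role` (one of `"FSC-A"`, `"FSC-H"`, `"SSC-A"`,
#'   `"viability"`, `"dump"`, `"CD3"`, `"CD8"`, `"multimer-PE"`,
#'   `"multimer-APC"`, `"unused"`). Each role other than `"unused"` may be
#'   assigned to at most one channel.
#' @slot eventIds integer vector of stable 0-based identifiers, unique
#'   within the table.
#' @slot labels character vector of per-event population labels (length
#'   `nEvents` or 0 when no ground truth is available).
#' @slot transformState `"raw"` or `"arcsinh"`.
#' @slot sourceTable integer vector recording, for concatenated tables, the
#'   1-based index of the source table each event came from (length
#'   `nEvents` or 0).
#'
#' @seealso [EventTable()] for the constructor, [readFCS()], [dagFilter()].
#' @name EventTable-class
#' @rdname EventTable-class
#' @exportClass EventTable
setClass("EventTable",
         representation(exprs = "matrix",
                        channels = "data.frame",
                        eventIds = "integer",
                        labels = "character",
                        transformState = "character",
                        sourceTable = "integer"))

setValidity("EventTable", function(object) {
  msg <- character()
  ex <- object@exprs
  ch <- object@channels
  if (!is.numeric(ex))
    msg <- c(msg, "'exprs' must be a numeric matrix")
  if (nrow(ch) != ncol(ex))
    msg <- c(msg, "channel metadata rows must match exprs columns")
  need <- c("shortName", "stainLabel", "role")
  if (!all(need %in% names(ch))) {
    msg <- c(msg, sprintf("'channels' must have columns %s",
                          paste(need, collapse = ", ")))
  } else {
    sn <- ch$shortName
    if (any(!nzchar(sn)) || anyNA(sn))
      msg <- c(msg, "channel shortName entries must be non-empty")
    if (anyDuplicated(sn))
      msg <- c(msg, "channel shortName entries must be unique")
    if (!all(ch$role %in% .ALL_ROLES))
      msg <- c(msg, sprintf("unknown channel role(s): %s",
                            paste(setdiff(ch$role, .ALL_ROLES),
                                  collapse = ", ")))
    assigned <- ch$role[ch$role != "unused"]
    if (anyDuplicated(assigned))
      msg <- c(msg, sprintf("role(s) assigned to more than one channel: %s",
                            paste(unique(assigned[duplicated(assigned)]),
                                  collapse = ", ")))
  }
  if (length(ex) && any(!is.finite(ex)))
    msg <- c(msg, "all intensities must be finite")
  if (length(object@eventIds) != nrow(ex))
    msg <- c(msg, "'eventIds' must have one entry per event")
  if (anyDuplicated(object@eventIds))
    msg <- c(msg, "'eventIds' must be unique")
  if (!length(object@transformState) == 1 ||
      !object@transformState %in% c("raw", "arcsinh"))
    msg <- c(msg, "'transformState' must be \"raw\" or \"arcsinh\"")
  if (length(object@labels) && length(object@labels) != nrow(ex))
    msg <- c(msg, "'labels', when present, must have one entry per event")
  if (length(object@sourceTable) &&
      length(object@sourceTable) != nrow(ex))
    msg <- c(msg, "'sourceTable', when present, must match the event count")
  if (length(msg)) msg else TRUE
})

#' GateStep: one rectangle-directed density gate
#'
#' A single step of a DAG gate sequence: a 2D projection (a pair of channel
#' roles) together with a rectangle, in the units of the current analysis
#' scale of those channels, that directs which density contour is kept.
#'
#' @slot xRole,yRole channel roles of the projection.
#' @slot rect numeric of length 4: `(xmin, xmax, ymin, ymax)` with
#'   `xmin < xmax` and `ymin < ymax`.
#' @name GateStep-class
#' @rdname GateStep-class
#' @exportClass GateStep
setClass("GateStep",
         representation(xRole = "character", yRole = "character",
                        rect = "numeric"))

setValidity("GateStep", function(object) {
  msg <- character()
  if (length(object@rect) != 4)
    msg <- c(msg, "'rect' must be (xmin, xmax, ymin, ymax)")
  else if (!(object@rect[1] < object@rect[2] &&
             object@rect[3] < object@rect[4]))
    msg <- c(msg, "'rect' must satisfy xmin < xmax and ymin < ymax")
  for (r in c(object@xRole, object@yRole))
    if (!r %in% .ALL_ROLES)
      msg <- c(msg, sprintf("unknown channel role '%s'", r))
  if (length(msg)) msg else TRUE
})

#' GateSequence: an ordered DAG prefiltering configuration
#'
#' @slot steps list of [GateStep-class] objects, applied in order. May be
#'   empty (identity filter).
#' @slot bins number of density-histogram bins per axis (>= 16).
#' @slot smoothing Gaussian smoothing width, in bin widths.
#' @slot nLevels number of evenly spaced density-contour levels (>= 2).
#' @name GateSequence-class
#' @rdname GateSequence-class
#' @exportClass GateSequence
setClass("GateSequence",
         representation(steps = "list", bins = "numeric",
                        smoothing = "numeric", nLevels = "numeric"))

setValidity("GateSequence", function(object) {
  msg <- character()
  if (!all(vapply(object@steps, is, logical(1), class2 = "GateStep")))
    msg <- c(msg, "'steps' must be a list of GateStep objects")
  if (object@bins < 16) msg <- c(msg, "'bins' must be >= 16")
  if (object@nLevels < 2) msg <- c(msg, "'nLevels' must be >= 2")
  if (object@smoothing <= 0) msg <- c(msg, "'smoothing' must be positive")
  if (length(msg)) msg else TRUE
})

#' ClusterModel: centroids from grid-based density clustering
#'
#' Holds the result of [gridDensityCluster()] in a form reusable as a
#' template for cross-sample assignment: cluster centroids on the analysis
#' scale, per-cluster event counts, the clustering channel roles, and the
#' frozen per-channel `(min, max)` normalization range so that assignment of
#' new samples happens in exactly the space the model was fitted in.
#'
#' @slot centroids numeric matrix, clusters x channels, analysis-scale units.
#' @slot counts numeric vector of events per cluster (sums to the number of
#'   clustered events).
#' @slot channelRoles character vector of clustering roles (matrix columns).
#' @slot scaleRange numeric matrix 2 x channels: observed `(min, max)` per
#'   channel used for `[0, 1]` normalization.
#' @slot params list of fitting parameters (`bins`, `minDensity`).
#' @name ClusterModel-class
#' @rdname ClusterModel-class
#' @exportClass ClusterModel
setClass("ClusterModel",
         representation(centroids = "matrix", counts = "numeric",
                        channelRoles = "character", scaleRange = "matrix",
                        params = "list"))

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (nrow(object@centroids) < 1)
    msg <- c(msg, "a ClusterModel must contain at least one cluster")
  if (any(!is.finite(object@centroids)))
    msg <- c(msg, "centroids must be finite")
  if (length(object@counts) != nrow(object@centroids))
    msg <- c(msg, "'counts' must have one entry per cluster")
  if (ncol(object@centroids) != length(object@channelRoles))
    msg <- c(msg, "centroid columns must match 'channelRoles'")
  if (!identical(dim(object@scaleRange),
                 c(2L, ncol(object@centroids))))
    msg <- c(msg, "'scaleRange' must be a 2 x channels matrix")
  if (length(msg)) msg else TRUE
})

#' PopulationCall: a quantified multimer-positive population
#'
#' The end product of the annotation stage: which clusters were called
#' multimer-positive, how many events they hold, the two reporting
#' denominators, the derived frequencies, and the detection flag under the
#' conventional minimum-event threshold.
#'
#' @slot multimerClusterIds integer vector of selected cluster indices.
#' @slot eventCount events in the selected clusters.
#' @slot denominatorLiveSingle live single lymphocyte count (primary
#'   denominator).
#' @slot denominatorCD8 CD8+ T cell count (secondary denominator, `NA` when
#'   not configured).
#' @slot freqOfLymphocytes percentage of live single lymphocytes.
#' @slot freqOfCD8 percentage of CD8+ T cells (`NA` when not configured).
#' @slot detected `TRUE` when `eventCount >= thresholdEvents`.
#' @slot thresholdEvents detection threshold in events (default 10).
#' @name PopulationCall-class
#' @rdname PopulationCall-class
#' @exportClass PopulationCall
setClass("PopulationCall",
         representation(multimerClusterIds = "integer",
                        eventCount = "numeric",
                        denominatorLiveSingle = "numeric",
                        denominatorCD8 = "numeric",
                        freqOfLymphocytes = "numeric",
                        freqOfCD8 = "numeric",
                        detected = "logical",
                        thresholdEvents = "numeric"))

setValidity("PopulationCall", function(object) {
  msg <- character()
  fl <- object@freqOfLymphocytes
  if (!is.na(fl) && (fl < 0 || fl > 100))
    msg <- c(msg, "'freqOfLymphocytes' must be in [0, 100]")
  fc <- object@freqOfCD8
  if (!is.na(fc) && (fc < 0 || fc > 100))
    msg <- c(msg, "'freqOfCD8' must be in [0, 100]")
  if (!is.na(object@denominatorLiveSingle) &&
      object@eventCount > object@denominatorLiveSingle)
    msg <- c(msg, "'eventCount' cannot exceed the lymphocyte denominator")
  if (!identical(object@detected,
                 object@eventCount >= object@thresholdEvents))
    msg <- c(msg, "'detected' must equal eventCount >= thresholdEvents")
  if (length(msg)) msg else TRUE
})
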