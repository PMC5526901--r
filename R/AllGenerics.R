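#' @export
setGeneric("exprs", function(object, ...) standardGeneric("exprs"))

#' @export
setGeneric("channelInfo", function(object, ...)
  standardGeneric("channelInfo"))

#' @export
setGeneric("eventLabels", function(object, ...)
  standardGeneric("eventLabels"))

#' @export
setGeneric("eventIds", function(object, ...) standardGeneric("eventIds"))

#' @export
setGeneric("transformState", function(object, ...)
  standardGeneric("transformState"))

#' @export
setGeneric("sourceTable", function(object, ...)
  standardGeneric("sourceTable"))

#' @export
setGeneric("nEvents", function(object, ...) standardGeneric("nEvents"))

#' @export
setGeneric("channelRoles", function(object, ...)
  standardGeneric("channelRoles"))

#' @export
setGeneric("centroids", function(object, ...) standardGeneric("centroids"))

#' @export
setGeneric("clusterCounts", function(object, ...)
  standardGeneric("clusterCounts"))

#' @export
setGeneric("nClusters", function(object, ...) standardGeneric("nClusters"))
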