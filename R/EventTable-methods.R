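#' Construct an EventTable
#'
#' @param exprs numeric matrix of intensities, events in rows, channels in
#'   columns.
#' @param channels `data.frame` with columns `shortName`, `stainLabel` and
#'   `role`; see [EventTable-class]. A character vector of short names is
#'   also accepted, in which case stain labels are `NA` and roles `"unused"`.
#' @param eventIds integer vector of unique 0-based event identifiers;
#'   defaults to `0:(n-1)`.
#' @param labels optional character vector of per-event population labels.
#' @param transformState `"raw"` (default) or `"arcsinh"`.
#' @param sourceTable optional integer vector of source-table provenance.
#'
#' @return A validated [EventTable-class] object.
#' @examples
#' et <- EventTable(matrix(rnorm(20, 100, 5), 10, 2),
#'                  channels = c("FSC-A", "SSC-A"))
#' nEvents(et)
#' @export
EventTable <- function(exprs, channels,
                       eventIds = NULL, labels = NULL,
                       transformState = "raw", sourceTable = NULL) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  if (is.character(channels))
    channels <- data.frame(shortName = channels,
                           stainLabel = NA_character_,
                           role = "unused",
                           stringsAsFactors = FALSE)
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  if (is.null(channels$stainLabel)) channels$stainLabel <- NA_character_
  if (is.null(channels$role)) channels$role <- "unused"
  rownames(channels) <- NULL
  colnames(exprs) <- channels$shortName
  if (is.null(eventIds)) eventIds <- seq_len(nrow(exprs)) - 1L
  new("EventTable", exprs = exprs, channels = channels,
      eventIds = as.integer(eventIds),
      labels = if (is.null(labels)) character() else as.character(labels),
      transformState = transformState,
      sourceTable = if (is.null(sourceTable)) integer()
                    else as.integer(sourceTable))
}

#' @describeIn EventTable-class the intensity matrix.
#' @param object,x an `EventTable`.
#' @export
setMethod("exprs", "EventTable", function(object) object@exprs)

#' @describeIn EventTable-class the channel metadata `data.frame`.
#' @export
setMethod("channelInfo", "EventTable", function(object) object@channels)

#' @describeIn EventTable-class per-event population labels (may be empty).
#' @export
setMethod("eventLabels", "EventTable", function(object) object@labels)

#' @describeIn EventTable-class stable 0-based event identifiers.
#' @export
setMethod("eventIds", "EventTable", function(object) object@eventIds)

#' @describeIn EventTable-class `"raw"` or `"arcsinh"`.
#' @export
setMethod("transformState", "EventTable",
          function(object) object@transformState)

#' @describeIn EventTable-class source-table provenance of concatenated
#'   tables (may be empty).
#' @export
setMethod("sourceTable", "EventTable", function(object) object@sourceTable)

#' @describeIn EventTable-class number of events.
#' @export
setMethod("nEvents", "EventTable", function(object) nrow(object@exprs))

#' @describeIn EventTable-class the role assigned to each channel.
#' @export
setMethod("channelRoles", "EventTable",
          function(object) object@channels$role)

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable: %d events x %d channels [%s]\n",
              nEvents(object), ncol(object@exprs), object@transformState))
  ch <- object@channels
  lab <- ifelse(is.na(ch$stainLabel), "", paste0(" (", ch$stainLabel, ")"))
  cat(sprintf("  %-14s%-22s%s\n", "role", "shortName", ""))
  for (i in seq_len(nrow(ch)))
    cat(sprintf("  %-14s%-22s\n", ch$role[i],
                paste0(ch$shortName[i], lab[i])))
  if (length(object@labels)) {
    tab <- sort(table(object@labels), decreasing = TRUE)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
  }
})

#' @describeIn EventTable-class subset events (`i`) and/or channels (`j`);
#'   preserves labels, identifiers and provenance.
#' @param i,j event and channel indices.
#' @param drop ignored.
#' @export
setMethod("[", "EventTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@exprs))
  if (missing(j)) j <- seq_len(ncol(x@exprs))
  new("EventTable",
      exprs = x@exprs[i, j, drop = FALSE],
      channels = x@channels[j, , drop = FALSE],
      eventIds = x@eventIds[i],
      labels = if (length(x@labels)) x@labels[i] else character(),
      transformState = x@transformState,
      sourceTable = if (length(x@sourceTable)) x@sourceTable[i]
                    else integer())
})

## Internal: column index of a channel role; errors (optionally) if absent.
.roleCol <- function(table, role, required = TRUE) {
  idx <- which(channelRoles(table) == role)
  if (!length(idx)) {
    if (required)
      stop(sprintf("channel role '%s' is not present in the table", role),
           call. = FALSE)
    return(NA_integer_)
  }
  idx[1]
}

#' Assign channel roles from a role map
#'
#' Attaches analysis roles (scatter, viability, dump, CD3, CD8, multimer) to
#' the channels of a table, matching map keys against stain labels first and
#' short names second, mirroring how heterogeneous multi-lab panels are
#' harmonized in practice.
#'
#' @param table an [EventTable-class].
#' @param roleMap named character vector or list: `name -> role`, where
#'   `name` matches a channel's `stainLabel` or `shortName`.
#' @return The table with roles assigned.
#' @export
assignChannelRoles <- function(table, roleMap) {
  ch <- channelInfo(table)
  for (key in names(roleMap)) {
    role <- as.character(roleMap[[key]])
    if (!role %in% .ALL_ROLES)
      stop(sprintf("unknown channel role '%s'", role), call. = FALSE)
    hit <- which(!is.na(ch$stainLabel) & ch$stainLabel == key)
    if (!length(hit)) hit <- which(ch$shortName == key)
    if (!length(hit)) {
      warning(sprintf("role map key '%s' matches no channel", key),
              call. = FALSE)
      next
    }
    ch$role[hit[1]] <- role
  }
  initialize(table, channels = ch)
}
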