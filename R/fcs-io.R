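## FCS list-mode file input/output.
##
## A deliberately small implementation of the Flow Cytometry Standard:
## reading of FCS 2.0/3.0/3.1 list-mode files with delimited TEXT segments
## (datatypes F, D and fixed-width I), and writing of FCS 3.1 float
## list-mode files. ANALYSIS and supplemental TEXT segments are ignored;
## keyword escaping by delimiter doubling is not supported. Ground-truth
## population labels have no standard FCS segment and therefore travel in a
## CSV sidecar file (`<path>.labels.csv` with columns event_id,label).

.fcsHeaderOffsets <- function(raw) {
  if (length(raw) < 58)
    stop("malformed FCS HEADER: file shorter than 58 bytes", call. = FALSE)
  fields <- vapply(0:5, function(i) {
    s <- rawToChar(raw[(11 + 8 * i):(18 + 8 * i)])
    s
  }, character(1))
  vals <- suppressWarnings(as.numeric(trimws(fields)))
  if (anyNA(vals))
    stop("malformed FCS HEADER: non-numeric segment offsets at byte 11",
         call. = FALSE)
  setNames(vals, c("textStart", "textEnd", "dataStart", "dataEnd",
                   "anaStart", "anaEnd"))
}

.fcsParseText <- function(raw, textStart, textEnd) {
  if (textEnd > length(raw) || textStart < 1 || textEnd <= textStart)
    stop(sprintf("malformed FCS TEXT segment: offsets %d-%d out of range",
                 textStart, textEnd), call. = FALSE)
  delim <- rawToChar(raw[textStart])
  body <- rawToChar(raw[(textStart + 1):textEnd])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # drop a trailing empty piece from the final delimiter
  if (length(parts) && parts[length(parts)] == "")
    parts <- parts[-length(parts)]
  if (length(parts) < 2 || length(parts) %% 2 != 0)
    stop(sprintf(
      "malformed FCS TEXT segment at byte %d: odd keyword/value count",
      textStart), call. = FALSE)
  keys <- toupper(parts[seq(1, length(parts), by = 2)])
  vals <- parts[seq(2, length(parts), by = 2)]
  as.list(setNames(vals, keys))
}

#' Read an FCS list-mode file
#'
#' Parses FCS 2.0, 3.0 or 3.1 list-mode files (datatypes `F`, `D`, `I`).
#' Channel short names are taken from `$PnN`, stain labels from `$PnS`.
#' If a sidecar `<path>.labels.csv` (written by [writeFCS()]) exists, the
#' per-event population labels are re-attached. A `$SPILLOVER` keyword, if
#' present, triggers a warning and is not applied: input is assumed
#' compensated.
#'
#' @param path path to the FCS file.
#' @return An [EventTable-class] with `transformState = "raw"`.
#' @seealso [writeFCS()], [assignChannelRoles()]
#' @export
readFCS <- function(path) {
  if (!file.exists(path))
    stop(sprintf("FCS file '%s' does not exist", path), call. = FALSE)
  raw <- readBin(path, what = "raw", n = file.size(path))
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1"))
    stop(sprintf("unsupported FCS version identifier '%s'", version),
         call. = FALSE)
  off <- .fcsHeaderOffsets(raw)
  kw <- .fcsParseText(raw, off["textStart"] + 1, off["textEnd"] + 1)

  mode <- kw[["$MODE"]]
  if (is.null(mode) || mode != "L")
    stop(sprintf("unsupported $MODE '%s': only list mode is supported",
                 if (is.null(mode)) "<missing>" else mode), call. = FALSE)
  dtype <- kw[["$DATATYPE"]]
  if (!dtype %in% c("F", "D", "I"))
    stop(sprintf("unsupported $DATATYPE '%s'", dtype), call. = FALSE)
  byteord <- kw[["$BYTEORD"]]
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"

  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  dataStart <- off["dataStart"]
  dataEnd <- off["dataEnd"]
  if (dataStart == 0) {
    dataStart <- as.numeric(kw[["$BEGINDATA"]])
    dataEnd <- as.numeric(kw[["$ENDDATA"]])
  }

  if (dtype == "I") {
    bits <- as.integer(kw[["$P1B"]])
    if (!bits %in% c(16L, 32L))
      stop(sprintf("unsupported $PnB %d for integer data", bits),
           call. = FALSE)
    size <- bits %/% 8L
  } else size <- if (dtype == "F") 4L else 8L

  needed <- as.numeric(ntot) * npar * size
  avail <- length(raw) - dataStart
  if (dataStart + needed > length(raw))
    stop(sprintf(
      "truncated DATA segment at byte %.0f: need %.0f bytes, have %.0f",
      dataStart, needed, avail), call. = FALSE)

  con <- rawConnection(raw[(dataStart + 1):length(raw)])
  on.exit(close(con))
  values <- if (dtype == "I")
    readBin(con, "integer", n = ntot * npar, size = size,
            signed = size > 2, endian = endian)
  else
    readBin(con, "double", n = ntot * npar, size = size, endian = endian)
  mat <- matrix(as.double(values), nrow = ntot, ncol = npar, byrow = TRUE)

  shortName <- vapply(seq_len(npar), function(i) {
    v <- kw[[sprintf("$P%dN", i)]]
    if (is.null(v)) sprintf("P%d", i) else v
  }, character(1))
  stainLabel <- vapply(seq_len(npar), function(i) {
    v <- kw[[sprintf("$P%dS", i)]]
    if (is.null(v)) NA_character_ else v
  }, character(1))

  if (!is.null(kw[["$SPILLOVER"]]) || !is.null(kw[["SPILL"]]))
    warning("$SPILLOVER keyword present; not applied (input is assumed ",
            "compensated)", call. = FALSE)

  labels <- NULL
  sidecar <- paste0(path, ".labels.csv")
  if (file.exists(sidecar)) {
    lab <- read.csv(sidecar, stringsAsFactors = FALSE)
    labels <- lab$label[order(lab$event_id)]
  }

  EventTable(mat,
             channels = data.frame(shortName = shortName,
                                   stainLabel = stainLabel,
                                   role = "unused",
                                   stringsAsFactors = FALSE),
             labels = labels)
}

#' Write an EventTable as an FCS 3.1 file
#'
#' Writes float ($DATATYPE=F) list-mode FCS 3.1 with little-endian byte
#' order. `$PnN`/`$PnS` keywords are preserved from the channel metadata.
#' Population labels, when present, are written to a CSV sidecar file
#' (`<path>.labels.csv`), since FCS has no standard label segment. Two
#' writes of the same table are byte-identical except for the `$DATE` and
#' `$BTIM` keywords.
#'
#' @param table an [EventTable-class] with at least one channel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFCS <- function(table, path) {
  ex <- exprs(table)
  ch <- channelInfo(table)
  if (ncol(ex) == 0)
    stop("cannot write an FCS file with zero channels", call. = FALSE)
  npar <- ncol(ex)
  ntot <- nrow(ex)
  delim <- "/"

  now <- Sys.time()
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0",
          "$TOT" = as.character(ntot), "$PAR" = as.character(npar),
          "$DATE" = toupper(format(now, "%d-%b-%Y")),
          "$BTIM" = format(now, "%H:%M:%S"))
  for (i in seq_len(npar)) {
    kw[sprintf("$P%dN", i)] <- ch$shortName[i]
    if (!is.na(ch$stainLabel[i]))
      kw[sprintf("$P%dS", i)] <- ch$stainLabel[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- as.character(
      max(262144, 2^ceiling(log2(max(1, max(ex[, i], na.rm = TRUE))))))
  }

  renderText <- function(kw) {
    paste0(delim,
           paste0(names(kw), delim, unname(kw), delim, collapse = ""))
  }
  ## fixed point for the data offsets (their digit count feeds back into
  ## the TEXT segment length)
  headerLen <- 58
  beginData <- 0; endData <- 0
  for (rep in 1:5) {
    kw2 <- c(kw, "$BEGINDATA" = as.character(beginData),
             "$ENDDATA" = as.character(endData))
    text <- renderText(kw2)
    newBegin <- headerLen + nchar(text, type = "bytes")
    newEnd <- newBegin + ntot * npar * 4 - 1
    if (newBegin == beginData && newEnd == endData) break
    beginData <- newBegin; endData <- newEnd
  }
  kw2 <- c(kw, "$BEGINDATA" = as.character(beginData),
           "$ENDDATA" = as.character(endData))
  text <- renderText(kw2)
  textStart <- headerLen
  textEnd <- textStart + nchar(text, type = "bytes") - 1

  fmt8 <- function(x) {
    s <- as.character(x)
    if (nchar(s) > 8) s <- "0"  # too large for the HEADER; TEXT carries it
    formatC(s, width = 8, flag = " ")
  }
  header <- paste0("FCS3.1    ",
                   fmt8(textStart), fmt8(textEnd),
                   fmt8(if (endData <= 99999999) beginData else 0),
                   fmt8(if (endData <= 99999999) endData else 0),
                   fmt8(0), fmt8(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  writeBin(as.vector(t(ex)), con, size = 4, endian = "little")

  if (length(eventLabels(table))) {
    write.csv(data.frame(event_id = eventIds(table),
                         label = eventLabels(table)),
              paste0(path, ".labels.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Harmonize channel nomenclature across files
#'
#' Renames channels so that files from different instruments or
#' laboratories share a uniform nomenclature before concatenation or
#' template clustering. Map keys are matched against stain labels first,
#' falling back to short names; the new name is stored as the stain label.
#' The intensity matrix is never touched.
#'
#' @param table an [EventTable-class].
#' @param renameMap named character vector/list: `old name -> new name`.
#' @return The renamed table.
#' @examples
#' et <- EventTable(matrix(1:4, 2, 2), channels = c("PE-A", "APC-A"))
#' et2 <- harmonizeChannels(et, c("PE-A" = "Multimer-PE"))
#' channelInfo(et2)$stainLabel
#' @export
harmonizeChannels <- function(table, renameMap) {
  ch <- channelInfo(table)
  renameMap <- unlist(renameMap)
  if (!length(renameMap)) return(table)
  target <- rep(NA_character_, nrow(ch))
  for (key in names(renameMap)) {
    hit <- which(!is.na(ch$stainLabel) & ch$stainLabel == key)
    if (!length(hit)) hit <- which(ch$shortName == key)
    if (!length(hit)) {
      warning(sprintf("rename key '%s' matches no channel", key),
              call. = FALSE)
      next
    }
    target[hit[1]] <- renameMap[[key]]
  }
  dup <- stats::na.omit(target[duplicated(target) & !is.na(target)])
  if (length(dup))
    stop(sprintf(
      "conflicting rename: multiple channels mapped to '%s'",
      paste(unique(dup), collapse = "', '")), call. = FALSE)
  ch$stainLabel[!is.na(target)] <- target[!is.na(target)]
  initialize(table, channels = ch)
}

#' Arcsinh transform of fluorescence channels
#'
#' Maps each fluorescence channel `x` to `asinh(x / cofactor)`, the standard
#' variance-stabilizing analysis scale for cytometry fluorescence. Scatter
#' channels are left untouched. Applying the transform twice is an error.
#'
#' @param table an [EventTable-class] with `transformState = "raw"`.
#' @param cofactor positive scalar, or named vector keyed by channel role,
#'   of transform cofactors (default 150, a customary value for
#'   conventional flow data).
#' @return The transformed table with `transformState = "arcsinh"`.
#' @export
arcsinhTransform <- function(table, cofactor = 150) {
  if (transformState(table) != "raw")
    stop("table is already arcsinh-transformed", call. = FALSE)
  if (any(cofactor <= 0))
    stop("'cofactor' must be positive", call. = FALSE)
  ex <- exprs(table)
  roles <- channelRoles(table)
  for (j in which(roles %in% .FLUOR_ROLES)) {
    cf <- if (length(cofactor) > 1) {
      if (!roles[j] %in% names(cofactor))
        stop(sprintf("no cofactor given for role '%s'", roles[j]),
             call. = FALSE)
      cofactor[[roles[j]]]
    } else cofactor
    ex[, j] <- asinh(ex[, j] / cf)
  }
  initialize(table, exprs = ex, transformState = "arcsinh")
}

#' Subsample and concatenate tables into a consensus table
#'
#' Draws a uniform random sample without replacement of
#' `min(nPerTable, nEvents)` events from each table and concatenates them,
#' e.g. to build the consensus sample that a clustering template is fitted
#' on. Source-table provenance is recorded per event, and the draw is
#' deterministic given `seed`. Tables smaller than `nPerTable` contribute
#' all their events, with a warning.
#'
#' @param tables list of [EventTable-class] objects sharing an identical,
#'   harmonized channel set and transform state.
#' @param nPerTable events to draw from each table.
#' @param seed integer seed.
#' @return The concatenated [EventTable-class]; `sourceTable()` gives each
#'   event's source index.
#' @export
subsampleConcat <- function(tables, nPerTable, seed = 1L) {
  stopifnot(length(tables) >= 1)
  ref <- channelInfo(tables[[1]])$shortName
  refState <- transformState(tables[[1]])
  for (i in seq_along(tables)) {
    sn <- channelInfo(tables[[i]])$shortName
    if (!identical(sn, ref)) {
      diffs <- c(setdiff(ref, sn), setdiff(sn, ref))
      stop(sprintf(
        "channel mismatch between table 1 and table %d: %s", i,
        paste(unique(diffs), collapse = ", ")), call. = FALSE)
    }
    if (!identical(transformState(tables[[i]]), refState))
      stop("tables differ in transform state", call. = FALSE)
  }
  allLabeled <- all(vapply(tables, function(t) length(eventLabels(t)) > 0,
                           logical(1)))
  .withSeed(seed, {
    picks <- lapply(seq_along(tables), function(i) {
      n <- nEvents(tables[[i]])
      if (n < nPerTable)
        warning(sprintf(
          "table %d has only %d events; taking all of them", i, n),
          call. = FALSE)
      sample.int(n, min(n, nPerTable))
    })
    mats <- vector("list", length(tables))
    labs <- vector("list", length(tables))
    src <- vector("list", length(tables))
    for (i in seq_along(tables)) {
      mats[[i]] <- exprs(tables[[i]])[picks[[i]], , drop = FALSE]
      if (allLabeled) labs[[i]] <- eventLabels(tables[[i]])[picks[[i]]]
      src[[i]] <- rep(i, length(picks[[i]]))
    }
    EventTable(do.call(rbind, mats),
               channels = channelInfo(tables[[1]]),
               labels = if (allLabeled) unlist(labs) else NULL,
               transformState = refState,
               sourceTable = unlist(src))
  })
}
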