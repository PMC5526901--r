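## Directed Automated Gating (DAG).
##
## Sequential 2D density-contour prefiltering: for each configured 2D
## projection, a smoothed histogram density is estimated, iso-density
## contour lines are traced, and the events inside the largest closed
## contour that lies entirely within the step's rectangle gate are kept and
## passed to the next step. The procedure is fully deterministic.

#' Construct a gate step
#'
#' @param xRole,yRole channel roles of the 2D projection.
#' @param rect numeric `(xmin, xmax, ymin, ymax)` in the units of the
#'   channels' current analysis scale.
#' @return A [GateStep-class].
#' @export
gateStep <- function(xRole, yRole, rect) {
  new("GateStep", xRole = xRole, yRole = yRole, rect = as.numeric(rect))
}

#' Construct a gate sequence
#'
#' @param steps list of [gateStep()] objects (may be empty: identity
#'   filter).
#' @param bins density-histogram bins per axis (default 128).
#' @param smoothing Gaussian smoothing width in bins (default 2).
#' @param nLevels number of contour levels (default 32).
#' @return A [GateSequence-class].
#' @export
gateSequence <- function(steps = list(), bins = 128, smoothing = 2,
                         nLevels = 32) {
  new("GateSequence", steps = steps, bins = bins, smoothing = smoothing,
      nLevels = nLevels)
}

#' Default DAG configuration: lymphocytes, singlets, live cells
#'
#' The standard pregating sequence for multimer analysis: lymphocytes on
#' SSC-A/FSC-A, singlets on FSC-H/FSC-A, then (when the panel carries a
#' viability stain) live cells in the viability-low window against FSC-A.
#' The default rectangles are matched to the synthetic generator's raw
#' scatter scale and arcsinh viability scale.
#'
#' @param viability include the viability step (set `FALSE` for panels
#'   without a live/dead stain, where the step is skipped).
#' @param ... passed to [gateSequence()] (`bins`, `smoothing`, `nLevels`).
#' @return A [GateSequence-class].
#' @export
defaultGateSequence <- function(viability = TRUE, ...) {
  steps <- list(
    gateStep("SSC-A", "FSC-A", c(2e3, 90e3, 45e3, 170e3)),
    gateStep("FSC-H", "FSC-A", c(40e3, 160e3, 45e3, 170e3)))
  if (viability)
    steps <- c(steps, gateStep("viability", "FSC-A",
                               c(-1, 3.6, 45e3, 170e3)))
  gateSequence(steps = steps, ...)
}

#' Estimate a smoothed 2D density on a gate step's projection
#'
#' Bins the two channels of `step` into a `bins x bins` histogram over the
#' observed range padded by 1% per side, smooths it with a separable
#' Gaussian kernel of width `smoothing` bins, and normalizes the grid to
#' total mass 1.
#'
#' @param table a non-empty [EventTable-class].
#' @param step a [gateStep()].
#' @param bins bins per axis.
#' @param smoothing Gaussian sd in bin widths.
#' @return A `DensityGrid`: list with `grid` (bins x bins, x indexes rows),
#'   `xEdges`, `yEdges` (length bins+1), `xMid`, `yMid`.
#' @export
estimateDensity2D <- function(table, step, bins = 128, smoothing = 2) {
  if (nEvents(table) == 0)
    stop("cannot estimate a density from zero events", call. = FALSE)
  x <- exprs(table)[, .roleCol(table, step@xRole)]
  y <- exprs(table)[, .roleCol(table, step@yRole)]
  pad <- function(r) {
    w <- diff(r)
    if (w == 0) w <- max(abs(r[1]), 1)   # degenerate: all-equal values
    r + c(-1, 1) * 0.01 * w
  }
  rx <- pad(range(x)); ry <- pad(range(y))
  xEdges <- seq(rx[1], rx[2], length.out = bins + 1)
  yEdges <- seq(ry[1], ry[2], length.out = bins + 1)
  ix <- pmin(pmax(findInterval(x, xEdges, rightmost.closed = TRUE), 1L),
             bins)
  iy <- pmin(pmax(findInterval(y, yEdges, rightmost.closed = TRUE), 1L),
             bins)
  counts <- matrix(tabulate(ix + (iy - 1L) * bins, nbins = bins * bins),
                   nrow = bins)
  sm <- .gaussSmooth2d(counts, smoothing)
  grid <- sm / sum(sm)
  structure(list(grid = grid, xEdges = xEdges, yEdges = yEdges,
                 xMid = (xEdges[-1] + xEdges[-(bins + 1)]) / 2,
                 yMid = (yEdges[-1] + yEdges[-(bins + 1)]) / 2),
            class = "DensityGrid")
}

#' Trace closed iso-density contour lines
#'
#' Extracts contour polygons at `nLevels` evenly spaced density levels in
#' `(0, max density)`. Contours that touch the grid boundary (open
#' contours) are discarded; the remaining closed polygons are returned in
#' data units with their enclosed (shoelace) area.
#'
#' @param density a `DensityGrid` from [estimateDensity2D()].
#' @param nLevels number of levels.
#' @return List of `PolygonGate` objects: `list(vertices, level, area)`;
#'   empty for a flat zero grid.
#' @export
extractContours <- function(density, nLevels = 32) {
  zmax <- max(density$grid)
  if (zmax <= 0) return(list())
  levels <- zmax * seq_len(nLevels) / (nLevels + 1)
  cl <- contourLines(x = density$xMid, y = density$yMid,
                     z = density$grid, levels = levels)
  out <- list()
  for (cc in cl) {
    n <- length(cc$x)
    closed <- n >= 4 && cc$x[1] == cc$x[n] && cc$y[1] == cc$y[n]
    if (!closed) next
    area <- .shoelaceArea(cc$x, cc$y)
    if (area <= 0) next
    out[[length(out) + 1L]] <-
      structure(list(vertices = cbind(x = cc$x, y = cc$y),
                     level = cc$level, area = area),
                class = "PolygonGate")
  }
  out
}

#' Select the largest contour inside a rectangle gate
#'
#' Among closed contours whose vertices all lie inside `rect`, returns the
#' one with maximal enclosed area; ties are broken toward the lower density
#' level. Returns `NULL` when no contour qualifies.
#'
#' @param contours list of `PolygonGate` objects.
#' @param rect numeric `(xmin, xmax, ymin, ymax)`.
#' @return A `PolygonGate` or `NULL`.
#' @export
selectLargestContour <- function(contours, rect) {
  stopifnot(length(rect) == 4, rect[1] < rect[2], rect[3] < rect[4])
  best <- NULL
  for (cg in contours) {
    v <- cg$vertices
    if (any(v[, 1] < rect[1] | v[, 1] > rect[2] |
            v[, 2] < rect[3] | v[, 2] > rect[4])) next
    if (is.null(best) || cg$area > best$area ||
        (cg$area == best$area && cg$level < best$level))
      best <- cg
  }
  best
}

#' Apply a DAG gate sequence
#'
#' Applies the steps of `config` in order. At each step the density is
#' estimated on the current events, contours are traced, the largest
#' closed contour inside the step's rectangle is selected, and events
#' inside that polygon (even-odd rule; boundary counts as inside) are kept.
#' When no closed contour qualifies, the plain rectangle gate is used as a
#' fallback and a warning is raised. Filtering is monotone (each step's
#' output is a subset of its input, order preserved) and deterministic.
#'
#' @param table an [EventTable-class].
#' @param config a [GateSequence-class]; an empty step list returns the
#'   input unchanged.
#' @return `list(table = <filtered EventTable>, report = <data.frame>)`
#'   where the report records `step`, `xRole`, `yRole`, `kept`, `total`,
#'   `fraction` and `fallbackUsed` per step.
#' @examples
#' et <- simulateDonor(donorPreset("spikein1_positive"), labProfile(),
#'                     nEvents = 20000, seed = 1)
#' et <- arcsinhTransform(et)
#' res <- dagFilter(et, defaultGateSequence())
#' res$report
#' @export
dagFilter <- function(table, config) {
  stopifnot(is(config, "GateSequence"))
  report <- data.frame(step = integer(), xRole = character(),
                       yRole = character(), kept = integer(),
                       total = integer(), fraction = numeric(),
                       fallbackUsed = logical(),
                       stringsAsFactors = FALSE)
  current <- table
  for (si in seq_along(config@steps)) {
    step <- config@steps[[si]]
    for (r in c(step@xRole, step@yRole))
      if (!r %in% channelRoles(current))
        stop(sprintf("gate step %d requires channel role '%s', absent ",
                     si, r), call. = FALSE)
    total <- nEvents(current)
    if (total == 0) {
      report[nrow(report) + 1L, ] <- list(si, step@xRole, step@yRole,
                                          0L, 0L, NA_real_, FALSE)
      next
    }
    dens <- estimateDensity2D(current, step, bins = config@bins,
                              smoothing = config@smoothing)
    contours <- extractContours(dens, nLevels = config@nLevels)
    sel <- selectLargestContour(contours, step@rect)
    x <- exprs(current)[, .roleCol(current, step@xRole)]
    y <- exprs(current)[, .roleCol(current, step@yRole)]
    fallback <- is.null(sel)
    keep <- if (fallback) {
      warning(sprintf(
        "step %d (%s/%s): no closed contour inside the rectangle; %s",
        si, step@xRole, step@yRole, "falling back to the rectangle gate"),
        call. = FALSE)
      x >= step@rect[1] & x <= step@rect[2] &
        y >= step@rect[3] & y <= step@rect[4]
    } else {
      .pointInPolygon(x, y, sel$vertices)
    }
    current <- current[which(keep), ]
    report[nrow(report) + 1L, ] <- list(si, step@xRole, step@yRole,
                                        nEvents(current), total,
                                        nEvents(current) / total, fallback)
  }
  list(table = current, report = report)
}
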