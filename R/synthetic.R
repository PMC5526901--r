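## Synthetic flow-cytometry sample generator.
##
## Emulates multimer-staining PBMC samples at the population level: each
## sample is a multinomial mixture of seven cell populations (debris,
## doublets, dead cells, non-T lymphocytes, CD3+CD8- T cells, CD8+
## multimer- T cells and CD8+ multimer+ T cells) whose channel intensities
## are drawn lognormally around per-population medians. Forward scatter
## height is tied to forward scatter area so that the singlet gate is
## meaningful, and doublets follow an FSC-A ~ 2 x FSC-H relation.
## Per-laboratory variation enters as multiplicative channel gain shifts
## and a spread multiplier on the lognormal shapes.
##
## The donor frequencies of the emulated proficiency panel and spike-in
## experiments are encoded in `donorPreset()`; all per-population
## fluorescence medians and spreads are package choices (no reference
## intensities exist for these scenario donors) and are documented as
## such in the methods vignette.

.DEFAULT_CHANNELS <- data.frame(
  shortName = c("FSC-A", "FSC-H", "SSC-A", "APC-Cy7-A", "FITC-A",
                "BV421-A", "PerCP-A", "PE-A", "APC-A"),
  stainLabel = c(NA, NA, NA, "LiveDead-NIR", "Dump-FITC", "CD3", "CD8",
                 "Multimer-PE", "Multimer-APC"),
  role = c("FSC-A", "FSC-H", "SSC-A", "viability", "dump", "CD3", "CD8",
           "multimer-PE", "multimer-APC"),
  stringsAsFactors = FALSE)

## Per-population channel medians and lognormal CVs (raw scale). The
## scatter geometry places debris low, lymphocytes in a compact blob and
## doublets at doubled FSC-A; dead cells share lymphocyte scatter but are
## bright on the viability channel, which is why a viability gate step is
## needed at all.
.popChannelDefaults <- function(multimerMedian = 9000, multimerCV = 0.25,
                                backgroundCV = 0.7) {
  bg <- function(cv = backgroundCV) c(90, cv)
  list(
    debris = list("FSC-A" = c(25e3, 0.25), "SSC-A" = c(12e3, 0.30),
                  viability = c(300, 1.0), dump = c(200, 1.0),
                  CD3 = bg(0.9), CD8 = bg(0.9),
                  "multimer-PE" = bg(0.9), "multimer-APC" = bg(0.9)),
    doublet = list("FSC-A" = c(190e3, 0.10), "SSC-A" = c(55e3, 0.20),
                   viability = c(250, 0.8), dump = c(2500, 1.2),
                   CD3 = c(3000, 1.0), CD8 = c(1500, 1.2),
                   "multimer-PE" = bg(0.8), "multimer-APC" = bg(0.8)),
    dead = list("FSC-A" = c(85e3, 0.15), "SSC-A" = c(45e3, 0.25),
                viability = c(20e3, 0.5), dump = c(600, 1.0),
                CD3 = c(400, 1.0), CD8 = c(250, 1.0),
                "multimer-PE" = c(200, 1.0), "multimer-APC" = c(200, 1.0)),
    nonT_lymph = list("FSC-A" = c(100e3, 0.10), "SSC-A" = c(30e3, 0.18),
                      viability = c(200, 0.7), dump = c(8000, 0.5),
                      CD3 = c(100, 0.8), CD8 = c(110, 0.8),
                      "multimer-PE" = bg(), "multimer-APC" = bg()),
    CD3pos_CD8neg = list("FSC-A" = c(100e3, 0.10), "SSC-A" = c(30e3, 0.18),
                         viability = c(200, 0.7), dump = c(120, 0.8),
                         CD3 = c(6000, 0.35), CD8 = c(120, 0.8),
                         "multimer-PE" = bg(), "multimer-APC" = bg()),
    CD8pos_multimer_neg = list("FSC-A" = c(100e3, 0.10),
                               "SSC-A" = c(30e3, 0.18),
                               viability = c(200, 0.7), dump = c(120, 0.8),
                               CD3 = c(6000, 0.35), CD8 = c(9000, 0.35),
                               "multimer-PE" = bg(),
                               "multimer-APC" = bg()),
    CD8pos_multimer_pos = list("FSC-A" = c(100e3, 0.10),
                               "SSC-A" = c(30e3, 0.18),
                               viability = c(200, 0.7), dump = c(120, 0.8),
                               CD3 = c(6000, 0.35), CD8 = c(9000, 0.35),
                               "multimer-PE" = c(multimerMedian, multimerCV),
                               "multimer-APC" = c(multimerMedian,
                                                  multimerCV)))
}

#' Describe one synthetic cell population
#'
#' @param name population name, one of `"debris"`, `"doublet"`, `"dead"`,
#'   `"nonT_lymph"`, `"CD3pos_CD8neg"`, `"CD8pos_multimer_neg"`,
#'   `"CD8pos_multimer_pos"`.
#' @param fraction proportion of total events in `[0, 1]`.
#' @param channels named list: role -> `c(median, cv)` on the raw scale.
#'   Missing roles fall back to the package defaults for that population.
#' @return A `PopulationSpec` (list).
#' @export
populationSpec <- function(name, fraction, channels = list()) {
  stopifnot(name %in% .POPULATIONS, fraction >= 0, fraction <= 1)
  defaults <- .popChannelDefaults()[[name]]
  for (role in names(channels)) defaults[[role]] <- channels[[role]]
  if (any(vapply(defaults, function(p) p[2] <= 0, logical(1))))
    stop("channel cvs must be positive", call. = FALSE)
  structure(list(name = name, fraction = fraction, channels = defaults),
            class = "PopulationSpec")
}

#' Build a donor population mixture
#'
#' Composes the seven-population mixture of a synthetic donor from a
#' multimer-positive frequency stated either as percent of live single
#' lymphocytes or as percent of CD8+ T cells (exactly one of the two).
#' The acquisition-level composition is fixed: 8% debris, 7% doublets, 8%
#' dead cells, leaving 77% live single lymphocytes, of which 25% are non-T
#' lymphocytes and `cd8FracOfLymph` are CD8+ T cells.
#'
#' @param multimerFreqLymph multimer+ frequency in percent of live single
#'   lymphocytes.
#' @param multimerFreqCD8 multimer+ frequency in percent of CD8+ T cells.
#' @param cd8FracOfLymph CD8+ fraction of live single lymphocytes
#'   (default 0.30).
#' @param separation `"distinct"` (default: bright, tight multimer signal
#'   with clean background, as in a high-avidity spike-in staining) or
#'   `"noisy_lab"` (dimmer, broader multimer signal over a noisier
#'   background, emulating heterogeneous proficiency-panel stainings).
#' @return List of [populationSpec()] objects with fractions summing to 1.
#' @export
donorPopulations <- function(multimerFreqLymph = NULL,
                             multimerFreqCD8 = NULL,
                             cd8FracOfLymph = 0.30,
                             separation = c("distinct", "noisy_lab")) {
  separation <- match.arg(separation)
  fLS <- if (!is.null(multimerFreqLymph)) multimerFreqLymph / 100
         else if (!is.null(multimerFreqCD8))
           multimerFreqCD8 / 100 * cd8FracOfLymph
         else stop("give multimerFreqLymph or multimerFreqCD8",
                   call. = FALSE)
  if (fLS > cd8FracOfLymph)
    stop("multimer+ fraction exceeds the CD8+ compartment", call. = FALSE)
  liveSingle <- 0.77
  fractions <- c(debris = 0.08, doublet = 0.07, dead = 0.08,
                 nonT_lymph = liveSingle * 0.25,
                 CD3pos_CD8neg = liveSingle * (0.75 - cd8FracOfLymph),
                 CD8pos_multimer_neg = liveSingle * (cd8FracOfLymph - fLS),
                 CD8pos_multimer_pos = liveSingle * fLS)
  chan <- if (separation == "distinct") list()
          else list("CD8pos_multimer_pos" =
                      list("multimer-PE" = c(3500, 0.45),
                           "multimer-APC" = c(3500, 0.45)))
  lapply(names(fractions), function(nm)
    populationSpec(nm, unname(fractions[nm]),
                   channels = if (nm %in% names(chan)) chan[[nm]]
                              else list()))
}

#' Donor presets encoding the emulated study frequencies
#'
#' Returns the population mixture of a named donor sample. Proficiency
#' panel donors: `"518_EBV"` (0.3% of live single lymphocytes, 1.13% of
#' CD8), `"518_FLU"` (0.02% / 0.09%), `"519_EBV"` (1.5% / 5.33%),
#' `"519_FLU"` (0.01% / 0.04%). Spike-in experiments:
#' `"spikein1_positive"` (1.7% of live single lymphocytes),
#' `"spikein2_positive"` (CMV 0.87% of lymphocytes on the PE multimer),
#' and the corresponding `"*_negative"` donors carrying no multimer+
#' population. The CD8+ compartment size is set per donor so that both
#' reporting denominators reproduce their stated frequencies.
#'
#' @param name preset name (see Details).
#' @param separation passed to [donorPopulations()].
#' @return List of [populationSpec()] objects.
#' @export
donorPreset <- function(name, separation = "distinct") {
  presets <- list(
    "518_EBV" = list(lymph = 0.3,  cd8frac = 0.003 / 0.0113),
    "518_FLU" = list(lymph = 0.02, cd8frac = 0.0002 / 0.0009),
    "519_EBV" = list(cd8 = 5.33,   cd8frac = 0.015 / 0.0533),
    "519_FLU" = list(lymph = 0.01, cd8frac = 0.0001 / 0.0004),
    "spikein1_positive" = list(lymph = 1.7,  cd8frac = 0.30),
    "spikein1_negative" = list(lymph = 0,    cd8frac = 0.30),
    "spikein2_positive" = list(lymph = 0.87, cd8frac = 0.30),
    "spikein2_negative" = list(lymph = 0,    cd8frac = 0.30))
  if (!name %in% names(presets))
    stop(sprintf("unknown donor preset '%s' (available: %s)", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  p <- presets[[name]]
  donorPopulations(multimerFreqLymph = p$lymph, multimerFreqCD8 = p$cd8,
                   cd8FracOfLymph = p$cd8frac, separation = separation)
}

#' Laboratory acquisition profile
#'
#' Captures the between-laboratory heterogeneity of the emulated panel:
#' per-channel multiplicative gain shifts, a spread multiplier on all
#' lognormal shapes, and which channel roles the lab's panel includes
#' (at minimum CD8 and a multimer channel, plus CD3 or a dump channel).
#'
#' @param labId identifier string.
#' @param gainShift named numeric vector of per-role multiplicative
#'   factors (> 0); roles not named keep gain 1.
#' @param backgroundSpread multiplier (> 0) applied to every channel cv.
#' @param panel character vector of roles present.
#' @return A `LabProfile` (list).
#' @export
labProfile <- function(labId = "lab1", gainShift = numeric(),
                       backgroundSpread = 1,
                       panel = c("FSC-A", "FSC-H", "SSC-A", "viability",
                                 "dump", "CD3", "CD8", "multimer-PE")) {
  if (any(gainShift <= 0)) stop("gain shifts must be > 0", call. = FALSE)
  if (backgroundSpread <= 0)
    stop("'backgroundSpread' must be > 0", call. = FALSE)
  if (!"CD8" %in% panel || !any(.MULTIMER_ROLES %in% panel) ||
      !any(c("CD3", "dump") %in% panel))
    stop("panel must include CD8, a multimer channel, and CD3 or dump",
         call. = FALSE)
  structure(list(labId = labId, gainShift = gainShift,
                 backgroundSpread = backgroundSpread, panel = panel),
            class = "LabProfile")
}

#' Simulate one labeled donor sample
#'
#' Draws population sizes multinomially from the mixture fractions, then
#' draws each event's channel intensities lognormally around the
#' population's medians (times the lab's gain shift) with the population's
#' cvs (times the lab's spread multiplier). FSC-H is tied to FSC-A
#' (singlets: `FSC-H = 0.95 x FSC-A` with 5% jitter; doublets:
#' `FSC-A = 2 x FSC-H` with 5% jitter) so the FSC-H/FSC-A singlet gate
#' discriminates doublets. Every event carries its ground-truth population
#' label.
#'
#' @param populations list of [populationSpec()] (fractions summing to 1).
#' @param profile a [labProfile()].
#' @param nEvents number of events to draw.
#' @param seed integer seed; the draw is reproducible.
#' @return A labeled [EventTable-class] (`transformState = "raw"`).
#' @examples
#' et <- simulateDonor(donorPreset("519_EBV"), labProfile(),
#'                     nEvents = 5000, seed = 7)
#' table(eventLabels(et))
#' @export
simulateDonor <- function(populations, profile = labProfile(),
                          nEvents, seed = 1L) {
  stopifnot(nEvents >= 1)
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("population fractions must sum to 1", call. = FALSE)
  panel <- profile$panel
  if (!any(.MULTIMER_ROLES %in% panel))
    stop("lab panel lacks a multimer channel role", call. = FALSE)
  chans <- .DEFAULT_CHANNELS[.DEFAULT_CHANNELS$role %in% panel, ,
                             drop = FALSE]
  rownames(chans) <- NULL

  gain <- function(role) {
    g <- profile$gainShift
    if (role %in% names(g)) g[[role]] else 1
  }

  .withSeed(seed, {
    sizes <- as.vector(rmultinom(1, nEvents, fr))
    blocks <- vector("list", length(populations))
    for (p in seq_along(populations)) {
      np <- sizes[p]
      spec <- populations[[p]]
      if (np == 0) { blocks[[p]] <- NULL; next }
      mat <- matrix(0, np, nrow(chans))
      colnames(mat) <- chans$shortName
      fscA <- NULL
      for (ci in seq_len(nrow(chans))) {
        role <- chans$role[ci]
        if (role == "FSC-H") next   # derived from FSC-A below
        par <- spec$channels[[role]]
        if (is.null(par))
          stop(sprintf("population '%s' lacks parameters for role '%s'",
                       spec$name, role), call. = FALSE)
        x <- .rlnormMedian(np, par[1] * gain(role),
                           par[2] * profile$backgroundSpread)
        if (role == "FSC-A") fscA <- x
        mat[, ci] <- x
      }
      hi <- which(chans$role == "FSC-H")
      if (length(hi)) {
        jitter <- exp(rnorm(np, sd = 0.05))
        if (spec$name == "doublet") {
          # doublets: area doubled relative to height
          fscH <- fscA / 2 * jitter
        } else {
          fscH <- 0.95 * fscA * jitter
        }
        mat[, hi] <- fscH
      }
      blocks[[p]] <- mat
    }
    keep <- !vapply(blocks, is.null, logical(1))
    mat <- do.call(rbind, blocks[keep])
    labels <- rep(vapply(populations, `[[`, character(1), "name")[keep],
                  sizes[keep])
    perm <- sample.int(nrow(mat))
    EventTable(mat[perm, , drop = FALSE], channels = chans,
               labels = labels[perm])
  })
}

#' Mix a positive and a negative donor (spike-in)
#'
#' Resamples events (with replacement) from a multimer-positive donor and a
#' negative donor in a given proportion, emulating one step of a spike-in
#' dilution. Labels and donor of origin (`sourceTable()`: 1 = positive,
#' 2 = negative) are preserved; the number of positive-donor events is
#' binomially distributed around `positiveFraction * nEvents`.
#'
#' @param positive,negative labeled [EventTable-class] objects with
#'   identical channel sets.
#' @param positiveFraction proportion of events drawn from the positive
#'   donor, in `[0, 1]`.
#' @param nEvents total output events.
#' @param seed integer seed.
#' @return A labeled [EventTable-class] of exactly `nEvents` events.
#' @export
mixSpikeIn <- function(positive, negative, positiveFraction, nEvents,
                       seed = 1L) {
  stopifnot(positiveFraction >= 0, positiveFraction <= 1, nEvents >= 1)
  if (!identical(channelInfo(positive)$shortName,
                 channelInfo(negative)$shortName))
    stop("channel mismatch between positive and negative donor",
         call. = FALSE)
  .withSeed(seed, {
    nPos <- rbinom(1, nEvents, positiveFraction)
    if (positiveFraction == 1) nPos <- nEvents
    if (positiveFraction == 0) nPos <- 0L
    iPos <- if (nPos > 0) sample.int(nEvents(positive), nPos,
                                     replace = TRUE) else integer()
    iNeg <- if (nPos < nEvents) sample.int(nEvents(negative),
                                           nEvents - nPos,
                                           replace = TRUE) else integer()
    mat <- rbind(exprs(positive)[iPos, , drop = FALSE],
                 exprs(negative)[iNeg, , drop = FALSE])
    labs <- c(eventLabels(positive)[iPos], eventLabels(negative)[iNeg])
    src <- c(rep(1L, length(iPos)), rep(2L, length(iNeg)))
    perm <- sample.int(nrow(mat))
    EventTable(mat[perm, , drop = FALSE],
               channels = channelInfo(positive),
               labels = if (length(labs)) labs[perm] else NULL,
               sourceTable = src[perm])
  })
}

#' Spike-in dilution series design
#'
#' @param f0 starting multimer+ frequency, percent of live single
#'   lymphocytes, in `(0, 100]`.
#' @param d dilution factor (> 1).
#' @param nSteps number of dilution steps (>= 1).
#' @param nEventsPerSample events per simulated sample (default 2e5).
#' @param duplicates replicate samples per step (default 2).
#' @param includePureNegative append a pure negative-donor sample.
#' @param seed integer seed.
#' @return A `SpikeInDesign` (list).
#' @export
spikeInDesign <- function(f0 = 1.7, d = 5, nSteps = 7,
                          nEventsPerSample = 2e5, duplicates = 2,
                          includePureNegative = FALSE, seed = 1L) {
  stopifnot(f0 > 0, f0 <= 100, d > 1, nSteps >= 1, duplicates >= 1)
  structure(list(f0 = f0, d = d, nSteps = nSteps,
                 nEventsPerSample = nEventsPerSample,
                 duplicates = duplicates,
                 includePureNegative = includePureNegative,
                 seed = as.integer(seed)),
            class = "SpikeInDesign")
}

#' Theoretical multimer+ frequency at a dilution step
#'
#' Step `k` (1-based) of a series starting at `f0` percent with dilution
#' factor `d` has theoretical frequency `f0 * d^-(k-1)` percent.
#'
#' @param design a [spikeInDesign()].
#' @param k step index, `1 <= k <= nSteps`.
#' @return Frequency in percent.
#' @examples
#' theoreticalFrequency(spikeInDesign(f0 = 1.7, d = 5, nSteps = 7), 7)
#' @export
theoreticalFrequency <- function(design, k) {
  if (any(k < 1 | k > design$nSteps))
    stop(sprintf("step index %s out of range 1..%d",
                 paste(k[k < 1 | k > design$nSteps], collapse = ","),
                 design$nSteps), call. = FALSE)
  design$f0 * design$d^-(k - 1)
}

#' Generate a spike-in dilution series
#'
#' Mixes the positive donor into the negative donor at fractions
#' `d^-(k-1)` for steps `k = 1..nSteps`, each in `duplicates` replicates
#' under distinct sub-seeds, optionally appending a pure-negative sample
#' (theoretical frequency 0).
#'
#' @param design a [spikeInDesign()].
#' @param positive,negative labeled donor [EventTable-class] objects.
#' @return List of entries `list(table, theoretical, step, duplicate,
#'   seed)`, ordered by step then duplicate; the pure-negative sample, when
#'   requested, is last with `step = NA`.
#' @export
makeDilutionSeries <- function(design, positive, negative) {
  out <- list()
  idx <- 0L
  for (k in seq_len(design$nSteps)) {
    for (dup in seq_len(design$duplicates)) {
      idx <- idx + 1L
      s <- .subSeed(design$seed, idx)
      tab <- mixSpikeIn(positive, negative, design$d^-(k - 1),
                        design$nEventsPerSample, seed = s)
      out[[idx]] <- list(table = tab,
                         theoretical = theoreticalFrequency(design, k),
                         step = k, duplicate = dup, seed = s)
    }
  }
  if (design$includePureNegative) {
    idx <- idx + 1L
    s <- .subSeed(design$seed, idx)
    tab <- mixSpikeIn(positive, negative, 0, design$nEventsPerSample,
                      seed = s)
    out[[idx]] <- list(table = tab, theoretical = 0, step = NA_integer_,
                       duplicate = 1L, seed = s)
  }
  out
}
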