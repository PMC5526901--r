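test_that("label bookkeeping is exact and fractions are validated", {
  et <- simulateDonor(donorPreset("spikein1_negative"), labProfile(),
                      20000, seed = 1)
  expect_length(eventLabels(et), nEvents(et))
  # zero multimer fraction: no multimer+ labels at all
  expect_equal(sum(eventLabels(et) == "CD8pos_multimer_pos"), 0)
  # fractions must sum to one
  bad <- donorPreset("519_EBV")
  bad[[1]]$fraction <- bad[[1]]$fraction + 0.1
  expect_error(simulateDonor(bad, labProfile(), 100, seed = 1), "sum to 1")
  # panel without a multimer channel is a config error
  expect_error(labProfile(panel = c("FSC-A", "CD3", "CD8")), "multimer")
})

test_that("realized multimer+ counts follow the configured frequency", {
  # spike-in 1 donor: 1.7% of live single lymphocytes
  et <- simulateDonor(donorPreset("spikein1_positive"), labProfile(),
                      1e5, seed = 21)
  lab <- eventLabels(et)
  nLS <- sum(lab %in% LIVE_SINGLE_LABELS)
  nPos <- sum(lab == "CD8pos_multimer_pos")
  expect_lt(abs(nPos - nLS * 0.017), 3 * sqrt(nLS * 0.017 * 0.983))
  # high-frequency donor: 5.33% of CD8+ T cells
  et <- simulateDonor(donorPreset("519_EBV"), labProfile(), 1e5, seed = 22)
  lab <- eventLabels(et)
  nCD8 <- sum(lab %in% CD8_LABELS)
  nPos <- sum(lab == "CD8pos_multimer_pos")
  expect_lt(abs(nPos - nCD8 * 0.0533), 3 * sqrt(nCD8 * 0.0533 * 0.9467))
})

test_that("channel medians track configured location times gain shift", {
  prof <- labProfile(gainShift = c(CD8 = 1.5))
  et <- simulateDonor(donorPreset("519_EBV"), prof, 1e5, seed = 33)
  lab <- eventLabels(et)
  cd8col <- which(channelRoles(et) == "CD8")
  x <- exprs(et)[lab %in% CD8_LABELS, cd8col]
  # configured CD8+ location 9000, shifted by 1.5; median SE via the
  # asymptotic formula for the lognormal median
  sigma <- sqrt(log(1 + 0.35^2))
  se <- 9000 * 1.5 * sigma * sqrt(pi / (2 * length(x)))
  expect_lt(abs(median(x) - 9000 * 1.5), 3 * se)
})

test_that("doublets follow the FSC-A ~ 2 x FSC-H relation", {
  et <- simulateDonor(donorPreset("519_EBV"), labProfile(), 5e4, seed = 5)
  lab <- eventLabels(et)
  a <- exprs(et)[, which(channelRoles(et) == "FSC-A")]
  h <- exprs(et)[, which(channelRoles(et) == "FSC-H")]
  ratioD <- median(a[lab == "doublet"] / h[lab == "doublet"])
  ratioS <- median(a[lab == "CD3pos_CD8neg"] / h[lab == "CD3pos_CD8neg"])
  expect_equal(ratioD, 2, tolerance = 0.05)
  expect_equal(ratioS, 1 / 0.95, tolerance = 0.05)
})

test_that("theoreticalFrequency follows f0 * d^-(k-1)", {
  d1 <- spikeInDesign(f0 = 1.7, d = 5, nSteps = 7)
  expect_identical(theoreticalFrequency(d1, 1), 1.7)
  expect_equal(theoreticalFrequency(d1, 7), 1.088e-4, tolerance = 1e-7)
  # the published series end point: rounds to 0.0001%
  expect_equal(round(theoreticalFrequency(d1, 7), 4), 1e-4)
  d2 <- spikeInDesign(f0 = 0.87, d = 2, nSteps = 9)
  expect_equal(theoreticalFrequency(d2, 4), 0.10875)
  expect_error(theoreticalFrequency(d1, 8), "out of range")
  expect_error(theoreticalFrequency(d1, 0), "out of range")
  # strictly decreasing in k for d > 1
  f <- theoreticalFrequency(d1, 1:7)
  expect_true(all(diff(f) < 0))
})

test_that("mixSpikeIn mixes donors in the requested proportion", {
  prof <- labProfile()
  pos <- simulateDonor(donorPreset("spikein1_positive"), prof, 5e4,
                       seed = 41)
  neg <- simulateDonor(donorPreset("spikein1_negative"), prof, 5e4,
                       seed = 42)
  # fraction 1: everything from the positive donor
  m1 <- mixSpikeIn(pos, neg, 1, 10000, seed = 1)
  expect_true(all(sourceTable(m1) == 1L))
  expect_equal(nEvents(m1), 10000)
  # fraction 0.2 of a 1.7% donor: expect 0.34% of live single lymphocytes
  m2 <- mixSpikeIn(pos, neg, 0.2, 2e5, seed = 2)
  lab <- eventLabels(m2)
  nLS <- sum(lab %in% LIVE_SINGLE_LABELS)
  nPos <- sum(lab == "CD8pos_multimer_pos")
  expect_lt(abs(nPos - nLS * 0.0034), 3 * sqrt(nLS * 0.0034))
  # channel mismatch
  expect_error(mixSpikeIn(pos, neg[, 1:5], 0.5, 100), "mismatch")
})

test_that("makeDilutionSeries produces the designed ladder", {
  prof <- labProfile()
  pos <- simulateDonor(donorPreset("spikein1_positive"), prof, 2e4,
                       seed = 51)
  neg <- simulateDonor(donorPreset("spikein1_negative"), prof, 2e4,
                       seed = 52)
  des <- spikeInDesign(f0 = 1.7, d = 5, nSteps = 7,
                       nEventsPerSample = 5000, duplicates = 2,
                       includePureNegative = TRUE, seed = 3)
  series <- makeDilutionSeries(des, pos, neg)
  expect_length(series, 15)  # 7 steps x 2 duplicates + pure negative
  th <- vapply(series[1:14], `[[`, numeric(1), "theoretical")
  expect_true(all(diff(th[seq(1, 13, 2)]) < 0))
  # duplicates share the theoretical value but differ in realized events
  expect_identical(series[[1]]$theoretical, series[[2]]$theoretical)
  expect_false(identical(exprs(series[[1]]$table),
                         exprs(series[[2]]$table)))
  # pure negative: frequency 0, no spiked labels
  last <- series[[15]]
  expect_identical(last$theoretical, 0)
  expect_equal(sum(eventLabels(last$table) == "CD8pos_multimer_pos"), 0)
  expect_true(all(sourceTable(last$table) == 2L))
})
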