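test_that("density estimation normalizes and localizes mass", {
  # delta input: all mass near the point
  et <- makeTable(cbind(rep(5, 100), rep(5, 100), rep(7, 100)))
  st <- gateStep("FSC-A", "SSC-A", c(0, 10, 0, 10))
  dg <- estimateDensity2D(et, st, bins = 64, smoothing = 2)
  expect_equal(sum(dg$grid), 1, tolerance = 1e-9)
  ix <- which(dg$grid == max(dg$grid), arr.ind = TRUE)[1, ]
  w <- 6  # 3 x smoothing bins
  sub <- dg$grid[max(1, ix[1] - w):min(64, ix[1] + w),
                 max(1, ix[2] - w):min(64, ix[2] + w)]
  expect_gt(sum(sub), 0.99)
  # empty input errors
  expect_error(estimateDensity2D(et[integer(0), ], st), "zero events")
})

test_that("density is flat on a regular uniform lattice", {
  g <- as.matrix(expand.grid(x = seq(0, 1, length.out = 256),
                             y = seq(0, 1, length.out = 256)))
  et <- makeTable(cbind(g[, 1], g[, 1], g[, 2]))
  st <- gateStep("FSC-A", "SSC-A", c(0, 1, 0, 1))
  dg <- estimateDensity2D(et, st, bins = 128, smoothing = 2)
  interior <- dg$grid[20:109, 20:109]
  expect_lt(max(interior) / min(interior), 1.5)
  expect_equal(sum(dg$grid), 1, tolerance = 1e-9)
})

test_that("contours of an isotropic Gaussian are near-circular", {
  set.seed(7)
  n <- 50000
  et <- makeTable(cbind(rnorm(n), rnorm(n), rnorm(n)))
  st <- gateStep("FSC-A", "SSC-A", c(-5, 5, -5, 5))
  dg <- estimateDensity2D(et, st, bins = 64, smoothing = 2)
  cts <- extractContours(dg, nLevels = 16)
  expect_gt(length(cts), 5)
  for (cg in cts) {
    r <- sqrt(cg$vertices[, 1]^2 + cg$vertices[, 2]^2)
    expect_lt(sd(r) / mean(r), 0.10)
  }
  # flat zero grid gives no contours
  flat <- dg
  flat$grid[] <- 0
  expect_identical(extractContours(flat, 8), list())
})

test_that("a bimodal sample yields two disjoint high-level contours", {
  set.seed(8)
  n <- 20000
  x <- c(rnorm(n, -3, 0.5), rnorm(n, 3, 0.5))
  y <- c(rnorm(n, 0, 0.5), rnorm(n, 0, 0.5))
  et <- makeTable(cbind(x, x, y))
  dg <- estimateDensity2D(et, gateStep("FSC-A", "SSC-A", c(-6, 6, -3, 3)),
                          bins = 128, smoothing = 2)
  cts <- extractContours(dg, nLevels = 8)
  high <- Filter(function(cg) cg$level > 0.75 * max(dg$grid), cts)
  expect_gte(length(high), 2)
  centersX <- vapply(high, function(cg) mean(cg$vertices[, 1]), numeric(1))
  expect_true(any(centersX < 0) && any(centersX > 0))
})

test_that("the selected contour's mass matches the Gaussian oracle", {
  set.seed(9)
  n <- 2e5
  sx <- rnorm(n); sy <- rnorm(n)
  et <- makeTable(cbind(sx, sx, sy))
  st <- gateStep("FSC-A", "SSC-A", c(-6, 6, -6, 6))
  dg <- estimateDensity2D(et, st, bins = 128, smoothing = 2)
  cts <- extractContours(dg, nLevels = 32)
  sel <- selectLargestContour(cts, st@rect)
  expect_false(is.null(sel))
  kept <- flowDAG:::.pointInPolygon(sx, sy, sel$vertices)
  # analytic mass inside an iso-density contour of a 2D Gaussian at level
  # c (in per-bin mass units): 1 - c / fmax, with fmax the peak bin mass
  # of the smoothing-widened density
  binA <- diff(dg$xEdges)[1] * diff(dg$yEdges)[1]
  sigEff2 <- 1 + (2 * diff(dg$xEdges)[1])^2
  fmax <- binA / (2 * pi * sigEff2)
  expected <- 1 - sel$level / fmax
  expect_equal(mean(kept), expected, tolerance = 0.02)
})

test_that("contour selection respects the rectangle and tie rules", {
  # two clusters; only one inside the rectangle
  set.seed(10)
  n <- 30000
  x <- c(rnorm(n, 2, 0.4), rnorm(n, 8, 0.4))
  y <- c(rnorm(n, 2, 0.4), rnorm(n, 8, 0.4))
  labs <- rep(c("in", "out"), each = n)
  et <- makeTable(cbind(x, x, y), labels = labs)
  rect <- c(0, 4.5, 0, 4.5)
  dg <- estimateDensity2D(et, gateStep("FSC-A", "SSC-A", rect),
                          bins = 128, smoothing = 2)
  sel <- selectLargestContour(extractContours(dg, 32), rect)
  expect_false(is.null(sel))
  kept <- flowDAG:::.pointInPolygon(x, y, sel$vertices)
  expect_gt(mean(labs[kept] == "in"), 0.95)
  # empty contour list
  expect_null(selectLargestContour(list(), rect))
})

test_that("dagFilter is monotone, deterministic and label-accurate", {
  et <- simulateDonor(donorPreset("spikein1_positive"), labProfile(),
                      1e5, seed = 77)
  tt <- arcsinhTransform(et)
  cfg <- defaultGateSequence()
  res <- dagFilter(tt, cfg)
  # subset property, order preserved
  expect_true(all(eventIds(res$table) %in% eventIds(tt)))
  expect_false(is.unsorted(match(eventIds(res$table), eventIds(tt))))
  expect_false(anyDuplicated(eventIds(res$table)) > 0)
  # per-step report is monotone
  expect_true(all(res$report$kept <= res$report$total))
  # determinism: no randomness anywhere in DAG
  res2 <- dagFilter(tt, cfg)
  expect_identical(eventIds(res2$table), eventIds(res$table))
  expect_identical(res2$report, res$report)
  # >= 90% purity and >= 90% recall of live single lymphocytes
  lab <- eventLabels(res$table)
  labAll <- eventLabels(tt)
  expect_gt(mean(lab %in% LIVE_SINGLE_LABELS), 0.90)
  expect_gt(sum(lab %in% LIVE_SINGLE_LABELS) /
              sum(labAll %in% LIVE_SINGLE_LABELS), 0.90)
  # empty step list: identity
  ident <- dagFilter(tt, gateSequence())
  expect_identical(eventIds(ident$table), eventIds(tt))
  # missing role is a config error naming the role
  noViab <- tt[, which(channelRoles(tt) != "viability")]
  expect_error(dagFilter(noViab, cfg), "viability")
})

test_that("dagFilter falls back to the rectangle when no contour fits", {
  set.seed(11)
  et <- makeTable(cbind(rnorm(5000, 5, 1), rnorm(5000, 5, 1),
                        rnorm(5000, 5, 1)))
  # rectangle far too small for any closed contour
  cfg <- gateSequence(list(gateStep("FSC-A", "SSC-A",
                                    c(4.9, 5.1, 4.9, 5.1))))
  expect_warning(res <- dagFilter(et, cfg), "rectangle")
  expect_true(res$report$fallbackUsed[1])
  ex <- exprs(res$table)
  expect_true(all(ex[, 1] >= 4.9 & ex[, 1] <= 5.1))
})
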