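test_that("FCS write/read round-trips events, channels and values", {
  et <- simulateDonor(donorPreset("519_EBV"), labProfile(), 1000, seed = 3)
  p <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(et, p)
  et2 <- readFCS(p)
  expect_equal(nEvents(et2), nEvents(et))
  expect_identical(channelInfo(et2)$shortName, channelInfo(et)$shortName)
  expect_identical(channelInfo(et2)$stainLabel, channelInfo(et)$stainLabel)
  # float32 storage: relative error bounded by single precision
  expect_lt(max(abs(exprs(et2) - exprs(et)) /
                  pmax(abs(exprs(et)), 1)), 1e-6)
  # labels travel in the CSV sidecar
  expect_true(file.exists(paste0(p, ".labels.csv")))
  expect_identical(eventLabels(et2), eventLabels(et))
})

test_that("read-back column means match the generator's table", {
  # oracle: the in-memory table the file was written from
  et <- simulateDonor(donorPreset("518_EBV"), labProfile(), 2000, seed = 9)
  p <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(et, p)
  got <- colMeans(exprs(readFCS(p)))
  want <- colMeans(exprs(et))
  expect_true(all(abs(got - want) / abs(want) < 1e-6))
})

test_that("two writes are byte-identical except $DATE/$BTIM", {
  et <- makeTable(matrix(runif(50, 10, 1000), 10, 5))
  p1 <- withr::local_tempfile(fileext = ".fcs")
  p2 <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(et, p1)
  writeFCS(et, p2)
  a <- readBin(p1, "raw", file.size(p1))
  b <- readBin(p2, "raw", file.size(p2))
  expect_equal(length(a), length(b))
  # header+TEXT are ASCII; mask the timestamp keywords there, then
  # require the binary DATA bytes to match exactly
  mask <- function(raw) {
    textEnd <- as.integer(trimws(rawToChar(raw[19:26])))
    s <- rawToChar(raw[1:(textEnd + 1)])
    s <- sub("\\$DATE/[^/]*/", "$DATE/X/", s)
    s <- sub("\\$BTIM/[^/]*/", "$BTIM/X/", s)
    list(text = s, data = raw[(textEnd + 2):length(raw)])
  }
  expect_identical(mask(a), mask(b))
})

test_that("malformed and truncated files raise format errors", {
  et <- makeTable(matrix(runif(40, 1, 10), 10, 4))
  p <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(et, p)
  raw <- readBin(p, "raw", file.size(p))
  # truncated mid-DATA: no partial table
  p2 <- withr::local_tempfile(fileext = ".fcs")
  writeBin(raw[1:(length(raw) - 37)], p2)
  expect_error(readFCS(p2), "truncated DATA")
  # wrong magic
  bad <- raw
  bad[1:6] <- charToRaw("NOTFCS")
  writeBin(bad, p2)
  expect_error(readFCS(p2), "version")
  expect_error(readFCS(tempfile()), "does not exist")
})

test_that("writing a table with zero channels is refused", {
  et <- makeTable(matrix(runif(10), 5, 2))
  broken <- et[, integer(0)]
  expect_error(writeFCS(broken, tempfile()), "zero channels")
})

test_that("harmonizeChannels renames without touching values", {
  et <- EventTable(matrix(1:8, 4, 2),
                   channels = data.frame(
                     shortName = c("PE-A", "PE-Cy7-A"),
                     stainLabel = c(NA, "CD19"),
                     role = "unused", stringsAsFactors = FALSE))
  et2 <- harmonizeChannels(et, c("PE-A" = "Multimer-PE"))
  expect_identical(channelInfo(et2)$stainLabel[1], "Multimer-PE")
  expect_identical(exprs(et2), exprs(et))
  # empty map: identity
  expect_identical(harmonizeChannels(et, list()), et)
  # stain label matched before short name
  et3 <- harmonizeChannels(et, c("CD19" = "Dump"))
  expect_identical(channelInfo(et3)$stainLabel[2], "Dump")
  # conflict: two sources onto one target
  expect_error(harmonizeChannels(et, c("PE-A" = "X", "PE-Cy7-A" = "X")),
               "conflict")
  # unmatched key warns but does not fail
  expect_warning(harmonizeChannels(et, c("nope" = "Y")), "matches no")
})

test_that("arcsinh transform obeys its closed form and state rules", {
  et <- makeTable(cbind(c(0, 150, 300), c(0, 150, 300), c(0, 150, 300),
                        c(0, 150, 300), c(0, 150, 300), c(0, 150, 300)))
  tt <- arcsinhTransform(et, cofactor = 150)
  # scatter untouched, fluorescence mapped
  expect_identical(unname(exprs(tt)[, 1]), c(0, 150, 300))
  expect_equal(unname(exprs(tt)[1, 4]), 0)
  expect_equal(unname(exprs(tt)[2, 4]), asinh(1), tolerance = 1e-12)
  expect_equal(unname(exprs(tt)[2, 4]), 0.8814, tolerance = 1e-4)
  # monotone
  expect_true(all(diff(exprs(tt)[, 5]) > 0))
  expect_identical(transformState(tt), "arcsinh")
  expect_error(arcsinhTransform(tt), "already")
  expect_error(arcsinhTransform(et, cofactor = -1), "positive")
})

test_that("subsampleConcat draws exactly min(n, size) per table", {
  prof <- labProfile()
  pops <- donorPreset("519_EBV")
  tabs <- lapply(1:3, function(i)
    simulateDonor(pops, prof, c(5000, 3000, 1200)[i], seed = i))
  expect_warning(cons <- subsampleConcat(tabs, 2000, seed = 4),
                 "only 1200")
  expect_equal(nEvents(cons), 2000 + 2000 + 1200)
  expect_equal(as.vector(table(sourceTable(cons))), c(2000, 2000, 1200))
  # deterministic given the seed
  cons2 <- suppressWarnings(subsampleConcat(tabs, 2000, seed = 4))
  expect_identical(exprs(cons2), exprs(cons))
  # single table at full size: a permutation
  perm <- subsampleConcat(tabs[1], 5000, seed = 1)
  expect_equal(nEvents(perm), 5000)
  expect_equal(sort(exprs(perm)[, 1]), sort(exprs(tabs[[1]])[, 1]))
  # channel mismatch is an error naming the difference
  other <- tabs[[2]][, 1:5]
  expect_error(subsampleConcat(list(tabs[[1]], other), 100),
               "channel mismatch")
})
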