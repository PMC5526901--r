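test_that("three well-separated blobs give exactly three clusters", {
  set.seed(5)
  mu <- rbind(c(0.2, 0.2), c(0.8, 0.3), c(0.5, 0.8))
  n <- 30000
  g <- sample(1:3, n, replace = TRUE)
  X <- mu[g, ] + matrix(rnorm(2 * n, sd = 0.02), n, 2)
  et <- makeTable(X, roles = c("CD8", "multimer-PE"))
  fit <- gridDensityCluster(et, roles = c("CD8", "multimer-PE"))
  expect_equal(nClusters(fit$model), 3)
  cent <- centroids(fit$model)
  for (b in 1:3) {
    dmin <- min(sqrt(rowSums(sweep(cent, 2, mu[b, ])^2)))
    expect_lt(dmin, 0.02)
  }
  # partition conservation
  expect_equal(sum(clusterCounts(fit$model)), n)
  expect_equal(length(fit$assignment), n)
})

test_that("degenerate and sparse inputs fall back sanely", {
  # all events identical: one cluster holding everything
  et <- makeTable(matrix(3, 1000, 2), roles = c("CD8", "multimer-PE"))
  fit <- gridDensityCluster(et, roles = c("CD8", "multimer-PE"))
  expect_equal(nClusters(fit$model), 1)
  expect_equal(clusterCounts(fit$model), 1000)
  # nothing dense: single-cluster fallback with a warning
  set.seed(6)
  sparse <- makeTable(matrix(runif(60), 30, 2),
                      roles = c("CD8", "multimer-PE"))
  expect_warning(fit2 <- gridDensityCluster(sparse,
                                            c("CD8", "multimer-PE"),
                                            minDensity = 50),
                 "single cluster")
  expect_equal(nClusters(fit2$model), 1)
})

test_that("assignToCentroids is self-consistent, total and order-free", {
  et <- simulateDonor(donorPreset("519_EBV"), labProfile(), 3e4, seed = 12)
  tt <- arcsinhTransform(et)
  fit <- gridDensityCluster(tt, roles = c("CD3", "CD8", "multimer-PE"))
  # assigning the fitted table reproduces the model's counts exactly
  asg <- assignToCentroids(tt, fit$model)
  expect_identical(asg$counts, clusterCounts(fit$model))
  expect_identical(asg$assignment, fit$assignment)
  # order invariance
  perm <- sample(nEvents(tt))
  asgP <- assignToCentroids(tt[perm, ], fit$model)
  expect_identical(asgP$counts, asg$counts)
  expect_identical(asgP$assignment, asg$assignment[perm])
  # missing role
  expect_error(assignToCentroids(tt[, 1:5], fit$model), "CD3")
})

test_that("nearest-centroid ties go to the lowest cluster index", {
  cent <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(0.5, 0.5))
  rng <- rbind(c(0, 0), c(1, 1))
  colnames(cent) <- colnames(rng) <- c("CD8", "multimer-PE")
  model <- new("ClusterModel", centroids = cent,
               counts = rep(0, 5), channelRoles = c("CD8", "multimer-PE"),
               scaleRange = rng, params = list(bins = 12, minDensity = 5))
  # the point (0.25, 0.75) is equidistant from centroids 2 and 5
  et <- makeTable(rbind(c(0.25, 0.75), c(0.99, 0.99)),
                  roles = c("CD8", "multimer-PE"))
  asg <- assignToCentroids(et, model)
  expect_identical(asg$assignment, c(2L, 4L))
  # single-centroid model: everything goes there
  m1 <- new("ClusterModel", centroids = cent[1, , drop = FALSE],
            counts = 0, channelRoles = c("CD8", "multimer-PE"),
            scaleRange = rng, params = list())
  expect_true(all(assignToCentroids(et, m1)$assignment == 1L))
})

test_that("templates map all samples onto one shared cluster set", {
  prof <- labProfile()
  tabs <- list(
    simulateDonor(donorPreset("519_EBV"), prof, 2e4, seed = 13),
    simulateDonor(donorPreset("518_EBV"), prof, 2e4, seed = 14),
    simulateDonor(donorPreset("spikein2_positive"), prof, 2e4, seed = 15))
  filt <- lapply(tabs, function(t)
    dagFilter(arcsinhTransform(t), defaultGateSequence())$table)
  cons <- suppressWarnings(subsampleConcat(filt, 15000, seed = 16))
  tmpl <- buildTemplate(cons, roles = c("CD3", "CD8", "multimer-PE"))
  expect_lte(nClusters(tmpl), 100)
  # each sample's populations land coherently on the shared clusters:
  # multimer+ events of every sample map to the same template cluster(s)
  multClusters <- lapply(filt, function(f) {
    asg <- assignToCentroids(f, tmpl)
    unique(asg$assignment[eventLabels(f) == "CD8pos_multimer_pos"])
  })
  shared <- Reduce(intersect, multClusters)
  expect_gte(length(shared), 1)
  # and those clusters are annotated multimer-positive
  called <- callMultimerPopulation(categorizeExpression(tmpl))
  expect_true(all(shared %in% called))
})

test_that("the cluster cap keeps the largest seed components", {
  set.seed(17)
  mu <- as.matrix(expand.grid(seq(0.1, 0.9, 0.2), seq(0.1, 0.9, 0.2)))
  n <- 25000
  g <- sample(nrow(mu), n, replace = TRUE)
  X <- mu[g, ] + matrix(rnorm(2 * n, sd = 0.015), n, 2)
  et <- makeTable(X, roles = c("CD8", "multimer-PE"))
  fit <- gridDensityCluster(et, c("CD8", "multimer-PE"), bins = 24,
                            maxClusters = 10)
  expect_lte(nClusters(fit$model), 10)
  expect_equal(sum(clusterCounts(fit$model)), n)
})

test_that("cluster models serialize losslessly to JSON", {
  et <- simulateDonor(donorPreset("519_EBV"), labProfile(), 1e4, seed = 18)
  fit <- gridDensityCluster(arcsinhTransform(et),
                            roles = c("CD3", "CD8", "multimer-PE"))
  p <- withr::local_tempfile(fileext = ".json")
  writeClusterModel(fit$model, p)
  back <- readClusterModel(p)
  expect_equal(centroids(back), centroids(fit$model))
  expect_equal(clusterCounts(back), clusterCounts(fit$model))
  expect_identical(channelRoles(back), channelRoles(fit$model))
  expect_equal(back@scaleRange, fit$model@scaleRange)
})

test_that("multimer+ centroids separate from multimer- by >= 3 sigma", {
  res <- analyzeDonor("519_EBV", 5e4, seed = 19)
  cent <- centroids(res$fit$model)
  mcol <- which(channelRoles(res$fit$model) == "multimer-PE")
  lab <- eventLabels(res$filtered)
  mval <- exprs(res$filtered)[, which(channelRoles(res$filtered) ==
                                        "multimer-PE")]
  sigma <- sd(mval[lab == "CD8pos_multimer_pos"])
  top <- max(cent[, mcol])
  rest <- max(cent[cent[, mcol] < top, mcol])
  expect_gt(top - rest, 3 * sigma)
})
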