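test_that("standardization centres, scales and is idempotent", {
  m <- cbind(a = c(9, 10, 11), b = c(5, 5, 5), c = c(0, 3, 6))
  std <- suppressWarnings(standardizeColumns(m))
  expect_equal(unname(std[, "a"]), c(-1, 0, 1))
  expect_equal(unname(std[, "b"]), c(0, 0, 0))
  expect_warning(standardizeColumns(m), "zero-variance")
  twice <- suppressWarnings(standardizeColumns(std))
  expect_equal(twice[, c("a", "c")], std[, c("a", "c")], tolerance = 1e-12)
  mNA <- m; mNA[2, 1] <- NA
  expect_error(standardizeColumns(mNA), "missing values.*a")
})

test_that("PCA retains the right rank and reconstructs the input", {
  # exactly correlated pair -> one component explains everything
  withr::local_seed(4)
  x <- cbind(x = rnorm(50))
  m <- suppressWarnings(standardizeColumns(cbind(x, y = 2 * x[, 1])))
  p <- pcaReduce(m, 0.95)
  expect_equal(p$nComponents, 1)
  expect_equal(p$explainedVariance[1], 1, tolerance = 1e-12)

  # isotropic noise in 3 dimensions needs all 3 components at 95%
  withr::local_seed(5)
  iso <- standardizeColumns(matrix(rnorm(3000), ncol = 3,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  expect_equal(pcaReduce(iso, 0.95)$nComponents, 3)

  # full-rank projection is lossless
  pf <- pcaReduce(iso, 1.0)
  expect_equal(pf$reduced %*% t(pf$loadings), iso, tolerance = 1e-10,
               ignore_attr = TRUE)

  # sign convention: dominant loading of every component is positive
  for (j in seq_len(ncol(pf$loadings)))
    expect_gt(pf$loadings[which.max(abs(pf$loadings[, j])), j], 0)
})

test_that("PCA agrees with an eigen-decomposition oracle", {
  withr::local_seed(8)
  m <- standardizeColumns(matrix(rnorm(40 * 6), ncol = 6,
                                 dimnames = list(NULL, letters[1:6])))
  e <- eigen(stats::cov(m), symmetric = TRUE)
  p <- pcaReduce(m, 1.0)
  evPkg <- p$explainedVariance * sum(e$values)
  expect_equal(evPkg, e$values, tolerance = 1e-9)
  for (j in 1:6) # loadings match up to sign
    expect_equal(abs(p$loadings[, j]), abs(e$vectors[, j]), tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("k-means recovers well-separated blobs and matches stats::kmeans", {
  withr::local_seed(3)
  centres <- rbind(c(0, 0), c(10, 0), c(5, 10 * sqrt(3) / 2))
  truth <- rep(1:3, each = 100)
  x <- centres[truth, ] + matrix(rnorm(600, sd = 0.1), ncol = 2)

  km <- kmeansCluster(x, k = 3, seed = 1, nInit = 10)
  expect_equal(bestLabelAgreement(truth, km$labels, 3), 1)

  # independent route: stock kmeans with many random starts, same inertia
  ref <- stats::kmeans(x, centers = 3, nstart = 25)
  expect_equal(km$inertia, ref$tot.withinss, tolerance = 1e-9)

  expect_identical(kmeansCluster(x, 3, seed = 7, nInit = 5)$labels,
                   kmeansCluster(x, 3, seed = 7, nInit = 5)$labels)
})

test_that("k-means edge cases: k = 1, k = N, k > N", {
  withr::local_seed(11)
  x <- matrix(rnorm(20), ncol = 2)
  one <- kmeansCluster(x, 1, seed = 1)
  expect_true(all(one$labels == 1))
  expect_equal(one$centers[1, ], colMeans(x), tolerance = 1e-12,
               ignore_attr = TRUE)
  full <- kmeansCluster(x, nrow(x), seed = 1)
  expect_equal(sort(unique(full$labels)), 1:nrow(x))
  expect_equal(full$inertia, 0, tolerance = 1e-12)
  expect_error(kmeansCluster(x, nrow(x) + 1, seed = 1), "exceeds")
})

test_that("medoid selection minimizes summed within-cluster distance", {
  red <- cbind(c(0, 1, 10), 0)
  reps <- selectRepresentatives(red, c(1, 1, 1), c("a", "b", "c"))
  expect_equal(reps$model_id, "b")   # sums 11, 10, 19

  # symmetric tie breaks to the lower index
  red2 <- cbind(c(-1, 1), 0)
  expect_equal(selectRepresentatives(red2, c(1, 1), c("a", "b"))$model_id, "a")

  # singleton cluster is its own representative
  red3 <- cbind(c(0, 5, 6), 0)
  reps3 <- selectRepresentatives(red3, c(1, 2, 2), c("a", "b", "c"))
  expect_equal(reps3$model_id, c("a", "b"))

  # brute-force check on random clusters
  withr::local_seed(17)
  x <- matrix(rnorm(60), ncol = 2)
  lab <- sample(1:3, 30, replace = TRUE)
  reps4 <- selectRepresentatives(x, lab, as.character(1:30))
  for (r in seq_len(nrow(reps4))) {
    ix <- which(lab == reps4$cluster[r])
    sums <- vapply(ix, function(i)
      sum(sqrt(colSums((t(x[ix, , drop = FALSE]) - x[i, ])^2))), 0)
    expect_equal(as.integer(reps4$model_id[r]), ix[which.min(sums)])
  }
})

test_that("lowest-DOPE baseline picks the minimum with first-wins ties", {
  sc <- data.frame(model_id = c("m1", "m2", "m3"), dope = c(-100, -120, -90))
  expect_equal(lowestDope(sc), "m2")
  expect_equal(lowestDope(sc[1, ]), "m1")
  tie <- data.frame(model_id = c("m1", "m2"), dope = c(-5, -5))
  expect_equal(lowestDope(tie), "m1")
  expect_error(lowestDope(sc[0, ]), "empty")
})

test_that("full selection pipeline finds one representative per regime", {
  gen <- generateStateSeries(StateSeriesSpec(
    nFrames = 999, stateFractions = c(1, 1, 1) / 3, meanDwell = 5,
    noise = 0.25, seed = 23))
  dm <- descriptorMatrix(gen$ensemble, gen$spec)
  res <- runSelection(dm, config = SelectionConfig(k = 3, seed = 1))

  reps <- representatives(res)
  expect_equal(nrow(reps), 3)
  regimeOf <- gen$trueLabels[match(reps$model_id, modelIds(gen$ensemble))]
  expect_equal(sort(regimeOf), 1:3)  # one from each generating regime

  # every representative carries its own cluster's label (validity) and is
  # the exhaustive-medoid of that cluster in the reduced space
  lab <- clusterLabels(res)
  for (r in seq_len(nrow(reps))) {
    ix <- which(lab == reps$cluster[r])
    sums <- vapply(ix, function(i)
      sum(sqrt(colSums((t(res@reduced[ix, , drop = FALSE]) -
                          res@reduced[i, ])^2))), 0)
    expect_equal(reps$model_id[r], names(lab)[ix[which.min(sums)]])
  }
  expect_gte(sum(explainedVariance(res)), 0.95)
})

test_that("selection with scores yields k representatives plus a baseline", {
  gen <- generateLoopEnsemble(EnsembleSpec(nModels = 60, seed = 2,
                                           regime = "flexible"))
  dm <- descriptorMatrix(gen$ensemble, gen$spec, scores = gen$scores)
  res <- runSelection(dm, scores = gen$scores,
                      config = SelectionConfig(k = 3, seed = 1))
  expect_equal(nrow(representatives(res)), 3)
  expect_equal(res@lowestDope,
               gen$scores$model_id[which.min(gen$scores$dope)])
  # the candidate set is 3 medoids + 1 baseline
  expect_length(c(representatives(res)$model_id, res@lowestDope), 4)
  expect_equal(anyDuplicated(representatives(res)$model_id), 0L)

  # N = k degenerates to one singleton cluster per model
  dm4 <- descriptorMatrix(modelStructure(gen$ensemble, 1:4), gen$spec)
  res4 <- runSelection(dm4, config = SelectionConfig(k = 4, seed = 1))
  expect_equal(sort(representatives(res4)$model_id), sort(modelIds(dm4)))
})

test_that("selection is deterministic and row-permutation stable", {
  gen <- generateStateSeries(StateSeriesSpec(
    nFrames = 300, stateFractions = c(1, 1, 1) / 3, meanDwell = 10,
    noise = 0.2, seed = 6))
  dm <- descriptorMatrix(gen$ensemble, gen$spec)
  cfg <- SelectionConfig(k = 3, seed = 5)
  r1 <- suppressWarnings(runSelection(dm, config = cfg))
  r2 <- suppressWarnings(runSelection(dm, config = cfg))
  expect_identical(representatives(r1), representatives(r2))
  expect_identical(clusterLabels(r1), clusterLabels(r2))

  withr::local_seed(10)
  perm <- sample(nModels(gen$ensemble))
  dmP <- methods::new("DescriptorMatrix",
                      values = descriptorValues(dm)[perm, ],
                      geometricFeatures = geometricFeatures(dm))
  rP <- suppressWarnings(runSelection(dmP, config = cfg))
  # cluster geometry (inertia of the partition) must match
  inertia <- function(res) {
    sum(vapply(unique(res@labels), function(cl) {
      pts <- res@reduced[res@labels == cl, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }, 0))
  }
  expect_equal(inertia(rP), inertia(r1), tolerance = 1e-9)
})

test_that("undefined columns are dropped with a warning, not imputed", {
  gen <- generateLoopEnsemble(EnsembleSpec(nModels = 30, seed = 12,
                                           regime = "flexible"))
  dm <- descriptorMatrix(gen$ensemble, gen$spec)
  vals <- descriptorValues(dm)
  vals[, "loop_prot_sh"] <- NA_real_   # e.g. a loop-only fixture
  dmNA <- methods::new("DescriptorMatrix", values = vals,
                       geometricFeatures = geometricFeatures(dm))
  expect_warning(res <- runSelection(dmNA, config = SelectionConfig(k = 2)),
                 "loop_prot_sh")
  expect_equal(nrow(representatives(res)), 2)
})

test_that("silhouette sweep reports the generating cluster count", {
  withr::local_seed(2)
  centres <- rbind(c(0, 0), c(12, 0), c(6, 12))
  x <- centres[rep(1:3, each = 40), ] + matrix(rnorm(240, sd = 0.3), ncol = 2)
  sweep <- silhouetteSweep(x, kMax = 6, seed = 1)
  expect_equal(sweep$k[which.max(sweep$meanSilhouette)], 3)
})
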