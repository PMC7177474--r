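# Representative-model selection: standardize the descriptor matrix, reduce
# it by PCA, cluster with K-means (k-means++ seeding, best of nInit
# restarts) and keep the medoid of each cluster plus the lowest-DOPE
# baseline model.

#' Selection configuration
#'
#' @param varianceRetained fraction of variance the retained principal
#'   components must explain, in (0, 1].
#' @param k number of K-means clusters (= number of representatives).
#' @param seed RNG seed making the clustering deterministic.
#' @param nInit number of k-means++ restarts; the lowest-inertia run wins.
#' @param useScores include `dope`/`soap` columns (when present) as PCA
#'   features alongside the nine geometric descriptors?
#' @returns a list with the validated settings.
#' @export
SelectionConfig <- function(varianceRetained = 0.95, k = 3L, seed = 1L,
                            nInit = 10L, useScores = TRUE) {
  stopifnot(varianceRetained > 0, varianceRetained <= 1,
            k >= 1L, nInit >= 1L)
  list(varianceRetained = varianceRetained, k = as.integer(k),
       seed = as.integer(seed), nInit = as.integer(nInit),
       useScores = isTRUE(useScores))
}

# Column-wise standardization of a plain matrix: mean 0, sample sd 1;
# zero-variance columns become all-zero with a warning.
standardizeColumns <- function(m) {
  if (nrow(m) < 2L) stop("standardization needs at least 2 rows")
  if (anyNA(m))
    stop("missing values in column(s): ",
         paste(colnames(m)[colSums(is.na(m)) > 0], collapse = ", "),
         call. = FALSE)
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  zero <- s == 0
  if (any(zero)) {
    warning("zero-variance column(s) standardized to 0: ",
            paste(colnames(m)[zero], collapse = ", "))
    s[zero] <- 1
  }
  scale(m, center = mu, scale = s)[, , drop = FALSE]
}

#' Standardize a descriptor matrix
#'
#' Centres every column to mean 0 and scales it to sample standard
#' deviation 1 (the descriptors mix length scales, so PCA without
#' standardization would be dominated by the largest-magnitude feature).
#' Zero-variance columns map to all-zeros with a warning.
#'
#' @param x a [DescriptorMatrix-class] with no missing values.
#' @returns a [DescriptorMatrix-class] of the same shape.
#' @export
standardizeDescriptors <- function(x) {
  stopifnot(is(x, "DescriptorMatrix"))
  new("DescriptorMatrix", values = standardizeColumns(x@values),
      geometricFeatures = x@geometricFeatures)
}

#' PCA reduction of a standardized feature matrix
#'
#' Principal components are the eigenvectors of the sample covariance
#' matrix, sorted by descending eigenvalue; the number of retained
#' components is the smallest m whose cumulative explained variance reaches
#' `varianceRetained`. Sign convention: each component's largest-magnitude
#' loading is positive.
#'
#' @param m numeric matrix (rows = models), already standardized.
#' @param varianceRetained fraction in (0, 1].
#' @returns list with `reduced` (N x m scores), `loadings` (P x m),
#'   `explainedVariance` (length m) and `nComponents`.
#' @export
pcaReduce <- function(m, varianceRetained = 0.95) {
  stopifnot(nrow(m) >= 2L, !anyNA(m))
  p <- prcomp(m, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2
  frac <- ev / sum(ev)
  keep <- which(cumsum(frac) >= varianceRetained - 1e-12)[1]
  if (is.na(keep)) keep <- length(frac)
  rot <- p$rotation[, seq_len(keep), drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  red <- m %*% rot
  list(reduced = red, loadings = rot,
       explainedVariance = frac[seq_len(keep)], nComponents = keep)
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, each
# further centre sampled with probability proportional to squared distance
# to the nearest centre already chosen.
kmeansPPInit <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2, x[centers[1], ])^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        pool <- setdiff(seq_len(n), centers[seq_len(j - 1L)])
        centers[j] <- if (length(pool)) sample(pool, 1L) else sample.int(n, 1L)
      } else {
        centers[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[j], ])^2))
    }
  }
  x[centers, , drop = FALSE]
}

# Plain Lloyd iterations with farthest-point repair of empty clusters; used
# when stats::kmeans aborts (empty cluster or duplicate initial centres).
lloydWithRepair <- function(x, centers, iterMax = 100L) {
  k <- nrow(centers)
  labels <- rep(1L, nrow(x))
  for (it in seq_len(iterMax)) {
    d <- crossDist(x, centers)
    newLabels <- max.col(-d, ties.method = "first")
    for (j in which(tabulate(newLabels, k) == 0L)) {
      far <- which.max(d[cbind(seq_len(nrow(x)), newLabels)])
      newLabels[far] <- j
      d <- crossDist(x, centers)
    }
    if (identical(newLabels, labels) && it > 1L) break
    labels <- newLabels
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
  }
  inertia <- sum((x - centers[labels, , drop = FALSE])^2)
  list(cluster = labels, centers = centers, tot.withinss = inertia)
}

#' K-means clustering with k-means++ seeding
#'
#' Lloyd's algorithm started from k-means++ centres, best total
#' within-cluster sum of squares over `nInit` restarts; deterministic for a
#' fixed seed. Empty clusters are repaired by reassigning the point farthest
#' from its centre.
#'
#' @param x numeric matrix, rows = observations.
#' @param k number of clusters, `k <= nrow(x)`.
#' @param seed RNG seed.
#' @param nInit number of restarts.
#' @returns list with `labels` (integer), `centers` (k x m) and `inertia`.
#' @export
kmeansCluster <- function(x, k, seed = 1L, nInit = 10L) {
  x <- as.matrix(x)
  if (k > nrow(x))
    stop("k (", k, ") exceeds the number of observations (", nrow(x), ")",
         call. = FALSE)
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nInit)) {
      init <- kmeansPPInit(x, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = init, iter.max = 100L,
                                       algorithm = "Lloyd")),
        error = function(e) lloydWithRepair(x, init))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  list(labels = as.integer(best$cluster),
       centers = unname(as.matrix(best$centers)),
       inertia = best$tot.withinss)
}

#' Medoid representative of each cluster
#'
#' The representative of a cluster is its medoid in the reduced space: the
#' member minimizing the sum of Euclidean distances to all members of its
#' cluster. Ties break towards the lowest model index.
#'
#' @param reduced N x m matrix of model coordinates.
#' @param labels integer cluster index per row.
#' @param ids model ids per row.
#' @returns data.frame with columns `cluster`, `model_id`.
#' @export
selectRepresentatives <- function(reduced, labels, ids) {
  stopifnot(nrow(reduced) == length(labels), length(ids) == length(labels))
  out <- lapply(sort(unique(labels)), function(cl) {
    ix <- which(labels == cl)
    sub <- reduced[ix, , drop = FALSE]
    sums <- rowSums(as.matrix(stats::dist(sub)))
    if (length(ix) == 1L) sums <- 0
    data.frame(cluster = cl, model_id = ids[ix[which.min(sums)]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Lowest-DOPE baseline model
#'
#' The single model with the minimum DOPE score — the conventional
#' pick-the-best-scoring-model selection that the cluster representatives
#' are compared against. Ties break to the first record in input order.
#'
#' @param scores data.frame with columns `model_id` and `dope`.
#' @returns the winning model id (character).
#' @export
lowestDope <- function(scores) {
  if (is.null(scores) || nrow(scores) == 0L)
    stop("empty score table", call. = FALSE)
  as.character(scores$model_id[which.min(scores$dope)])
}

#' Run the full representative-selection pipeline
#'
#' standardize -> PCA (retaining `varianceRetained` of the variance) ->
#' K-means (k clusters, k-means++ seeding, best of `nInit`) -> one medoid
#' representative per cluster, plus the lowest-DOPE baseline when scores are
#' available. Columns that are entirely `NA` (e.g. the loop-to-protein
#' contact distance of a context-free synthetic ensemble) are dropped with a
#' warning before standardization.
#'
#' @param x a [DescriptorMatrix-class].
#' @param scores optional data.frame from [readScores()]; may also be
#'   omitted when `x` already carries `dope`/`soap` columns.
#' @param config a [SelectionConfig()].
#' @returns a [SelectionResult-class].
#' @export
#' @examples
#' gen <- generateLoopEnsemble(EnsembleSpec(nModels = 50, seed = 1))
#' dm <- descriptorMatrix(gen$ensemble, gen$spec, scores = gen$scores)
#' runSelection(dm, config = SelectionConfig(k = 3, seed = 1))
runSelection <- function(x, scores = NULL, config = SelectionConfig()) {
  stopifnot(is(x, "DescriptorMatrix"))
  vals <- x@values
  ids <- rownames(vals)
  if (!is.null(scores) && !all(SCORE_NAMES %in% colnames(vals))) {
    hit <- match(ids, scores$model_id)
    if (anyNA(hit))
      stop("join error: no score record for model '", ids[is.na(hit)][1],
           "'", call. = FALSE)
    vals <- cbind(vals, dope = scores$dope[hit], soap = scores$soap[hit])
  }
  feat <- if (config$useScores) colnames(vals) else
    intersect(colnames(vals), x@geometricFeatures)
  vals <- vals[, feat, drop = FALSE]
  allNA <- colSums(!is.na(vals)) == 0L
  if (any(allNA)) {
    warning("dropping undefined descriptor column(s): ",
            paste(colnames(vals)[allNA], collapse = ", "))
    vals <- vals[, !allNA, drop = FALSE]
  }
  if (nrow(vals) < config$k)
    stop("fewer models than clusters", call. = FALSE)

  std <- suppressWarnings(standardizeColumns(vals))
  pca <- pcaReduce(std, config$varianceRetained)
  km <- kmeansCluster(pca$reduced, config$k, seed = config$seed,
                      nInit = config$nInit)
  reps <- selectRepresentatives(pca$reduced, km$labels, ids)

  ld <- character(0)
  if (!is.null(scores)) ld <- lowestDope(scores)
  else if ("dope" %in% colnames(vals))
    ld <- lowestDope(data.frame(model_id = ids, dope = vals[, "dope"]))

  new("SelectionResult", loadings = pca$loadings,
      explainedVariance = pca$explainedVariance,
      reduced = pca$reduced, labels = setNames(km$labels, ids),
      representatives = reps, lowestDope = ld, config = config)
}

#' Silhouette sweep over candidate cluster counts
#'
#' Reports the mean silhouette width for k = 2..kMax on the PCA-reduced
#' matrix; diagnostic only — it is never applied automatically.
#'
#' @param reduced N x m matrix (e.g. the `reduced` slot of a
#'   [SelectionResult-class]).
#' @param kMax largest k to try.
#' @param seed,nInit passed to [kmeansCluster()].
#' @returns data.frame with columns `k`, `meanSilhouette`.
#' @export
silhouetteSweep <- function(reduced, kMax = 10L, seed = 1L, nInit = 10L) {
  d <- stats::dist(reduced)
  ks <- 2:min(kMax, nrow(reduced) - 1L)
  out <- vapply(ks, function(k) {
    lab <- kmeansCluster(reduced, k, seed = seed, nInit = nInit)$labels
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  data.frame(k = ks, meanSilhouette = out)
}
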