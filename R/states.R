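# Conformational-state assignment of trajectory frames, plus ensemble
# averaging and Kabsch-superposition RMSD utilities.

#' Build a FrameSeries from a trajectory ensemble
#'
#' Computes the four arch-shape state parameters (loop_anchor_mean,
#' loop_ref_min, ach_ach_dist, loop_max_distance) for every frame of a
#' trajectory stored as a multi-model ensemble.
#'
#' @param ensemble a [ConformerEnsemble-class] of trajectory frames.
#' @param spec a [LoopSpec-class].
#' @param runId label for the run.
#' @param frameSpacing time between frames (optional).
#' @param caOnly passed to [computeDescriptors()].
#' @returns a [FrameSeries-class].
#' @export
frameSeries <- function(ensemble, spec, runId = "run1",
                        frameSpacing = NA_real_, caOnly = FALSE) {
  dm <- descriptorMatrix(ensemble, spec, caOnly = caOnly, allowShort = TRUE)
  FrameSeries(runId, dm@values[, STATE_PARAMS, drop = FALSE], frameSpacing)
}

#' Cluster trajectory frames into loop conformational states
#'
#' Frames from all runs are pooled, each four-parameter vector is
#' standardized by the pooled mean and standard deviation, and the pool is
#' partitioned by K-means ([kmeansCluster()], fixed seed). States are then
#' named by the ascending mean raw `loop_ref_min` of their members: the
#' state closest to the reference centroid (loop wrapped towards the active
#' site) is `"closed"`, the farthest is `"open"`, the middle one
#' `"semi-open"`; for `k != 3` the ordinal names `state-1..state-k` are used.
#' Per-run occupancies and transition-count matrices are computed from the
#' per-run label sequences.
#'
#' @param series a [FrameSeries-class] or a list of them (one per run).
#' @param k number of states (default 3).
#' @param seed,nInit passed to [kmeansCluster()].
#' @returns a [StateModel-class].
#' @export
#' @examples
#' gen <- generateStateSeries(StateSeriesSpec(nFrames = 500, seed = 1))
#' sm <- clusterStates(gen$series, k = 3, seed = 1)
#' sm@occupancy
clusterStates <- function(series, k = 3L, seed = 1L, nInit = 10L) {
  if (is(series, "FrameSeries")) series <- list(series)
  stopifnot(all(vapply(series, is, logical(1), "FrameSeries")))
  runIds <- vapply(series, function(s) s@runId, character(1))
  if (anyDuplicated(runIds)) stop("run ids must be unique", call. = FALSE)
  pooled <- do.call(rbind, lapply(series, function(s) s@frames))
  if (nrow(pooled) < k)
    stop("k exceeds the pooled number of frames", call. = FALSE)
  std <- suppressWarnings(standardizeColumns(pooled))
  # fewer distinct frames than states (e.g. a constant series): cluster what
  # is there and leave the remaining states genuinely empty
  kEff <- min(k, nrow(unique(std)))
  km <- kmeansCluster(std, kEff, seed = seed, nInit = nInit)

  # order states by mean raw loop_ref_min of their members
  refMean <- vapply(seq_len(kEff), function(j) {
    ix <- km$labels == j
    if (any(ix)) mean(pooled[ix, "loop_ref_min"]) else Inf
  }, numeric(1))
  ord <- order(refMean)                  # ord[new] = old
  relabel <- match(seq_len(kEff), ord)   # old -> new
  labelsPooled <- relabel[km$labels]
  stateNames <- if (k == 3L) c("closed", "semi-open", "open")
                else paste0("state-", seq_len(k))
  centroids <- do.call(rbind, lapply(seq_len(k), function(j) {
    ix <- labelsPooled == j
    if (any(ix)) colMeans(pooled[ix, , drop = FALSE])
    else rep(NA_real_, ncol(pooled))
  }))
  colnames(centroids) <- STATE_PARAMS
  rownames(centroids) <- stateNames

  lens <- vapply(series, function(s) nrow(s@frames), integer(1))
  splits <- split(labelsPooled, rep(seq_along(series), lens))
  labels <- setNames(lapply(splits, as.integer), runIds)
  occ <- lapply(labels, function(l) {
    o <- tabulate(l, nbins = k) / length(l)
    setNames(o, stateNames)
  })
  trans <- lapply(labels, function(l) {
    m <- transitions(l, k = k)
    dimnames(m) <- list(stateNames, stateNames)
    m
  })

  new("StateModel", k = as.integer(k), centroids = centroids,
      stateNames = stateNames, labels = labels, occupancy = occ,
      transitions = trans)
}

#' Per-run state occupancy
#'
#' Fraction of frames each state occupies in one run; fractions sum to 1.
#'
#' @param model a [StateModel-class].
#' @param runId which run.
#' @returns named numeric vector of fractions.
#' @export
occupancy <- function(model, runId) {
  stopifnot(is(model, "StateModel"))
  if (!runId %in% names(model@occupancy))
    stop("unknown run: ", runId, call. = FALSE)
  model@occupancy[[runId]]
}

#' Transition-count matrix of a label sequence
#'
#' Counts of consecutive (from, to) state pairs, diagonal (self-transitions
#' between saved frames) included. The number of state *changes* is the
#' off-diagonal sum.
#'
#' @param labels ordered integer state indices (>= 2).
#' @param k number of states (default: max label).
#' @returns k x k integer matrix, rows = from, columns = to.
#' @export
#' @examples
#' transitions(c(1, 1, 2, 2))  # one 1 -> 2 change
transitions <- function(labels, k = max(labels)) {
  labels <- as.integer(labels)
  if (length(labels) < 2L) stop("need at least 2 labels", call. = FALSE)
  m <- matrix(0L, k, k)
  from <- labels[-length(labels)]
  to <- labels[-1L]
  for (i in seq_along(from)) m[from[i], to[i]] <- m[from[i], to[i]] + 1L
  m
}

#' Number of state changes in a label sequence
#'
#' @param labels ordered state indices.
#' @returns integer: the off-diagonal sum of [transitions()].
#' @export
stateChanges <- function(labels) {
  tr <- transitions(labels)
  sum(tr) - sum(diag(tr))
}

#' Coordinate-averaged structure of an ensemble
#'
#' Per-atom arithmetic mean of the coordinates across all models. By default
#' no superposition is performed; with `fit = TRUE` every model is first
#' Kabsch-fitted onto the first model.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param fit superpose each model on the first model before averaging?
#' @returns a one-model [ConformerEnsemble-class] with model id
#'   `"average"`.
#' @export
averageStructure <- function(ensemble, fit = FALSE) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  xyz <- ensemble@coords
  if (fit && nModels(ensemble) > 1L) {
    ref <- xyz[, , 1]
    for (m in 2:nModels(ensemble))
      xyz[, , m] <- kabschFit(xyz[, , m], ref)
  }
  avg <- apply(xyz, c(1, 2), mean)
  ConformerEnsemble(ensemble@atoms, avg, modelIds = "average",
                    source = ensemble@source)
}

# Superpose coordinate set a onto b (least-squares rotation + translation,
# reflections excluded); returns the transformed copy of a.
kabschFit <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(crossprod(a0, b0))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(a0 %*% rot, 2, cb, "+")
}

#' RMSD between two coordinate sets, with optional Kabsch superposition
#'
#' With `fit = TRUE` (default) the first set is optimally superposed onto
#' the second (least-squares rotation excluding reflections, plus
#' translation) before the root-mean-square deviation is taken; with
#' `fit = FALSE` the raw RMSD of the coordinates as given is returned.
#' Atoms correspond by row position.
#'
#' @param a,b numeric matrices, n x 3 with the same n >= 3.
#' @param fit superpose before measuring?
#' @returns RMSD in the units of the inputs (Angstrom).
#' @export
#' @examples
#' sq <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0))
#' lifted <- sq; lifted[2, 3] <- 1
#' kabschRmsd(sq, lifted, fit = FALSE)  # sqrt(1/4) = 0.5
kabschRmsd <- function(a, b, fit = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)) || nrow(a) < 3L || ncol(a) != 3L)
    stop("coordinate sets must be equal-sized n x 3 matrices with n >= 3",
         call. = FALSE)
  if (fit) a <- kabschFit(a, b)
  sqrt(mean(rowSums((a - b)^2)))
}
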