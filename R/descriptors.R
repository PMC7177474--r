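# The nine geometric loop-shape descriptors. All are plain Euclidean
# functions of the resolved selection and are therefore invariant under
# rigid motion and equivariant under uniform scaling.

#' Convex-hull volume-to-area ratio
#'
#' Sphericity proxy of a point cloud: the ratio of the volume to the surface
#' area of its 3-D convex hull (units of length; for a sphere of radius r
#' this is r/3). Degenerate (coplanar/collinear) point sets return 0 with a
#' warning.
#'
#' @param points numeric matrix, n x 3, n >= 4.
#' @returns single numeric, Angstrom when inputs are Angstrom.
#' @export
#' @examples
#' cube <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
#' convexHullV2A(cube)  # 8 / 24 = 1/3
convexHullV2A <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4L)
    stop("convex hull needs at least 4 points", call. = FALSE)
  h <- .hull_volume_area(points)
  if (h$degenerate) {
    warning("degenerate (rank < 3) point set; volume-to-area ratio set to 0")
    return(0)
  }
  h$volume / h$area
}

#' Compute the nine loop-shape descriptors for one conformer
#'
#' Given a resolved [LoopSelection-class], returns (all distances over
#' C-alpha atoms unless stated, Angstrom):
#' \describe{
#'   \item{loop_anchor_mean}{mean distance of loop C-alphas to the centroid
#'     (midpoint) of the two anchor C-alphas; tracks how far the arch bends
#'     away from its attachment points.}
#'   \item{loop_ref_min}{minimum distance of loop C-alphas to the reference
#'     centroid (e.g. a conserved active-site tryptophan); small values mean
#'     the loop is wrapped towards the reference.}
#'   \item{ach_ach_dist}{distance between the two anchor C-alphas.}
#'   \item{loop_max_distance}{maximum pairwise distance among loop C-alphas.}
#'   \item{every_two_mean}{mean distance between C-alphas two positions
#'     apart along the loop.}
#'   \item{every_three_mean}{mean distance between C-alphas three positions
#'     apart (needs loop length >= 4).}
#'   \item{loop_max_cons_distance_bb}{maximum distance between consecutive
#'     bonded backbone atoms (N-CA, CA-C, C-N of the next residue) along the
#'     loop.}
#'   \item{loop_prot_sh}{minimum distance between any loop heavy atom and
#'     any non-loop (protein) heavy atom; `NA` when the selection has no
#'     protein context.}
#'   \item{loop_prot_v2a}{convex-hull volume-to-area ratio of the loop heavy
#'     atoms (see [convexHullV2A()]).}
#' }
#'
#' @param sel a [LoopSelection-class].
#' @param caOnly use the C-alpha trace in place of full heavy-atom/backbone
#'   sets (for C-alpha-only structures): the backbone descriptor uses
#'   consecutive C-alpha distances and the contact/hull descriptors use
#'   C-alpha points.
#' @param allowShort return `NA` for `every_three_mean` on loops shorter
#'   than 4 residues instead of erroring.
#' @returns named numeric vector of length 9, canonical order.
#' @export
computeDescriptors <- function(sel, caOnly = FALSE, allowShort = FALSE) {
  stopifnot(is(sel, "LoopSelection"))
  ca <- sel@loopCa
  L <- nrow(ca)

  anchorCentroid <- colMeans(sel@anchorCa)
  loop_anchor_mean <- mean(rowNorms(sweep(ca, 2, anchorCentroid)))
  loop_ref_min <- min(rowNorms(sweep(ca, 2, sel@referenceCentroid)))
  ach_ach_dist <- vecNorm(sel@anchorCa[1, ] - sel@anchorCa[2, ])
  loop_max_distance <- max(dist(ca))

  skipMean <- function(k) {
    if (L - k < 1L) return(NA_real_)
    mean(rowNorms(ca[seq_len(L - k), , drop = FALSE] -
                  ca[seq_len(L - k) + k, , drop = FALSE]))
  }
  every_two_mean <- skipMean(2L)
  every_three_mean <- skipMean(3L)
  if (is.na(every_three_mean) && !allowShort)
    stop("loop too short for every_three_mean (need >= 4 residues); ",
         "set allowShort = TRUE to return NA", call. = FALSE)

  bb <- if (caOnly) ca else sel@loopBackbone
  if (!caOnly && nrow(bb) != 3L * length(sel@loopResIds))
    stop("incomplete N/CA/C backbone for the loop; use caOnly = TRUE for ",
         "C-alpha-trace structures", call. = FALSE)
  steps <- rowNorms(bb[-nrow(bb), , drop = FALSE] - bb[-1, , drop = FALSE])
  loop_max_cons_distance_bb <- max(steps)

  loopPts <- if (caOnly) ca else sel@loopHeavy
  protPts <- sel@proteinHeavy
  loop_prot_sh <- if (nrow(protPts) == 0L) NA_real_ else
    min(crossDist(loopPts, protPts))
  loop_prot_v2a <- if (nrow(loopPts) < 4L) NA_real_ else
    convexHullV2A(loopPts)

  c(loop_anchor_mean = loop_anchor_mean, loop_ref_min = loop_ref_min,
    ach_ach_dist = ach_ach_dist, loop_max_distance = loop_max_distance,
    every_two_mean = every_two_mean, every_three_mean = every_three_mean,
    loop_max_cons_distance_bb = loop_max_cons_distance_bb,
    loop_prot_sh = loop_prot_sh, loop_prot_v2a = loop_prot_v2a)
}

#' Assemble the descriptor matrix of an ensemble
#'
#' Resolves the loop in every model, computes the nine descriptors per
#' conformer and optionally joins DOPE/SOAP score columns.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param spec a [LoopSpec-class].
#' @param scores optional data.frame as returned by [readScores()]; every
#'   model id of the ensemble must have a score row.
#' @param caOnly,allowShort passed to [computeDescriptors()].
#' @returns a [DescriptorMatrix-class] (N models x 9 descriptors, plus
#'   `dope` and `soap` columns when scores are given).
#' @export
#' @examples
#' gen <- generateLoopEnsemble(EnsembleSpec(nModels = 10, seed = 1))
#' dm <- descriptorMatrix(gen$ensemble, gen$spec, scores = gen$scores)
#' dim(descriptorValues(dm))
descriptorMatrix <- function(ensemble, spec, scores = NULL,
                             caOnly = FALSE, allowShort = FALSE) {
  stopifnot(is(ensemble, "ConformerEnsemble"), is(spec, "LoopSpec"))
  ids <- modelIds(ensemble)
  vals <- t(vapply(seq_along(ids), function(m)
    computeDescriptors(resolveLoop(spec, ensemble, m),
                       caOnly = caOnly, allowShort = allowShort),
    numeric(length(DESCRIPTOR_NAMES))))
  rownames(vals) <- ids
  if (!is.null(scores)) {
    hit <- match(ids, scores$model_id)
    if (anyNA(hit))
      stop("join error: no score record for model '", ids[is.na(hit)][1],
           "'", call. = FALSE)
    vals <- cbind(vals, dope = scores$dope[hit], soap = scores$soap[hit])
  }
  new("DescriptorMatrix", values = vals,
      geometricFeatures = DESCRIPTOR_NAMES)
}

#' Write a DescriptorMatrix as TSV
#'
#' @param x a [DescriptorMatrix-class].
#' @param path output path.
#' @returns `path`, invisibly.
#' @export
writeDescriptors <- function(x, path) {
  stopifnot(is(x, "DescriptorMatrix"))
  df <- data.frame(model_id = rownames(x@values), x@values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DescriptorMatrix from TSV
#'
#' @param path TSV with a `model_id` column plus descriptor (and optionally
#'   score) columns.
#' @returns a [DescriptorMatrix-class].
#' @export
readDescriptors <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  if (!"model_id" %in% names(df))
    stop("descriptor table must have a model_id column", call. = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), "model_id"), drop = FALSE])
  rownames(vals) <- as.character(df$model_id)
  new("DescriptorMatrix", values = vals,
      geometricFeatures = intersect(DESCRIPTOR_NAMES, colnames(vals)))
}
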