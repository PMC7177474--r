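# S4 containers. Coordinates are always plain numeric matrices in Angstrom
# with one row per atom; ensembles store one shared atom table plus an
# nAtoms x 3 x nModels coordinate array, which makes the identical-topology
# invariant structural rather than checked per use.

ATOM_COLS <- c("serial", "name", "resName", "resId", "chain", "element")

#' Loop specification
#'
#' Declares a loop on a chain by its two anchor (attachment-point) residues
#' plus one or more reference residues (typically a conserved active-site
#' tryptophan) whose C-alpha centroid anchors the loop-to-reference distance
#' descriptor. By default the loop consists of the residues *strictly
#' between* the anchors: anchors are attachment points welded to fixed
#' secondary structure. Set `includeAnchors = TRUE` to count the anchors as
#' loop residues.
#'
#' @slot chain single chain identifier.
#' @slot anchorStart,anchorEnd author residue numbers of the two anchors,
#'   `anchorStart < anchorEnd`.
#' @slot includeAnchors logical; are the anchors part of the loop?
#' @slot referenceResIds integer vector of reference residue numbers,
#'   disjoint from `[anchorStart, anchorEnd]`.
#' @aliases LoopSpec-class
#' @export LoopSpec
#' @exportClass LoopSpec
#' @examples
#' LoopSpec(chain = "A", anchorStart = 318, anchorEnd = 326,
#'          referenceResIds = 117)
setClass("LoopSpec",
  representation(chain = "character", anchorStart = "integer",
                 anchorEnd = "integer", includeAnchors = "logical",
                 referenceResIds = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@chain) != 1L || !nzchar(object@chain))
      msg <- c(msg, "chain must be a single non-empty identifier")
    if (object@anchorStart >= object@anchorEnd)
      msg <- c(msg, "anchorStart must be < anchorEnd")
    if (length(object@referenceResIds) < 1L)
      msg <- c(msg, "at least one reference residue is required")
    if (any(object@referenceResIds >= object@anchorStart &
            object@referenceResIds <= object@anchorEnd))
      msg <- c(msg, "reference residues must lie outside [anchorStart, anchorEnd]")
    if (length(msg)) msg else TRUE
  })

#' @param chain,anchorStart,anchorEnd,includeAnchors,referenceResIds see slots.
#' @rdname LoopSpec-class
LoopSpec <- function(chain, anchorStart, anchorEnd,
                     referenceResIds, includeAnchors = FALSE) {
  new("LoopSpec", chain = as.character(chain),
      anchorStart = as.integer(anchorStart),
      anchorEnd = as.integer(anchorEnd),
      includeAnchors = isTRUE(includeAnchors),
      referenceResIds = as.integer(referenceResIds))
}

#' Conformer ensemble
#'
#' An ordered set of conformers (models of one protein, or trajectory
#' frames) sharing a single atom topology. The atom table holds one row per
#' atom (serial, name, resName, resId, chain, element); coordinates live in
#' an `nAtoms x 3 x nModels` array so all models are guaranteed to share the
#' `(chain, resId, name)` topology.
#'
#' @slot atoms data.frame with columns serial, name, resName, resId, chain,
#'   element.
#' @slot coords numeric array, `nAtoms x 3 x nModels`, Angstrom.
#' @slot modelIds character labels, one per model.
#' @slot source origin of the ensemble (file path or `"synthetic"`).
#' @aliases ConformerEnsemble-class
#' @export ConformerEnsemble
#' @exportClass ConformerEnsemble
setClass("ConformerEnsemble",
  representation(atoms = "data.frame", coords = "array",
                 modelIds = "character", source = "character"),
  validity = function(object) {
    msg <- character()
    if (!all(ATOM_COLS %in% names(object@atoms)))
      msg <- c(msg, paste("atoms must have columns:",
                          paste(ATOM_COLS, collapse = ", ")))
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L)
      msg <- c(msg, "coords must be an nAtoms x 3 x nModels array")
    else {
      if (d[1] != nrow(object@atoms))
        msg <- c(msg, "coords first dimension must match atom count")
      if (d[3] != length(object@modelIds))
        msg <- c(msg, "coords third dimension must match modelIds length")
      if (d[3] < 1L) msg <- c(msg, "an ensemble holds at least one model")
    }
    if (anyDuplicated(object@modelIds))
      msg <- c(msg, "modelIds must be unique")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "all coordinates must be finite")
    key <- paste(object@atoms$chain, object@atoms$resId, object@atoms$name)
    if (anyDuplicated(key))
      msg <- c(msg, paste("duplicate (chain, resId, name) atom:",
                          key[anyDuplicated(key)][1]))
    if (length(msg)) msg else TRUE
  })

#' @param atoms,coords,modelIds,source see slots. `coords` may also be a
#'   single `nAtoms x 3` matrix for a one-model ensemble.
#' @rdname ConformerEnsemble-class
ConformerEnsemble <- function(atoms, coords, modelIds = NULL,
                              source = "synthetic") {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  if (is.null(modelIds)) modelIds <- as.character(seq_len(dim(coords)[3]))
  new("ConformerEnsemble", atoms = atoms, coords = coords,
      modelIds = as.character(modelIds), source = source)
}

#' Resolved loop selection
#'
#' Concrete coordinate sets extracted from one conformer under a
#' [LoopSpec()]: loop C-alpha trace, loop backbone (N, CA, C per residue in
#' chain order), loop heavy atoms, the two anchor C-alphas, the reference
#' C-alpha centroid, and the heavy atoms of everything outside the loop and
#' anchors (`proteinHeavy`; may have zero rows for loop-only synthetic
#' fixtures, in which case the loop-to-protein contact descriptor is
#' undefined).
#'
#' @slot loopCa,loopBackbone,loopHeavy,anchorCa,proteinHeavy coordinate
#'   matrices (rows = atoms, 3 columns), Angstrom.
#' @slot referenceCentroid numeric length-3.
#' @slot loopResIds integer residue numbers of the loop.
#' @aliases LoopSelection-class
#' @exportClass LoopSelection
setClass("LoopSelection",
  representation(loopCa = "matrix", loopBackbone = "matrix",
                 loopHeavy = "matrix", anchorCa = "matrix",
                 referenceCentroid = "numeric", proteinHeavy = "matrix",
                 loopResIds = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@loopCa) < 3L)
      msg <- c(msg, "a loop needs at least 3 C-alpha atoms")
    if (nrow(object@anchorCa) != 2L)
      msg <- c(msg, "exactly two anchor C-alpha atoms are required")
    if (length(object@referenceCentroid) != 3L)
      msg <- c(msg, "referenceCentroid must be a 3-vector")
    if (nrow(object@loopHeavy) < 1L)
      msg <- c(msg, "loopHeavy must be non-empty")
    if (length(msg)) msg else TRUE
  })

#' Descriptor matrix
#'
#' N models x P features. Columns are the nine geometric descriptors, in
#' canonical order, optionally followed by `dope` and `soap` score columns.
#' `geometricFeatures` records which columns are geometry (score columns are
#' excluded from RSD profiles).
#'
#' @slot values numeric matrix, rownames = model ids.
#' @slot geometricFeatures character subset of `colnames(values)`.
#' @aliases DescriptorMatrix-class
#' @exportClass DescriptorMatrix
setClass("DescriptorMatrix",
  representation(values = "matrix", geometricFeatures = "character"),
  validity = function(object) {
    msg <- character()
    if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
      msg <- c(msg, "values must have model-id rownames and feature colnames")
    else {
      if (anyDuplicated(colnames(object@values)))
        msg <- c(msg, "feature names must be unique")
      if (!all(object@geometricFeatures %in% colnames(object@values)))
        msg <- c(msg, "geometricFeatures must be a subset of feature names")
    }
    if (length(msg)) msg else TRUE
  })

#' Representative-selection result
#'
#' Output of [runSelection()]: PCA loadings and explained variance for the
#' retained components, per-model cluster labels, one medoid representative
#' per cluster, and (when scores are supplied) the lowest-DOPE baseline
#' model.
#'
#' @slot loadings P x m loading matrix (features x retained components).
#' @slot explainedVariance fraction of variance per retained component.
#' @slot reduced N x m matrix of model coordinates in PCA space.
#' @slot labels integer cluster index per model (named by model id).
#' @slot representatives data.frame with columns `cluster`, `model_id`.
#' @slot lowestDope model id of the minimum-DOPE model (length 0 if no
#'   scores were supplied).
#' @slot config list echoing the [SelectionConfig()] used.
#' @aliases SelectionResult-class
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(loadings = "matrix", explainedVariance = "numeric",
                 reduced = "matrix", labels = "integer",
                 representatives = "data.frame", lowestDope = "character",
                 config = "list"),
  validity = function(object) {
    msg <- character()
    reps <- object@representatives
    if (!all(c("cluster", "model_id") %in% names(reps)))
      msg <- c(msg, "representatives needs columns cluster, model_id")
    else {
      if (anyDuplicated(reps$model_id))
        msg <- c(msg, "representatives must be unique models")
      own <- object@labels[reps$model_id]
      if (length(own) && any(own != reps$cluster))
        msg <- c(msg, "each representative must carry its own cluster's label")
    }
    if (length(msg)) msg else TRUE
  })

#' RSD profile of an ensemble
#'
#' Relative standard deviation (100 * sample sd / mean, percent) of each
#' geometric descriptor over an ensemble of models.
#'
#' @slot rsd named numeric vector, percent.
#' @slot nModels integer, number of models profiled.
#' @aliases RSDProfile-class
#' @exportClass RSDProfile
setClass("RSDProfile",
  representation(rsd = "numeric", nModels = "integer"),
  validity = function(object) {
    if (object@nModels < 2L) "RSD needs at least 2 models" else TRUE
  })

#' Static/flexible verdict
#'
#' @slot verdict one of `"static"`, `"flexible"`, `"indeterminate"`.
#' @slot thresholdPct RSD threshold in percent (default 8).
#' @slot overThreshold names of arch descriptors exceeding the threshold.
#' @slot profile the underlying [RSDProfile-class].
#' @aliases FlexibilityCall-class
#' @exportClass FlexibilityCall
setClass("FlexibilityCall",
  representation(verdict = "character", thresholdPct = "numeric",
                 overThreshold = "character", profile = "RSDProfile"),
  validity = function(object) {
    if (!object@verdict %in% c("static", "flexible", "indeterminate"))
      "verdict must be static, flexible or indeterminate" else TRUE
  })

#' Per-run descriptor time series
#'
#' Ordered frames of the four arch-shape state parameters
#' (loop_anchor_mean, loop_ref_min, ach_ach_dist, loop_max_distance) for one
#' simulation run.
#'
#' @slot runId run label.
#' @slot frames numeric matrix, frames x 4, canonical column order.
#' @slot frameSpacing time between saved frames (any unit; `NA` if unknown).
#' @aliases FrameSeries-class
#' @export FrameSeries
#' @exportClass FrameSeries
setClass("FrameSeries",
  representation(runId = "character", frames = "matrix",
                 frameSpacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@frames) < 2L)
      msg <- c(msg, "a series needs at least 2 frames")
    if (!identical(colnames(object@frames), STATE_PARAMS))
      msg <- c(msg, paste("frame columns must be:",
                          paste(STATE_PARAMS, collapse = ", ")))
    if (anyNA(object@frames))
      msg <- c(msg, "state parameters must not contain missing values")
    if (length(msg)) msg else TRUE
  })

#' @param runId,frames,frameSpacing see slots.
#' @rdname FrameSeries-class
FrameSeries <- function(runId, frames, frameSpacing = NA_real_) {
  frames <- as.matrix(frames)
  new("FrameSeries", runId = as.character(runId), frames = frames,
      frameSpacing = as.numeric(frameSpacing))
}

#' Loop conformational state model
#'
#' Frames pooled over runs, clustered in the standardized four-parameter
#' arch space; states named closed / semi-open / open by ascending mean
#' loop_ref_min (distance of the loop to the reference-residue centroid):
#' the state wrapped towards the active site is "closed", the most
#' solvent-exposed is "open". For `k != 3` ordinal names `state-1..k` are
#' used instead.
#'
#' @slot k number of states.
#' @slot centroids k x 4 state centroids in raw parameter space (Angstrom).
#' @slot stateNames character of length k, index -> name.
#' @slot labels named list: per run, integer state index per frame.
#' @slot occupancy named list: per run, fraction of frames per state.
#' @slot transitions named list: per run, k x k counts of consecutive
#'   (from, to) label pairs, diagonal included.
#' @aliases StateModel-class
#' @exportClass StateModel
setClass("StateModel",
  representation(k = "integer", centroids = "matrix", stateNames = "character",
                 labels = "list", occupancy = "list", transitions = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@stateNames) != object@k ||
        anyDuplicated(object@stateNames))
      msg <- c(msg, "stateNames must be k unique names")
    for (run in names(object@labels)) {
      occ <- object@occupancy[[run]]
      if (abs(sum(occ) - 1) > 1e-12)
        msg <- c(msg, sprintf("occupancy of run %s must sum to 1", run))
      lab <- object@labels[[run]]
      tr <- object@transitions[[run]]
      cnt <- tabulate(lab, nbins = object@k)
      last <- as.integer(seq_len(object@k) == lab[length(lab)])
      if (!all(rowSums(tr) == cnt - last))
        msg <- c(msg, sprintf(
          "transition row sums of run %s must equal label counts minus final state", run))
    }
    if (length(msg)) msg else TRUE
  })
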