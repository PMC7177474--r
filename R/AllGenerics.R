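#' @name ensemble-accessors
#' @title Accessors for ConformerEnsemble objects
#' @param x a [ConformerEnsemble-class].
#' @param model model index or id; `NULL` returns the full array.
#' @param i model index or id.
#' @returns `nModels()` the number of models; `modelIds()` their labels;
#'   `atomTable()` the shared atom data.frame; `coords()` an `nAtoms x 3`
#'   matrix for one model or the full 3-D array; `modelStructure()` a
#'   [ConformerEnsemble-class] restricted to the selected model(s).
NULL

#' @rdname ensemble-accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @rdname ensemble-accessors
#' @export
setGeneric("modelIds", function(x) standardGeneric("modelIds"))

#' @rdname ensemble-accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname ensemble-accessors
#' @export
setGeneric("coords", function(x, model = NULL) standardGeneric("coords"))

#' @rdname ensemble-accessors
#' @export
setGeneric("modelStructure", function(x, i) standardGeneric("modelStructure"))

#' @rdname ensemble-accessors
setMethod("nModels", "ConformerEnsemble", function(x) dim(x@coords)[3])

#' @rdname ensemble-accessors
setMethod("modelIds", "ConformerEnsemble", function(x) x@modelIds)

#' @rdname ensemble-accessors
setMethod("atomTable", "ConformerEnsemble", function(x) x@atoms)

#' @rdname ensemble-accessors
setMethod("coords", "ConformerEnsemble", function(x, model = NULL) {
  if (is.null(model)) return(x@coords)
  if (is.character(model)) {
    model <- match(model, x@modelIds)
    if (anyNA(model)) stop("unknown model id")
  }
  m <- x@coords[, , model, drop = FALSE]
  if (dim(m)[3] == 1L) dim(m) <- dim(m)[1:2]
  m
})

#' @rdname ensemble-accessors
setMethod("modelStructure", "ConformerEnsemble", function(x, i) {
  if (is.character(i)) {
    i <- match(i, x@modelIds)
    if (anyNA(i)) stop("unknown model id")
  }
  ConformerEnsemble(x@atoms, coords(x, i), modelIds = x@modelIds[i],
                    source = x@source)
})

#' @name descriptor-accessors
#' @title Accessors for DescriptorMatrix objects
#' @param x a [DescriptorMatrix-class].
#' @returns `descriptorValues()` the numeric matrix (models x features);
#'   `featureNames()` its column names; `geometricFeatures()` the subset of
#'   geometry columns (scores excluded).
NULL

#' @rdname descriptor-accessors
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))

#' @rdname descriptor-accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname descriptor-accessors
#' @export
setGeneric("geometricFeatures", function(x) standardGeneric("geometricFeatures"))

#' @rdname descriptor-accessors
setMethod("descriptorValues", "DescriptorMatrix", function(x) x@values)

#' @rdname descriptor-accessors
setMethod("featureNames", "DescriptorMatrix", function(x) colnames(x@values))

#' @rdname descriptor-accessors
setMethod("geometricFeatures", "DescriptorMatrix",
          function(x) x@geometricFeatures)

#' @rdname descriptor-accessors
setMethod("modelIds", "DescriptorMatrix", function(x) rownames(x@values))

#' @name selection-accessors
#' @title Accessors for SelectionResult objects
#' @param x a [SelectionResult-class].
#' @returns `representatives()` a data.frame (cluster, model_id);
#'   `clusterLabels()` the named integer label vector; `lowestDope()` on a
#'   SelectionResult, the baseline model id (character(0) when no scores
#'   were given); `explainedVariance()` the retained variance fractions.
NULL

#' @rdname selection-accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname selection-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname selection-accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname selection-accessors
setMethod("representatives", "SelectionResult", function(x) x@representatives)

#' @rdname selection-accessors
setMethod("clusterLabels", "SelectionResult", function(x) x@labels)

#' @rdname selection-accessors
setMethod("explainedVariance", "SelectionResult",
          function(x) x@explainedVariance)

#' @name state-accessors
#' @title Accessors for StateModel objects
#' @param x a [StateModel-class].
#' @returns `stateNames()` index -> name map; `stateLabels()` per-run integer
#'   label vectors; `stateCentroids()` the k x 4 centroid matrix in raw
#'   parameter space (Angstrom).
NULL

#' @rdname state-accessors
#' @export
setGeneric("stateNames", function(x) standardGeneric("stateNames"))

#' @rdname state-accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname state-accessors
#' @export
setGeneric("stateCentroids", function(x) standardGeneric("stateCentroids"))

#' @rdname state-accessors
setMethod("stateNames", "StateModel", function(x) x@stateNames)

#' @rdname state-accessors
setMethod("stateLabels", "StateModel", function(x) x@labels)

#' @rdname state-accessors
setMethod("stateCentroids", "StateModel", function(x) x@centroids)

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf("ConformerEnsemble: %d model(s), %d atoms, %d residue(s), chain(s) %s\n",
              nModels(object), nrow(object@atoms),
              length(unique(paste(object@atoms$chain, object@atoms$resId))),
              paste(unique(object@atoms$chain), collapse = ",")))
  cat(sprintf("source: %s\n", object@source))
})

setMethod("show", "LoopSpec", function(object) {
  cat(sprintf("LoopSpec: chain %s, anchors %d-%d (%s), reference residue(s) %s\n",
              object@chain, object@anchorStart, object@anchorEnd,
              if (object@includeAnchors) "included in loop" else "excluded from loop",
              paste(object@referenceResIds, collapse = ",")))
})

setMethod("show", "DescriptorMatrix", function(object) {
  cat(sprintf("DescriptorMatrix: %d models x %d features\n",
              nrow(object@values), ncol(object@values)))
  cat("features:", paste(featureNames(object), collapse = ", "), "\n")
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d clusters over %d models, %d PC(s) (%.1f%% variance)\n",
              nrow(object@representatives), length(object@labels),
              length(object@explainedVariance),
              100 * sum(object@explainedVariance)))
  reps <- object@representatives
  cat("representatives:",
      paste(sprintf("cluster %d -> %s", reps$cluster, reps$model_id),
            collapse = "; "), "\n")
  if (length(object@lowestDope))
    cat("lowest-DOPE baseline:", object@lowestDope, "\n")
})

setMethod("show", "RSDProfile", function(object) {
  cat(sprintf("RSDProfile over %d models (%% = 100*sd/mean):\n", object@nModels))
  print(round(object@rsd, 2))
})

setMethod("show", "FlexibilityCall", function(object) {
  cat(sprintf("FlexibilityCall: %s (threshold %.1f%%)\n",
              toupper(object@verdict), object@thresholdPct))
  if (length(object@overThreshold))
    cat("arch descriptors over threshold:",
        paste(object@overThreshold, collapse = ", "), "\n")
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel: %d states (%s), %d run(s)\n", object@k,
              paste(object@stateNames, collapse = ", "),
              length(object@labels)))
  for (run in names(object@occupancy)) {
    occ <- object@occupancy[[run]]
    cat(sprintf("  run %s occupancy: %s\n", run,
                paste(sprintf("%s=%.3f", object@stateNames, occ),
                      collapse = " ")))
  }
})

setMethod("show", "FrameSeries", function(object) {
  cat(sprintf("FrameSeries: run %s, %d frames\n", object@runId,
              nrow(object@frames)))
})
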