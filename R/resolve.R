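#' Resolve a loop specification against one conformer
#'
#' Maps a [LoopSpec()] onto the atoms of one model of an ensemble, yielding
#' the concrete coordinate sets all descriptors are computed from. Loop
#' residues are the residues strictly between the anchors (plus the anchors
#' themselves when `includeAnchors` is set); `proteinHeavy` contains the
#' heavy atoms of everything outside the loop *and* both anchors, so the
#' loop-to-protein contact distance never reports a trivially bonded
#' contact.
#'
#' @param spec a [LoopSpec-class].
#' @param ensemble a [ConformerEnsemble-class].
#' @param model model index or id to resolve (default first).
#' @returns a [LoopSelection-class].
#' @export
#' @examples
#' gen <- generateLoopEnsemble(EnsembleSpec(nModels = 2, seed = 1))
#' sel <- resolveLoop(gen$spec, gen$ensemble)
#' nrow(sel@loopCa)
resolveLoop <- function(spec, ensemble, model = 1L) {
  stopifnot(is(spec, "LoopSpec"), is(ensemble, "ConformerEnsemble"))
  at <- ensemble@atoms
  xyz <- coords(ensemble, model)

  onChain <- at$chain == spec@chain
  if (!any(onChain))
    stop("resolution error: chain '", spec@chain, "' not found", call. = FALSE)

  betweenIds <- seq(spec@anchorStart + 1L, spec@anchorEnd - 1L)
  loopIds <- if (spec@includeAnchors)
    c(spec@anchorStart, betweenIds, spec@anchorEnd) else betweenIds
  anchorIds <- c(spec@anchorStart, spec@anchorEnd)

  caOf <- function(resId) {
    ix <- which(onChain & at$resId == resId & at$name == "CA")
    if (length(ix) != 1L)
      stop("resolution error: residue ", resId, " on chain ", spec@chain,
           " is missing (or lacks a CA atom)", call. = FALSE)
    xyz[ix, , drop = FALSE]
  }

  loopCa <- do.call(rbind, lapply(loopIds, caOf))
  anchorCa <- do.call(rbind, lapply(anchorIds, caOf))
  refCa <- do.call(rbind, lapply(spec@referenceResIds, caOf))
  referenceCentroid <- colMeans(refCa)

  # backbone rows in strict N, CA, C order per loop residue; incomplete
  # backbones (C-alpha traces) simply yield fewer rows -- computeDescriptors
  # decides whether that is acceptable
  bbRows <- integer(0)
  for (r in loopIds)
    for (nmat in c("N", "CA", "C")) {
      ix <- which(onChain & at$resId == r & at$name == nmat)
      bbRows <- c(bbRows, ix)
    }
  loopBackbone <- xyz[bbRows, , drop = FALSE]
  rownames(loopBackbone) <- at$name[bbRows]

  heavy <- !(at$element %in% c("H", "D"))
  inLoop <- onChain & at$resId %in% loopIds
  inAnchors <- onChain & at$resId %in% anchorIds
  loopHeavy <- xyz[inLoop & heavy, , drop = FALSE]
  proteinHeavy <- xyz[heavy & !inLoop & !inAnchors, , drop = FALSE]

  new("LoopSelection", loopCa = loopCa, loopBackbone = loopBackbone,
      loopHeavy = loopHeavy, anchorCa = anchorCa,
      referenceCentroid = as.numeric(referenceCentroid),
      proteinHeavy = proteinHeavy, loopResIds = as.integer(loopIds))
}
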