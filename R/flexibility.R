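# Static vs flexible classification from descriptor dispersion.
#
# Over a large conformer ensemble, a flexible loop spreads its arch-shape
# descriptors (loop_anchor_mean, loop_ref_min, loop_max_distance) widely,
# while a static loop keeps its arch and varies mainly near the anchoring
# residues — which inflates ach_ach_dist in BOTH loop types, so that
# descriptor is reported but deliberately excluded from the decision rule.

ARCH_DECISION_SET <- c("loop_anchor_mean", "loop_ref_min",
                       "loop_max_distance")

#' Relative standard deviation profile of an ensemble
#'
#' RSD_j = 100 * sample sd / mean (percent) per geometric descriptor column
#' (score columns are excluded). RSD is scale-free: uniformly rescaling all
#' coordinates leaves the profile unchanged.
#'
#' @param x a [DescriptorMatrix-class] with at least 2 models.
#' @returns an [RSDProfile-class].
#' @export
rsdProfile <- function(x) {
  stopifnot(is(x, "DescriptorMatrix"))
  vals <- x@values[, x@geometricFeatures, drop = FALSE]
  vals <- vals[, colSums(!is.na(vals)) > 0L, drop = FALSE]
  if (nrow(vals) < 2L) stop("RSD needs at least 2 models", call. = FALSE)
  mu <- colMeans(vals)
  if (any(mu <= 0))
    stop("RSD undefined for column(s) with non-positive mean: ",
         paste(colnames(vals)[mu <= 0], collapse = ", "), call. = FALSE)
  rsd <- 100 * apply(vals, 2, sd) / mu
  new("RSDProfile", rsd = rsd, nModels = nrow(vals))
}

#' Classify a loop as static or flexible
#'
#' Decision rule: among the three arch descriptors `loop_anchor_mean`,
#' `loop_ref_min` and `loop_max_distance`, the loop is called **flexible**
#' when at least two exceed the RSD threshold (default 8%), **static** when
#' none do, and **indeterminate** when exactly one does. `ach_ach_dist` is
#' always reported alongside but never votes, because high anchor-distance
#' dispersion is characteristic of static ensembles too.
#'
#' @param profile an [RSDProfile-class] containing the three arch
#'   descriptors and `ach_ach_dist`.
#' @param thresholdPct RSD threshold, percent.
#' @returns a [FlexibilityCall-class].
#' @export
#' @examples
#' gen <- generateLoopEnsemble(EnsembleSpec(nModels = 100, seed = 1,
#'                                          sigmaArch = 0.6, sigmaRadial = 0.15))
#' classifyLoop(rsdProfile(descriptorMatrix(gen$ensemble, gen$spec)))
classifyLoop <- function(profile, thresholdPct = 8.0) {
  stopifnot(is(profile, "RSDProfile"))
  need <- c(ARCH_DECISION_SET, "ach_ach_dist")
  missing <- setdiff(need, names(profile@rsd))
  if (length(missing))
    stop("profile lacks required descriptor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  over <- ARCH_DECISION_SET[profile@rsd[ARCH_DECISION_SET] > thresholdPct]
  verdict <- if (length(over) >= 2L) "flexible"
             else if (length(over) == 0L) "static"
             else "indeterminate"
  new("FlexibilityCall", verdict = verdict, thresholdPct = thresholdPct,
      overThreshold = over, profile = profile)
}
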