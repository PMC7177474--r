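# Synthetic loop-conformer ensembles with controlled geometry.
#
# A loop is modelled as L C-alpha atoms on a circular arc joining two anchor
# residues, with pseudo N/C backbone atoms set 1.2 A along the local chain
# tangent. Conformational variability enters through three dials that mimic
# the two empirical regimes of loop-model ensembles:
#   sigmaArch   - sd (radians) of a random rotation of the arc plane about
#                 the anchor-anchor axis: arch-shape variability (flexible
#                 loops);
#   sigmaRadial - sd of a multiplicative arc-radius jitter, rebuilding the
#                 arc at constant C-alpha spacing (so the anchor separation
#                 varies with it);
#   sigmaAnchor - per-axis Gaussian jitter (A) of the two anchor residues:
#                 anchor-region variability (static loops). The loop C-alphas
#                 themselves are untouched, so the consecutive loop C-alpha
#                 spacing stays exact in every regime.

#' Synthetic ensemble specification
#'
#' @param nModels number of conformers (>= 2).
#' @param loopLength loop residues strictly between the anchors (>= 4).
#' @param anchorSeparation base anchor-to-anchor distance, Angstrom.
#' @param caSpacing consecutive C-alpha spacing, Angstrom (3.8 is the
#'   canonical trans-peptide value).
#' @param sigmaAnchor per-axis jitter (Angstrom) of the two anchor residues
#'   (the loop itself is untouched, preserving the C-alpha spacing).
#' @param sigmaArch sd (radians) of the arc-plane rotation.
#' @param sigmaRadial sd of the fractional arc-radius jitter.
#' @param context `"shell"` surrounds the loop with 60 fixed pseudo-protein
#'   atoms on a hemisphere (so the loop-to-protein contact descriptor is
#'   exercised); `"none"` emits only loop, anchors and reference.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @param regime convenience presets: `"static"` sets
#'   `sigmaArch = 0.02, sigmaAnchor = 0.6, sigmaRadial = 0` (arch pinned,
#'   anchors wobbling); `"flexible"` sets
#'   `sigmaArch = 0.6, sigmaRadial = 0.15, sigmaAnchor = 0` (arch swinging).
#' @returns a validated list of settings.
#' @export
EnsembleSpec <- function(nModels = 200L, loopLength = 7L,
                         anchorSeparation = 10, caSpacing = 3.8,
                         sigmaAnchor = 0, sigmaArch = 0, sigmaRadial = 0,
                         context = c("shell", "none"), seed = 1L,
                         regime = NULL) {
  context <- match.arg(context)
  if (!is.null(regime)) {
    regime <- match.arg(regime, c("static", "flexible"))
    if (regime == "static") {
      sigmaArch <- 0.02; sigmaAnchor <- 0.6; sigmaRadial <- 0
    } else {
      sigmaArch <- 0.6; sigmaRadial <- 0.15; sigmaAnchor <- 0
    }
  }
  stopifnot(nModels >= 2L, loopLength >= 4L, anchorSeparation > 0,
            caSpacing > 0, sigmaAnchor >= 0, sigmaArch >= 0,
            sigmaRadial >= 0)
  list(nModels = as.integer(nModels), loopLength = as.integer(loopLength),
       anchorSeparation = anchorSeparation, caSpacing = caSpacing,
       sigmaAnchor = sigmaAnchor, sigmaArch = sigmaArch,
       sigmaRadial = sigmaRadial, context = context,
       seed = as.integer(seed))
}

# Solve for the per-segment arc angle theta of a circular arc with nSeg
# equal chords of length `spacing` whose end-to-end chord is `sep`.
arcAngle <- function(nSeg, sep, spacing) {
  if (nSeg * spacing <= sep)
    stop(sprintf(paste0(
      "infeasible loop geometry: %d segments of %.2f A cannot span %.2f A; ",
      "need anchorSeparation < %.2f A"), nSeg, spacing, sep, nSeg * spacing),
      call. = FALSE)
  f <- function(th) sin(nSeg * th / 2) - (sep / spacing) * sin(th / 2)
  stats::uniroot(f, c(1e-9, 2 * pi / nSeg - 1e-9), tol = 1e-14)$root
}

# C-alpha positions (anchors + loop) of an arc with radius factor s,
# centred on the x axis, bulging towards +y. Spacing is held at `spacing`
# exactly; the chord (anchor separation) absorbs the radius jitter.
arcChain <- function(nSeg, sep, spacing, s = 1) {
  th0 <- arcAngle(nSeg, sep, spacing)
  R0 <- spacing / (2 * sin(th0 / 2))
  # keep the scaled radius large enough that nSeg chords still fit on < 2*pi
  Rmin <- spacing / (2 * sin(pi / nSeg)) * (1 + 1e-9)
  R <- max(s * R0, Rmin)
  th <- 2 * asin(spacing / (2 * R))
  Th <- nSeg * th
  chord <- 2 * R * sin(Th / 2)
  ctr <- c(sep / 2, -R * cos(Th / 2), 0)
  i <- 0:nSeg
  phi <- pi / 2 + Th / 2 - i * th
  cbind(ctr[1] + R * cos(phi), ctr[2] + R * sin(phi), 0)
}

rotX <- function(alpha) {
  rbind(c(1, 0, 0),
        c(0, cos(alpha), -sin(alpha)),
        c(0, sin(alpha), cos(alpha)))
}

# Fibonacci hemisphere (z <= 0) of n points, radius rho, centred at ctr.
hemisphereShell <- function(n, ctr, rho) {
  i <- seq_len(n) - 0.5
  z <- -i / n                       # z in (-1, 0)
  r <- sqrt(1 - z^2)
  ga <- pi * (3 - sqrt(5))
  pts <- cbind(r * cos(ga * i), r * sin(ga * i), z) * rho
  sweep(pts, 2, ctr, "+")
}

# Assemble the shared atom table + per-model coordinates from a list of
# C-alpha chains (anchors + loop). N/C pseudo atoms sit +-1.2 A along the
# local tangent of each loop residue.
buildModels <- function(chains, spec) {
  L <- spec$loopLength
  nSeg <- L + 1L
  sep <- spec$anchorSeparation

  refXyz <- c(sep / 2, 0, -8)
  shell <- if (spec$context == "shell") {
    base <- arcChain(nSeg, sep, spec$caSpacing)
    ctr <- colMeans(base)
    rho <- max(rowNorms(sweep(base, 2, ctr))) + 6
    hemisphereShell(60L, ctr, rho)
  } else NULL

  atoms <- data.frame(serial = integer(0), name = character(0),
                      resName = character(0), resId = integer(0),
                      chain = character(0), element = character(0),
                      stringsAsFactors = FALSE)
  addAtom <- function(name, resName, resId, element = "C")
    atoms <<- rbind(atoms, data.frame(serial = nrow(atoms) + 1L, name = name,
                                      resName = resName, resId = resId,
                                      chain = "A", element = element,
                                      stringsAsFactors = FALSE))
  addAtom("CA", "TRP", 1L)                      # reference residue
  addAtom("CA", "GLY", 100L)                    # anchor 1
  loopIds <- 100L + seq_len(L)
  for (r in loopIds) {
    addAtom("N", "GLY", r, "N")
    addAtom("CA", "GLY", r)
    addAtom("C", "GLY", r)
  }
  addAtom("CA", "GLY", 100L + L + 1L)           # anchor 2
  if (!is.null(shell))
    for (j in seq_len(60L)) addAtom("CA", "DUM", 1000L + j)

  nA <- nrow(atoms)
  xyz <- array(NA_real_, c(nA, 3L, length(chains)))
  for (m in seq_along(chains)) {
    chain <- chains[[m]]                        # (nSeg + 1) x 3, anchors + loop
    co <- matrix(NA_real_, nA, 3L)
    co[1, ] <- refXyz
    co[2, ] <- chain[1, ]
    row <- 3L
    for (i in seq_len(L)) {
      ca <- chain[i + 1L, ]
      tangent <- chain[i + 2L, ] - chain[i, ]
      tangent <- tangent / vecNorm(tangent)
      # local binormal: out-of-plane zigzag so the loop atoms are never
      # coplanar (a real backbone is not flat either)
      curv <- (chain[i + 2L, ] + chain[i, ]) / 2 - ca
      bn <- c(tangent[2] * curv[3] - tangent[3] * curv[2],
              tangent[3] * curv[1] - tangent[1] * curv[3],
              tangent[1] * curv[2] - tangent[2] * curv[1])
      if (vecNorm(bn) < 1e-8) bn <- c(-tangent[2], tangent[1], 0)
      if (vecNorm(bn) < 1e-8) bn <- c(0, -tangent[3], tangent[2])
      bn <- bn / vecNorm(bn)
      co[row, ] <- ca - 1.2 * tangent + 0.3 * bn
      co[row + 1L, ] <- ca
      co[row + 2L, ] <- ca + 1.2 * tangent - 0.3 * bn
      row <- row + 3L
    }
    co[row, ] <- chain[nSeg + 1L, ]
    if (!is.null(shell)) co[(row + 1L):nA, ] <- shell
    xyz[, , m] <- co
  }
  list(atoms = atoms, xyz = xyz,
       contextCentroid = if (is.null(shell)) refXyz else colMeans(shell))
}

#' Generate a synthetic loop-conformer ensemble
#'
#' Produces `nModels` conformers of one pseudo-protein whose loop C-alphas
#' lie on a jittered circular arc between two anchors, together with the
#' matching [LoopSpec()] and a pseudo score table. The pseudo-DOPE score is
#' an explicit toy: the mean distance of the loop C-alphas to the context
#' (shell) centroid plus small noise, so that the lowest-DOPE model is
#' always one of the most compact, context-proximal conformers — the known
#' bias of statistical potentials towards folded shapes. Generation is
#' deterministic for a fixed spec.
#'
#' @param spec an [EnsembleSpec()].
#' @returns list with `ensemble` ([ConformerEnsemble-class]), `spec`
#'   ([LoopSpec-class]), `scores` (data.frame model_id/dope/soap) and
#'   `truth` (list of the per-model arch angles and radius factors).
#' @export
#' @examples
#' gen <- generateLoopEnsemble(EnsembleSpec(nModels = 5, seed = 7,
#'                                          regime = "flexible"))
#' gen$ensemble
generateLoopEnsemble <- function(spec) {
  L <- spec$loopLength
  nSeg <- L + 1L
  arcAngle(nSeg, spec$anchorSeparation, spec$caSpacing)  # feasibility check

  withSeed(spec$seed, {
    alphas <- rnorm(spec$nModels, 0, spec$sigmaArch)
    scales <- 1 + rnorm(spec$nModels, 0, spec$sigmaRadial)
    jitter <- array(rnorm(spec$nModels * 2L * 3L, 0, spec$sigmaAnchor),
                    c(2L, 3L, spec$nModels))
    dopeNoise <- rnorm(spec$nModels, 0, 0.1)
    soapNoise <- rnorm(spec$nModels, 0, 0.15)
  })

  chains <- lapply(seq_len(spec$nModels), function(m) {
    ch <- arcChain(nSeg, spec$anchorSeparation, spec$caSpacing, scales[m])
    ch <- ch %*% t(rotX(alphas[m]))
    if (spec$sigmaAnchor > 0) {
      near <- c(1L, nSeg + 1L)             # the two anchor residues
      ch[near, ] <- ch[near, ] + jitter[, , m]
    }
    ch
  })

  built <- buildModels(chains, spec)
  ids <- paste0("m", seq_len(spec$nModels))
  ens <- ConformerEnsemble(built$atoms, built$xyz, modelIds = ids,
                           source = "synthetic")
  loopSpec <- LoopSpec(chain = "A", anchorStart = 100L,
                       anchorEnd = 100L + L + 1L, referenceResIds = 1L)

  compact <- vapply(seq_len(spec$nModels), function(m) {
    ca <- chains[[m]][1L + seq_len(L), , drop = FALSE]
    mean(rowNorms(sweep(ca, 2, built$contextCentroid)))
  }, numeric(1))
  scores <- data.frame(model_id = ids,
                       dope = compact + dopeNoise,
                       soap = 0.8 * compact + soapNoise,
                       stringsAsFactors = FALSE)
  list(ensemble = ens, spec = loopSpec, scores = scores,
       truth = list(archAngle = alphas, radiusFactor = scales))
}

#' State-switching frame-series specification
#'
#' @param nFrames number of trajectory frames.
#' @param stateFractions target occupancy per state, summing to 1; states
#'   are index-aligned with `arcOrientations` in ascending-orientation
#'   (closed to open) order.
#' @param meanDwell mean dwell time, frames, of a stay in one state.
#' @param arcOrientations arc-plane angle (radians) defining each state's
#'   geometry; negative angles rotate the arch towards the reference
#'   residue ("closed"), positive away ("open").
#' @param radialFactors per-state arc-radius factor; a closed, wrapped loop
#'   is more compact than an open, solvent-exposed one, so by default the
#'   factors grow from 0.85 to 1.15 with the orientation. This makes the
#'   states differ in all four arch parameters, not just the
#'   loop-to-reference distance.
#' @param noise per-axis Gaussian coordinate noise, Angstrom.
#' @param seed RNG seed.
#' @param loopLength,anchorSeparation,caSpacing as in [EnsembleSpec()].
#' @returns a validated list of settings.
#' @export
StateSeriesSpec <- function(nFrames = 5000L,
                            stateFractions = c(0.6, 0.3, 0.1),
                            meanDwell = 20, arcOrientations = NULL,
                            radialFactors = NULL,
                            noise = 0.3, seed = 1L, loopLength = 7L,
                            anchorSeparation = 10, caSpacing = 3.8) {
  k <- length(stateFractions)
  if (is.null(arcOrientations))
    arcOrientations <- seq(-0.9, 0.9, length.out = max(k, 2L))[seq_len(k)]
  if (is.null(radialFactors))
    radialFactors <- if (k == 1L) 1 else
      1 + 0.15 * seq(-1, 1, length.out = k)[rank(arcOrientations)]
  stopifnot(nFrames >= 2L, k >= 1L, all(stateFractions > 0),
            abs(sum(stateFractions) - 1) <= 1e-9, meanDwell >= 1,
            length(arcOrientations) == k, length(radialFactors) == k,
            all(radialFactors > 0), noise >= 0)
  list(nFrames = as.integer(nFrames), stateFractions = stateFractions,
       meanDwell = meanDwell, arcOrientations = arcOrientations,
       radialFactors = radialFactors, noise = noise,
       seed = as.integer(seed), loopLength = as.integer(loopLength),
       anchorSeparation = anchorSeparation, caSpacing = caSpacing)
}

# Label sequence hitting the target per-state frame counts exactly:
# each state's allocation is cut into geometric-like dwell segments and the
# segments are interleaved in random order.
dwellLabels <- function(nFrames, fractions, meanDwell) {
  counts <- diff(round(cumsum(c(0, fractions)) * nFrames))
  counts[length(counts)] <- nFrames - sum(counts[-length(counts)])
  segs <- list()
  for (s in seq_along(counts)) {
    left <- counts[s]
    while (left > 0L) {
      d <- min(left, 1L + stats::rgeom(1L, min(1, 1 / meanDwell)))
      segs[[length(segs) + 1L]] <- rep(s, d)
      left <- left - d
    }
  }
  unlist(segs[sample.int(length(segs))], use.names = FALSE)
}

#' Generate a synthetic state-switching trajectory
#'
#' Builds a frame series in which the loop dwells in k discrete
#' conformational states (arc-plane orientations) with geometric-like dwell
#' times; the per-state frame counts match `stateFractions` exactly, so the
#' target occupancies are recovered up to clustering error. Each frame's
#' loop atoms additionally receive iid Gaussian coordinate noise.
#'
#' @param spec a [StateSeriesSpec()].
#' @param runId label of the generated run.
#' @returns list with `ensemble` (frames as a [ConformerEnsemble-class]),
#'   `spec` ([LoopSpec-class]), `series` (a [FrameSeries-class] of the four
#'   state parameters) and `trueLabels` (integer ground truth per frame,
#'   ascending-orientation state indices).
#' @export
#' @examples
#' gen <- generateStateSeries(StateSeriesSpec(nFrames = 100, seed = 3))
#' table(gen$trueLabels) / 100
generateStateSeries <- function(spec, runId = "run1") {
  L <- spec$loopLength
  nSeg <- L + 1L
  stateChains <- lapply(seq_along(spec$arcOrientations), function(s) {
    ch <- arcChain(nSeg, spec$anchorSeparation, spec$caSpacing,
                   spec$radialFactors[s])
    ch %*% t(rotX(spec$arcOrientations[s]))
  })

  genSpec <- list(loopLength = L, anchorSeparation = spec$anchorSeparation,
                  caSpacing = spec$caSpacing, context = "none")

  withSeed(spec$seed, {
    labels <- dwellLabels(spec$nFrames, spec$stateFractions, spec$meanDwell)
    chains <- lapply(seq_len(spec$nFrames), function(f) {
      ch <- stateChains[[labels[f]]]
      ch + matrix(rnorm(length(ch), 0, spec$noise), nrow(ch), 3L)
    })
  })

  built <- buildModels(chains, genSpec)
  ids <- paste0("f", seq_len(spec$nFrames))
  ens <- ConformerEnsemble(built$atoms, built$xyz, modelIds = ids,
                           source = "synthetic")
  loopSpec <- LoopSpec(chain = "A", anchorStart = 100L,
                       anchorEnd = 100L + L + 1L, referenceResIds = 1L)
  series <- frameSeries(ens, loopSpec, runId = runId)
  list(ensemble = ens, spec = loopSpec, series = series,
       trueLabels = as.integer(labels))
}
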