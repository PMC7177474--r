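# Independent brute-force oracles. These share no code with the package:
# every quantity is recomputed with explicit loops (O(n^2) or worse) so that
# agreement with the package is a genuine dual-route check.

edist <- function(p, q) sqrt(sum((p - q)^2))

# Brute-force recomputation of all nine descriptors from a LoopSelection.
bruteDescriptors <- function(sel, caOnly = FALSE) {
  ca <- sel@loopCa
  L <- nrow(ca)
  a1 <- sel@anchorCa[1, ]; a2 <- sel@anchorCa[2, ]
  ctr <- (a1 + a2) / 2

  lam <- mean(vapply(seq_len(L), function(i) edist(ca[i, ], ctr), 0))
  lrm <- min(vapply(seq_len(L), function(i)
    edist(ca[i, ], sel@referenceCentroid), 0))
  aad <- edist(a1, a2)
  lmd <- 0
  for (i in seq_len(L - 1)) for (j in (i + 1):L)
    lmd <- max(lmd, edist(ca[i, ], ca[j, ]))
  e2 <- mean(vapply(seq_len(L - 2), function(i) edist(ca[i, ], ca[i + 2, ]), 0))
  e3 <- if (L >= 4) mean(vapply(seq_len(L - 3), function(i)
    edist(ca[i, ], ca[i + 3, ]), 0)) else NA_real_

  bb <- if (caOnly) ca else sel@loopBackbone
  mbb <- 0
  for (i in seq_len(nrow(bb) - 1)) mbb <- max(mbb, edist(bb[i, ], bb[i + 1, ]))

  loopPts <- if (caOnly) ca else sel@loopHeavy
  sh <- NA_real_
  if (nrow(sel@proteinHeavy) > 0) {
    sh <- Inf
    for (i in seq_len(nrow(loopPts))) for (j in seq_len(nrow(sel@proteinHeavy)))
      sh <- min(sh, edist(loopPts[i, ], sel@proteinHeavy[j, ]))
  }
  v2a <- if (nrow(loopPts) >= 4) bruteHullV2A(loopPts) else NA_real_

  c(loop_anchor_mean = lam, loop_ref_min = lrm, ach_ach_dist = aad,
    loop_max_distance = lmd, every_two_mean = e2, every_three_mean = e3,
    loop_max_cons_distance_bb = mbb, loop_prot_sh = sh, loop_prot_v2a = v2a)
}

# Brute-force 3-D convex hull volume/area by facet-plane enumeration:
# every point triple whose plane has all points on one side spans a facet
# plane; coplanar points on that plane are merged, their 2-D hull polygon
# gives the facet area and the divergence theorem the volume.
bruteHullV2A <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  scale <- max(abs(pts), 1)
  tol <- 1e-9 * scale
  planes <- list()
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    u <- pts[j, ] - pts[i, ]; v <- pts[k, ] - pts[i, ]
    nn <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    nl <- sqrt(sum(nn^2))
    if (nl < tol * scale) next
    nn <- nn / nl
    d <- as.numeric(pts %*% nn - sum(nn * pts[i, ]))
    if (max(d) <= tol) nn <- -nn
    else if (min(d) >= -tol) nn <- nn
    else next
    off <- sum(nn * pts[i, ])
    key <- paste(round(c(nn, off) / tol / 10), collapse = "_")
    if (is.null(planes[[key]]))
      planes[[key]] <- list(n = nn, members = which(abs(d) <= tol))
  }
  if (!length(planes)) return(0)
  vol <- 0; area <- 0
  for (pl in planes) {
    sub <- pts[pl$members, , drop = FALSE]
    if (nrow(sub) < 3) next
    # orthonormal in-plane basis
    e1 <- sub[2, ] - sub[1, ]; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(pl$n[2] * e1[3] - pl$n[3] * e1[2],
            pl$n[3] * e1[1] - pl$n[1] * e1[3],
            pl$n[1] * e1[2] - pl$n[2] * e1[1])
    xy <- cbind(as.numeric(sweep(sub, 2, sub[1, ]) %*% e1),
                as.numeric(sweep(sub, 2, sub[1, ]) %*% e2))
    h <- grDevices::chull(xy)
    poly <- xy[h, , drop = FALSE]
    m <- nrow(poly)
    a <- 0
    for (q in seq_len(m)) {
      r <- if (q == m) 1 else q + 1
      a <- a + poly[q, 1] * poly[r, 2] - poly[r, 1] * poly[q, 2]
    }
    a <- abs(a) / 2
    area <- area + a
    vol <- vol + a * sum(pl$n * sub[1, ]) / 3
  }
  if (area == 0) return(0)
  abs(vol) / area
}

# Uniform random 3-D rotation matrix (QR of a Gaussian matrix, det +1).
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Transform every coordinate set of a LoopSelection rigidly (or scale it).
transformSelection <- function(sel, rot = diag(3), shift = c(0, 0, 0),
                               scale = 1) {
  tf <- function(m) {
    if (nrow(m) == 0) return(m)
    out <- scale * (m %*% t(rot))
    out <- sweep(out, 2, shift, "+")
    rownames(out) <- rownames(m)
    out
  }
  methods::new("LoopSelection",
    loopCa = tf(sel@loopCa), loopBackbone = tf(sel@loopBackbone),
    loopHeavy = tf(sel@loopHeavy), anchorCa = tf(sel@anchorCa),
    referenceCentroid = as.numeric(scale * (rot %*% sel@referenceCentroid) +
                                     shift),
    proteinHeavy = tf(sel@proteinHeavy), loopResIds = sel@loopResIds)
}

# A random but geometrically sane LoopSelection built directly (no PDB, no
# generator): a C-alpha random walk with ~3.8 A steps, N/CA/C backbone with
# out-of-line offsets, and a protein cloud well away from the loop.
randomSelection <- function(L = 7, nProt = 30) {
  steps <- matrix(rnorm(3 * (L + 1)), ncol = 3)
  steps <- 3.8 * steps / sqrt(rowSums(steps^2))
  chain <- apply(rbind(c(0, 0, 0), steps), 2, cumsum)  # anchors + loop
  anchors <- chain[c(1, L + 2), , drop = FALSE]
  ca <- chain[2:(L + 1), , drop = FALSE]
  bb <- matrix(0, 3 * L, 3)
  for (i in seq_len(L)) {
    t0 <- chain[i + 2, ] - chain[i, ]
    t0 <- t0 / sqrt(sum(t0^2))
    off <- rnorm(3, 0, 0.3)
    bb[3 * i - 2, ] <- ca[i, ] - 1.2 * t0 + off
    bb[3 * i - 1, ] <- ca[i, ]
    bb[3 * i, ] <- ca[i, ] + 1.2 * t0 - off
  }
  rownames(bb) <- rep(c("N", "CA", "C"), L)
  prot <- matrix(rnorm(3 * nProt, 0, 4), ncol = 3)
  prot <- sweep(prot, 2, c(0, 0, 25), "+")
  methods::new("LoopSelection", loopCa = ca, loopBackbone = bb,
               loopHeavy = bb, anchorCa = anchors,
               referenceCentroid = rnorm(3, 0, 5), proteinHeavy = prot,
               loopResIds = as.integer(seq_len(L)))
}

# Best label agreement over all permutations of k cluster labels.
bestLabelAgreement <- function(truth, labels, k = 3) {
  perms <- permutationsOf(seq_len(k))
  max(vapply(perms, function(p) mean(p[truth] == labels), 0))
}

permutationsOf <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutationsOf(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# A minimal hand-built C-alpha-trace ensemble for I/O and resolution tests:
# one chain, CA-only residues at the given ids, coordinates supplied per
# model as a list of (nRes x 3) matrices.
caTraceEnsemble <- function(resIds, coordList, chain = "A") {
  atoms <- data.frame(serial = seq_along(resIds), name = "CA",
                      resName = "GLY", resId = as.integer(resIds),
                      chain = chain, element = "C",
                      stringsAsFactors = FALSE)
  xyz <- array(NA_real_, c(length(resIds), 3, length(coordList)))
  for (m in seq_along(coordList)) xyz[, , m] <- coordList[[m]]
  ConformerEnsemble(atoms, xyz, modelIds = paste0("m", seq_along(coordList)))
}
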