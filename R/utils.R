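# Canonical feature names, in the fixed column order used everywhere.
DESCRIPTOR_NAMES <- c("loop_anchor_mean", "loop_ref_min", "ach_ach_dist",
                      "loop_max_distance", "every_two_mean",
                      "every_three_mean", "loop_max_cons_distance_bb",
                      "loop_prot_sh", "loop_prot_v2a")

# The four arch-shape parameters used for state assignment.
STATE_PARAMS <- c("loop_anchor_mean", "loop_ref_min", "ach_ach_dist",
                  "loop_max_distance")

SCORE_NAMES <- c("dope", "soap")

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Euclidean norms of matrix rows.
rowNorms <- function(m) sqrt(rowSums(m * m))

# All pairwise distances between rows of a and rows of b (n_a x n_b).
crossDist <- function(a, b) {
  aa <- rowSums(a * a)
  bb <- rowSums(b * b)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

vecNorm <- function(v) sqrt(sum(v * v))
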