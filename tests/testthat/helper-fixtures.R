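# Shared fixtures and independent brute-force oracles for the test suite.
# Phantom cohorts are cached per session because several files reuse them.

.fix_cache <- new.env(parent = emptyenv())

# small cohort for registration-heavy tests (coarser grid, same shapes)
small_cohort <- function() {
  if (is.null(.fix_cache$small))
    .fix_cache$small <- makePhantomCohort(dim = c(20L, 64L, 64L),
                                          spacing = c(1.2, 1, 1),
                                          noiseSigma = 2, seed = 1L)
  .fix_cache$small
}

# registration control sized for the small cohort
small_control <- function(seed = 11L)
  regControl(samples = 1200L, bsplineIterations = c(60L, 40L), seed = seed)

# full-resolution cohort (acceptance surface)
full_cohort <- function() {
  if (is.null(.fix_cache$full))
    .fix_cache$full <- makePhantomCohort(seed = 1L)
  .fix_cache$full
}

# random proper orthonormal matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random axis permutation/flip matrix (signed permutation)
random_signed_permutation <- function() {
  p <- sample(3)
  s <- sample(c(-1, 1), 3, replace = TRUE)
  m <- matrix(0, 3, 3)
  for (t in 1:3) m[p[t], t] <- s[t]
  m
}

# random small binary mask as an array (guaranteed nonempty)
random_mask_array <- function(dim = c(8L, 8L, 8L), p = 0.3) {
  a <- array(as.double(stats::runif(prod(dim)) < p), dim)
  if (sum(a) == 0) a[1, 1, 1] <- 1
  a
}

# ---- independent oracles (plain R, straight from the definitions) ----

oracle_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i] > 0) na <- na + 1
    if (b[i] > 0) nb <- nb + 1
    if (a[i] > 0 && b[i] > 0) inter <- inter + 1
  }
  2 * inter / (na + nb)
}

# boundary voxels by the 6-neighbour face rule, via explicit loops
oracle_boundary <- function(arr) {
  d <- dim(arr)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (arr[i, j, k] <= 0) next
    nb <- c(
      if (i > 1) arr[i - 1, j, k] else 0,
      if (i < d[1]) arr[i + 1, j, k] else 0,
      if (j > 1) arr[i, j - 1, k] else 0,
      if (j < d[2]) arr[i, j + 1, k] else 0,
      if (k > 1) arr[i, j, k - 1] else 0,
      if (k < d[3]) arr[i, j, k + 1] else 0)
    if (any(nb == 0)) out <- rbind(out, c(i, j, k) - 1)
  }
  out
}

oracle_asd <- function(nm, gt) {
  bn <- indexToPhysical(geometry(nm), oracle_boundary(nm@voxels))
  bg <- indexToPhysical(geometry(gt), oracle_boundary(gt@voxels))
  dmat <- matrix(0, nrow(bn), nrow(bg))
  for (i in seq_len(nrow(bn))) for (j in seq_len(nrow(bg)))
    dmat[i, j] <- sqrt(sum((bn[i, ] - bg[j, ])^2))
  (sum(apply(dmat, 1, min)) + sum(apply(dmat, 2, min))) /
    (nrow(bn) + nrow(bg))
}

oracle_nn_dists <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i)
    min(sqrt(rowSums(sweep(b, 2, a[i, ])^2))), numeric(1))
}

# convenience constructors
mask_from <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      direction = diag(3))
  BinaryMask(arr, spacing, origin, direction)

img_from <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     direction = diag(3))
  Image3D(arr, spacing, origin, direction)
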