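# Shared fixture builders and independent oracles.

# pack a symmetric 3x3 matrix into lower-triangular order xx, xy, yy, xz, yz, zz
pack_tensor <- function(S) {
  c(S[1, 1], S[1, 2], S[2, 2], S[1, 3], S[2, 3], S[3, 3])
}

unpack_tensor <- function(v) {
  matrix(c(v[1], v[2], v[4],
           v[2], v[3], v[5],
           v[4], v[5], v[6]), 3, 3)
}

# single-voxel tensor field from a symmetric matrix
one_voxel_field <- function(S) {
  comp <- array(0, c(1, 1, 1, 6))
  comp[1, 1, 1, ] <- pack_tensor(S)
  strain_tensor_field(voxel_grid(c(1, 1, 1)), comp,
                      array(TRUE, c(1, 1, 1)))
}

# tensor field holding n random symmetric tensors along the first axis
tensor_field_from_list <- function(tensors) {
  n <- length(tensors)
  comp <- array(0, c(n, 1, 1, 6))
  for (i in seq_len(n)) comp[i, 1, 1, ] <- pack_tensor(tensors[[i]])
  strain_tensor_field(voxel_grid(c(n, 1, 1)), comp, array(TRUE, c(n, 1, 1)))
}

random_symmetric <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  (A + t(A)) / 2
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
}

# eigenvalue-based OSS/MPS oracle (definitional route, per-voxel eigen())
oss_eigen_oracle <- function(S) {
  e <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
            decreasing = TRUE)
  (2 / 3) * sqrt((e[1] - e[2])^2 + (e[2] - e[3])^2 + (e[3] - e[1])^2)
}

mps_eigen_oracle <- function(S) {
  max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
}

# literal step-up BH oracle: sort, p * m / rank, cumulative min from the
# largest, unsort
bh_brute_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- (m / seq_len(m)) * ps
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# small scalar map on a fresh grid
tiny_map <- function(values, mask = NULL, kind = "oss") {
  values <- as.array(values)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  scalar_map(voxel_grid(dim(values)), values, mask, kind = kind)
}

# small ground-truth spec for statistics-level tests (fast to simulate)
small_spec <- function(seed = 5, shape = c(24, 24, 24), ...) {
  grid <- voxel_grid(shape, c(2, 2, 2))
  make_normative_field(grid, blob_spec = default_blobs(grid, radius_mm = 7),
                       seed = seed, ...)
}

# spec with no planted structure at all (exact voxelwise null)
null_spec <- function(seed = 5, shape = c(16, 16, 16), ...) {
  grid <- voxel_grid(shape, c(2, 2, 2))
  make_normative_field(grid, blob_spec = list(), background_sd = 0,
                       seed = seed, ...)
}

# build subject z maps for an MRE cohort
cohort_zmaps <- function(mre) {
  lapply(mre$subjects, function(s) zscore_within_subject(s$oss))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
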