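make_zmaps <- function(X) {
  # X: subjects x voxels matrix -> list of maps on a 1-D grid
  nv <- ncol(X)
  lapply(seq_len(nrow(X)), function(i) {
    tiny_map(array(X[i, ], c(nv, 1, 1)), kind = "oss_z")
  })
}

test_that("voxelwise one-sample t matches hand computation", {
  X <- rbind(c(1, 1), c(2, -1), c(3, 1), c(4, -1))
  st <- voxelwise_one_sample_t(make_zmaps(X))
  # subject values 1,2,3,4: t = 2.5 / (sd/2) = 3.873
  expect_equal(st$t[1, 1, 1], mean(1:4) / (stats::sd(1:4) / 2),
               tolerance = 1e-12)
  expect_equal(st$n, 4)
  # symmetric about zero: t = 0, p = 1
  expect_equal(st$t[2, 1, 1], 0)
  expect_equal(st$p[2, 1, 1], 1)
  expect_error(voxelwise_one_sample_t(make_zmaps(X[1:2, ])), "at least 3")
})

test_that("degenerate zero-variance voxels are retained with a warning", {
  X <- rbind(c(1, 5), c(2, 5), c(3, 5))
  expect_warning(st <- voxelwise_one_sample_t(make_zmaps(X)), "degenerate")
  expect_equal(st$t[2, 1, 1], 0)
  expect_equal(st$p[2, 1, 1], 1)
  expect_equal(st$n_degenerate, 1)
})

test_that("BH adjustment equals the hand-worked step-up example", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, -0.01)), "\\[0, 1\\]")
})

test_that("BH adjustment equals the brute-force step-up oracle exactly", {
  set.seed(99)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    expect_identical(bh_fdr(p), bh_brute_oracle(p))
  }
})

test_that("the joint q/t rule defines the partition exactly", {
  # three voxels: (q .01, t 5) -> HS; (q .01, t 3) -> LS; (q .10, t 6) -> LS
  st <- structure(list(
    t = array(c(5, 3, 6), c(3, 1, 1)),
    p = array(0.01, c(3, 1, 1)),
    q = array(c(0.01, 0.01, 0.10), c(3, 1, 1)),
    mask = array(TRUE, c(3, 1, 1)),
    grid = voxel_grid(c(3, 1, 1)), n = 10, n_degenerate = 0, sided = "two"),
    class = "voxel_stat_map")
  roi <- define_hs_mask(st, st$mask)
  expect_equal(as.vector(roi$hs), c(TRUE, FALSE, FALSE))
  expect_equal(as.vector(roi$ls), c(FALSE, TRUE, TRUE))
  st$q[] <- 0.8
  expect_error(define_hs_mask(st, st$mask), "empty")
})

test_that("mask rule matches voxelwise brute force on random stat maps", {
  set.seed(3)
  for (i in 1:50) {
    nv <- 60
    st <- structure(list(
      t = array(stats::rnorm(nv, 2, 3), c(nv, 1, 1)),
      p = array(stats::runif(nv), c(nv, 1, 1)),
      q = array(stats::runif(nv), c(nv, 1, 1)),
      mask = array(TRUE, c(nv, 1, 1)),
      grid = voxel_grid(c(nv, 1, 1)), n = 10, n_degenerate = 0,
      sided = "two"), class = "voxel_stat_map")
    expected <- vapply(seq_len(nv), function(v) {
      st$q[v, 1, 1] < 0.05 && st$t[v, 1, 1] >= 4
    }, logical(1))
    if (!any(expected)) {
      expect_error(define_hs_mask(st, st$mask), "empty")
    } else {
      roi <- define_hs_mask(st, st$mask)
      expect_equal(as.vector(roi$hs), expected)
      # partition invariant
      expect_false(any(roi$hs & roi$ls))
      expect_true(all((roi$hs | roi$ls) == roi$brain_mask))
    }
  }
})

test_that("mask intersection is idempotent and counts voxels correctly", {
  g <- voxel_grid(c(10, 1, 1))
  brain <- array(TRUE, c(10, 1, 1))
  a <- strain_roi_mask(array(1:10 <= 5, c(10, 1, 1)), brain, g)
  b <- strain_roi_mask(array(1:10 >= 4, c(10, 1, 1)), brain, g)
  expect_equal(intersect_masks(a, a)$hs, a$hs)
  ab <- intersect_masks(a, b)
  expect_equal(sum(ab$hs), 2)  # voxels 4 and 5
  expect_equal(which(ab$hs), 4:5)
  disj <- strain_roi_mask(array(1:10 >= 9, c(10, 1, 1)), brain, g)
  expect_warning(empty <- intersect_masks(a, disj), "empty")
  expect_equal(sum(empty$hs), 0)
  other <- strain_roi_mask(array(TRUE, c(10, 1, 1)), brain,
                           voxel_grid(c(10, 1, 1), c(1, 1, 1)))
  expect_error(intersect_masks(a, other), "Grid mismatch")
})

test_that("tissue composition fractions count correctly and sum to one", {
  g <- voxel_grid(c(10, 1, 1))
  brain <- array(TRUE, c(10, 1, 1))
  hs <- array(1:10 <= 10, c(10, 1, 1))  # HS = whole brain
  labels <- array(c(rep("GM", 6), rep("WM", 4)), c(10, 1, 1))
  roi_all <- strain_roi_mask(hs, brain, g)
  comp <- tissue_composition(roi_all, labels)
  expect_equal(comp$hs_frac_brain, 1)
  expect_equal(comp$gm_frac_in_hs, 0.6)
  expect_equal(comp$wm_frac_in_hs, 0.4)
  expect_equal(comp$gm_frac_in_hs + comp$wm_frac_in_hs +
                 comp$other_frac_in_hs, 1)
  # HS entirely inside GM
  roi_gm <- strain_roi_mask(array(1:10 <= 3, c(10, 1, 1)), brain, g)
  comp2 <- tissue_composition(roi_gm, labels)
  expect_equal(comp2$gm_frac_in_hs, 1)
  expect_equal(comp2$hs_share_of_gm, 0.5)
  expect_error(tissue_composition(roi_gm, array("GM", c(2, 1, 1))),
               "dimensions")
})

test_that("null cohorts keep false-positive HS fractions within the FDR bound", {
  # no planted blobs, no shared background: voxelwise null is exactly true
  spec <- null_spec(seed = 21)
  n_sim <- 60
  frac <- vapply(seq_len(n_sim), function(s) {
    mre <- simulate_mre_cohort(spec, 8, seed = 400 + s, tensors = FALSE)
    zm <- cohort_zmaps(mre)
    st <- voxelwise_one_sample_t(zm)
    roi <- tryCatch(define_hs_mask(st, spec$mask),
                    error = function(e) NULL)
    if (is.null(roi)) 0 else sum(roi$hs) / sum(roi$brain_mask)
  }, numeric(1))
  expect_gte(mean(frac <= 0.05), 0.95)
})
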