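#' Voxelwise one-sample t-test across subjects
#'
#' Tests H0: mean = 0 at every in-mask voxel across a cohort of co-registered
#' maps (typically within-subject OSS z-scores), with df = n - 1 and
#' two-sided p from the t distribution. Voxels with zero across-subject
#' variance are degenerate: they are retained with t = 0 and p = 1 (keeping
#' the multiplicity count stable for FDR) and counted in a warning.
#'
#' @param zmaps List of [scalar_map()]s on one grid with one mask, one per
#'   subject.
#' @param sided `"two"` (default) or `"one"` (upper tail) for the p-value
#'   fed to FDR correction; the joint mask rule applies its own t threshold
#'   either way.
#' @return An object of class `voxel_stat_map`: list with 3-D arrays `t`,
#'   `p`, `q` (Benjamini-Hochberg adjusted over in-mask voxels), the shared
#'   `mask` and `grid`, subject count `n`, and `n_degenerate`.
#' @export
voxelwise_one_sample_t <- function(zmaps, sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(is.list(zmaps))
  n <- length(zmaps)
  if (n < 3) {
    stop("Need at least 3 subjects for the voxelwise t-test.", call. = FALSE)
  }
  ref <- zmaps[[1]]
  for (m in zmaps) {
    check_same_grid(ref$grid, m$grid, "maps entering the voxelwise t-test")
    if (!identical(ref$mask, m$mask)) {
      stop("All subject maps must share one mask.", call. = FALSE)
    }
  }
  X <- vapply(zmaps, function(m) m$values[m$mask], numeric(sum(ref$mask)))
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (n - 1))
  degenerate <- sdv == 0
  tvec <- rep(0, length(mu))
  pvec <- rep(1, length(mu))
  ok <- !degenerate
  tvec[ok] <- mu[ok] / (sdv[ok] / sqrt(n))
  pvec[ok] <- if (sided == "two") {
    2 * stats::pt(abs(tvec[ok]), df = n - 1, lower.tail = FALSE)
  } else {
    stats::pt(tvec[ok], df = n - 1, lower.tail = FALSE)
  }
  if (any(degenerate)) {
    warning(sum(degenerate), " degenerate (zero-variance) voxel(s) set to ",
            "t = 0, p = 1.", call. = FALSE)
  }
  qvec <- bh_fdr(pvec)
  put <- function(v) {
    a <- array(NA_real_, dim = dim(ref$mask)); a[ref$mask] <- v; a
  }
  structure(
    list(t = put(tvec), p = put(pvec), q = put(qvec),
         mask = ref$mask, grid = ref$grid, n = n,
         n_degenerate = sum(degenerate), sided = sided),
    class = "voxel_stat_map"
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, order-preserving with the input indexing and
#' capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("All p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Define the high-strain / low-strain partition
#'
#' Applies the joint rule: a voxel is high strain (HS) iff its FDR-adjusted
#' q < `q_thr` AND its t-statistic is at least `t_thr`. The low-strain (LS)
#' region is the complement of HS within the brain mask, so HS and LS always
#' partition the mask.
#'
#' @param stats A `voxel_stat_map` from [voxelwise_one_sample_t()].
#' @param brain_mask 3-D logical array; must equal the mask the statistics
#'   were computed on.
#' @param q_thr FDR threshold (default 0.05).
#' @param t_thr Effect-size threshold on t (default 4).
#' @param min_cluster Minimum connected-component size (6-connectivity) kept
#'   in HS; default 1 (no filtering).
#' @return An object of class `strain_roi_mask`: logical arrays `hs`, `ls`,
#'   `brain_mask`, the `thresholds`, `grid` and a `provenance` string.
#' @export
define_hs_mask <- function(stats, brain_mask, q_thr = 0.05, t_thr = 4,
                           min_cluster = 1L) {
  stopifnot(inherits(stats, "voxel_stat_map"))
  brain_mask <- array(as.logical(brain_mask), dim = dim(brain_mask))
  if (!identical(brain_mask, stats$mask)) {
    stop("`brain_mask` must be the mask the voxel statistics were computed on.",
         call. = FALSE)
  }
  hs <- brain_mask & !is.na(stats$q) & !is.na(stats$t) &
    (stats$q < q_thr) & (stats$t >= t_thr)
  if (min_cluster > 1L) hs <- drop_small_clusters(hs, min_cluster)
  if (!any(hs)) {
    stop("High-strain mask is empty at q < ", q_thr, " and t >= ", t_thr,
         "; review thresholds or cohort size.", call. = FALSE)
  }
  strain_roi_mask(
    hs = hs, brain_mask = brain_mask, grid = stats$grid,
    thresholds = c(q_thr = q_thr, t_thr = t_thr),
    provenance = sprintf(
      "one-sample t (n=%d, %s-sided p) + BH FDR; joint rule q<%g & t>=%g",
      stats$n, stats$sided, q_thr, t_thr)
  )
}

#' Construct a strain ROI partition directly
#'
#' @param hs Logical 3-D array of high-strain voxels (subset of
#'   `brain_mask`).
#' @param brain_mask Logical 3-D brain mask.
#' @param grid The shared [voxel_grid()].
#' @param thresholds Named numeric vector recording `q_thr` and `t_thr`.
#' @param provenance Free-text description of how `hs` was derived.
#' @return An object of class `strain_roi_mask`; `ls` is always the
#'   complement of `hs` within `brain_mask`.
#' @export
strain_roi_mask <- function(hs, brain_mask, grid,
                            thresholds = c(q_thr = NA, t_thr = NA),
                            provenance = "") {
  hs <- array(as.logical(hs), dim = dim(hs))
  brain_mask <- array(as.logical(brain_mask), dim = dim(brain_mask))
  stopifnot(identical(dim(hs), dim(brain_mask)))
  if (any(hs & !brain_mask)) {
    stop("`hs` must lie inside `brain_mask`.", call. = FALSE)
  }
  ls <- brain_mask & !hs
  structure(
    list(hs = hs, ls = ls, brain_mask = brain_mask, grid = grid,
         thresholds = thresholds, provenance = provenance),
    class = "strain_roi_mask"
  )
}

#' @export
print.strain_roi_mask <- function(x, ...) {
  cat(sprintf(
    "<strain_roi_mask> HS %d voxels (%.1f%% of brain), LS %d voxels\n",
    sum(x$hs), 100 * sum(x$hs) / sum(x$brain_mask), sum(x$ls)))
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

# 6-connectivity connected components, iterative flood fill
drop_small_clusters <- function(hs, min_cluster) {
  dims <- dim(hs)
  lab <- array(0L, dim = dims)
  cur <- 0L
  idx_all <- which(hs)
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      co <- arrayInd(v, dims)
      for (k in seq_len(6)) {
        nb <- co + offsets[k, ]
        if (any(nb < 1) || any(nb > dims)) next
        j <- nb[1] + dims[1] * (nb[2] - 1) + dims[1] * dims[2] * (nb[3] - 1)
        if (hs[j] && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  keep <- which(tabulate(lab[hs]) >= min_cluster)
  hs & array(lab %in% keep, dim = dims)
}

#' Intersect two strain ROI partitions
#'
#' High-strain voxels surviving in both partitions (e.g. occipital and
#' lateral actuation), with LS redefined as the complement within the shared
#' brain mask. An empty intersection is returned with a warning.
#'
#' @param a,b [strain_roi_mask()]s on the same grid and brain mask.
#' @return A [strain_roi_mask()].
#' @export
intersect_masks <- function(a, b) {
  stopifnot(inherits(a, "strain_roi_mask"), inherits(b, "strain_roi_mask"))
  check_same_grid(a$grid, b$grid, "ROI masks")
  if (!identical(a$brain_mask, b$brain_mask)) {
    stop("ROI masks must share one brain mask.", call. = FALSE)
  }
  hs <- a$hs & b$hs
  if (!any(hs)) {
    warning("Intersection of high-strain masks is empty.", call. = FALSE)
  }
  strain_roi_mask(
    hs = hs, brain_mask = a$brain_mask, grid = a$grid,
    thresholds = a$thresholds,
    provenance = paste0("intersection of [", a$provenance, "] and [",
                        b$provenance, "]")
  )
}

#' Tissue composition of the high-strain mask
#'
#' Summarizes how the high-strain region distributes over gray and white
#' matter: the HS fraction of total brain volume, the share of all GM (WM)
#' voxels captured by HS, and the GM/WM/other make-up within HS.
#'
#' @param roi A [strain_roi_mask()].
#' @param labels 3-D array of tissue labels covering the brain mask; values
#'   `"GM"`, `"WM"`, anything else counts as other. Integer codes 1 (GM) and
#'   2 (WM) are also accepted.
#' @return A one-row tibble: `hs_frac_brain`, `hs_share_of_gm`,
#'   `hs_share_of_wm`, `gm_frac_in_hs`, `wm_frac_in_hs`, `other_frac_in_hs`.
#' @export
tissue_composition <- function(roi, labels) {
  stopifnot(inherits(roi, "strain_roi_mask"))
  labels <- as.array(labels)
  if (!identical(dim(labels), dim(roi$brain_mask))) {
    stop("Tissue label volume does not match the brain mask dimensions.",
         call. = FALSE)
  }
  lab <- labels
  if (is.numeric(lab)) {
    lab <- array(ifelse(lab == 1, "GM", ifelse(lab == 2, "WM", "other")),
                 dim = dim(lab))
  }
  gm <- roi$brain_mask & lab == "GM"
  wm <- roi$brain_mask & lab == "WM"
  n_hs <- sum(roi$hs)
  tibble::tibble(
    hs_frac_brain = n_hs / sum(roi$brain_mask),
    hs_share_of_gm = if (any(gm)) sum(roi$hs & gm) / sum(gm) else NA_real_,
    hs_share_of_wm = if (any(wm)) sum(roi$hs & wm) / sum(wm) else NA_real_,
    gm_frac_in_hs = sum(roi$hs & gm) / n_hs,
    wm_frac_in_hs = sum(roi$hs & wm) / n_hs,
    other_frac_in_hs = sum(roi$hs & !gm & !wm) / n_hs
  )
}
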