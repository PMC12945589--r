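#' Octahedral shear strain
#'
#' Computes the octahedral shear strain (OSS) per voxel,
#' \deqn{\gamma_{oct} = \tfrac{2}{3}\sqrt{(\epsilon_1-\epsilon_2)^2 +
#'   (\epsilon_2-\epsilon_3)^2 + (\epsilon_3-\epsilon_1)^2},}
#' where \eqn{\epsilon_1 \ge \epsilon_2 \ge \epsilon_3} are the strain-tensor
#' eigenvalues. OSS summarizes the maximum shear strain at a voxel regardless
#' of direction; it is rotation invariant and insensitive to the volumetric
#' (hydrostatic) part of the tensor. Evaluated via the equivalent invariant
#' form \eqn{\gamma_{oct} = (2/\sqrt{3})\,\lVert \mathrm{dev}\,\epsilon
#' \rVert_F}, which avoids per-voxel eigendecomposition.
#'
#' @param field A [strain_tensor_field()].
#' @return A [scalar_map()] of kind `"oss"`, non-negative inside the mask.
#' @export
compute_oss <- function(field) {
  stopifnot(inherits(field, "strain_tensor_field"))
  cmp <- field$components
  dims <- dim(field$mask)
  comp <- function(k) array(cmp[, , , k], dim = dims)
  xx <- comp(1); xy <- comp(2); yy <- comp(3)
  xz <- comp(4); yz <- comp(5); zz <- comp(6)
  m <- (xx + yy + zz) / 3
  dev2 <- (xx - m)^2 + (yy - m)^2 + (zz - m)^2 + 2 * (xy^2 + xz^2 + yz^2)
  oss <- (2 / sqrt(3)) * sqrt(pmax(dev2, 0))
  oss[!field$mask] <- 0
  scalar_map(field$grid, oss, field$mask, kind = "oss")
}

#' Maximum principal strain
#'
#' Largest eigenvalue of the strain tensor per voxel (the first principal
#' strain). Unlike OSS it mixes shear and longitudinal strain. Computed with
#' the closed-form trigonometric eigenvalue solution for symmetric 3x3
#' matrices, vectorized over voxels.
#'
#' @param field A [strain_tensor_field()].
#' @return A [scalar_map()] of kind `"mps"`.
#' @export
compute_mps <- function(field) {
  stopifnot(inherits(field, "strain_tensor_field"))
  cm <- tensor_component_matrix(field$components, field$mask)
  xx <- cm[, 1]; xy <- cm[, 2]; yy <- cm[, 3]
  xz <- cm[, 4]; yz <- cm[, 5]; zz <- cm[, 6]
  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  # det((A - qI)/p) for the trigonometric formula; guard isotropic voxels
  safe_p <- ifelse(p > 0, p, 1)
  bxx <- (xx - q) / safe_p; byy <- (yy - q) / safe_p; bzz <- (zz - q) / safe_p
  bxy <- xy / safe_p; bxz <- xz / safe_p; byz <- yz / safe_p
  detb <- bxx * (byy * bzz - byz^2) -
    bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  lam1 <- q + 2 * p * cos(phi)
  lam1[p == 0] <- q[p == 0]
  out <- array(0, dim = dim(field$mask))
  out[field$mask] <- lam1
  scalar_map(field$grid, out, field$mask, kind = "mps")
}

#' Z-score a map within subject
#'
#' Standardizes the in-mask values of a map to mean 0 and sample standard
#' deviation 1 (denominator n - 1), across all in-mask voxels of that
#' subject. This removes subject-level scale differences so strain maps are
#' comparable across subjects before group averaging.
#'
#' @param map A [scalar_map()].
#' @return A [scalar_map()] with kind suffixed `"_z"`; values outside the
#'   mask are set to 0 and are undefined.
#' @export
zscore_within_subject <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  v <- map$values[map$mask]
  if (length(v) < 2) {
    stop("Need at least 2 in-mask voxels to z-score.", call. = FALSE)
  }
  s <- stats::sd(v)
  if (s == 0) {
    stop("Constant map inside mask: zero variance, cannot z-score.",
         call. = FALSE)
  }
  out <- array(0, dim = dim(map$values))
  out[map$mask] <- (v - mean(v)) / s
  scalar_map(map$grid, out, map$mask, kind = paste0(map$kind, "_z"))
}

#' Damping ratio from the complex shear modulus
#'
#' \eqn{\xi = G'' / (2 G')}: the relative ability of tissue to dissipate
#' (rather than elastically store) shear-wave energy. Dimensionless.
#'
#' @param moduli A [modulus_field()].
#' @return A [scalar_map()] of kind `"damping"`, non-negative inside mask.
#' @export
damping_ratio <- function(moduli) {
  stopifnot(inherits(moduli, "modulus_field"))
  xi <- array(0, dim = dim(moduli$mask))
  xi[moduli$mask] <- moduli$loss[moduli$mask] / (2 * moduli$storage[moduli$mask])
  scalar_map(moduli$grid, xi, moduli$mask, kind = "damping")
}

#' Voxelwise mean of subject maps
#'
#' Averages a list of co-registered maps (typically within-subject z-scored
#' OSS maps of healthy subjects) voxel by voxel, producing the normative map
#' that defines each voxel's population-level strain exposure.
#'
#' @param zmaps List of [scalar_map()]s on one grid with one mask.
#' @return A [scalar_map()] of the voxelwise arithmetic mean.
#' @export
normative_mean_map <- function(zmaps) {
  stopifnot(is.list(zmaps), length(zmaps) >= 1)
  ref <- zmaps[[1]]
  acc <- array(0, dim = dim(ref$values))
  for (m in zmaps) {
    stopifnot(inherits(m, "scalar_map"))
    check_same_grid(ref$grid, m$grid, "maps entering the normative mean")
    if (!identical(ref$mask, m$mask)) {
      stop("All maps entering the normative mean must share one mask.",
           call. = FALSE)
    }
    acc <- acc + m$values
  }
  acc <- acc / length(zmaps)
  acc[!ref$mask] <- 0
  scalar_map(ref$grid, acc, ref$mask, kind = paste0(ref$kind, "_mean"))
}

#' Paired high-strain vs low-strain contrast of a mechanical map
#'
#' For each subject, averages a map (storage modulus, damping ratio, ...)
#' within the high-strain and low-strain regions, then runs a paired t-test
#' across subjects on the within-subject difference (HS - LS). Positive t
#' means the quantity is larger in high-strain tissue.
#'
#' @param maps List of per-subject [scalar_map()]s on the ROI's grid.
#' @param roi A [strain_roi_mask()] partitioning the brain mask.
#' @return A list of class `region_contrast` with elements `summary`
#'   (tibble: subject, hs_mean, ls_mean, diff), `t`, `df`, `p` (two-sided),
#'   `direction` (`"hs_greater"` or `"ls_greater"`).
#' @export
region_contrast <- function(maps, roi) {
  stopifnot(is.list(maps), inherits(roi, "strain_roi_mask"))
  if (length(maps) < 2) {
    stop("Need at least 2 subjects for a paired contrast.", call. = FALSE)
  }
  if (!any(roi$hs) || !any(roi$ls)) {
    stop("High-strain or low-strain region is empty.", call. = FALSE)
  }
  hs_mean <- vapply(maps, function(m) mean(m$values[roi$hs]), numeric(1))
  ls_mean <- vapply(maps, function(m) mean(m$values[roi$ls]), numeric(1))
  d <- hs_mean - ls_mean
  sdd <- stats::sd(d)
  if (sdd == 0) {
    stop("Degenerate paired contrast: all within-subject differences equal.",
         call. = FALSE)
  }
  n <- length(d)
  tval <- mean(d) / (sdd / sqrt(n))
  structure(
    list(
      summary = tibble::tibble(
        subject = seq_len(n), hs_mean = hs_mean, ls_mean = ls_mean, diff = d),
      t = tval,
      df = n - 1,
      p = 2 * stats::pt(abs(tval), df = n - 1, lower.tail = FALSE),
      direction = if (mean(d) >= 0) "hs_greater" else "ls_greater"
    ),
    class = "region_contrast"
  )
}

#' @export
print.region_contrast <- function(x, ...) {
  cat(sprintf("<region_contrast> paired t = %.3f (df = %d), p = %.3g, %s\n",
              x$t, x$df, x$p, x$direction))
  invisible(x)
}
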