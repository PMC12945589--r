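#' Define a voxel grid
#'
#' A voxel grid fixes the geometry shared by every volume in an analysis:
#' the array dimensions, the voxel size in millimetres, and the 4x4 affine
#' mapping voxel indices (0-based) to world coordinates. All volumes entering
#' a pipeline must live on one grid; the package performs no registration.
#'
#' @param shape Integer vector of length 3: voxels along each axis.
#' @param voxel_size Numeric vector of length 3, voxel edge lengths in mm.
#' @param affine Optional 4x4 voxel-to-world matrix. Defaults to a diagonal
#'   scaling by `voxel_size` centred at the origin.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size = c(2, 2, 2), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (shape - 1) / 2
  }
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("`affine` must be invertible.", call. = FALSE)
  }
  structure(
    list(shape = shape, voxel_size = voxel_size, affine = affine),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$shape, collapse = " x "),
      " voxels @ ", paste(x$voxel_size, collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-8) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) {
    stop("Grid mismatch: ", what, " must share one voxel grid and affine.",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a scalar map
#'
#' A scalar map is a 3-D volume with a brain mask and a label saying what the
#' values are (`"oss"`, `"oss_z"`, `"mps"`, `"damping"`, `"storage"`,
#' `"afd"`, ...). Values outside the mask are carried but undefined.
#'
#' @param grid A [voxel_grid()].
#' @param values 3-D numeric array matching `grid$shape`.
#' @param mask 3-D logical array matching `grid$shape`.
#' @param kind Character label recording the quantity stored.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(grid, values, mask, kind = "scalar") {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- as.array(values)
  mask <- array(as.logical(mask), dim = dim(mask))
  stopifnot(identical(dim(values), as.integer(grid$shape)),
            identical(dim(mask), as.integer(grid$shape)))
  if (anyNA(mask)) stop("`mask` must not contain NA.", call. = FALSE)
  if (!all(is.finite(values[mask]))) {
    stop("Non-finite values inside the mask for kind '", kind, "'.",
         call. = FALSE)
  }
  structure(
    list(grid = grid, values = values, mask = mask, kind = kind),
    class = "scalar_map"
  )
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat("<scalar_map:", x$kind, "> ", paste(x$grid$shape, collapse = "x"),
      sprintf(", %d in-mask voxels, range [%.4g, %.4g]\n",
              sum(x$mask), min(v), max(v)), sep = "")
  invisible(x)
}

# Lower-triangular component order used throughout for symmetric tensors.
TENSOR_COMPONENTS <- c("xx", "xy", "yy", "xz", "yz", "zz")

#' Construct a voxelwise strain-tensor field
#'
#' Stores the six independent components of a symmetric 3x3 strain tensor per
#' voxel, in lower-triangular order `xx, xy, yy, xz, yz, zz` along the fourth
#' array dimension. Strain is dimensionless.
#'
#' @param grid A [voxel_grid()].
#' @param components 4-D numeric array, `c(grid$shape, 6)`.
#' @param mask 3-D logical array matching `grid$shape`.
#' @return An object of class `strain_tensor_field`.
#' @export
strain_tensor_field <- function(grid, components, mask) {
  stopifnot(inherits(grid, "voxel_grid"))
  components <- as.array(components)
  if (!identical(dim(components), c(as.integer(grid$shape), 6L))) {
    stop("`components` must be a 4-D array with 6 tensor components ",
         "(lower-triangular order xx, xy, yy, xz, yz, zz).", call. = FALSE)
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  stopifnot(identical(dim(mask), as.integer(grid$shape)))
  cmat <- tensor_component_matrix(components, mask)
  bad <- !stats::complete.cases(cmat) | rowSums(!is.finite(cmat)) > 0
  if (any(bad)) {
    idx <- which(mask, arr.ind = TRUE)[which(bad)[1], ]
    stop(sprintf(
      "Non-finite tensor components inside the mask at voxel (%d, %d, %d).",
      idx[1], idx[2], idx[3]), call. = FALSE)
  }
  structure(
    list(grid = grid, components = components, mask = mask),
    class = "strain_tensor_field"
  )
}

# in-mask voxels x 6 matrix of tensor components
tensor_component_matrix <- function(components, mask) {
  n <- prod(dim(mask))
  m <- matrix(components, nrow = n, ncol = 6)
  m[as.vector(mask), , drop = FALSE]
}

#' Construct a complex shear-modulus field
#'
#' Holds the storage modulus G' (Pa) and loss modulus G'' (Pa) of the complex
#' viscoelastic shear modulus G* = G' + iG'' per voxel.
#'
#' @param grid A [voxel_grid()].
#' @param storage 3-D array of storage moduli (Pa), positive inside the mask.
#' @param loss 3-D array of loss moduli (Pa), non-negative inside the mask.
#' @param mask 3-D logical array.
#' @return An object of class `modulus_field`.
#' @export
modulus_field <- function(grid, storage, loss, mask) {
  stopifnot(inherits(grid, "voxel_grid"))
  storage <- as.array(storage); loss <- as.array(loss)
  mask <- array(as.logical(mask), dim = dim(mask))
  stopifnot(identical(dim(storage), as.integer(grid$shape)),
            identical(dim(loss), as.integer(grid$shape)),
            identical(dim(mask), as.integer(grid$shape)))
  if (any(storage[mask] <= 0) || !all(is.finite(storage[mask]))) {
    stop("Storage modulus must be finite and > 0 inside the mask.",
         call. = FALSE)
  }
  if (any(loss[mask] < 0) || !all(is.finite(loss[mask]))) {
    stop("Loss modulus must be finite and >= 0 inside the mask.",
         call. = FALSE)
  }
  structure(
    list(grid = grid, storage = storage, loss = loss, mask = mask),
    class = "modulus_field"
  )
}
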