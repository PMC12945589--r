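# NIfTI-1 and text I/O. All volumes written double precision so round trips
# are bit-identical; symmetric tensor fields travel as 4-D volumes with 6
# components in lower-triangular order (xx, xy, yy, xz, yz, zz), recorded in
# the NIfTI description field.

grid_from_nifti <- function(img) {
  d <- dim(img)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  # voxel size from the affine column norms (authoritative over pixdim)
  voxel_grid(shape = d[1:3],
             voxel_size = sqrt(colSums(aff[1:3, 1:3]^2)),
             affine = aff)
}

write_nifti_grid <- function(values, grid, path, description = "") {
  img <- RNifti::asNifti(values, datatype = "double")
  img <- RNifti::asNifti(img, pixdim = grid$voxel_size)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  img$descrip <- substr(description, 1, 79)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a volume to NIfTI-1
#'
#' Scalar maps and masks are written as 3-D volumes; strain tensor fields as
#' 4-D volumes with 6 components (lower-triangular order, noted in the
#' header description). Values are stored double precision, so a write/read
#' round trip is bit-identical.
#'
#' @param x A [scalar_map()], [strain_tensor_field()], logical mask array
#'   with an accompanying `grid`, or [strain_roi_mask()] (written as 0/1/2 =
#'   outside/LS/HS... see details).
#' @param path Output `.nii` or `.nii.gz` path.
#' @param grid Required when `x` is a bare array.
#' @details A `strain_roi_mask` is written as a single labelled volume:
#'   0 outside the brain mask, 1 low strain, 2 high strain.
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, grid = NULL) {
  if (inherits(x, "scalar_map")) {
    write_nifti_grid(x$values, x$grid, path, description = x$kind)
  } else if (inherits(x, "strain_tensor_field")) {
    write_nifti_grid(x$components, x$grid, path,
                     description = "tensor6 xx,xy,yy,xz,yz,zz")
  } else if (inherits(x, "strain_roi_mask")) {
    lab <- array(0, dim = dim(x$brain_mask))
    lab[x$ls] <- 1
    lab[x$hs] <- 2
    write_nifti_grid(lab, x$grid, path, description = "roi 0=out,1=LS,2=HS")
  } else if (is.array(x)) {
    stopifnot(!is.null(grid))
    write_nifti_grid(x * 1, grid, path, description = "volume")
  } else {
    stop("Don't know how to write an object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' 3-D volumes are returned as [scalar_map()]s; 4-D volumes with 6 components
#' as [strain_tensor_field()]s; 4-D volumes with `bvals`/`bvecs` supplied as
#' [dwi_dataset()]s. Any other 4th-dimension size is rejected with the
#' expected layout named.
#'
#' @param path NIfTI file path.
#' @param mask Optional [scalar_map()] or logical array used as the mask; a
#'   map on a mismatching grid is an error. Defaults to all-TRUE.
#' @param kind Label for scalar maps.
#' @param bvals,bvecs Optional gradient-table paths (FSL convention) to read
#'   a 4-D volume as DWI.
#' @return A `scalar_map`, `strain_tensor_field`, or `dwi_dataset`.
#' @export
read_volume <- function(path, mask = NULL, kind = "scalar",
                        bvals = NULL, bvecs = NULL) {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  vals <- array(as.numeric(img), dim = dim(img))
  get_mask <- function() {
    if (is.null(mask)) return(array(TRUE, grid$shape))
    if (inherits(mask, "scalar_map")) {
      check_same_grid(grid, mask$grid, "volume and mask")
      return(mask$values != 0)
    }
    m <- array(as.logical(mask), dim = dim(mask))
    if (!identical(dim(m), as.integer(grid$shape))) {
      stop("Mask dimensions do not match the volume.", call. = FALSE)
    }
    m
  }
  nd <- length(dim(vals))
  if (nd == 3) {
    scalar_map(grid, vals, get_mask(), kind = kind)
  } else if (nd == 4 && !is.null(bvals) && !is.null(bvecs)) {
    gt <- read_gradient_table(bvals, bvecs)
    dwi_dataset(vals, gt$bvals, gt$bvecs, mask = get_mask(), grid = grid)
  } else if (nd == 4 && dim(vals)[4] == 6) {
    strain_tensor_field(grid, vals, get_mask())
  } else {
    stop("Unsupported volume layout: expected 3-D scalar, 4-D with 6 tensor ",
         "components (xx, xy, yy, xz, yz, zz), or 4-D DWI with bvals/bvecs.",
         call. = FALSE)
  }
}

#' Read and write FSL-style gradient tables
#'
#' `bvals` is one row of b-values; `bvecs` is three rows (x, y, z), one
#' column per volume.
#'
#' @param bvals,bvecs File paths.
#' @return List with `bvals` (vector) and `bvecs` (volumes x 3 matrix).
#' @export
read_gradient_table <- function(bvals, bvecs) {
  bv <- scan(bvals, quiet = TRUE)
  gv <- as.matrix(utils::read.table(bvecs))
  if (nrow(gv) != 3) stop("bvecs file must have 3 rows (x, y, z).",
                          call. = FALSE)
  if (ncol(gv) != length(bv)) {
    stop("bvals and bvecs describe different numbers of volumes.",
         call. = FALSE)
  }
  list(bvals = bv, bvecs = t(gv))
}

#' @rdname read_gradient_table
#' @param gt List with `bvals` and `bvecs` (volumes x 3).
#' @param bvals_path,bvecs_path Output paths.
#' @export
write_gradient_table <- function(gt, bvals_path, bvecs_path) {
  cat(paste(gt$bvals, collapse = " "), "\n", file = bvals_path)
  utils::write.table(t(gt$bvecs), bvecs_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}

#' Read/write cohort tables as TSV
#'
#' Fixed column names: subject_id, group, phase, sex, plus any file-reference
#' columns. On write, referenced files (columns ending `_file`) are checked
#' to exist.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_cohort_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "phase", "sex")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("Cohort table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(d$subject_id)) {
    stop("Cohort table has duplicate subject_id values.", call. = FALSE)
  }
  tibble::as_tibble(d)
}

#' @rdname read_cohort_table
#' @param table Cohort tibble.
#' @export
write_cohort_table <- function(table, path) {
  if (anyDuplicated(table$subject_id)) {
    stop("Cohort table has duplicate subject_id values.", call. = FALSE)
  }
  file_cols <- grep("_file$", names(table), value = TRUE)
  for (fc in file_cols) {
    missing <- !file.exists(table[[fc]])
    if (any(missing)) {
      stop("Referenced file(s) do not exist: ",
           paste(table[[fc]][missing], collapse = ", "), call. = FALSE)
    }
  }
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
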