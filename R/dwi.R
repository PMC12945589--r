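#' Construct a DWI dataset
#'
#' Diffusion-weighted signals with their gradient table. Signals may be given
#' as a voxels x volumes matrix (synthetic voxel sets) or a 4-D array on a
#' grid. At least one b = 0 volume is required; all b > 0 volumes must sit on
#' a single shell (within `shell_tol` of the nominal b) and have unit-norm
#' gradient vectors (within 1e-6).
#'
#' @param signals Numeric matrix (voxels x volumes) or 4-D array.
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs Volumes x 3 matrix of gradient directions (rows for b = 0 may
#'   be zero).
#' @param mask Optional 3-D logical mask (4-D array input only).
#' @param grid Optional [voxel_grid()] (4-D array input only).
#' @param shell_tol Tolerance around the nominal shell b-value.
#' @return An object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(signals, bvals, bvecs, mask = NULL, grid = NULL,
                        shell_tol = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  stopifnot(ncol(bvecs) == 3, nrow(bvecs) == length(bvals))
  if (is.matrix(signals)) {
    sig <- signals
  } else {
    signals <- as.array(signals)
    stopifnot(length(dim(signals)) == 4)
    if (is.null(mask)) mask <- array(TRUE, dim(signals)[1:3])
    sig <- matrix(signals, ncol = dim(signals)[4])[as.vector(mask), ,
                                                   drop = FALSE]
  }
  if (ncol(sig) != length(bvals)) {
    stop("Number of volumes (", ncol(sig), ") does not match the gradient ",
         "table (", length(bvals), ").", call. = FALSE)
  }
  b0 <- bvals <= shell_tol
  if (!any(b0)) stop("DWI dataset must contain a b = 0 volume.", call. = FALSE)
  shell <- bvals[!b0]
  if (length(shell)) {
    nominal <- stats::median(shell)
    if (any(abs(shell - nominal) > shell_tol)) {
      stop("b > 0 volumes must lie on a single shell (nominal b = ",
           nominal, ").", call. = FALSE)
    }
    norms <- sqrt(rowSums(bvecs[!b0, , drop = FALSE]^2))
    if (any(abs(norms - 1) > 1e-6)) {
      stop("Gradient vectors for b > 0 volumes must have unit norm ",
           "(max deviation ", format(max(abs(norms - 1))), ").",
           call. = FALSE)
    }
  } else {
    nominal <- 0
  }
  structure(
    list(signals = sig, bvals = bvals, bvecs = bvecs, b0 = b0,
         shell_b = nominal, mask = mask, grid = grid),
    class = "dwi_dataset"
  )
}

#' @export
print.dwi_dataset <- function(x, ...) {
  cat(sprintf(
    "<dwi_dataset> %d voxels, %d volumes (%d b=0, shell b = %g)\n",
    nrow(x$signals), length(x$bvals), sum(x$b0), x$shell_b))
  invisible(x)
}

#' Single-shell gradient table
#'
#' Quasi-uniform hemisphere directions (Fibonacci spiral) plus leading b = 0
#' volumes: the synthetic stand-in for a 60-64-direction b = 1000 s/mm^2
#' acquisition.
#'
#' @param n_dirs Number of diffusion-encoding directions.
#' @param bval Shell b-value (s/mm^2).
#' @param n_b0 Number of b = 0 volumes.
#' @return List with `bvals` and `bvecs` (volumes x 3).
#' @export
gradient_table <- function(n_dirs = 64, bval = 1000, n_b0 = 1) {
  dirs <- fibonacci_sphere(n_dirs, hemisphere = TRUE)
  list(
    bvals = c(rep(0, n_b0), rep(bval, n_dirs)),
    bvecs = rbind(matrix(0, n_b0, 3), dirs)
  )
}

# cylindrically symmetric tensor signal: exp(-b g' D g), D = (ax - rad) uu' + rad I
tensor_signal <- function(bvals, bvecs, u, axial, radial) {
  dot <- as.vector(bvecs %*% u)
  exp(-bvals * (radial + (axial - radial) * dot^2))
}

#' Forward-simulate diffusion-weighted signals
#'
#' Multi-compartment tensor model: each fiber compartment is a cylindrically
#' symmetric diffusion tensor along its orientation, the remaining volume
#' fraction is isotropic, and Rician noise is added at the stated SNR
#' (referenced to the b = 0 signal).
#'
#' @param fiber_config List with one element per voxel; each element is a
#'   list of fibers `list(orientation = unit 3-vector, fraction = f)`. An
#'   empty list means a purely isotropic voxel. Fractions per voxel must sum
#'   to <= 1; the remainder diffuses isotropically at `iso_diffusivity`.
#' @param response_params Numeric `c(axial, radial)` diffusivities (mm^2/s)
#'   of the fiber compartments.
#' @param bvals,bvecs Gradient table, e.g. from [gradient_table()].
#' @param snr Signal-to-noise ratio at b = 0; `Inf` for noiseless.
#' @param s0 b = 0 signal amplitude.
#' @param iso_diffusivity Diffusivity of the isotropic remainder (mm^2/s).
#' @param seed Integer seed for the noise.
#' @return A [dwi_dataset()] with one row per configured voxel.
#' @export
simulate_dwi <- function(fiber_config,
                         response_params = c(axial = 1.7e-3, radial = 0.3e-3),
                         bvals = gradient_table()$bvals,
                         bvecs = gradient_table()$bvecs,
                         snr = Inf, s0 = 1000, iso_diffusivity = 1.0e-3,
                         seed = 1L) {
  bvecs <- as.matrix(bvecs)
  if (!any(bvals <= 50)) {
    stop("Gradient table must include a b = 0 volume.", call. = FALSE)
  }
  hi <- bvals > 50
  norms <- sqrt(rowSums(bvecs[hi, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("Gradient vectors must have unit norm.", call. = FALSE)
  }
  stopifnot(snr > 0)
  ax <- response_params[[1]]; rad <- response_params[[2]]
  nvol <- length(bvals)
  sig <- t(vapply(fiber_config, function(fibers) {
    ftot <- 0
    s <- numeric(nvol)
    for (fb in fibers) {
      u <- fb$orientation / sqrt(sum(fb$orientation^2))
      ftot <- ftot + fb$fraction
      s <- s + fb$fraction * tensor_signal(bvals, bvecs, u, ax, rad)
    }
    if (ftot > 1 + 1e-9) {
      stop("Fiber volume fractions must sum to <= 1 per voxel.",
           call. = FALSE)
    }
    s0 * (s + (1 - ftot) * exp(-bvals * iso_diffusivity))
  }, numeric(nvol)))
  if (is.finite(snr)) {
    sigma <- s0 / snr
    sig <- with_seed(seed, {
      n1 <- matrix(stats::rnorm(length(sig), 0, sigma), nrow(sig))
      n2 <- matrix(stats::rnorm(length(sig), 0, sigma), nrow(sig))
      sqrt((sig + n1)^2 + n2^2)
    })
  }
  dwi_dataset(sig, bvals, bvecs)
}
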