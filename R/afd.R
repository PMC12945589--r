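#' Weighted log-linear diffusion-tensor fit
#'
#' Per voxel, fits `log S = log S0 - b g' D g` by ordinary least squares
#' followed by one reweighted step with weights equal to the squared
#' predicted signals (the standard WLS estimator for log-transformed Rician
#' data). FA and MD are computed from the tensor eigenvalues; negative
#' eigenvalues are clamped to zero for FA, with a count of affected voxels.
#'
#' @param dwi A [dwi_dataset()] with at least 6 directions plus b = 0.
#' @return A list of class `tensor_fit`: `tensor` (voxels x 6, lower
#'   triangular xx, xy, yy, xz, yz, zz, mm^2/s), `fa`, `md`, `evecs1`
#'   (principal eigenvector per voxel), `s0`, `n_clamped`, `excluded`
#'   (voxels with non-positive b0, dropped with a warning).
#' @export
fit_tensor <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  ndir <- sum(!dwi$b0)
  if (ndir < 6 || length(dwi$bvals) < 7) {
    stop("Tensor fit needs at least 6 diffusion directions plus b = 0.",
         call. = FALSE)
  }
  g <- dwi$bvecs
  b <- dwi$bvals
  # design: log S = X beta, beta = (log S0, Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)
  X <- cbind(1,
             -b * g[, 1]^2, -2 * b * g[, 1] * g[, 2], -b * g[, 2]^2,
             -2 * b * g[, 1] * g[, 3], -2 * b * g[, 2] * g[, 3],
             -b * g[, 3]^2)
  S <- dwi$signals
  s0 <- rowMeans(S[, dwi$b0, drop = FALSE])
  excluded <- s0 <= 0 | rowSums(S <= 0) > 0
  if (any(excluded)) {
    warning(sum(excluded),
            " voxel(s) with non-positive signal excluded from tensor fit.",
            call. = FALSE)
  }
  nv <- nrow(S)
  beta <- matrix(NA_real_, nv, 7)
  ok <- which(!excluded)
  if (length(ok)) {
    logS <- log(S[ok, , drop = FALSE])
    # OLS init (shared design): beta = (X'X)^-1 X' y
    XtXi <- solve(crossprod(X))
    b_ols <- logS %*% X %*% XtXi
    # one WLS step per voxel, weights = predicted signal squared
    for (i in seq_along(ok)) {
      w <- as.vector(exp(X %*% b_ols[i, ]))^2
      Xw <- X * w
      beta[ok[i], ] <- solve(crossprod(Xw, X), crossprod(Xw, logS[i, ]))
    }
  }
  nv_ok <- length(ok)
  fa <- rep(NA_real_, nv); md <- rep(NA_real_, nv)
  evec1 <- matrix(NA_real_, nv, 3)
  n_clamped <- 0L
  for (i in ok) {
    D <- matrix(c(beta[i, 2], beta[i, 3], beta[i, 5],
                  beta[i, 3], beta[i, 4], beta[i, 6],
                  beta[i, 5], beta[i, 6], beta[i, 7]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    lam <- e$values
    md[i] <- mean(lam)
    lam_fa <- pmax(lam, 0)
    if (any(lam < 0)) n_clamped <- n_clamped + 1L
    denom <- sum(lam_fa^2)
    fa[i] <- if (denom > 0) {
      sqrt(1.5 * sum((lam_fa - mean(lam_fa))^2) / denom)
    } else 0
    evec1[i, ] <- e$vectors[, 1]
  }
  if (n_clamped > 0) {
    warning(n_clamped, " voxel(s) had negative eigenvalues clamped for FA.",
            call. = FALSE)
  }
  structure(
    list(tensor = beta[, c(2, 3, 4, 5, 6, 7), drop = FALSE],
         fa = pmin(fa, 1), md = md, evecs1 = evec1,
         s0 = exp(beta[, 1]), n_clamped = n_clamped, excluded = excluded),
    class = "tensor_fit"
  )
}

#' Calibrate the single-fiber response function from high-FA voxels
#'
#' Selects up to `max_voxels` voxels with FA above `fa_threshold` (highest FA
#' first), rotates each voxel's b0-normalized signal so its principal
#' eigenvector points to the pole, projects onto the zonal (m = 0) even
#' spherical harmonics, and averages. The result is the axially symmetric
#' signal profile of a coherent single-fiber population, used as the
#' deconvolution kernel.
#'
#' @param dwi A [dwi_dataset()].
#' @param fit The matching [fit_tensor()] result.
#' @param fa_threshold Minimum FA for calibration voxels (default 0.7).
#' @param max_voxels Cap on calibration voxels (default 300).
#' @param lmax Even maximum order of the response (default 8).
#' @return A list of class `response_function`: `coeffs` (zonal coefficient
#'   per even l), `lmax`, `calibration_n`, `fa_threshold`, `basis`.
#' @export
estimate_response <- function(dwi, fit, fa_threshold = 0.7, max_voxels = 300,
                              lmax = 8) {
  stopifnot(inherits(dwi, "dwi_dataset"), inherits(fit, "tensor_fit"))
  cand <- which(!fit$excluded & !is.na(fit$fa) & fit$fa > fa_threshold)
  if (length(cand) < 20) {
    stop("Only ", length(cand), " voxels exceed FA ", fa_threshold,
         "; need >= 20. Lower the threshold.", call. = FALSE)
  }
  cand <- cand[order(fit$fa[cand], decreasing = TRUE)]
  cand <- cand[seq_len(min(max_voxels, length(cand)))]
  hi <- !dwi$b0
  g <- dwi$bvecs[hi, , drop = FALSE]
  ls <- even_degrees(lmax)
  acc <- matrix(0, length(cand), length(ls))
  for (k in seq_along(cand)) {
    i <- cand[k]
    R <- rotation_to_pole(fit$evecs1[i, ])
    grot <- g %*% t(R)
    Bz <- sh_basis(grot, lmax)[, zonal_indices(lmax), drop = FALSE]
    s <- dwi$signals[i, hi] / mean(dwi$signals[i, dwi$b0])
    acc[k, ] <- stats::lsfit(Bz, s, intercept = FALSE)$coefficients
  }
  structure(
    list(coeffs = colMeans(acc), lmax = lmax,
         calibration_n = length(cand), fa_threshold = fa_threshold,
         basis = SH_BASIS_ID),
    class = "response_function"
  )
}

#' @export
print.response_function <- function(x, ...) {
  cat("<response_function> lmax", x$lmax, "from", x$calibration_n,
      "voxels (FA >", x$fa_threshold, ")\n  zonal coeffs:",
      paste(signif(x$coeffs, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Constrained spherical deconvolution
#'
#' Recovers the fiber orientation distribution function (fODF) per voxel by
#' deconvolving the b0-normalized single-shell signal with the single-fiber
#' response in spherical-harmonic space, under an iteratively reweighted
#' non-negativity constraint: fODF amplitudes sampled on a fixed
#' `n_sphere`-direction set that fall below `tau` times the mean initial
#' amplitude are penalized by `lambda`-weighted least squares, repeated until
#' the constraint set stops changing or `max_iter` is reached. The
#' initialization is the unconstrained fit truncated at order 4.
#'
#' @param dwi A [dwi_dataset()].
#' @param response A [estimate_response()] response function.
#' @param lmax Even maximum fODF order; lowered automatically (with a
#'   warning) if the shell has fewer directions than coefficients.
#' @param reg_lambda Constraint weight (default 1).
#' @param amp_threshold_tau Negativity threshold as a fraction of the mean
#'   initial fODF amplitude (default 0.1).
#' @param max_iter Maximum constraint iterations (default 50).
#' @param n_sphere Number of constraint directions (default 300).
#' @param sphere Optional explicit constraint-direction matrix (n x 3 unit
#'   vectors), overriding `n_sphere`. The fixed default set makes results
#'   deterministic; exact rotational equivariance holds only up to its
#'   discretization.
#' @return A list of class `fodf_field`: `sh` (voxels x coefficients),
#'   `lmax`, `basis`, `converged` (logical per voxel), `n_nonconverged`.
#' @export
fit_csd <- function(dwi, response, lmax = 8, reg_lambda = 1,
                    amp_threshold_tau = 0.1, max_iter = 50, n_sphere = 300,
                    sphere = NULL) {
  stopifnot(inherits(dwi, "dwi_dataset"),
            inherits(response, "response_function"))
  stopifnot(lmax %% 2 == 0)
  hi <- !dwi$b0
  ndir <- sum(hi)
  if (n_sh_coef(lmax) > ndir) {
    lmax0 <- lmax
    while (n_sh_coef(lmax) > ndir && lmax > 2) lmax <- lmax - 2
    warning("lmax lowered from ", lmax0, " to ", lmax, ": only ", ndir,
            " diffusion directions available.", call. = FALSE)
  }
  if (response$lmax < lmax) {
    stop("Response lmax (", response$lmax, ") is below the requested fODF ",
         "lmax (", lmax, ").", call. = FALSE)
  }
  nc <- n_sh_coef(lmax)
  g <- dwi$bvecs[hi, , drop = FALSE]
  B <- sh_basis(g, lmax)
  kern <- convolution_kernel(
    response$coeffs[seq_along(even_degrees(lmax))], lmax)
  A <- B * rep(kern, each = nrow(B))
  if (is.null(sphere)) sphere <- fibonacci_sphere(n_sphere)
  Bs <- sh_basis(sphere, lmax)
  # unconstrained init truncated at order 4
  nc4 <- n_sh_coef(min(4, lmax))
  A4 <- A[, seq_len(nc4), drop = FALSE]
  A4i <- solve(crossprod(A4), t(A4))
  AtA <- crossprod(A)
  s0 <- rowMeans(dwi$signals[, dwi$b0, drop = FALSE])
  S <- dwi$signals[, hi, drop = FALSE] / s0
  nv <- nrow(S)
  Fsh <- matrix(0, nv, nc)
  converged <- rep(FALSE, nv)
  for (v in seq_len(nv)) {
    s <- S[v, ]
    f <- numeric(nc)
    f[seq_len(nc4)] <- A4i %*% s
    thr <- amp_threshold_tau * mean(Bs %*% f)
    Ats <- crossprod(A, s)
    neg_prev <- NULL
    for (it in seq_len(max_iter)) {
      amp <- Bs %*% f
      neg <- which(amp < thr)
      if (!is.null(neg_prev) && identical(neg, neg_prev)) {
        converged[v] <- TRUE
        break
      }
      neg_prev <- neg
      if (length(neg) == 0) {
        f <- solve(AtA, Ats)
      } else {
        Bn <- Bs[neg, , drop = FALSE]
        f <- solve(AtA + reg_lambda^2 * crossprod(Bn), Ats)
      }
    }
    Fsh[v, ] <- f
  }
  n_bad <- sum(!converged)
  if (n_bad > 0) {
    warning(n_bad, " voxel(s) did not converge within ", max_iter,
            " constraint iterations (retained, flagged).", call. = FALSE)
  }
  structure(
    list(sh = Fsh, lmax = lmax, basis = SH_BASIS_ID,
         converged = converged, n_nonconverged = n_bad,
         sphere = sphere, tau = amp_threshold_tau, lambda = reg_lambda),
    class = "fodf_field"
  )
}

#' @export
print.fodf_field <- function(x, ...) {
  cat(sprintf("<fodf_field> %d voxels, lmax %d (%s), %d non-converged\n",
              nrow(x$sh), x$lmax, x$basis, x$n_nonconverged))
  invisible(x)
}

#' Total apparent fiber density
#'
#' AFDtotal is the l = 0 spherical-harmonic coefficient of the fODF: an
#' orientation-independent amplitude ("mass" term) of the fiber orientation
#' distribution. In the orthonormal basis used here, the spherical mean of
#' the fODF equals `c00 / sqrt(4 pi)`.
#'
#' @param fodf A [fit_csd()] result.
#' @return Numeric vector of AFDtotal values, one per voxel.
#' @export
afd_total <- function(fodf) {
  stopifnot(inherits(fodf, "fodf_field"))
  fodf$sh[, 1]
}

#' fODF peak directions
#'
#' Local maxima of the fODF amplitude on the constraint sphere, for checking
#' recovered fiber orientations.
#'
#' @param fodf A [fit_csd()] result.
#' @param voxel Voxel index.
#' @param n_peaks Number of peaks to return.
#' @param min_separation_deg Minimum angular separation between peaks.
#' @param n_search Size of the dense search sphere (quantization of the
#'   returned directions is roughly `sqrt(4 pi / n_search)` radians).
#' @return Matrix of peak unit vectors (rows), strongest first.
#' @export
fodf_peaks <- function(fodf, voxel = 1, n_peaks = 2, min_separation_deg = 25,
                       n_search = 8000) {
  sphere <- fibonacci_sphere(n_search)
  amp <- as.vector(sh_basis(sphere, fodf$lmax) %*% fodf$sh[voxel, ])
  ord <- order(amp, decreasing = TRUE)
  peaks <- matrix(numeric(0), 0, 3)
  for (i in ord) {
    d <- sphere[i, ]
    if (nrow(peaks) == 0) {
      peaks <- rbind(peaks, d)
    } else {
      ang <- acos(pmin(abs(peaks %*% d), 1)) * 180 / pi
      if (all(ang > min_separation_deg)) peaks <- rbind(peaks, d)
    }
    if (nrow(peaks) >= n_peaks) break
  }
  peaks
}
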