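# Real, orthonormal, even-order spherical-harmonic basis used for response
# functions and fODFs. Convention: for each even l, m runs -l..l;
# m = 0 is the zonal term, m > 0 carries cos(m phi), m < 0 carries
# sin(|m| phi), all normalized to unit L2 norm on the sphere. The l = 0
# coefficient of a function f therefore equals sqrt(4*pi) times its
# spherical mean.

SH_BASIS_ID <- "real_orthonormal_even"

even_degrees <- function(lmax) seq(0L, as.integer(lmax), by = 2L)

#' Number of even-order spherical-harmonic coefficients up to lmax
#' @param lmax Even maximum harmonic order.
#' @return Integer coefficient count `(lmax + 1) (lmax + 2) / 2`.
#' @export
n_sh_coef <- function(lmax) as.integer((lmax + 1) * (lmax + 2) / 2)

sh_index_table <- function(lmax) {
  do.call(rbind, lapply(even_degrees(lmax), function(l) {
    data.frame(l = l, m = -l:l)
  }))
}

# Associated Legendre P_l^m(x) for m = 0..l WITHOUT the Condon-Shortley
# phase, rows m = 0..l. pracma::legendre includes the (-1)^m phase
# (MATLAB convention); strip it so the real-basis signs are conventional.
assoc_legendre <- function(l, x) {
  if (l == 0) return(matrix(1, nrow = 1, ncol = length(x)))
  P <- pracma::legendre(l, x)
  phase <- (-1)^(0:l)
  P * phase
}

#' Evaluate the real even-order spherical-harmonic basis
#'
#' @param dirs n x 3 matrix of unit direction vectors.
#' @param lmax Even maximum order.
#' @return n x [n_sh_coef()] design matrix; columns ordered by even l
#'   ascending, m from -l to l within l.
#' @export
sh_basis <- function(dirs, lmax) {
  dirs <- as.matrix(dirs)
  stopifnot(ncol(dirs) == 3, lmax %% 2 == 0)
  theta_cos <- pmin(pmax(dirs[, 3], -1), 1)
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  B <- matrix(0, n, n_sh_coef(lmax))
  col <- 0L
  for (l in even_degrees(lmax)) {
    P <- assoc_legendre(l, theta_cos)  # (l+1) x n, rows m = 0..l
    for (m in -l:l) {
      col <- col + 1L
      am <- abs(m)
      nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      B[, col] <- if (m == 0) {
        nlm * P[1, ]
      } else if (m > 0) {
        sqrt(2) * nlm * P[am + 1, ] * cos(am * phi)
      } else {
        sqrt(2) * nlm * P[am + 1, ] * sin(am * phi)
      }
    }
  }
  B
}

# m = 0 (zonal) column indices within the full even basis
zonal_indices <- function(lmax) {
  idx <- sh_index_table(lmax)
  which(idx$m == 0)
}

# Per-coefficient rotational-convolution kernel: an axially symmetric
# response with zonal coefficients r_l convolves a fODF as
# (f * r)_{lm} = f_{lm} * sqrt(4 pi / (2l + 1)) * r_l.
convolution_kernel <- function(r_zonal, lmax) {
  idx <- sh_index_table(lmax)
  ls <- even_degrees(lmax)
  r <- stats::setNames(r_zonal, ls)
  sqrt(4 * pi / (2 * idx$l + 1)) * r[as.character(idx$l)]
}

#' Deterministic quasi-uniform unit directions (Fibonacci sphere)
#'
#' @param n Number of directions.
#' @param hemisphere If `TRUE`, fold all points into the z >= 0 hemisphere
#'   (adequate for antipodally symmetric sampling such as DWI gradients).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n, hemisphere = FALSE) {
  i <- seq_len(n) - 0.5
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- ga * (seq_len(n) - 1)
  d <- cbind(r * cos(phi), r * sin(phi), z)
  if (hemisphere) {
    flip <- d[, 3] < 0
    d[flip, ] <- -d[flip, ]
  }
  d
}

# rotation matrix taking unit vector u to the +z pole
rotation_to_pole <- function(u) {
  u <- u / sqrt(sum(u^2))
  z <- c(0, 0, 1)
  v <- pracma::cross(u, z)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    return(if (u[3] > 0) diag(3) else diag(c(1, -1, -1)))
  }
  c_ <- sum(u * z)
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}
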