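# Synthetic cohort generator: co-registered MRE fields, moduli, AFD maps and
# cohort tables with known ground truth, so every downstream stage is
# testable without clinical data.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Smooth mean-zero unit-sd Gaussian random field (FFT circular convolution
# with a Gaussian kernel of the given FWHM in mm).
smooth_gaussian_field <- function(shape, voxel_size, fwhm_mm) {
  noise <- array(stats::rnorm(prod(shape)), dim = shape)
  if (fwhm_mm <= 0) {
    return((noise - mean(noise)) / stats::sd(noise))
  }
  sigma_vox <- (fwhm_mm / 2.354820045) / voxel_size
  hs <- lapply(1:3, function(a) {
    f <- c(0:(shape[a] %/% 2), -((shape[a] - 1) %/% 2):-1) / shape[a]
    exp(-2 * pi^2 * sigma_vox[a]^2 * f^2)
  })
  H <- outer(outer(hs[[1]], hs[[2]]), hs[[3]])
  dim(H) <- shape
  sm <- Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) / prod(shape)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Default ellipsoidal brain mask for a grid
#'
#' An axis-aligned ellipsoid with semi-axes 90% of the half-extent of each
#' axis: a stand-in for a stereotaxic brain mask on the synthetic grid.
#'
#' @param grid A [voxel_grid()].
#' @return 3-D logical array.
#' @export
make_brain_mask <- function(grid) {
  s <- grid$shape
  cx <- (s + 1) / 2
  ax <- 0.9 * (s - 1) / 2
  ix <- slice.index(array(0, s), 1)
  iy <- slice.index(array(0, s), 2)
  iz <- slice.index(array(0, s), 3)
  ((ix - cx[1]) / ax[1])^2 + ((iy - cx[2]) / ax[2])^2 +
    ((iz - cx[3]) / ax[3])^2 <= 1
}

#' Default planted vulnerable blobs for a grid
#'
#' Three well-separated spherical high-strain blobs at fixed fractional
#' positions of the grid (deep central, inferior-posterior and
#' lateral-inferior locations, echoing where strain concentrates
#' anatomically), radius 10 mm, with graded amplitudes so the strain
#' continuum spans several z-score bins rather than a single step.
#'
#' @param grid A [voxel_grid()].
#' @param radius_mm Blob radius in mm; defaults to 12% of the smallest grid
#'   extent (10 mm on the default 48 x 56 x 48 grid at 2 mm), so blobs stay
#'   inside the mask on smaller grids.
#' @param amplitudes Added strain inside each blob (recycled to 3).
#' @return A list of `list(center, radius, amplitude)` blob descriptors;
#'   centers are voxel coordinates (1-based).
#' @export
default_blobs <- function(grid, radius_mm = NULL,
                          amplitudes = c(1.6, 1.2, 0.8)) {
  s <- grid$shape
  if (is.null(radius_mm)) {
    radius_mm <- round(0.105 * min(s * grid$voxel_size), 1)
  }
  frac <- rbind(c(0.50, 0.52, 0.55),
                c(0.50, 0.28, 0.30),
                c(0.28, 0.55, 0.32))
  amplitudes <- rep_len(amplitudes, nrow(frac))
  lapply(seq_len(nrow(frac)), function(i) {
    list(center = 1 + frac[i, ] * (s - 1), radius = radius_mm,
         amplitude = amplitudes[i])
  })
}

blob_volume <- function(grid, blobs, mask) {
  s <- grid$shape
  ix <- slice.index(array(0, s), 1)
  iy <- slice.index(array(0, s), 2)
  iz <- slice.index(array(0, s), 3)
  field <- array(0, s)
  region <- array(FALSE, s)
  for (b in blobs) {
    stopifnot(b$radius > 0)
    d2 <- ((ix - b$center[1]) * grid$voxel_size[1])^2 +
      ((iy - b$center[2]) * grid$voxel_size[2])^2 +
      ((iz - b$center[3]) * grid$voxel_size[3])^2
    inside <- d2 <= b$radius^2
    if (any(inside & !mask)) {
      stop("Blob at (", paste(round(b$center, 1), collapse = ", "),
           ") extends outside the brain mask.", call. = FALSE)
    }
    # union semantics: overlapping blobs take the larger amplitude
    field[inside] <- pmax(field[inside], b$amplitude)
    region <- region | inside
  }
  list(field = field, region = region)
}

#' Build the normative strain field and ground-truth specification
#'
#' Constructs a normative octahedral-shear-strain field as a constant
#' baseline plus a smooth mean-zero random background plus planted spherical
#' "vulnerable" blobs of stated amplitude, and packages it with the
#' generative parameters used by the cohort simulators. The blob union is
#' the ground-truth high-strain region that downstream mask definition
#' should recover.
#'
#' @param grid A [voxel_grid()].
#' @param blob_spec List of `list(center, radius, amplitude)` descriptors
#'   (voxel-coordinate centers, radius in mm, amplitude in strain units);
#'   defaults to [default_blobs()]. May be empty (`list()`).
#' @param background_smoothness Correlation scale (FWHM, mm) of the smooth
#'   background and of per-subject noise fields.
#' @param seed Integer seed; the field is deterministic given the seed.
#' @param mask Optional logical brain mask (defaults to [make_brain_mask()]).
#' @param baseline Constant baseline strain (arbitrary units; downstream
#'   analysis z-scores within subject, so only relative structure matters).
#' @param background_sd Standard deviation of the shared smooth background.
#'   Set to 0 for cohorts with no fixed spatial structure (null cohorts).
#' @param afd_intercept,slope_control,slope_mtbi AFD generative line:
#'   `AFD = intercept + slope_group * OSSz` (AFD units, AFD units per OSS z).
#' @param random_intercept_sd Between-subject AFD intercept SD (AFD units).
#' @param voxel_noise_sd Voxelwise AFD noise SD (AFD units).
#' @param subject_oss_noise_sd SD of the per-subject smooth OSS noise field
#'   (strain units, same scale as `baseline`/amplitudes).
#' @param modulus_params Named numeric vector `gp_base` (storage modulus
#'   baseline, Pa), `gp_hs_increment` (extra G' inside the true high-strain
#'   region, Pa), `xi_base` (damping-ratio baseline), `xi_hs_decrement`
#'   (damping reduction inside the region).
#' @return An object of class `ground_truth_spec`.
#' @export
make_normative_field <- function(grid,
                                 blob_spec = default_blobs(grid),
                                 background_smoothness = 12,
                                 seed = 1L,
                                 mask = NULL,
                                 baseline = 1.0,
                                 background_sd = 0.04,
                                 afd_intercept = 0.5,
                                 slope_control = 0.041,
                                 slope_mtbi = 0.029,
                                 random_intercept_sd = 0.05,
                                 voxel_noise_sd = 0.15,
                                 subject_oss_noise_sd = 0.15,
                                 modulus_params = c(gp_base = 2400,
                                                    gp_hs_increment = 600,
                                                    xi_base = 0.25,
                                                    xi_hs_decrement = 0.08)) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(mask)) mask <- make_brain_mask(grid)
  mask <- array(as.logical(mask), dim = dim(mask))
  stopifnot(identical(dim(mask), as.integer(grid$shape)))
  stopifnot(random_intercept_sd >= 0, voxel_noise_sd >= 0,
            subject_oss_noise_sd >= 0, background_sd >= 0)
  mp <- modulus_params
  stopifnot(all(c("gp_base", "gp_hs_increment", "xi_base",
                  "xi_hs_decrement") %in% names(mp)))
  if (mp[["xi_base"]] - mp[["xi_hs_decrement"]] <= 0) {
    stop("Damping-ratio baseline minus decrement must stay positive.",
         call. = FALSE)
  }
  background <- with_seed(seed, {
    background_sd *
      smooth_gaussian_field(grid$shape, grid$voxel_size, background_smoothness)
  })
  bl <- blob_volume(grid, blob_spec, mask)
  normative <- baseline + background + bl$field
  normative[!mask] <- 0
  structure(
    list(grid = grid, mask = mask,
         normative_oss_mean = normative,
         background = background,
         blob_field = bl$field,
         true_hs_region = bl$region,
         baseline = baseline,
         background_sd = background_sd,
         background_smoothness = background_smoothness,
         afd_intercept = afd_intercept,
         slope_control = slope_control,
         slope_mtbi = slope_mtbi,
         random_intercept_sd = random_intercept_sd,
         voxel_noise_sd = voxel_noise_sd,
         subject_oss_noise_sd = subject_oss_noise_sd,
         modulus_params = mp,
         seed = seed),
    class = "ground_truth_spec"
  )
}

#' @export
print.ground_truth_spec <- function(x, ...) {
  cat("<ground_truth_spec> grid ", paste(x$grid$shape, collapse = "x"),
      ", ", sum(x$mask), " in-mask voxels, true HS region ",
      sum(x$true_hs_region), " voxels\n", sep = "")
  invisible(x)
}

# normative OSS z-scored within the mask (the fixed spatial regressor)
normative_z_map <- function(spec) {
  m <- scalar_map(spec$grid, spec$normative_oss_mean, spec$mask, kind = "oss")
  zscore_within_subject(m)
}

#' Simulate an MRE cohort with planted mechanical structure
#'
#' Each subject receives an OSS field (normative field plus a per-subject
#' smooth noise field), a strain-tensor field whose eigenstructure reproduces
#' that OSS map exactly (a unit deviatoric template, scaled voxelwise to the
#' target OSS and carried through a smoothly varying rotation field), and
#' storage/loss modulus maps in which the true high-strain region is stiffer
#' (`gp_hs_increment`) and less dissipative (`xi_hs_decrement`).
#'
#' The `lateral` actuation variant redraws the shared smooth background (a
#' different skull-loading pattern) while keeping the planted blobs
#' identical, so occipital and lateral runs with the same seed share the
#' same ground-truth vulnerable region.
#'
#' @param spec A [make_normative_field()] ground-truth specification.
#' @param n_subjects Number of subjects (>= 3).
#' @param actuation `"occipital"` (uses the spec's background unchanged) or
#'   `"lateral"`.
#' @param seed Integer seed.
#' @param tensors If `FALSE`, skip tensor-field synthesis and return OSS maps
#'   only (faster for statistics-level studies).
#' @return An object of class `mre_cohort`: `subjects` (list with per-subject
#'   `oss` [scalar_map()], `tensors` [strain_tensor_field()], `moduli`
#'   [modulus_field()]), `cohort` (tibble: subject_id, group, phase, sex),
#'   `actuation`, and the `spec`.
#' @export
simulate_mre_cohort <- function(spec, n_subjects, actuation = "occipital",
                                seed = 1L, tensors = TRUE) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  actuation <- match.arg(actuation, c("occipital", "lateral"))
  if (n_subjects < 3) {
    stop("Need at least 3 subjects (voxelwise t-test needs df >= 2).",
         call. = FALSE)
  }
  grid <- spec$grid; mask <- spec$mask
  background <- if (actuation == "occipital") {
    spec$background
  } else {
    with_seed(spec$seed + 7901L, {
      spec$background_sd * smooth_gaussian_field(
        grid$shape, grid$voxel_size, spec$background_smoothness)
    })
  }
  normative <- spec$baseline + background + spec$blob_field
  mp <- spec$modulus_params
  subjects <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      noise <- if (spec$subject_oss_noise_sd > 0) {
        spec$subject_oss_noise_sd * smooth_gaussian_field(
          grid$shape, grid$voxel_size, spec$background_smoothness)
      } else 0
      oss_vals <- pmax(normative + noise, 0)
      oss_vals[!mask] <- 0
      oss <- scalar_map(grid, oss_vals, mask, kind = "oss")
      gp <- mp[["gp_base"]] + mp[["gp_hs_increment"]] * spec$true_hs_region +
        30 * array(stats::rnorm(prod(grid$shape)), grid$shape)
      gp <- pmax(gp, 100)
      xi <- mp[["xi_base"]] - mp[["xi_hs_decrement"]] * spec$true_hs_region +
        0.005 * array(stats::rnorm(prod(grid$shape)), grid$shape)
      xi <- pmax(xi, 0.01)
      out <- list(
        oss = oss,
        moduli = modulus_field(grid, gp, 2 * gp * xi, mask)
      )
      if (tensors) out$tensors <- oss_to_tensor_field(oss, seed_offset = i)
      out
    })
  })
  n <- n_subjects
  structure(
    list(
      subjects = subjects,
      cohort = tibble::tibble(
        subject_id = sprintf("mre%03d", seq_len(n)),
        group = "control",
        phase = "normative",
        sex = rep_len(c("F", "M"), n)
      ),
      actuation = actuation,
      spec = spec,
      seed = seed
    ),
    class = "mre_cohort"
  )
}

# Build a tensor field whose voxelwise OSS equals the given map: a unit
# deviatoric template u u' - w w' (orthonormal u, w; eigenvalues 1, 0, -1,
# OSS = (2/3) sqrt(6)) scaled to the target and rotated by a smooth field.
oss_to_tensor_field <- function(oss_map, seed_offset = 0L) {
  grid <- oss_map$grid
  shape <- grid$shape
  sm <- function(k) {
    with_seed(104729L + seed_offset * 31L + k, {
      smooth_gaussian_field(shape, grid$voxel_size, 20)
    })
  }
  alpha <- pi * sm(1L)
  beta <- (pi / 2) * sm(2L)
  # columns u = R e1, w = R e3 of R = Rz(alpha) Ry(beta)
  u1 <- cos(alpha) * cos(beta); u2 <- sin(alpha) * cos(beta); u3 <- -sin(beta)
  w1 <- cos(alpha) * sin(beta); w2 <- sin(alpha) * sin(beta); w3 <- cos(beta)
  scale <- oss_map$values / ((2 / 3) * sqrt(6))
  comp <- array(0, dim = c(shape, 6))
  comp[, , , 1] <- scale * (u1 * u1 - w1 * w1)
  comp[, , , 2] <- scale * (u1 * u2 - w1 * w2)
  comp[, , , 3] <- scale * (u2 * u2 - w2 * w2)
  comp[, , , 4] <- scale * (u1 * u3 - w1 * w3)
  comp[, , , 5] <- scale * (u2 * u3 - w2 * w3)
  comp[, , , 6] <- scale * (u3 * u3 - w3 * w3)
  strain_tensor_field(grid, comp, oss_map$mask)
}

#' AFD generative presets
#'
#' Group slopes (AFD units per OSS z-score) used by [simulate_afd_cohort()].
#' `subacute_chronic` and `acute` carry the reported mixed-model fits for
#' those phases as generative ground truth; `null` makes the groups
#' identical; `hs_deficit` plants equal slopes plus an AFD decrement confined
#' to the true high-strain region in the mTBI group.
#'
#' @param preset One of `"acute"`, `"subacute_chronic"`, `"null"`,
#'   `"hs_deficit"`.
#' @return Named list: `slope_control`, `slope_mtbi`, `hs_deficit`
#'   (AFD units), `phase`.
#' @export
afd_preset <- function(preset) {
  presets <- list(
    subacute_chronic = list(slope_control = 0.041, slope_mtbi = 0.029,
                            hs_deficit = 0, phase = "subacute"),
    acute = list(slope_control = 0.041, slope_mtbi = 0.043,
                 hs_deficit = 0, phase = "acute"),
    null = list(slope_control = 0.041, slope_mtbi = 0.041,
                hs_deficit = 0, phase = "chronic"),
    hs_deficit = list(slope_control = 0.041, slope_mtbi = 0.041,
                      hs_deficit = 0.02, phase = "acute")
  )
  if (!preset %in% names(presets)) {
    stop("Unknown preset '", preset, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[preset]]
}

#' Simulate an AFD cohort from the generative line
#'
#' Voxelwise, per subject:
#' `AFD(v, s) = intercept + slope_group * OSSz(v) + b_s + e(v, s)` with
#' subject random intercepts `b_s ~ N(0, random_intercept_sd^2)` and voxel
#' noise `e ~ N(0, voxel_noise_sd^2)`, where `OSSz` is the z-scored normative
#' strain field of the spec. The `hs_deficit` preset additionally subtracts a
#' constant inside the true high-strain region for mTBI subjects only.
#'
#' @param spec A [make_normative_field()] ground-truth specification.
#' @param preset Preset name, see [afd_preset()].
#' @param n_control,n_mtbi Subjects per group (each >= 2).
#' @param seed Integer seed.
#' @return An object of class `afd_cohort`: `afd` (named list of per-subject
#'   AFD [scalar_map()]s), `cohort` (tibble: subject_id, group, phase, sex),
#'   `oss_z` (the normative z [scalar_map()]), `preset`, `slopes`, `spec`.
#' @export
simulate_afd_cohort <- function(spec, preset = "subacute_chronic",
                                n_control = 31, n_mtbi = 31, seed = 1L) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  ps <- afd_preset(preset)
  if (n_control < 2 || n_mtbi < 2) {
    stop("Need at least 2 subjects per group.", call. = FALSE)
  }
  zmap <- normative_z_map(spec)
  z <- zmap$values
  grid <- spec$grid; mask <- spec$mask
  n <- n_control + n_mtbi
  group <- rep(c("control", "mtbi"), c(n_control, n_mtbi))
  ids <- sprintf("%s%03d", ifelse(group == "control", "ctl", "tbi"),
                 stats::ave(seq_len(n), group, FUN = seq_along))
  slope <- ifelse(group == "control", ps$slope_control, ps$slope_mtbi)
  nvox <- prod(grid$shape)
  afd <- with_seed(seed, {
    b <- stats::rnorm(n, 0, spec$random_intercept_sd)
    lapply(seq_len(n), function(s) {
      vals <- spec$afd_intercept + slope[s] * z + b[s] +
        array(stats::rnorm(nvox, 0, spec$voxel_noise_sd), grid$shape)
      if (ps$hs_deficit > 0 && group[s] == "mtbi") {
        vals[spec$true_hs_region] <- vals[spec$true_hs_region] - ps$hs_deficit
      }
      vals[!mask] <- 0
      scalar_map(grid, vals, mask, kind = "afd")
    })
  })
  names(afd) <- ids
  structure(
    list(
      afd = afd,
      cohort = tibble::tibble(
        subject_id = ids, group = group, phase = ps$phase,
        sex = rep_len(c("F", "M"), n)
      ),
      oss_z = zmap,
      preset = preset,
      slopes = c(control = ps$slope_control, mtbi = ps$slope_mtbi),
      hs_deficit = ps$hs_deficit,
      spec = spec,
      seed = seed
    ),
    class = "afd_cohort"
  )
}
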