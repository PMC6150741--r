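#' Specification of a synthetic tumor phantom
#'
#' Describes one synthetic T2-weighted tumor study: a stationary correlated
#' random intensity field and an ellipsoidal tumor mask with an irregular
#' boundary. Defaults mirror a pelvic T2 acquisition with a 6 mm section
#' thickness and 1.8 mm intersection gap (7.8 mm slice pitch) and a tumor of
#' roughly 50 mm extent, typical of locally advanced rectal cancer.
#'
#' @param shape integer length-3, voxels per axis (nx, ny, nz).
#' @param voxel_size numeric length-3, mm per voxel; the z value is the slice
#'   pitch (thickness + gap).
#' @param correlation_length mm; spatial smoothness of the base texture field.
#'   0 gives voxelwise white noise.
#' @param intensity_mean,intensity_sd target in-mask mean and SD, arbitrary
#'   MR units.
#' @param tumor_axes mm semi-axes of the ellipsoidal mask along (x, y, z).
#' @param boundary_irregularity unitless amplitude of the radial boundary
#'   perturbation (fraction of the local radius).
#' @param seed integer RNG seed; the same spec and seed give a bit-identical
#'   phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 10L),
                         voxel_size = c(0.68, 0.68, 7.8),
                         correlation_length = 3,
                         intensity_mean = 350,
                         intensity_sd = 60,
                         tumor_axes = c(20, 16, 25),
                         boundary_irregularity = 0.15,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            correlation_length >= 0, intensity_sd >= 0,
            length(tumor_axes) == 3L, all(tumor_axes > 0),
            boundary_irregularity >= 0)
  half_extent <- shape * voxel_size / 2
  if (any(tumor_axes * (1 + boundary_irregularity) >= half_extent)) {
    stop("tumor does not fit in the grid: reduce tumor_axes or enlarge shape")
  }
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 correlation_length = correlation_length,
                 intensity_mean = intensity_mean, intensity_sd = intensity_sd,
                 tumor_axes = as.numeric(tumor_axes),
                 boundary_irregularity = boundary_irregularity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specification of test-retest perturbation
#'
#' Controls how a day-2 (and day-1) study is derived from the common
#' underlying tumor. The intensity error has two multiplicative components,
#' drawn independently for each day:
#' a global per-study gain factor `(1 + eta)`, `eta ~ N(0, noise_cv^2)` —
#' the dominant MR test-retest effect (scanner gain / coil loading drift,
#' which no inter-study normalization removes) — and a local field
#' `(1 + eps)` with `eps ~ N(0, noise_cv^2)` constant over in-plane blocks of
#' side about one correlation length, emulating day-to-day physiologic
#' change at the texture scale (per-voxel noise would be absorbed almost
#' entirely by 32-bin quantization). `noise_cv` is therefore the true
#' within-subject coefficient of variation of the study-level signal.
#' `mask_jitter` perturbs the day-2 ROI by per-slice morphological
#' dilation/erosion, emulating manual re-delineation.
#'
#' @param noise_cv fraction, true multiplicative within-subject CV (>= 0).
#' @param mask_jitter voxels, maximum per-slice morphological perturbation
#'   radius of the day-2 mask (>= 0, integer).
#' @param seed integer RNG seed for the perturbations.
#' @return A `retest_spec` list.
#' @export
retest_spec <- function(noise_cv = 0.10, mask_jitter = 0L, seed = 1L) {
  stopifnot(noise_cv >= 0, mask_jitter >= 0)
  structure(list(noise_cv = noise_cv, mask_jitter = as.integer(mask_jitter),
                 seed = as.integer(seed)),
            class = "retest_spec")
}

# Separable Gaussian smoothing of a 3D array with per-axis sigma in voxels.
# Kernels are renormalized at the array edges so constants are preserved.
gaussian_smooth_3d <- function(a, sigma_vox) {
  dims <- dim(a)
  smooth_axis <- function(a, axis, sigma) {
    if (sigma <= 0 || dims[axis] == 1L) return(a)
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-r, r), sd = sigma)
    n <- dims[axis]
    band <- matrix(0, n, n)
    for (off in seq(-r, r)) {
      idx <- seq_len(n)
      ok <- idx + off >= 1 & idx + off <= n
      band[cbind(idx[ok], idx[ok] + off)] <- k[off + r + 1]
    }
    band <- band / rowSums(band)
    m <- matrix(aperm(a, c(axis, setdiff(1:3, axis))), nrow = dims[axis])
    m <- band %*% m
    out <- array(m, dim = c(dims[axis], dims[setdiff(1:3, axis)]))
    aperm(out, order(c(axis, setdiff(1:3, axis))))
  }
  a <- smooth_axis(a, 1L, sigma_vox[1])
  a <- smooth_axis(a, 2L, sigma_vox[2])
  smooth_axis(a, 3L, sigma_vox[3])
}

# Ellipsoidal mask with a band-limited azimuthal radial perturbation.
perturbed_ellipsoid <- function(shape, voxel_size, axes, irregularity) {
  ctr <- (shape + 1) / 2
  x <- (seq_len(shape[1]) - ctr[1]) * voxel_size[1]
  y <- (seq_len(shape[2]) - ctr[2]) * voxel_size[2]
  z <- (seq_len(shape[3]) - ctr[3]) * voxel_size[3]
  xg <- array(rep(x, times = shape[2] * shape[3]), dim = shape)
  yg <- array(rep(rep(y, each = shape[1]), times = shape[3]), dim = shape)
  zg <- array(rep(z, each = shape[1] * shape[2]), dim = shape)
  u <- sqrt((xg / axes[1])^2 + (yg / axes[2])^2 + (zg / axes[3])^2)
  thr <- 1
  if (irregularity > 0) {
    theta <- atan2(yg, xg)
    co <- stats::rnorm(3) / (1:3)
    si <- stats::rnorm(3) / (1:3)
    f <- co[1] * cos(theta) + co[2] * cos(2 * theta) + co[3] * cos(3 * theta) +
      si[1] * sin(theta) + si[2] * sin(2 * theta) + si[3] * sin(3 * theta)
    f <- f / max(abs(f), 1e-12)
    thr <- 1 + irregularity * f
  }
  u <= thr
}

#' Generate a synthetic tumor phantom
#'
#' Builds a stationary Gaussian random field (white noise convolved with a
#' Gaussian kernel of width `correlation_length`, then affinely rescaled so
#' the in-mask voxels have exactly the requested mean and SD) and an
#' ellipsoidal tumor mask with a smooth radial boundary perturbation. The
#' field covers the whole grid, so smoothing filters near the tumor border
#' see realistic surrounding tissue intensities.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([image_volume()]) and `mask`
#'   ([roi_mask()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  mask <- perturbed_ellipsoid(spec$shape, spec$voxel_size, spec$tumor_axes,
                              spec$boundary_irregularity)
  field <- array(stats::rnorm(prod(spec$shape)), dim = spec$shape)
  if (spec$correlation_length > 0) {
    field <- gaussian_smooth_3d(field, spec$correlation_length / spec$voxel_size)
  }
  if (spec$intensity_sd == 0) {
    field[] <- spec$intensity_mean
  } else {
    m <- mean(field[mask])
    s <- stats::sd(field[mask])
    field <- (field - m) / s * spec$intensity_sd + spec$intensity_mean
  }
  list(volume = image_volume(field, spec$voxel_size), mask = roi_mask(mask))
}

# Binary dilation (grow = TRUE) or erosion of one slice by a cross-shaped
# structuring element applied `radius` times.
morph_slice <- function(m, radius, grow) {
  for (i in seq_len(radius)) {
    nx <- nrow(m); ny <- ncol(m)
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-nx, , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, m[, -ny, drop = FALSE])
    m <- if (grow) m | up | dn | lf | rt else m & up & dn & lf & rt
  }
  m
}

# Per-slice random dilation/erosion of a 3D mask, radius <= jitter.
jitter_mask <- function(mask, jitter) {
  if (jitter <= 0) return(mask)
  out <- mask
  for (k in seq_len(dim(mask)[3])) {
    if (!any(mask[, , k])) next
    grow <- stats::runif(1) < 0.5
    radius <- sample.int(jitter, 1L)
    out[, , k] <- morph_slice(mask[, , k], radius, grow)
  }
  if (!any(out)) mask else out
}

# Multiplicative day factor: global gain times block-constant local noise.
# Blocks are in-plane squares of side ~ one correlation length, independent
# across slices.
day_noise_field <- function(spec, noise_cv) {
  dims <- spec$shape
  gain <- if (noise_cv > 0) stats::rnorm(1, 0, noise_cv) else 0
  eps <- array(0, dim = dims)
  if (noise_cv > 0) {
    b <- max(1L, as.integer(round(spec$correlation_length /
                                    mean(spec$voxel_size[1:2]))))
    nbx <- ceiling(dims[1] / b)
    nby <- ceiling(dims[2] / b)
    blk <- array(stats::rnorm(nbx * nby * dims[3], 0, noise_cv),
                 dim = c(nbx, nby, dims[3]))
    ix <- (seq_len(dims[1]) - 1L) %/% b + 1L
    iy <- (seq_len(dims[2]) - 1L) %/% b + 1L
    eps <- blk[ix, iy, , drop = FALSE]
  }
  (1 + gain) * (1 + eps)
}

#' Generate a paired test-retest study
#'
#' Produces two studies of the same underlying tumor. Each day's intensities
#' are the common base field times an independent multiplicative error field
#' (see [retest_spec()]); the day-2 mask is additionally perturbed by
#' per-slice morphological jitter. With `noise_cv = 0` and `mask_jitter = 0`
#' the two studies are identical.
#'
#' @param spec a [phantom_spec()].
#' @param retest a [retest_spec()].
#' @return list with elements `day1` and `day2`, each a list
#'   `(volume, mask)`.
#' @export
generate_retest_pair <- function(spec, retest) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(retest, "retest_spec"))
  base <- generate_phantom(spec)
  set.seed(retest$seed)
  f1 <- day_noise_field(spec, retest$noise_cv)
  f2 <- day_noise_field(spec, retest$noise_cv)
  mask2 <- jitter_mask(base$mask$data, retest$mask_jitter)
  list(
    day1 = list(volume = image_volume(base$volume$data * f1, spec$voxel_size),
                mask = base$mask),
    day2 = list(volume = image_volume(base$volume$data * f2, spec$voxel_size),
                mask = roi_mask(mask2))
  )
}

#' Simulate a test-retest cohort to disk
#'
#' Writes paired day-1/day-2 NIfTI studies for `n_subjects` synthetic
#' subjects plus a manifest CSV. Subjects differ in tumor size, boundary
#' shape and texture coarseness (correlation length drawn uniformly from
#' 2-5 mm, axes scaled by a uniform 0.75-1.25 factor), emulating a
#' heterogeneous patient cohort.
#'
#' @param n_subjects number of subjects.
#' @param out_dir output directory (created if needed).
#' @param noise_cv,mask_jitter test-retest perturbation, see [retest_spec()].
#' @param seed cohort-level seed; all per-subject seeds derive from it.
#' @param reader_id reader label recorded in the manifest.
#' @param base_spec template [phantom_spec()] for cohort defaults.
#' @return path of the manifest CSV (invisibly: data.frame attribute
#'   `manifest`).
#' @export
simulate_cohort <- function(n_subjects, out_dir,
                            noise_cv = 0.10, mask_jitter = 0L,
                            seed = 1L, reader_id = 1L,
                            base_spec = phantom_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path)) file.remove(manifest_path)
  set.seed(seed)
  subj_seeds <- sample.int(2^30, 2 * n_subjects)
  scale <- stats::runif(n_subjects, 0.75, 1.25)
  clen <- stats::runif(n_subjects, 2, 5)
  for (s in seq_len(n_subjects)) {
    sp <- phantom_spec(shape = base_spec$shape, voxel_size = base_spec$voxel_size,
                       correlation_length = clen[s],
                       intensity_mean = base_spec$intensity_mean,
                       intensity_sd = base_spec$intensity_sd,
                       tumor_axes = base_spec$tumor_axes * scale[s],
                       boundary_irregularity = base_spec$boundary_irregularity,
                       seed = subj_seeds[2 * s - 1])
    rt <- retest_spec(noise_cv = noise_cv, mask_jitter = mask_jitter,
                      seed = subj_seeds[2 * s])
    pair <- generate_retest_pair(sp, rt)
    sid <- sprintf("S%03d", s)
    write_study(pair$day1$volume, pair$day1$mask, out_dir,
                subject_id = sid, day = 1L, reader_id = reader_id,
                manifest = manifest_path)
    write_study(pair$day2$volume, pair$day2$mask, out_dir,
                subject_id = sid, day = 2L, reader_id = reader_id,
                manifest = manifest_path)
  }
  manifest_path
}

#' Add an independent second reader to a simulated cohort
#'
#' Emulates the second observer of a two-reader design: for every study in
#' the manifest, the reader-1 tumor delineation is perturbed by per-slice
#' morphological jitter (the volumes are untouched) and written back as a
#' reader-2 study. Repeatability can then be assessed independently per
#' reader.
#'
#' @param manifest path to the cohort manifest CSV.
#' @param mask_jitter per-slice morphological perturbation radius (voxels).
#' @param seed RNG seed for the reader's delineation differences.
#' @return the manifest path, now including reader-2 rows.
#' @export
simulate_second_reader <- function(manifest, mask_jitter = 1L, seed = 1L) {
  m <- read_manifest(manifest)
  r1 <- m[m$reader_id == 1L, ]
  set.seed(seed)
  for (i in seq_len(nrow(r1))) {
    st <- read_study(r1$volume_path[i], r1$mask_path[i])
    m2 <- jitter_mask(st$mask$data, as.integer(mask_jitter))
    write_study(st$volume, roi_mask(m2), dirname(r1$volume_path[i]),
                subject_id = r1$subject_id[i], day = r1$day[i],
                reader_id = 2L, manifest = manifest)
  }
  manifest
}
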