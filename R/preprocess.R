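#' Crop a study to the tumor bounding box
#'
#' Restricts the volume and mask to the mask's bounding box plus a 1-voxel
#' pad (clipped at the grid edge); slices entirely outside the padded box
#' are dropped. The in-mask voxel count is conserved exactly.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @return list `(volume, mask)` on the cropped grid.
#' @export
assemble_tumor_volume <- function(volume, mask) {
  check_same_grid(volume, mask)
  idx <- which(mask$data, arr.ind = TRUE)
  dims <- dim(mask$data)
  lo <- pmax(1L, apply(idx, 2, min) - 1L)
  hi <- pmin(dims, apply(idx, 2, max) + 1L)
  sub <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
  list(volume = image_volume(volume$data[sub[[1]], sub[[2]], sub[[3]], drop = FALSE],
                             volume$voxel_size),
       mask = roi_mask(mask$data[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]))
}

#' In-plane smoothing filter
#'
#' Applies a 2D smoothing filter to every axial slice independently; the
#' large through-plane pitch (6 mm sections + 1.8 mm gap) makes 3D filtering
#' inappropriate. `gaussian` is a separable Gaussian of standard deviation
#' `scale_mm` (edge-renormalized, so constants are preserved); `log` is a
#' Laplacian-of-Gaussian at the same scale; `none` is the identity.
#'
#' @param volume an [image_volume()].
#' @param mode one of `"none"`, `"gaussian"`, `"log"`.
#' @param scale_mm filter scale in mm (required positive unless
#'   `mode = "none"`).
#' @return filtered [image_volume()].
#' @export
apply_smoothing_filter <- function(volume, mode = c("gaussian", "none", "log"),
                                   scale_mm = 2) {
  mode <- match.arg(mode)
  if (mode == "none") return(volume)
  if (!is.numeric(scale_mm) || scale_mm <= 0) {
    stop("scale_mm must be > 0 for mode '", mode, "'")
  }
  sigma_vox <- scale_mm / volume$voxel_size[1:2]
  out <- volume$data
  for (k in seq_len(dim(out)[3])) {
    sl <- out[, , k, drop = FALSE]
    sl <- gaussian_smooth_3d(sl, c(sigma_vox, 0))
    if (mode == "log") {
      s2 <- sl[, , 1]
      nx <- nrow(s2); ny <- ncol(s2)
      # 5-point Laplacian with replicated edges
      up <- s2[c(2:nx, nx), ]; dn <- s2[c(1, 1:(nx - 1)), ]
      lf <- s2[, c(2:ny, ny)]; rt <- s2[, c(1, 1:(ny - 1))]
      sl[, , 1] <- up + dn + lf + rt - 4 * s2
    }
    out[, , k] <- sl
  }
  image_volume(out, volume$voxel_size)
}

#' Quantize a volume to G gray bins over the ROI
#'
#' Equal-width binning over the `[min, max]` of the in-mask intensities (the
#' dominant radiomics convention; it makes all downstream features invariant
#' to positive affine intensity rescaling). The maximum intensity maps to
#' bin `G` (right-closed top bin). Out-of-mask voxels carry `NA`.
#'
#' If the in-mask intensities are constant, every voxel is assigned bin 1
#' and the result carries `constant = TRUE`.
#'
#' @param volume an [image_volume()] (typically after
#'   [apply_smoothing_filter()]).
#' @param mask an [roi_mask()] on the same grid.
#' @param G number of gray bins (default 32).
#' @return A `quantized_volume`: list with `data` (integer array, in-mask
#'   values in 1..G, `NA` outside), `mask` (logical array), `G`, `bin_edges`
#'   (length G+1), `intensities` (in-mask original intensities, for
#'   first-order moments in physical units) and `constant` flag.
#' @export
quantize <- function(volume, mask, G = 32L) {
  check_same_grid(volume, mask)
  G <- as.integer(G)
  stopifnot(G >= 2L)
  m <- mask$data
  x <- volume$data[m]
  mn <- min(x); mx <- max(x)
  # treat float-epsilon spreads (e.g. a filtered constant image) as constant
  constant <- (mx - mn) <= 1e-8 * max(abs(mn), abs(mx), 1)
  if (constant) {
    warning("constant in-mask intensity: all voxels assigned bin 1")
    edges <- seq(mn, mn + 1, length.out = G + 1)
    bins_in <- rep(1L, length(x))
  } else {
    edges <- seq(mn, mx, length.out = G + 1)
    bins_in <- findInterval(x, edges, all.inside = TRUE)
  }
  bins <- array(NA_integer_, dim = dim(m))
  bins[m] <- bins_in
  structure(list(data = bins, mask = m, G = G, bin_edges = edges,
                 intensities = x, constant = constant),
            class = "quantized_volume")
}

#' @export
print.quantized_volume <- function(x, ...) {
  cat(sprintf("<quantized_volume> %s grid, %d in-mask voxels, G=%d bins%s\n",
              paste(dim(x$data), collapse = "x"), sum(x$mask), x$G,
              if (x$constant) " (constant)" else ""))
  invisible(x)
}

#' Full preprocessing chain
#'
#' Crop to the tumor bounding box, filter in-plane, quantize to `G` bins —
#' the segmentation-to-quantization chain applied before any feature
#' computation.
#'
#' @param volume,mask the study.
#' @param config a [run_config()] (filter and quantization settings).
#' @return a `quantized_volume`.
#' @export
preprocess_study <- function(volume, mask, config = run_config()) {
  cropped <- assemble_tumor_volume(volume, mask)
  filtered <- apply_smoothing_filter(cropped$volume,
                                     mode = config$filter$mode,
                                     scale_mm = config$filter$scale_mm)
  quantize(filtered, cropped$mask, G = config$quantization$bins)
}
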