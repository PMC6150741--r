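#' Image volume container
#'
#' A 3D intensity lattice with its voxel geometry. Arrays are stored in the
#' native R convention: 1-based indices, `dim = c(nx, ny, nz)` with x and y
#' in-plane and z through-plane, so `vol$data[, , k]` is axial slice `k`.
#'
#' @param data 3D numeric array of intensities (finite values).
#' @param voxel_size numeric length-3, mm per voxel along (x, y, z). The
#'   through-plane value is the slice pitch (slice thickness plus gap).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L)
  if (!all(is.finite(data))) stop("image intensities must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("voxel_size must be three strictly positive values (mm)")
  }
  structure(list(data = data, voxel_size = voxel_size), class = "image_volume")
}

#' Region-of-interest mask
#'
#' Binary tumor mask on the same grid as its paired [image_volume()].
#'
#' @param data 3D array coercible to logical; at least one voxel must be TRUE.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L)
  data <- array(as.logical(data), dim = dim(data))
  if (anyNA(data)) stop("mask may not contain NA")
  if (!any(data)) stop("mask is empty: at least one voxel must be inside the ROI")
  structure(list(data = data), class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels @ %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s grid, %d voxels in mask\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

check_same_grid <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data))) {
    stop(sprintf("volume grid (%s) and mask grid (%s) differ",
                 paste(dim(volume$data), collapse = "x"),
                 paste(dim(mask$data), collapse = "x")))
  }
  invisible(TRUE)
}

# Overlapping index ranges for a lattice offset d = c(dx, dy, dz): voxel A at
# (i,j,k) pairs with voxel B at (i,j,k) + d. Returns NULL when no overlap.
offset_ranges <- function(dims, d) {
  a <- pmax(1L, 1L - d)
  b <- pmin(dims, dims - d)
  if (any(a > b)) return(NULL)
  list(a = list(a[1]:b[1], a[2]:b[2], a[3]:b[3]),
       b = list((a[1] + d[1]):(b[1] + d[1]),
                (a[2] + d[2]):(b[2] + d[2]),
                (a[3] + d[3]):(b[3] + d[3])))
}

# Gray-level values of all in-mask voxel pairs at offset d.
# Returns a two-column matrix (level at A, level at B), one row per ordered
# pair with both endpoints in the mask.
offset_pairs <- function(bins, mask, d) {
  rg <- offset_ranges(dim(bins), as.integer(d))
  if (is.null(rg)) return(matrix(integer(0), ncol = 2))
  va <- bins[rg$a[[1]], rg$a[[2]], rg$a[[3]], drop = FALSE]
  vb <- bins[rg$b[[1]], rg$b[[2]], rg$b[[3]], drop = FALSE]
  ma <- mask[rg$a[[1]], rg$a[[2]], rg$a[[3]], drop = FALSE]
  mb <- mask[rg$b[[1]], rg$b[[2]], rg$b[[3]], drop = FALSE]
  keep <- ma & mb
  cbind(va[keep], vb[keep])
}

# The 13 unique 3D lattice directions (half of the 26-neighborhood).
directions_3d <- function() {
  list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
       c(1L, 1L, 0L), c(1L, -1L, 0L),
       c(1L, 0L, 1L), c(1L, 0L, -1L),
       c(0L, 1L, 1L), c(0L, 1L, -1L),
       c(1L, 1L, 1L), c(1L, 1L, -1L), c(1L, -1L, 1L), c(1L, -1L, -1L))
}

# The 4 unique in-plane directions used for second-order matrices.
directions_inplane <- function() {
  list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L), c(1L, -1L, 0L))
}
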