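#' Per-slice differential box-counting fractal dimension
#'
#' Treats the quantized gray level as a height field over each axial slice
#' and estimates the differential box-counting dimension of that surface:
#' for box scale `r` the slice bounding box is tiled with `r x r` columns of
#' height `h = r * G / M` (`M` = larger bounding-box side), each occupied
#' column contributes `ceil(max/h) - ceil(min/h) + 1` boxes (min/max over
#' in-mask pixels), and the dimension is the least-squares slope of
#' `log N(r)` on `log(1/r)` over dyadic scales. Slices whose bounding box
#' supports fewer than `min_scales` scales are skipped. Estimates are
#' aggregated across slices as mean and (n-1) SD; 2D per-slice estimation
#' avoids the strongly anisotropic through-plane pitch.
#'
#' @param q a `quantized_volume`.
#' @param scales dyadic box scales in pixels.
#' @param min_scales minimum number of usable scales per slice.
#' @return named list `fractal_fd_mean`, `fractal_fd_sd` (the latter `NA`
#'   with a flag if fewer than 2 slices contribute).
#' @export
boxcount_fd <- function(q, scales = c(2L, 4L, 8L, 16L), min_scales = 4L) {
  stopifnot(inherits(q, "quantized_volume"))
  fds <- numeric(0)
  for (k in seq_len(dim(q$data)[3])) {
    m <- q$mask[, , k]
    if (!any(m)) next
    fd <- slice_dbc_fd(q$data[, , k], m, q$G, scales, min_scales)
    if (!is.na(fd)) fds <- c(fds, fd)
  }
  flags <- character(0)
  if (length(fds) == 0) {
    return(structure(list(fractal_fd_mean = NA_real_, fractal_fd_sd = NA_real_),
                     flags = c("fractal_fd_mean", "fractal_fd_sd")))
  }
  sdv <- if (length(fds) >= 2) stats::sd(fds) else {
    flags <- "fractal_fd_sd"; 0
  }
  structure(list(fractal_fd_mean = mean(fds), fractal_fd_sd = sdv),
            flags = flags)
}

slice_dbc_fd <- function(bins, m, G, scales, min_scales) {
  idx <- which(m, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  bins <- bins[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE]
  m <- m[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE]
  M <- max(dim(m))
  scales <- scales[scales <= M]
  if (length(scales) < min_scales) return(NA_real_)
  logN <- vapply(scales, function(r) {
    h <- r * G / M
    gx <- (seq_len(nrow(m)) - 1L) %/% r
    gy <- (seq_len(ncol(m)) - 1L) %/% r
    box <- outer(gx, gy * (max(gx) + 1L), "+")  # unique box id per cell
    inm <- which(m)
    v <- bins[inm]
    b <- box[inm]
    mx <- tapply(v, b, max)
    mn <- tapply(v, b, min)
    log(sum(ceiling(mx / h) - ceiling(mn / h) + 1))
  }, numeric(1))
  unname(stats::coef(stats::lm(logN ~ I(-log(scales))))[2])
}

#' Gliding-box intensity lacunarity
#'
#' For each box size `r`, slides an `r x r` window over every position of
#' every axial slice; windows containing any out-of-mask voxel are excluded.
#' The box mass is the sum of quantized gray levels in the window and
#' `Lambda(r) = 1 + var(M) / mean(M)^2` (population variance, masses pooled
#' across slices). The reported value is the mean of `Lambda(r)` over the
#' usable box sizes. A spatially homogeneous texture gives 1; gappy,
#' heterogeneous mass distributions give larger values.
#'
#' @param q a `quantized_volume`.
#' @param box_sizes gliding-box sides in pixels.
#' @return scalar lacunarity (>= 1).
#' @export
lacunarity <- function(q, box_sizes = c(2L, 4L, 8L)) {
  stopifnot(inherits(q, "quantized_volume"))
  vals <- q$data
  vals[!q$mask] <- 0L
  lam <- numeric(0)
  for (r in box_sizes) {
    masses <- numeric(0)
    for (k in seq_len(dim(vals)[3])) {
      m <- q$mask[, , k]
      if (!any(m)) next
      if (nrow(m) < r || ncol(m) < r) next
      sm <- box_sums(vals[, , k], r)
      cnt <- box_sums(m * 1L, r)
      masses <- c(masses, sm[cnt == r * r])  # fully in-mask windows only
    }
    if (length(masses) == 0) next
    mu <- mean(masses)
    if (mu == 0) stop("lacunarity undefined: zero total box mass")
    lam <- c(lam, 1 + mean((masses - mu)^2) / mu^2)
  }
  if (length(lam) == 0) stop("no gliding box fits inside the mask")
  mean(lam)
}

# All r x r window sums of a matrix via a summed-area table.
box_sums <- function(x, r) {
  sat <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed SAT
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  n1 <- nrow(x) - r + 1L; n2 <- ncol(x) - r + 1L
  i <- seq_len(n1); j <- seq_len(n2)
  sat[i + r, j + r, drop = FALSE] - sat[i, j + r, drop = FALSE] -
    sat[i + r, j, drop = FALSE] + sat[i, j, drop = FALSE]
}

# Expected R/S of an i.i.d. Gaussian series of length w (Anis-Lloyd with
# the Peters finite-sample factor); used to de-bias the Hurst slope.
expected_rs <- function(w) {
  s <- sum(sqrt((w - seq_len(w - 1)) / seq_len(w - 1)))
  front <- (w - 0.5) / w
  if (w <= 340) {
    front * exp(lgamma((w - 1) / 2) - lgamma(w / 2)) / sqrt(pi) * s
  } else {
    front / sqrt(w * pi / 2) * s
  }
}

#' Rescaled-range Hurst exponent
#'
#' Extracts all maximal contiguous in-mask 1D gray-level profiles along
#' in-plane rows and columns of every slice, computes the rescaled range
#' R/S in non-overlapping windows of dyadic length, and estimates H as
#' `0.5 +` the least-squares slope of `log(mean R/S) - log E0[R/S]` on
#' `log w`, where `E0` is the expected R/S of an uncorrelated series
#' (Anis-Lloyd-Peters correction; the plain R/S slope is biased upward for
#' the short profiles a tumor ROI yields). H = 0.5 indicates an
#' uncorrelated profile, H > 0.5 a persistent (smooth) one.
#'
#' @param q a `quantized_volume`.
#' @param min_window smallest window length.
#' @param min_profile shortest usable profile length.
#' @return scalar H estimate, or `NA` with attribute `flags` if no profile
#'   is long enough.
#' @export
hurst_exponent <- function(q, min_window = 8L, min_profile = 16L) {
  stopifnot(inherits(q, "quantized_volume"))
  profiles <- list()
  dims <- dim(q$data)
  for (k in seq_len(dims[3])) {
    sl <- q$data[, , k]; m <- q$mask[, , k]
    if (!any(m)) next
    for (j in seq_len(dims[2])) profiles <- c(profiles, mask_segments(sl[, j], m[, j]))
    for (i in seq_len(dims[1])) profiles <- c(profiles, mask_segments(sl[i, ], m[i, ]))
  }
  profiles <- profiles[vapply(profiles, length, 1L) >= min_profile]
  if (length(profiles) == 0) {
    return(structure(NA_real_, flags = "fractal_hurst"))
  }
  max_len <- max(vapply(profiles, length, 1L))
  windows <- min_window * 2^(0:30)
  windows <- windows[windows <= max_len]
  rs_by_w <- lapply(windows, function(w) {
    out <- numeric(0)
    for (p in profiles) {
      nb <- length(p) %/% w
      if (nb < 1) next
      for (b in seq_len(nb)) {
        x <- p[((b - 1) * w + 1):(b * w)]
        s <- sqrt(mean((x - mean(x))^2))
        if (s == 0) next
        y <- cumsum(x - mean(x))
        out <- c(out, (max(y) - min(y)) / s)
      }
    }
    out
  })
  ok <- vapply(rs_by_w, length, 1L) > 0
  if (sum(ok) < 2) return(structure(NA_real_, flags = "fractal_hurst"))
  w <- windows[ok]
  y <- log(vapply(rs_by_w[ok], mean, numeric(1))) -
    log(vapply(w, expected_rs, numeric(1)))
  slope <- unname(stats::coef(stats::lm(y ~ log(w)))[2])
  0.5 + slope
}

# Maximal runs of consecutive in-mask values along a 1D line.
mask_segments <- function(v, m) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(i) as.numeric(v[starts[i]:ends[i]]))
}
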