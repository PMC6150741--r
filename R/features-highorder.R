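#' Neighborhood gray-tone difference matrix
#'
#' For every in-mask voxel with at least one in-mask neighbor, computes the
#' mean gray level of its neighborhood (center excluded, out-of-mask
#' neighbors excluded) and accumulates `s(g)`, the summed absolute
#' deviation of the level-`g` voxels from their neighborhood means, together
#' with the occupancy probabilities `p(g)`. The default neighborhood is the
#' full 3D 26-neighborhood (high-order features deliberately couple
#' adjacent imaging planes); `"8-in-plane"` restricts to the axial plane.
#'
#' @param q a `quantized_volume`.
#' @param neighborhood `"26"` or `"8-in-plane"`.
#' @return an `ngtdm` object: list with vectors `s`, `p`, `n_valid`,
#'   `levels` (occupied gray levels).
#' @export
compute_ngtdm <- function(q, neighborhood = c("26", "8-in-plane")) {
  neighborhood <- match.arg(neighborhood)
  dims <- dim(q$data)
  offs <- list()
  zr <- if (neighborhood == "26") -1:1 else 0L
  for (dz in zr) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    offs <- c(offs, list(c(dx, dy, dz)))
  }
  vals <- q$data
  vals[!q$mask] <- 0L
  nbr_sum <- array(0, dims)
  nbr_cnt <- array(0L, dims)
  for (d in offs) {
    rg <- offset_ranges(dims, as.integer(d))
    if (is.null(rg)) next
    nbr_sum[rg$a[[1]], rg$a[[2]], rg$a[[3]]] <-
      nbr_sum[rg$a[[1]], rg$a[[2]], rg$a[[3]]] +
      vals[rg$b[[1]], rg$b[[2]], rg$b[[3]]]
    nbr_cnt[rg$a[[1]], rg$a[[2]], rg$a[[3]]] <-
      nbr_cnt[rg$a[[1]], rg$a[[2]], rg$a[[3]]] +
      q$mask[rg$b[[1]], rg$b[[2]], rg$b[[3]]]
  }
  valid <- q$mask & nbr_cnt > 0L
  n_valid <- sum(valid)
  if (n_valid == 0) stop("no in-mask voxel has an in-mask neighbor")
  g <- q$data[valid]
  dev <- abs(g - nbr_sum[valid] / nbr_cnt[valid])
  s_full <- as.numeric(rowsum(dev, g))
  levels <- sort(unique(g))
  cnt <- as.numeric(table(factor(g, levels = levels)))
  structure(list(s = s_full, p = cnt / n_valid, levels = levels,
                 n_valid = n_valid),
            class = "ngtdm")
}

#' Amadasun-King NGTDM features
#'
#' Coarseness `1 / (eps + sum p s)` (capped at `1/eps`, `eps = 1e-12`),
#' contrast, busyness and complexity in their standard forms over the
#' occupied gray levels. A single occupied level makes contrast and
#' busyness degenerate; both are reported as 0 and flagged.
#'
#' @param m an `ngtdm` from [compute_ngtdm()].
#' @param eps numerical floor in coarseness.
#' @return named list of the 4 `ngtdm_*` features with attribute `flags`.
#' @export
ngtdm_features <- function(m, eps = 1e-12) {
  stopifnot(inherits(m, "ngtdm"))
  g <- m$levels
  p <- m$p
  s <- m$s
  n <- m$n_valid
  ng <- length(g)
  flags <- character(0)
  coarseness <- min(1 / (eps + sum(p * s)), 1 / eps)
  if (ng >= 2) {
    ii <- matrix(g, ng, ng); jj <- t(ii)
    pp <- outer(p, p)
    contrast <- sum(pp * (ii - jj)^2) / (ng * (ng - 1)) * sum(s) / n
    denom <- sum(abs(outer(g * p, g * p, "-")))
    busyness <- if (denom > 0) sum(p * s) / denom else {
      flags <- c(flags, "ngtdm_busyness"); 0
    }
    num <- abs(ii - jj) * (outer(p * s, p * s, "+")) / (outer(p, p, "+"))
    complexity <- sum(num) / n
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0
    flags <- c(flags, "ngtdm_contrast", "ngtdm_busyness", "ngtdm_complexity")
  }
  structure(list(
    ngtdm_coarseness = coarseness,
    ngtdm_contrast = contrast,
    ngtdm_busyness = busyness,
    ngtdm_complexity = complexity
  ), flags = flags)
}

#' Gray-level run-length matrix
#'
#' Counts maximal in-mask runs of identical gray level along each direction
#' of the 13 unique 3D lattice directions (pooled). A run is broken by a
#' gray-level change, a mask boundary, or the grid edge.
#'
#' @param q a `quantized_volume`.
#' @param directions list of integer length-3 offsets.
#' @return a `glrlm` object: list with `r` (G x Lmax count matrix), `Nr`
#'   (total runs), `Np` (in-mask voxels), `D` (number of directions).
#' @export
compute_glrlm <- function(q, directions = directions_3d()) {
  stopifnot(inherits(q, "quantized_volume"))
  dims <- dim(q$data)
  coords <- which(q$mask, arr.ind = TRUE)
  Np <- nrow(coords)
  vals <- q$data[q$mask]
  Lmax <- max(dims)
  counts <- matrix(0, q$G, Lmax)
  key_mult <- c(1, 4 * Lmax, 16 * Lmax^2)
  for (d in directions) {
    d <- as.integer(d)
    a <- which(d != 0)[1]
    t_pos <- coords[, a] * d[a]
    base <- coords - outer(t_pos, d)  # line origin: coords - t*d
    key <- (base %*% key_mult)[, 1]
    ord <- order(key, t_pos)
    kk <- key[ord]; tt <- t_pos[ord]; vv <- vals[ord]
    brk <- c(TRUE, kk[-1] != kk[-length(kk)] |
               tt[-1] != tt[-length(tt)] + 1 |
               vv[-1] != vv[-length(vv)])
    run_id <- cumsum(brk)
    len <- tabulate(run_id)
    lev <- vv[brk]
    counts <- counts + matrix(tabulate((len - 1L) * q$G + lev,
                                       nbins = q$G * Lmax), q$G, Lmax)
  }
  stopifnot(sum(counts %*% seq_len(Lmax)) == Np * length(directions))
  structure(list(r = counts, Nr = sum(counts), Np = Np,
                 D = length(directions)),
            class = "glrlm")
}

#' Run-length features
#'
#' Galloway-type statistics of the pooled run-length counts `r(g, l)`:
#' short/long-run emphasis, gray-level nonuniformity (also reported as
#' "intensity variability"), run-length nonuniformity, run percentage
#' `Nr / (Np * D)`, and low/high gray-level run emphasis.
#'
#' @param m a `glrlm` from [compute_glrlm()].
#' @return named list of the 7 `glrl_*` features.
#' @export
glrlm_features <- function(m) {
  stopifnot(inherits(m, "glrlm"))
  r <- m$r
  Nr <- m$Nr
  l <- seq_len(ncol(r))
  g <- seq_len(nrow(r))
  rg <- rowSums(r)  # per gray level
  rl <- colSums(r)  # per run length
  list(
    glrl_sre = sum(sweep(r, 2, l^2, "/")) / Nr,
    glrl_lre = sum(sweep(r, 2, l^2, "*")) / Nr,
    glrl_intensity_variability = sum(rg^2) / Nr,
    glrl_run_length_variability = sum(rl^2) / Nr,
    glrl_run_percentage = Nr / (m$Np * m$D),
    glrl_lgre = sum(rg / g^2) / Nr,
    glrl_hgre = sum(rg * g^2) / Nr
  )
}

#' Gray-level zone-size matrix
#'
#' Zones are connected components of iso-gray-level in-mask voxels; the
#' default connectivity is the full 3D 26-neighborhood (`"6"` restricts to
#' face neighbors). Components are found on the voxel adjacency graph.
#'
#' @param q a `quantized_volume`.
#' @param connectivity `"26"` or `"6"`.
#' @return a `glzsm` object: list with `zones` (data.frame of `level`,
#'   `size`, `count`), `Nz` (zone count), `Np` (in-mask voxels).
#' @export
compute_glzsm <- function(q, connectivity = c("26", "6")) {
  connectivity <- match.arg(connectivity)
  dirs <- if (connectivity == "26") directions_3d() else
    list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  dims <- dim(q$data)
  vox_id <- array(0L, dims)
  vox_id[q$mask] <- seq_len(sum(q$mask))
  Np <- sum(q$mask)
  edges <- integer(0)
  for (d in dirs) {
    rg <- offset_ranges(dims, as.integer(d))
    if (is.null(rg)) next
    ia <- vox_id[rg$a[[1]], rg$a[[2]], rg$a[[3]]]
    ib <- vox_id[rg$b[[1]], rg$b[[2]], rg$b[[3]]]
    va <- q$data[rg$a[[1]], rg$a[[2]], rg$a[[3]]]
    vb <- q$data[rg$b[[1]], rg$b[[2]], rg$b[[3]]]
    keep <- ia > 0L & ib > 0L & va == vb
    keep[is.na(keep)] <- FALSE
    edges <- c(edges, rbind(ia[keep], ib[keep]))
  }
  gr <- igraph::make_graph(edges, n = Np, directed = FALSE)
  comp <- igraph::components(gr)
  lev <- q$data[q$mask]
  zone_level <- as.integer(lev[match(seq_len(comp$no), comp$membership)])
  zone_size <- as.integer(comp$csize)
  stopifnot(sum(zone_size) == Np)
  tab <- stats::aggregate(list(count = rep(1L, comp$no)),
                          by = list(level = zone_level, size = zone_size),
                          FUN = sum)
  structure(list(zones = tab, Nz = as.integer(comp$no), Np = Np),
            class = "glzsm")
}

#' Zone-size features
#'
#' Thibault-type statistics of the zone counts `z(g, s)`: short/large-zone
#' emphasis, intensity nonuniformity (gray-level nonuniformity over zones),
#' intensity variability (the count-weighted variance of the zone gray
#' levels), size-zone variability (zone-size nonuniformity), zone
#' percentage `Nz / Np`, low/high gray-level zone emphasis and the
#' count-weighted variance of zone sizes.
#'
#' @param m a `glzsm` from [compute_glzsm()].
#' @return named list of the 9 `glzsm_*` features.
#' @export
glzsm_features <- function(m) {
  stopifnot(inherits(m, "glzsm"))
  z <- m$zones$count
  g <- m$zones$level
  s <- m$zones$size
  Nz <- m$Nz
  mu_g <- sum(z * g) / Nz
  mu_s <- sum(z * s) / Nz
  zg <- rowsum(z, g)  # counts per gray level
  zs <- rowsum(z, s)  # counts per size
  list(
    glzsm_short_zone_emphasis = sum(z / s^2) / Nz,
    glzsm_large_zone_emphasis = sum(z * s^2) / Nz,
    glzsm_intensity_nonuniformity = sum(zg^2) / Nz,
    glzsm_intensity_variability = sum(z * (g - mu_g)^2) / Nz,
    glzsm_size_zone_variability = sum(zs^2) / Nz,
    glzsm_zone_percentage = Nz / m$Np,
    glzsm_low_gray_emphasis = sum(z / g^2) / Nz,
    glzsm_high_gray_emphasis = sum(z * g^2) / Nz,
    glzsm_zone_size_variance = sum(z * (s - mu_s)^2) / Nz
  )
}
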