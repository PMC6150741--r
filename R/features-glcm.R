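#' Gray-level co-occurrence matrix
#'
#' Counts pairs of in-mask gray levels at lattice offset `distance` along
#' each in-plane direction, pooled over all slices and directions into a
#' single matrix, symmetrized and normalized to sum 1. Pairs with either
#' endpoint outside the mask are excluded. The default direction set is the
#' 4 unique in-plane offsets `{(1,0),(0,1),(1,1),(1,-1)}`, closed under 90
#' degree rotation.
#'
#' @param q a `quantized_volume`.
#' @param distance lattice step (>= 1).
#' @param directions list of integer length-3 offsets.
#' @return a `glcm` object: list with `p` (G x G probability matrix),
#'   `n_pairs` (ordered pair count before normalization), `distance`,
#'   `directions`.
#' @export
compute_glcm <- function(q, distance = 1L,
                         directions = directions_inplane()) {
  stopifnot(inherits(q, "quantized_volume"), distance >= 1)
  counts <- matrix(0, q$G, q$G)
  for (d in directions) {
    pr <- offset_pairs(q$data, q$mask, as.integer(d) * as.integer(distance))
    if (nrow(pr) == 0) next
    counts <- counts + glcm_tally(pr, q$G)
  }
  counts <- counts + t(counts)  # symmetrize: count both pair orders
  n <- sum(counts)
  if (n == 0) stop("no valid in-mask voxel pairs for the GLCM")
  structure(list(p = counts / n, n_pairs = n, distance = distance,
                 directions = directions),
            class = "glcm")
}

glcm_tally <- function(pairs, G) {
  matrix(tabulate((pairs[, 2] - 1L) * G + pairs[, 1], nbins = G * G), G, G)
}

#' Haralick features of a GLCM
#'
#' Standard second-order features of the normalized symmetric co-occurrence
#' matrix `p(i, j)` with gray-level indices the bin numbers `1..G`:
#' entropy `-sum p log2 p` (bits), energy `sum p^2`,
#' contrast `sum p (i-j)^2`, homogeneity `sum p / (1 + |i-j|)`, inverse
#' difference moment `sum p / (1 + (i-j)^2)`, correlation via the marginal
#' means/SDs, cluster shade and prominence
#' `sum p ((i - mu_i) + (j - mu_j))^{3,4}`, variance
#' `sum p (i - mu_i)^2`, and sum average/entropy and difference entropy on
#' the `i+j` and `|i-j|` marginals. A degenerate marginal SD makes
#' correlation undefined; it is reported as 0 and flagged.
#'
#' @param m a `glcm` from [compute_glcm()].
#' @return named list of the 12 `glcm_*` features with attribute `flags`.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm"))
  p <- m$p
  G <- nrow(p)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  pi_m <- rowSums(p)
  mu_i <- sum(seq_len(G) * pi_m)
  sd_i <- sqrt(sum((seq_len(G) - mu_i)^2 * pi_m))
  flags <- character(0)
  if (sd_i > 0) {
    correlation <- sum((i - mu_i) * (j - mu_i) * p) / sd_i^2
  } else {
    correlation <- 0
    flags <- "glcm_correlation"
  }
  # i+j and |i-j| marginals
  psum <- tapply(as.vector(p), as.vector(i + j), sum)
  pdiff <- tapply(as.vector(p), as.vector(abs(i - j)), sum)
  nz <- function(v) v[v > 0]
  structure(list(
    glcm_entropy = -sum(nz(p) * log2(nz(p))),
    glcm_energy = sum(p^2),
    glcm_contrast = sum(p * (i - j)^2),
    glcm_homogeneity = sum(p / (1 + abs(i - j))),
    glcm_idm = sum(p / (1 + (i - j)^2)),
    glcm_correlation = correlation,
    glcm_cluster_shade = sum(p * (i + j - 2 * mu_i)^3),
    glcm_cluster_prominence = sum(p * (i + j - 2 * mu_i)^4),
    glcm_sum_entropy = -sum(nz(psum) * log2(nz(psum))),
    glcm_difference_entropy = -sum(nz(pdiff) * log2(nz(pdiff))),
    glcm_sum_average = sum(as.numeric(names(psum)) * psum),
    glcm_variance = sum(p * (i - mu_i)^2)
  ), flags = flags)
}

#' Gray-level difference matrix
#'
#' Distribution of absolute gray-level differences `k = |i - j|` over the
#' same in-mask pair set as [compute_glcm()] (one count per ordered pair
#' per direction); by construction it equals the `|i - j|` marginal of the
#' symmetrized GLCM.
#'
#' @inheritParams compute_glcm
#' @return a `gldm` object: list with `pd` (probabilities over differences
#'   `0..G-1`) and `n_pairs`.
#' @export
compute_gldm <- function(q, distance = 1L,
                         directions = directions_inplane()) {
  stopifnot(inherits(q, "quantized_volume"), distance >= 1)
  counts <- numeric(q$G)  # index k+1 holds difference k
  n <- 0
  for (d in directions) {
    pr <- offset_pairs(q$data, q$mask, as.integer(d) * as.integer(distance))
    if (nrow(pr) == 0) next
    k <- abs(pr[, 1] - pr[, 2])
    counts <- counts + tabulate(k + 1L, nbins = q$G)
    n <- n + nrow(pr)
  }
  if (n == 0) stop("no valid in-mask voxel pairs for the GLDM")
  structure(list(pd = counts / n, n_pairs = n, distance = distance,
                 directions = directions),
            class = "gldm")
}

#' Features of a gray-level difference matrix
#'
#' `gldm_entropy = -sum pd log2 pd` (bits), `gldm_contrast = sum k^2 pd(k)`
#' and `gldm_mean = sum k pd(k)` over differences `k = 0..G-1`.
#'
#' @param m a `gldm` from [compute_gldm()].
#' @return named list of the 3 `gldm_*` features.
#' @export
gldm_features <- function(m) {
  stopifnot(inherits(m, "gldm"))
  k <- seq_along(m$pd) - 1
  pd <- m$pd
  nz <- pd[pd > 0]
  list(
    gldm_entropy = -sum(nz * log2(nz)),
    gldm_contrast = sum(k^2 * pd),
    gldm_mean = sum(k * pd)
  )
}
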