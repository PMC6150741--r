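# Independent brute-force oracles: explicit voxel/level loops, no shared
# code with the package implementations beyond the quantized_volume layout.

# Build a quantized_volume directly from an integer bin array (+ optional
# mask); intensities are taken equal to the bin values.
make_qv <- function(bins, mask = NULL, G = max(bins, na.rm = TRUE)) {
  bins <- as.array(bins)
  if (length(dim(bins)) == 2L) dim(bins) <- c(dim(bins), 1L)
  storage.mode(bins) <- "integer"
  if (is.null(mask)) mask <- !is.na(bins)
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  bins[!mask] <- NA_integer_
  structure(list(data = bins, mask = mask, G = as.integer(G),
                 bin_edges = seq(0.5, G + 0.5, length.out = G + 1),
                 intensities = as.numeric(bins[mask]), constant = FALSE),
            class = "quantized_volume")
}

inside <- function(p, dims) all(p >= 1L) && all(p <= dims)

bf_dirs_inplane <- list(c(1L,0L,0L), c(0L,1L,0L), c(1L,1L,0L), c(1L,-1L,0L))

bf_dirs_3d <- list(c(1L,0L,0L), c(0L,1L,0L), c(0L,0L,1L),
                   c(1L,1L,0L), c(1L,-1L,0L), c(1L,0L,1L), c(1L,0L,-1L),
                   c(0L,1L,1L), c(0L,1L,-1L),
                   c(1L,1L,1L), c(1L,1L,-1L), c(1L,-1L,1L), c(1L,-1L,-1L))

bf_glcm <- function(q, dirs = bf_dirs_inplane, distance = 1L) {
  dims <- dim(q$data); G <- q$G
  counts <- matrix(0, G, G)
  for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    if (!q$mask[i, j, k]) next
    for (d in dirs) {
      p2 <- c(i, j, k) + d * distance
      if (!inside(p2, dims)) next
      if (!q$mask[p2[1], p2[2], p2[3]]) next
      a <- q$data[i, j, k]; b <- q$data[p2[1], p2[2], p2[3]]
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts <- counts + t(counts)
  counts / sum(counts)
}

bf_gldm <- function(q, dirs = bf_dirs_inplane, distance = 1L) {
  dims <- dim(q$data); G <- q$G
  pd <- numeric(G)  # index k+1 = difference k
  for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    if (!q$mask[i, j, k]) next
    for (d in dirs) {
      p2 <- c(i, j, k) + d * distance
      if (!inside(p2, dims)) next
      if (!q$mask[p2[1], p2[2], p2[3]]) next
      dk <- abs(q$data[i, j, k] - q$data[p2[1], p2[2], p2[3]])
      pd[dk + 1] <- pd[dk + 1] + 1
    }
  }
  pd / sum(pd)
}

bf_ngtdm <- function(q, inplane = FALSE) {
  dims <- dim(q$data)
  zr <- if (inplane) 0L else -1:1
  s <- numeric(q$G); cnt <- numeric(q$G); n_valid <- 0
  for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    if (!q$mask[i, j, k]) next
    nb <- c()
    for (dz in zr) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p2 <- c(i + dx, j + dy, k + dz)
      if (!inside(p2, dims)) next
      if (q$mask[p2[1], p2[2], p2[3]]) nb <- c(nb, q$data[p2[1], p2[2], p2[3]])
    }
    if (length(nb) == 0) next
    g <- q$data[i, j, k]
    n_valid <- n_valid + 1
    cnt[g] <- cnt[g] + 1
    s[g] <- s[g] + abs(g - mean(nb))
  }
  occ <- which(cnt > 0)
  list(s = s[occ], p = cnt[occ] / n_valid, levels = occ, n_valid = n_valid)
}

bf_glrlm <- function(q, dirs = bf_dirs_3d) {
  dims <- dim(q$data)
  Lmax <- max(dims)
  counts <- matrix(0, q$G, Lmax)
  for (d in dirs) {
    for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
      if (!q$mask[i, j, k]) next
      g <- q$data[i, j, k]
      prev <- c(i, j, k) - d
      prev_same <- inside(prev, dims) && q$mask[prev[1], prev[2], prev[3]] &&
        q$data[prev[1], prev[2], prev[3]] == g
      if (prev_same) next  # not a run start
      len <- 1L
      nxt <- c(i, j, k) + d
      while (inside(nxt, dims) && q$mask[nxt[1], nxt[2], nxt[3]] &&
             q$data[nxt[1], nxt[2], nxt[3]] == g) {
        len <- len + 1L
        nxt <- nxt + d
      }
      counts[g, len] <- counts[g, len] + 1
    }
  }
  counts
}

bf_glzsm <- function(q, conn26 = TRUE) {
  dims <- dim(q$data)
  offs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (!conn26 && sum(abs(c(dx, dy, dz))) != 1) next
    offs <- c(offs, list(c(dx, dy, dz)))
  }
  seen <- array(FALSE, dims)
  zones <- list()
  for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    if (!q$mask[i, j, k] || seen[i, j, k]) next
    g <- q$data[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (d in offs) {
        p2 <- v + d
        if (!inside(p2, dims)) next
        if (seen[p2[1], p2[2], p2[3]]) next
        if (!q$mask[p2[1], p2[2], p2[3]]) next
        if (q$data[p2[1], p2[2], p2[3]] != g) next
        seen[p2[1], p2[2], p2[3]] <- TRUE
        queue <- c(queue, list(p2))
      }
    }
    zones <- c(zones, list(c(level = g, size = size)))
  }
  do.call(rbind, zones)
}

# Feature-level oracles: explicit double loops over levels.
bf_glcm_features <- function(p) {
  G <- nrow(p)
  ent <- en <- con <- hom <- idm <- cs <- cp <- va <- 0
  mu <- 0
  for (i in 1:G) for (j in 1:G) mu <- mu + i * p[i, j]
  sg <- 0
  for (i in 1:G) for (j in 1:G) sg <- sg + (i - mu)^2 * p[i, j]
  corr_num <- 0
  for (i in 1:G) for (j in 1:G) {
    pij <- p[i, j]
    if (pij > 0) ent <- ent - pij * log2(pij)
    en <- en + pij^2
    con <- con + pij * (i - j)^2
    hom <- hom + pij / (1 + abs(i - j))
    idm <- idm + pij / (1 + (i - j)^2)
    cs <- cs + pij * (i + j - 2 * mu)^3
    cp <- cp + pij * (i + j - 2 * mu)^4
    va <- va + pij * (i - mu)^2
    corr_num <- corr_num + (i - mu) * (j - mu) * pij
  }
  psum <- numeric(2 * G); pdif <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  se <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  de <- -sum(pdif[pdif > 0] * log2(pdif[pdif > 0]))
  sa <- sum(seq_along(psum) * psum)
  list(glcm_entropy = ent, glcm_energy = en, glcm_contrast = con,
       glcm_homogeneity = hom, glcm_idm = idm,
       glcm_correlation = if (sg > 0) corr_num / sg else 0,
       glcm_cluster_shade = cs, glcm_cluster_prominence = cp,
       glcm_sum_entropy = se, glcm_difference_entropy = de,
       glcm_sum_average = sa, glcm_variance = va)
}

bf_gldm_features <- function(pd) {
  ent <- con <- mn <- 0
  for (kk in seq_along(pd)) {
    k <- kk - 1
    if (pd[kk] > 0) ent <- ent - pd[kk] * log2(pd[kk])
    con <- con + k^2 * pd[kk]
    mn <- mn + k * pd[kk]
  }
  list(gldm_entropy = ent, gldm_contrast = con, gldm_mean = mn)
}

bf_ngtdm_features <- function(m, eps = 1e-12) {
  g <- m$levels; p <- m$p; s <- m$s; n <- m$n_valid
  ng <- length(g)
  coars <- min(1 / (eps + sum(p * s)), 1 / eps)
  if (ng < 2) {
    return(list(ngtdm_coarseness = coars, ngtdm_contrast = 0,
                ngtdm_busyness = 0, ngtdm_complexity = 0))
  }
  con1 <- bus_den <- comp <- 0
  for (a in 1:ng) for (b in 1:ng) {
    con1 <- con1 + p[a] * p[b] * (g[a] - g[b])^2
    bus_den <- bus_den + abs(g[a] * p[a] - g[b] * p[b])
    comp <- comp + abs(g[a] - g[b]) * (p[a] * s[a] + p[b] * s[b]) /
      (n * (p[a] + p[b]))
  }
  list(ngtdm_coarseness = coars,
       ngtdm_contrast = con1 / (ng * (ng - 1)) * sum(s) / n,
       ngtdm_busyness = if (bus_den > 0) sum(p * s) / bus_den else 0,
       ngtdm_complexity = comp)
}

bf_glrlm_features <- function(r, Np, D) {
  G <- nrow(r); Lmax <- ncol(r)
  Nr <- sum(r)
  sre <- lre <- lgre <- hgre <- 0
  for (g in 1:G) for (l in 1:Lmax) {
    sre <- sre + r[g, l] / l^2
    lre <- lre + r[g, l] * l^2
    lgre <- lgre + r[g, l] / g^2
    hgre <- hgre + r[g, l] * g^2
  }
  gln <- sum(rowSums(r)^2)
  rln <- sum(colSums(r)^2)
  list(glrl_sre = sre / Nr, glrl_lre = lre / Nr,
       glrl_intensity_variability = gln / Nr,
       glrl_run_length_variability = rln / Nr,
       glrl_run_percentage = Nr / (Np * D),
       glrl_lgre = lgre / Nr, glrl_hgre = hgre / Nr)
}

bf_glzsm_features <- function(zones, Np) {
  # zones: matrix with columns level, size (one row per zone)
  Nz <- nrow(zones)
  g <- zones[, "level"]; s <- zones[, "size"]
  mu_g <- mean(g); mu_s <- mean(s)
  list(glzsm_short_zone_emphasis = mean(1 / s^2),
       glzsm_large_zone_emphasis = mean(s^2),
       glzsm_intensity_nonuniformity = sum(table(g)^2) / Nz,
       glzsm_intensity_variability = mean((g - mu_g)^2),
       glzsm_size_zone_variability = sum(table(s)^2) / Nz,
       glzsm_zone_percentage = Nz / Np,
       glzsm_low_gray_emphasis = mean(1 / g^2),
       glzsm_high_gray_emphasis = mean(g^2),
       glzsm_zone_size_variance = mean((s - mu_s)^2))
}

# Random masked test volume.
random_qv <- function(dims, G, p_mask = 0.85) {
  mask <- array(stats::runif(prod(dims)) < p_mask, dims)
  if (!any(mask)) mask[1] <- TRUE
  bins <- array(sample.int(G, prod(dims), replace = TRUE), dims)
  make_qv(bins, mask, G = G)
}

# Small fast phantom spec for pipeline-level tests.
small_spec <- function(seed = 1L, ...) {
  args <- list(shape = c(40L, 40L, 6L), voxel_size = c(1, 1, 4),
               correlation_length = 2.5, tumor_axes = c(13, 11, 9),
               boundary_irregularity = 0.1, seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# Convert glzsm zones data.frame to a per-zone matrix for comparison.
zones_to_matrix <- function(z) {
  m <- z$zones[rep(seq_len(nrow(z$zones)), z$zones$count), c("level", "size")]
  m <- as.matrix(m)
  colnames(m) <- c("level", "size")
  m[order(m[, "level"], m[, "size"]), , drop = FALSE]
}
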