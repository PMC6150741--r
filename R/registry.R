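#' The canonical 46-feature registry
#'
#' Single source of truth for the feature panel: 7 first-order histogram,
#' 4 fractal, 12 GLCM, 3 GLDM, 4 NGTDM, 7 run-length and 9 zone-size
#' features. The panel contains every feature named in the source study's
#' text; the remaining slots are filled from the classical panels of each
#' family (a documented reconstruction — the exact published composition
#' is not recoverable). `table_id` groups features into the seven output
#' tables (2 = histogram ... 8 = GLZSM).
#'
#' @return data.frame with columns `name`, `class`
#'   (histogram/fractal/glcm/gldm/ngtdm/glrl/glzsm), `scope`
#'   (global/local-regional) and `table_id` (2..8).
#' @export
feature_registry <- function() {
  reg <- rbind(
    data.frame(name = c("hist_mean", "hist_median", "hist_sd",
                        "hist_skewness", "hist_kurtosis", "hist_entropy",
                        "hist_energy"),
               class = "histogram", scope = "global", table_id = 2L),
    data.frame(name = c("fractal_fd_mean", "fractal_fd_sd",
                        "fractal_lacunarity", "fractal_hurst"),
               class = "fractal", scope = "global", table_id = 3L),
    data.frame(name = c("glcm_entropy", "glcm_energy", "glcm_contrast",
                        "glcm_homogeneity", "glcm_idm", "glcm_correlation",
                        "glcm_cluster_shade", "glcm_cluster_prominence",
                        "glcm_sum_entropy", "glcm_difference_entropy",
                        "glcm_sum_average", "glcm_variance"),
               class = "glcm", scope = "local-regional", table_id = 4L),
    data.frame(name = c("gldm_entropy", "gldm_contrast", "gldm_mean"),
               class = "gldm", scope = "local-regional", table_id = 5L),
    data.frame(name = c("ngtdm_coarseness", "ngtdm_contrast",
                        "ngtdm_busyness", "ngtdm_complexity"),
               class = "ngtdm", scope = "local-regional", table_id = 6L),
    data.frame(name = c("glrl_sre", "glrl_lre", "glrl_intensity_variability",
                        "glrl_run_length_variability", "glrl_run_percentage",
                        "glrl_lgre", "glrl_hgre"),
               class = "glrl", scope = "local-regional", table_id = 7L),
    data.frame(name = c("glzsm_short_zone_emphasis", "glzsm_large_zone_emphasis",
                        "glzsm_intensity_nonuniformity",
                        "glzsm_intensity_variability",
                        "glzsm_size_zone_variability", "glzsm_zone_percentage",
                        "glzsm_low_gray_emphasis", "glzsm_high_gray_emphasis",
                        "glzsm_zone_size_variance"),
               class = "glzsm", scope = "local-regional", table_id = 8L)
  )
  stopifnot(nrow(reg) == 46L, !anyDuplicated(reg$name))
  reg
}
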