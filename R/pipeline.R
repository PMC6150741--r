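#' Run configuration
#'
#' Resolved settings for a full extraction run. Defaults reproduce the
#' reference analysis chain: in-plane Gaussian smoothing at 2 mm, 32-bin
#' ROI-relative quantization, distance-1 in-plane second-order matrices
#' pooled over 4 directions, and fully 3D high-order matrices
#' (26-neighborhood NGTDM and zones, 13 run directions).
#'
#' @param filter list: `mode` ("gaussian"/"none"/"log"), `scale_mm`.
#' @param quantization list: `bins` (default 32).
#' @param texture list: `distance`, `ngtdm_neighborhood` ("26"/"8-in-plane"),
#'   `zone_connectivity` ("26"/"6"), `in_plane_only` (logical; restricts
#'   run directions to the axial plane).
#' @return a `run_config` list.
#' @export
run_config <- function(filter = list(mode = "gaussian", scale_mm = 2),
                       quantization = list(bins = 32L),
                       texture = list(distance = 1L,
                                      ngtdm_neighborhood = "26",
                                      zone_connectivity = "26",
                                      in_plane_only = FALSE)) {
  defaults <- list(mode = "gaussian", scale_mm = 2)
  filter <- utils::modifyList(defaults, filter)
  quantization <- utils::modifyList(list(bins = 32L), quantization)
  texture <- utils::modifyList(list(distance = 1L, ngtdm_neighborhood = "26",
                                    zone_connectivity = "26",
                                    in_plane_only = FALSE), texture)
  structure(list(filter = filter, quantization = quantization,
                 texture = texture),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are `filter`, `quantization`,
#'   `texture` (all optional; missing keys keep package defaults).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(filter = if (is.null(y$filter)) list() else y$filter,
             quantization = if (is.null(y$quantization)) list() else y$quantization,
             texture = if (is.null(y$texture)) list() else y$texture)
}

#' Extract the 46-feature vector from one study
#'
#' Runs the full chain — crop, in-plane filter, 32-bin quantization, then
#' all seven feature families — and returns the named feature vector in
#' registry order. Feature families are error-isolated: a failure inside
#' one family leaves its features as `NA` (recorded in the `flags`
#' attribute) without aborting the remaining families.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @param config a [run_config()].
#' @return named numeric vector of length 46 with attribute `flags`
#'   (character vector of degenerate or failed feature names).
#' @export
extract_all_features <- function(volume, mask, config = run_config()) {
  reg <- feature_registry()
  out <- stats::setNames(rep(NA_real_, nrow(reg)), reg$name)
  flags <- character(0)
  q <- preprocess_study(volume, mask, config)
  run_dirs <- if (isTRUE(config$texture$in_plane_only))
    directions_inplane() else directions_3d()

  families <- list(
    function() histogram_features(q),
    function() boxcount_fd(q),
    function() list(fractal_lacunarity = lacunarity(q)),
    function() {
      h <- hurst_exponent(q)
      structure(list(fractal_hurst = as.numeric(h)), flags = attr(h, "flags"))
    },
    function() glcm_features(compute_glcm(q, distance = config$texture$distance)),
    function() gldm_features(compute_gldm(q, distance = config$texture$distance)),
    function() ngtdm_features(compute_ngtdm(q, config$texture$ngtdm_neighborhood)),
    function() glrlm_features(compute_glrlm(q, run_dirs)),
    function() glzsm_features(compute_glzsm(q, config$texture$zone_connectivity))
  )
  for (fam in families) {
    res <- tryCatch(fam(), error = function(e) e)
    if (inherits(res, "error")) next  # features stay NA; flagged below
    flags <- c(flags, attr(res, "flags"))
    vals <- unlist(res)
    keep <- intersect(names(vals), reg$name)
    out[keep] <- vals[keep]
  }
  flags <- unique(c(flags, names(out)[is.na(out)]))
  structure(out, flags = flags)
}

#' Run a full test-retest repeatability study
#'
#' Validates the manifest (exactly one day-1 and one day-2 study per
#' subject per reader), extracts the 46 features from every study, and
#' computes per-reader repeatability tables, one per feature class
#' (mirroring a seven-table layout: histogram, fractal, GLCM, GLDM, NGTDM,
#' run-length, zone-size).
#'
#' @param manifest a manifest data.frame or path to the manifest CSV.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, writes `features.csv`,
#'   the resolved `config.yaml`, and
#'   `repeatability_reader<k>/table<2..8>.csv`.
#' @return list with `features` (long data.frame) and `tables` (nested
#'   list: reader id -> table id -> data.frame).
#' @export
run_study <- function(manifest, config = run_config(), out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  keyed <- split(manifest, list(manifest$subject_id, manifest$reader_id),
                 drop = TRUE)
  for (g in keyed) {
    if (!setequal(g$day, c(1L, 2L)) || nrow(g) != 2L) {
      stop("subject ", g$subject_id[1], " reader ", g$reader_id[1],
           " does not have exactly one day-1 and one day-2 study")
    }
  }
  reg <- feature_registry()
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    st <- read_study(manifest$volume_path[i], manifest$mask_path[i])
    fv <- extract_all_features(st$volume, st$mask, config)
    data.frame(subject_id = manifest$subject_id[i],
               reader_id = manifest$reader_id[i],
               day = manifest$day[i],
               feature_name = names(fv), value = as.numeric(fv))
  })
  features <- do.call(rbind, rows)
  tables <- lapply(split(features, features$reader_id), function(fr) {
    tab <- repeatability_table(fr)
    tab <- merge(tab, reg, by.x = "feature_name", by.y = "name", sort = FALSE)
    stats::setNames(split(tab, tab$table_id),
                    paste0("table", sort(unique(tab$table_id))))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    for (rd in names(tables)) {
      rdir <- file.path(out_dir, paste0("repeatability_reader", rd))
      dir.create(rdir, showWarnings = FALSE)
      for (tb in names(tables[[rd]])) {
        utils::write.csv(tables[[rd]][[tb]], file.path(rdir, paste0(tb, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  list(features = features, tables = tables)
}
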