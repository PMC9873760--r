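#' The candidate feature catalog
#'
#' Assembles the registry of all candidate features: 12 whole-image statistics
#' in the graph-segmentation feature-bank lineage, 13 local statistics for each
#' of the two largest graph-backend segments, 11 local statistics for each of
#' the two largest statistical-region-merging (SRM) segments, 4 colour means
#' for each of the two largest k-means (Lab A/B) colour segments, 10 additional
#' whole-image statistics (five intensity-bin fractions, three HSV modes,
#' aspect ratio, global entropy), and 5 human-annotated high-level attributes
#' (concreteness, dynamics, temperature, valence, presence of a person). The
#' total is 83 entries, of which 5 are tagged `level = "high"`.
#'
#' High-level entries are inputs (annotations), never computed from pixels.
#'
#' @param intensity_bins number of intensity-bin features (default 5; 4 is
#'   supported for the narrower binning convention).
#' @return A data.frame of class `feature_catalog` with columns `name`,
#'   `level` ("low"/"high"), `scope` ("global"/"segment-1"/"segment-2"),
#'   `backend` ("none"/"srm"/"kmeans_lab"/"graph") and `ref` (source tag).
#' @export
feature_catalog <- function(intensity_bins = 5) {
  row <- function(name, level, scope, backend, ref)
    data.frame(name = name, level = level, scope = scope, backend = backend,
               ref = ref, stringsAsFactors = FALSE)

  glob12 <- c("mean_hue", "mean_saturation", "mean_value",
              "sd_hue", "sd_saturation", "sd_value",
              "mean_intensity", "sd_intensity",
              "blur", "edge_density", "mean_gradient", "colorfulness")
  seg13 <- c("segment_size", "mean_hue", "mean_saturation", "mean_value",
             "com_x", "com_y", "mass_variance", "mass_skew", "entropy",
             "symmetry_horizontal", "symmetry_vertical",
             "mean_intensity", "sd_intensity")
  seg11 <- setdiff(seg13, c("mean_intensity", "sd_intensity"))
  seg4  <- c("mean_r", "mean_hue", "mean_saturation", "mean_value")
  high5 <- c("concreteness", "dynamics", "temperature", "valence",
             "presence_person")

  entries <- list(
    row(paste0("global_", glob12), "low", "global", "none", "global-stat"))
  for (s in 1:2) {
    entries <- c(entries, list(
      row(sprintf("graph_seg%d_%s", s, seg13), "low",
          sprintf("segment-%d", s), "graph", "segment-stat"),
      row(sprintf("srm_seg%d_%s", s, seg11), "low",
          sprintf("segment-%d", s), "srm", "segment-stat"),
      row(sprintf("kmeans_seg%d_%s", s, seg4), "low",
          sprintf("segment-%d", s), "kmeans_lab", "segment-color")))
  }
  entries <- c(entries, list(
    row(paste0("global_intensity_bin", seq_len(intensity_bins)),
        "low", "global", "none", "intensity-histogram"),
    row(paste0("global_mode_", c("hue", "saturation", "value")),
        "low", "global", "none", "hsv-mode"),
    row("global_aspect_ratio", "low", "global", "none", "geometry"),
    row("global_entropy", "low", "global", "none", "intensity-histogram"),
    row(high5, "high", "global", "none", "annotation")))

  out <- do.call(rbind, entries)
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$name))
  class(out) <- c("feature_catalog", "data.frame")
  out
}

#' Extract all catalog features for one image
#'
#' Runs the three segmentation backends, computes every low-level catalog entry
#' from pixels and copies the high-level entries from `annotations`. The result
#' is aligned to catalog order. Extraction is deterministic for a fixed
#' `seed` (the k-means backend initialization is seeded).
#'
#' @param image a [raster_image()]
#' @param catalog a [feature_catalog()]
#' @param annotations named list/vector providing every `level = "high"`
#'   catalog entry (e.g. concreteness). Required if the catalog has high-level
#'   entries.
#' @param seed integer seed for the k-means backend.
#' @param params optional list of backend parameter lists keyed `srm`,
#'   `kmeans_lab`, `graph`, plus `normalize_coords`, `gray_standard`,
#'   `hue_circular`.
#' @return Named numeric vector with one value per catalog entry (a feature
#'   vector). Missing-segment statistics are `NA`.
#' @export
extract_features <- function(image, catalog = feature_catalog(),
                             annotations = NULL, seed = 1L, params = list()) {
  stopifnot(inherits(image, "raster_image"),
            inherits(catalog, "feature_catalog"))
  norm <- params$normalize_coords %||% TRUE
  gstd <- params$gray_standard %||% "601"
  hcirc <- params$hue_circular %||% FALSE

  segs <- list(
    srm = segment_image(image, "srm", params$srm %||% list()),
    kmeans_lab = segment_image(image, "kmeans_lab",
                               utils::modifyList(list(k = 3L, seed = seed),
                                                 params$kmeans_lab %||% list())),
    graph = segment_image(image, "graph", params$graph %||% list())
  )
  seg_feats <- lapply(segs, function(sg) list(
    compute_segment_features(image, sg, 0L, norm, hue_circular = hcirc,
                             gray_standard = gstd),
    compute_segment_features(image, sg, 1L, norm, hue_circular = hcirc,
                             gray_standard = gstd)))
  n_bins <- sum(grepl("^global_intensity_bin", catalog$name))
  glob <- compute_global_features(image, intensity_bins = n_bins,
                                  gray_standard = gstd)

  high_names <- catalog$name[catalog$level == "high"]
  if (length(high_names)) {
    missing <- setdiff(high_names, names(annotations))
    if (length(missing))
      stop("missing high-level annotation(s): ", paste(missing, collapse = ", "))
  }

  vals <- vapply(seq_len(nrow(catalog)), function(i) {
    nm <- catalog$name[i]
    if (catalog$level[i] == "high") return(as.numeric(annotations[[nm]]))
    if (catalog$scope[i] == "global")
      return(unname(glob[sub("^global_", "", nm)]))
    s <- as.integer(sub("segment-", "", catalog$scope[i]))
    stat <- sub(sprintf("^(graph|srm|kmeans)_seg%d_", s), "", nm)
    unname(seg_feats[[catalog$backend[i]]][[s]][stat])
  }, numeric(1))
  stats::setNames(vals, catalog$name)
}

#' Extract the stimuli x features matrix for a set of images
#'
#' @param images list of [raster_image()] objects (optionally named)
#' @param catalog a [feature_catalog()]
#' @param annotations data.frame with one row per image and one column per
#'   high-level catalog entry, or NULL if the catalog has none.
#' @param seed,params passed to [extract_features()].
#' @return Numeric matrix, images x features, columns in catalog order.
#' @export
extract_feature_matrix <- function(images, catalog = feature_catalog(),
                                   annotations = NULL, seed = 1L,
                                   params = list()) {
  out <- t(vapply(seq_along(images), function(i) {
    ann <- if (is.null(annotations)) NULL else as.list(annotations[i, ])
    extract_features(images[[i]], catalog, ann, seed = seed, params = params)
  }, numeric(nrow(catalog))))
  rownames(out) <- names(images) %||% paste0("stim", seq_along(images))
  out
}

#' Write/read a feature table as tab-separated values
#'
#' One row per image, header = catalog names, first column `stimulus`.
#' @param features images x features matrix
#' @param path output path
#' @return `path` (write) or the matrix (read).
#' @export
write_feature_tsv <- function(features, path) {
  df <- data.frame(stimulus = rownames(features) %||%
                     paste0("stim", seq_len(nrow(features))),
                   features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Serialize a feature catalog as JSON
#' @param catalog a [feature_catalog()]
#' @param path output path
#' @export
write_catalog_json <- function(catalog, path) {
  jsonlite::write_json(as.data.frame(catalog), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_catalog_json
#' @export
read_catalog_json <- function(path) {
  out <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  class(out) <- c("feature_catalog", "data.frame")
  out
}
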