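test_that("SRM segmentation finds the solid bands, largest first", {
  img <- band_image()
  seg <- segment_image(img, "srm")
  expect_equal(seg$n_segments, 3)
  expect_true(all(seg$label_map[1:32, ] == 0))   # 32-row band is segment 0
  expect_equal(seg$sizes, c(2048, 1024, 1024))
  expect_false(seg$target_not_met)
})

test_that("degenerate single-colour image yields one SRM segment with a flag", {
  seg <- segment_image(uniform_image(), "srm")
  expect_equal(seg$n_segments, 1)
  expect_true(seg$target_not_met)
})

test_that("k-means on Lab chroma recovers colour classes of a checkerboard", {
  img <- checker_image()
  seg <- segment_image(img, "kmeans_lab", list(k = 2, seed = 1))
  expect_equal(seg$n_segments, 2)
  classes <- img$pixels[, , 1]
  # label map equals the colour classes up to label permutation
  expect_equal(length(unique(as.vector(seg$label_map + 10 * classes))), 2)
})

test_that("k-means k above the number of distinct colours is reduced and flagged", {
  seg <- segment_image(checker_image(), "kmeans_lab", list(k = 5, seed = 1))
  expect_lte(seg$n_segments, 2)
  expect_true(seg$target_not_met)
})

test_that("graph backend matches the connected-component oracle on quadrants", {
  img <- quadrant_image(48)
  seg <- segment_image(img, "graph", list(target = 4))
  expect_equal(seg$n_segments, 4)
  expect_equal(seg$sizes, rep(576L, 4))
  oracle <- cc_oracle(img)
  # identical partitions up to relabelling
  expect_equal(length(unique(paste(seg$label_map, oracle))), 4)
})

test_that("blur is 0 for uniform images and ~1 for Nyquist stripes", {
  expect_equal(as.numeric(compute_blur(uniform_image())), 0)
  st <- array(0, c(32, 32, 3)); st[, seq(1, 32, 2), ] <- 1
  expect_gte(compute_blur(raster_image(st)), 0.99)
})

test_that("blur is non-increasing under Gaussian smoothing and DC-invariant", {
  stim <- make_stimulus_images(1, seed = 4, width = 48, height = 48,
                               blur_levels = 0)
  img <- stim$images[[1]]
  seq_blur <- vapply(c(0, 1, 2, 4), function(sg) {
    px <- img$pixels
    if (sg > 0) for (ch in 1:3) px[, , ch] <- lfsvalue:::gaussian_blur(px[, , ch], sg)
    as.numeric(compute_blur(raster_image(px)))
  }, numeric(1))
  expect_true(all(diff(seq_blur) <= 1e-12))
  expect_lt(seq_blur[4], seq_blur[1])   # sigma 4 strictly blurrier than sharp
  # adding a constant changes only the DC component
  base <- array(0.2, c(16, 16, 3)); base[5:9, 3:12, ] <- 0.6
  shifted <- pmin(base + 0.2, 1)
  expect_equal(as.numeric(compute_blur(raster_image(base))),
               as.numeric(compute_blur(raster_image(shifted))))
})

test_that("segment features recover analytic values on constructed segments", {
  img <- band_image()
  seg <- segment_image(img, "srm")
  f0 <- compute_segment_features(img, seg, 0L)
  expect_equal(unname(f0["segment_size"]), 0.5)
  expect_equal(unname(f0["entropy"]), 0)              # single intensity
  expect_equal(unname(f0["symmetry_horizontal"]), 0)  # bands are L-R symmetric
  expect_equal(unname(f0["mass_skew"]), 0, tolerance = 1e-12)
  # centre of mass of the top band: rows 0..31, cols 0..63, normalized
  expect_equal(unname(f0["com_x"]), mean((0:63) / 64))
  expect_equal(unname(f0["com_y"]), mean((0:31) / 64))
  expect_gte(unname(f0["mass_variance"]), 0)
  # whole image as one segment
  segu <- segment_image(uniform_image(), "srm")
  fu <- compute_segment_features(uniform_image(), segu, 0L)
  expect_equal(unname(fu["segment_size"]), 1.0)
})

test_that("missing second segment yields NA sentinel with a flag", {
  segu <- segment_image(uniform_image(), "srm")
  f1 <- compute_segment_features(uniform_image(), segu, 1L)
  expect_true(all(is.na(f1)))
  expect_equal(attr(f1, "flag"), "missing_segment")
})

test_that("segment sizes over all segments sum to one", {
  stim <- make_stimulus_images(3, seed = 9)
  for (img in stim$images) {
    seg <- segment_image(img, "srm")
    expect_equal(sum(seg$sizes) / (img$width * img$height), 1, tolerance = 1e-9)
  }
})

test_that("global features match analytic cases", {
  black <- raster_image(array(0, c(16, 16, 3)))
  g <- compute_global_features(black)
  expect_equal(unname(g["intensity_bin1"]), 1.0)
  expect_equal(unname(g[paste0("intensity_bin", 2:5)]), rep(0, 4),
               ignore_attr = TRUE)
  wide <- raster_image(array(0.5, c(200, 300, 3)))
  expect_equal(unname(compute_global_features(wide)["aspect_ratio"]), 1.5)
  # dominant hue lands in the mode bin containing it
  px <- array(0, c(16, 16, 3))
  hsv_dom <- grDevices::hsv(0.5, 1, 1)
  rgbv <- grDevices::col2rgb(hsv_dom) / 255
  for (ch in 1:3) px[, , ch] <- rgbv[ch]
  px[1, 1:3, ] <- 0.9   # 3 off-hue pixels
  gm <- compute_global_features(raster_image(px))
  expect_lt(abs(unname(gm["mode_hue"]) - 0.5), 1 / 64)
})

test_that("intensity bins are non-negative and sum to one; entropy is bounded", {
  stim <- make_stimulus_images(4, seed = 3)
  for (img in stim$images) {
    g <- compute_global_features(img)
    b <- g[paste0("intensity_bin", 1:5)]
    expect_true(all(b >= 0))
    expect_equal(sum(b), 1, tolerance = 1e-9)
    expect_gte(unname(g["entropy"]), 0)
    expect_lte(unname(g["entropy"]), log2(256))
  }
})

test_that("the catalog has 83 uniquely named entries, 5 of them high-level", {
  cat83 <- feature_catalog()
  expect_equal(nrow(cat83), 83)
  expect_equal(anyDuplicated(cat83$name), 0)
  expect_equal(sum(cat83$level == "high"), 5)
  expect_setequal(cat83$name[cat83$level == "high"],
                  c("concreteness", "dynamics", "temperature", "valence",
                    "presence_person"))
  expect_true(all(cat83$backend %in% c("none", "srm", "kmeans_lab", "graph")))
  # the narrower 4-bin convention is also constructible
  expect_equal(nrow(feature_catalog(intensity_bins = 4)), 82)
})

test_that("extract_features is aligned, deterministic, and flip-invariant", {
  img <- band_image(heights = c(20, 14, 14), width = 40)
  ann <- dummy_annotations()
  fv1 <- extract_features(img, annotations = ann, seed = 7)
  fv2 <- extract_features(img, annotations = ann, seed = 7)
  expect_identical(fv1, fv2)
  expect_equal(length(fv1), 83)
  expect_named(fv1, feature_catalog()$name)
  expect_equal(unname(fv1["concreteness"]), 0.4)
  # histogram-based global features are invariant to horizontal mirroring
  mir <- raster_image(img$pixels[, img$width:1, , drop = FALSE])
  fm <- extract_features(mir, annotations = ann, seed = 7)
  hist_feats <- c(paste0("global_intensity_bin", 1:5), "global_entropy",
                  "global_aspect_ratio", "global_mean_saturation")
  expect_equal(fv1[hist_feats], fm[hist_feats], tolerance = 1e-12)
})

test_that("missing high-level annotation raises a named error", {
  expect_error(extract_features(uniform_image(), annotations = list(
    concreteness = 1, dynamics = 0, temperature = 0, valence = 0)),
    "presence_person")
})

test_that("feature tables and catalogs round-trip through TSV/JSON", {
  stim <- make_stimulus_images(2, seed = 5, width = 32, height = 32)
  ann <- data.frame(concreteness = c(0.1, 0.2), dynamics = c(0, 1),
                    temperature = c(0.5, 0.5), valence = c(-1, 1),
                    presence_person = c(0, 1))
  fm <- extract_feature_matrix(stim$images, annotations = ann)
  tsv <- tempfile(fileext = ".tsv")
  write_feature_tsv(fm, tsv)
  expect_equal(read_feature_tsv(tsv), fm, tolerance = 1e-12)
  js <- tempfile(fileext = ".json")
  write_catalog_json(feature_catalog(), js)
  expect_equal(read_catalog_json(js)$name, feature_catalog()$name)
})
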