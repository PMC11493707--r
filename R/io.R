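# Configuration, TIFF bundle input/output, and the per-ROI quantification
# driver that ties the pipeline together.

#' Pipeline configuration
#'
#' All tunable parameters of the quantification pipeline in one validated
#' object. `break_seal_px` is fixed at 1 by the viral-passage rule (breaks
#' greater than one pixel classify the net as fragmented) and overriding it
#' triggers a warning.
#'
#' @param pixel_size_um Pixel size in micrometres (default 0.325).
#' @param scales_px Ridge-enhancement scales in px.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold Fixed threshold on the `[0, 1]` response scale (only for
#'   `threshold_method = "fixed"`).
#' @param min_component_px Minimum strand component size kept, px.
#' @param closing_radius_px Disc radius for layer segmentation, px.
#' @param break_seal_px Maximum break width sealed before flooding, px.
#' @param lld LLD substitution table, as from [lld_defaults()].
#' @param output_dir Output directory for CSVs and QC images.
#' @param seed Optional seed recorded into output provenance.
#' @param verbose Logical; log progress to stderr.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um = 0.325,
                            scales_px = c(1, 2, 3, 4),
                            threshold_method = "otsu",
                            threshold = NULL,
                            min_component_px = 20L,
                            closing_radius_px = 15L,
                            break_seal_px = 1L,
                            lld = lld_defaults(),
                            output_dir = ".",
                            seed = NULL,
                            verbose = FALSE) {
  stopifnot(pixel_size_um > 0, length(scales_px) >= 1L, all(scales_px > 0),
            min_component_px >= 1L, closing_radius_px >= 0L,
            break_seal_px >= 1L)
  threshold_method <- match.arg(threshold_method, c("otsu", "fixed"))
  if (break_seal_px != 1L) {
    warning("break_seal_px != 1 departs from the one-pixel viral-passage rule")
  }
  structure(list(pixel_size_um = as.numeric(pixel_size_um),
                 scales_px = as.numeric(scales_px),
                 threshold_method = threshold_method,
                 threshold = if (is.null(threshold)) NULL else as.numeric(threshold),
                 min_component_px = as.integer(min_component_px),
                 closing_radius_px = as.integer(closing_radius_px),
                 break_seal_px = as.integer(break_seal_px),
                 lld = rapply(lld, as.numeric, how = "replace"),
                 output_dir = output_dir,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path written by [write_config()].
#' @return A validated [pipeline_config()]; `read_config(write_config(x))`
#'   reproduces `x`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Read an image bundle (intensity TIFF plus label-mask TIFF)
#'
#' The label mask uses the convention 0 = outside, 1 = compartment interior,
#' 2 = apical border, 3 = basal border. Unknown codes, missing borders, or a
#' shape mismatch raise errors.
#'
#' @param image_path Path to the grayscale intensity TIFF (16-bit).
#' @param mask_path Path to the label-mask TIFF (8-bit).
#' @param pixel_size_um Pixel size in micrometres.
#' @param channel Junction protein channel label.
#' @param roi_id,sample_id Identifiers.
#' @return List with `image` ([fluorescence_image()]) and `roi`
#'   ([epithelium_roi()]).
#' @export
read_image_bundle <- function(image_path, mask_path, pixel_size_um = 0.325,
                              channel = "other", roi_id = "roi1",
                              sample_id = "sample1") {
  img <- tiff::readTIFF(image_path, as.is = TRUE)
  lab <- tiff::readTIFF(mask_path, as.is = TRUE)
  if (length(dim(img)) > 2L) img <- img[, , 1L]
  if (length(dim(lab)) > 2L) lab <- lab[, , 1L]
  storage.mode(lab) <- "integer"
  if (!all(dim(img) == dim(lab))) {
    stop("image and label mask shapes differ")
  }
  roi <- roi_from_labels(lab, roi_id = roi_id, sample_id = sample_id)
  list(image = fluorescence_image(img + 0.0, pixel_size_um, channel),
       roi = roi)
}

#' Write an image bundle to TIFF files
#'
#' Writes the intensity image as 16-bit grayscale TIFF, the ROI as an 8-bit
#' label-mask TIFF, and (optionally) a ground-truth sidecar JSON with the
#' scalar truth values of a synthetic bundle.
#'
#' @param image A [fluorescence_image()].
#' @param roi An [epithelium_roi()].
#' @param dir Output directory (created if needed).
#' @param basename File stem; writes `<stem>_image.tif`, `<stem>_mask.tif`
#'   and, with truth, `<stem>_truth.json`.
#' @param truth Optional ground-truth list from [generate_epithelium()].
#' @return Named character vector of the paths written, invisibly.
#' @export
write_image_bundle <- function(image, roi, dir, basename, truth = NULL) {
  stopifnot(inherits(image, "fluorescence_image"),
            inherits(roi, "epithelium_roi"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_path <- file.path(dir, paste0(basename, "_image.tif"))
  mask_path <- file.path(dir, paste0(basename, "_mask.tif"))
  img16 <- clamp(round(image$intensities), 0, 65535)
  tiff::writeTIFF(img16 / 65535, img_path, bits.per.sample = 16L)
  tiff::writeTIFF(labels_from_roi(roi) / 255, mask_path,
                  bits.per.sample = 8L)
  paths <- c(image = img_path, mask = mask_path)
  if (!is.null(truth)) {
    truth_path <- file.path(dir, paste0(basename, "_truth.json"))
    side <- list(true_gap_fraction = truth$true_gap_fraction,
                 true_height_um = truth$true_height_um,
                 n_edges = nrow(truth$edges),
                 n_broken_edges = sum(truth$edges$broken),
                 params = truth$params[c("pixel_size_um", "cell_diameter_px",
                                         "strand_width_px", "gap_rate",
                                         "gap_width_px", "noise_sd")])
    jsonlite::write_json(side, truth_path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truth = truth_path)
  }
  invisible(paths)
}

#' Quantify one image bundle
#'
#' Full per-ROI analysis: curvilinear enhancement, strand binarisation, layer
#' segmentation, net-integrity analysis, MFI of the whole compartment and of
#' the intermediate layer, and epithelial height.
#'
#' @param image A [fluorescence_image()].
#' @param roi An [epithelium_roi()].
#' @param config A [pipeline_config()].
#' @return One-row data frame of per-ROI metrics.
#' @export
quantify_bundle <- function(image, roi, config = pipeline_config()) {
  resp <- enhance_curvelinear(image, config$scales_px, roi)
  strands <- binarize_strands(resp, roi, config$threshold_method,
                              config$threshold, config$min_component_px)
  layers <- segment_layers(strands, roi, config$closing_radius_px)
  ni <- net_integrity(strands, roi, layers)
  data.frame(
    sample_id = roi$sample_id,
    roi_id = roi$roi_id,
    channel = image$channel,
    mfi_epithelium = compute_mfi(image, roi$interior),
    mfi_intermediate = compute_mfi(image, layers$intermediate),
    height_um = compute_height(roi, image$pixel_size_um),
    pct_accessible = ni$pct_accessible,
    pct_intact = ni$pct_intact,
    pct_fragmented_intermediate = ni$pct_fragmented_intermediate,
    n_interior_px = ni$n_interior_px,
    n_intermediate_px = ni$n_intermediate_px)
}

#' Quantify a set of image bundles
#'
#' Runs [quantify_bundle()] over a list of bundles. A failing ROI is recorded
#' as an NA row with the error logged, and the pipeline continues. Output is
#' deterministic for fixed inputs and configuration apart from the
#' `timestamp` column.
#'
#' @param bundles List of bundles, each a list with `image` and `roi` (the
#'   format produced by [generate_epithelium()] and [read_image_bundle()]).
#' @param config A [pipeline_config()].
#' @param out_csv Optional path; when given the table is also written as CSV.
#' @return Data frame with one row per ROI, including provenance columns
#'   `config_hash`, `seed`, `version` and `timestamp`.
#' @export
run_quantify <- function(bundles, config = pipeline_config(),
                         out_csv = NULL) {
  stopifnot(length(bundles) >= 1L)
  na_row <- function(b) data.frame(
    sample_id = tryCatch(b$roi$sample_id, error = function(e) NA_character_),
    roi_id = tryCatch(b$roi$roi_id, error = function(e) NA_character_),
    channel = tryCatch(b$image$channel, error = function(e) NA_character_),
    mfi_epithelium = NA_real_, mfi_intermediate = NA_real_,
    height_um = NA_real_, pct_accessible = NA_real_, pct_intact = NA_real_,
    pct_fragmented_intermediate = NA_real_,
    n_interior_px = NA_integer_, n_intermediate_px = NA_integer_)
  rows <- lapply(bundles, function(b) {
    tryCatch(quantify_bundle(b$image, b$roi, config),
             error = function(e) {
               message(sprintf("ROI %s/%s failed: %s",
                               tryCatch(b$roi$sample_id, error = function(.) "?"),
                               tryCatch(b$roi$roi_id, error = function(.) "?"),
                               conditionMessage(e)))
               na_row(b)
             })
  })
  out <- do.call(rbind, rows)
  prov <- config
  prov$output_dir <- NULL
  out$config_hash <- rlang::hash(prov)
  out$seed <- if (is.null(config$seed)) NA_integer_ else config$seed
  out$version <- as.character(utils::packageVersion("ejpnet"))
  out$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  rownames(out) <- NULL
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
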