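# Core domain containers. Lightweight S3: plain lists of matrices plus
# metadata, validated on construction.

EJP_CHANNELS <- c("DSG1", "CLDN1", "ZO1", "ECAD", "other")

#' Fluorescence image
#'
#' A single-channel grayscale fluorescence image with physical pixel size.
#' Intensities are in arbitrary units (AU) and must be non-negative; 16-bit
#' scanner output is handled as plain numeric values.
#'
#' @param intensities Numeric matrix of non-negative intensities, rows running
#'   apical to basal.
#' @param pixel_size_um Physical pixel size in micrometres (default 0.325, the
#'   pixel pitch of a 20x slide scan).
#' @param channel Junction protein channel label, one of `"DSG1"`, `"CLDN1"`,
#'   `"ZO1"`, `"ECAD"`, `"other"`.
#' @return An object of class `fluorescence_image` with elements
#'   `intensities`, `pixel_size_um` and `channel`.
#' @export
fluorescence_image <- function(intensities, pixel_size_um = 0.325,
                               channel = "other") {
  if (!is.matrix(intensities) || !is.numeric(intensities) ||
      length(intensities) == 0L) {
    stop("'intensities' must be a non-empty numeric matrix")
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0) {
    stop("'pixel_size_um' must be a positive scalar")
  }
  channel <- match.arg(channel, EJP_CHANNELS)
  structure(list(intensities = intensities,
                 pixel_size_um = as.numeric(pixel_size_um),
                 channel = channel),
            class = "fluorescence_image")
}

#' @export
print.fluorescence_image <- function(x, ...) {
  cat(sprintf("<fluorescence_image> %d x %d px, %.3f um/px, channel %s\n",
              nrow(x$intensities), ncol(x$intensities), x$pixel_size_um,
              x$channel))
  invisible(x)
}

#' Epithelial compartment region of interest
#'
#' The manually annotated epithelial compartment of one ROI, with its apical
#' (lumen-facing) and basal (basement-membrane-facing) border pixel sets. The
#' `interior` mask is the full compartment and includes the border pixels;
#' borders must be disjoint, non-empty subsets of the compartment.
#'
#' @param interior Logical mask of the epithelial compartment.
#' @param apical_border Logical mask of apical border pixels.
#' @param basal_border Logical mask of basal border pixels.
#' @param roi_id,sample_id Identifiers carried into output tables.
#' @return An object of class `epithelium_roi`.
#' @export
epithelium_roi <- function(interior, apical_border, basal_border,
                           roi_id = "roi1", sample_id = "sample1") {
  interior <- as_mask(interior)
  apical_border <- as_mask(apical_border)
  basal_border <- as_mask(basal_border)
  if (!all(dim(interior) == dim(apical_border)) ||
      !all(dim(interior) == dim(basal_border))) {
    stop("interior and border masks must share dimensions")
  }
  if (!any(apical_border)) stop("apical border is empty")
  if (!any(basal_border)) stop("basal border is empty")
  if (any(apical_border & basal_border)) {
    stop("apical and basal borders must be disjoint")
  }
  if (any(apical_border & !interior) || any(basal_border & !interior)) {
    stop("border pixels must lie within the compartment interior")
  }
  structure(list(interior = interior, apical_border = apical_border,
                 basal_border = basal_border,
                 roi_id = roi_id, sample_id = sample_id),
            class = "epithelium_roi")
}

#' @export
print.epithelium_roi <- function(x, ...) {
  cat(sprintf("<epithelium_roi> %s/%s: %d px compartment, %d apical / %d basal border px\n",
              x$sample_id, x$roi_id, sum(x$interior), sum(x$apical_border),
              sum(x$basal_border)))
  invisible(x)
}

#' Build an ROI from an integer label mask
#'
#' Label convention: 0 = outside the compartment, 1 = compartment interior,
#' 2 = apical border, 3 = basal border.
#'
#' @param labels Integer matrix with codes 0--3.
#' @param roi_id,sample_id Identifiers.
#' @return An [epithelium_roi()].
#' @export
roi_from_labels <- function(labels, roi_id = "roi1", sample_id = "sample1") {
  stopifnot(is.matrix(labels))
  codes <- sort(unique(as.integer(labels)))
  bad <- setdiff(codes, 0:3)
  if (length(bad)) {
    stop(sprintf("unknown label code(s): %s", paste(bad, collapse = ", ")))
  }
  if (!any(labels == 2)) stop("no apical border (label code 2) in mask")
  if (!any(labels == 3)) stop("no basal border (label code 3) in mask")
  epithelium_roi(labels > 0, labels == 2, labels == 3,
                 roi_id = roi_id, sample_id = sample_id)
}

#' Convert an ROI back to the integer label convention
#'
#' @param roi An [epithelium_roi()].
#' @return Integer matrix with codes 0--3.
#' @export
labels_from_roi <- function(roi) {
  stopifnot(inherits(roi, "epithelium_roi"))
  lab <- matrix(0L, nrow(roi$interior), ncol(roi$interior))
  lab[roi$interior] <- 1L
  lab[roi$apical_border] <- 2L
  lab[roi$basal_border] <- 3L
  lab
}

ridge_response <- function(response, scales_px) {
  structure(list(response = response, scales_px = scales_px),
            class = "ridge_response")
}

#' @export
print.ridge_response <- function(x, ...) {
  cat(sprintf("<ridge_response> %d x %d px, scales {%s} px, max %.3f\n",
              nrow(x$response), ncol(x$response),
              paste(x$scales_px, collapse = ", "), max(x$response)))
  invisible(x)
}

new_strand_mask <- function(mask, min_component_px) {
  structure(list(mask = mask, min_component_px = min_component_px),
            class = "strand_mask")
}

#' @export
print.strand_mask <- function(x, ...) {
  cat(sprintf("<strand_mask> %d strand px (pruned below %d px)\n",
              sum(x$mask), x$min_component_px))
  invisible(x)
}
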