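# Layer segmentation, mean fluorescence intensity, and epithelial height.

#' Segment the epithelial compartment into three layers
#'
#' The intermediate layer is where junction-protein strands are expressed:
#' a morphological closing of the strand mask (disc of radius
#' `closing_radius_px`, about half a cell diameter) intersected with the
#' compartment, with fully enclosed holes folded in so it forms a single
#' band. The superficial layer is every remaining compartment pixel whose
#' 4-connected geodesic path to the apical border avoids the intermediate
#' band; the basal layer is everything else. The three masks always partition
#' the compartment.
#'
#' @param strands A `strand_mask` (or logical matrix) restricted to the ROI.
#' @param roi An [epithelium_roi()].
#' @param closing_radius_px Disc radius of the closing, px (default 15, about
#'   half the expected cell diameter).
#' @return A list of class `layer_segmentation` with logical masks
#'   `superficial`, `intermediate`, `basal` and a `flags` character vector
#'   noting degenerate outcomes (empty superficial/basal layer).
#' @export
segment_layers <- function(strands, roi, closing_radius_px = 15L) {
  mask <- as_mask(strands)
  stopifnot(inherits(roi, "epithelium_roi"),
            all(dim(mask) == dim(roi$interior)))
  mask <- mask & roi$interior
  if (!any(mask)) {
    stop("no EJP expression: strand mask is empty, cannot segment layers")
  }
  side <- 2L * as.integer(closing_radius_px) + 1L
  inter <- if (side >= 3L) {
    brush <- makeBrush(side, shape = "disc")
    cl <- imageData(closing(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                            brush))
    matrix(cl > 0.5, nrow(mask), ncol(mask)) & roi$interior
  } else mask

  free <- roi$interior & !inter
  lab <- label_components(free, connectivity = 4L)
  apical_touch <- unique(lab[adjacent4(free, roi$apical_border)])
  basal_touch <- unique(lab[adjacent4(free, roi$basal_border)])
  apical_touch <- setdiff(apical_touch, 0L)
  basal_touch <- setdiff(basal_touch, 0L)

  superficial <- free & matrix(lab %in% apical_touch, nrow(mask), ncol(mask))
  basal <- free & !superficial &
    matrix(lab %in% basal_touch, nrow(mask), ncol(mask))
  # components reaching neither border are enclosed holes: fold into the band
  inter <- roi$interior & !superficial & !basal

  flags <- character(0)
  if (!any(superficial)) {
    flags <- c(flags, "empty_superficial")
    warning("intermediate band touches the apical border; superficial layer is empty")
  }
  if (!any(basal)) {
    flags <- c(flags, "empty_basal")
    warning("intermediate band touches the basal border; basal layer is empty")
  }
  if (length(intersect(apical_touch, basal_touch))) {
    flags <- c(flags, "apical_basal_connected")
  }
  structure(list(superficial = superficial, intermediate = inter,
                 basal = basal, flags = flags),
            class = "layer_segmentation")
}

#' @export
print.layer_segmentation <- function(x, ...) {
  cat(sprintf("<layer_segmentation> superficial %d / intermediate %d / basal %d px%s\n",
              sum(x$superficial), sum(x$intermediate), sum(x$basal),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Mean fluorescence intensity over a mask
#'
#' Arithmetic mean of the raw (not enhanced) intensities over the mask pixels;
#' MFI serves as the proxy for protein expression.
#'
#' @param image A [fluorescence_image()].
#' @param mask Logical mask of matching shape.
#' @return Mean intensity (AU), a single number.
#' @export
compute_mfi <- function(image, mask) {
  stopifnot(inherits(image, "fluorescence_image"))
  mask <- as_mask(mask)
  if (!all(dim(mask) == dim(image$intensities))) {
    stop("mask and image must share shape")
  }
  if (!any(mask)) stop("cannot compute MFI over an empty mask")
  mean(image$intensities[mask])
}

#' Epithelial height from a Euclidean distance transform
#'
#' A distance-transform image seeded on the basal border gives, at every
#' apical-border pixel, the straight-line distance to the nearest basal
#' pixel. Height is the mean of these one-way distances plus one pixel (so a
#' band occupying n pixel rows reports n pixels of thickness), converted to
#' micrometres. Set `report_round_trip = TRUE` to report the apical-to-basal-
#' and-back round trip (twice the one-way value) instead.
#'
#' @param roi An [epithelium_roi()] with non-empty borders.
#' @param pixel_size_um Pixel size in micrometres.
#' @param report_round_trip Report the doubled round-trip distance.
#' @return Height in micrometres, a single number.
#' @export
compute_height <- function(roi, pixel_size_um = 0.325,
                           report_round_trip = FALSE) {
  stopifnot(inherits(roi, "epithelium_roi"), pixel_size_um > 0)
  seedimg <- matrix(1, nrow(roi$interior), ncol(roi$interior))
  seedimg[roi$basal_border] <- 0
  d <- imageData(distmap(seedimg, metric = "euclidean"))
  h_px <- mean(d[roi$apical_border]) + 1
  h <- h_px * pixel_size_um
  if (report_round_trip) 2 * h else h
}
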