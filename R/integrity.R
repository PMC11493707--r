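# Net integrity: the one-pixel break rule, apical flooding, and the
# intact/fragmented partition of the intermediate layer.
#
# Connectivity duality throughout: strands act as 8-connected barriers while
# the traversable background is 4-connected, so flow can never slip through
# the corner between two diagonally touching strand pixels.

#' Seal breaks of one pixel in a strand mask
#'
#' A break greater than one pixel (0.325 um at the default pixel size) is
#' regarded as wide enough for viral passage and classifies the net as
#' fragmented; a one-pixel break is not. Sealing therefore bridges exactly the
#' one-pixel breaks: a background pixel becomes strand when two opposite
#' 8-neighbours (left/right, up/down, or either diagonal pair) are both
#' strand. Two-pixel and wider breaks have strand on at most one side of any
#' such pair and remain open.
#'
#' @param strands A `strand_mask` or logical matrix.
#' @return Logical matrix of the sealed strands.
#' @export
seal_small_breaks <- function(strands) {
  m <- as_mask(strands)
  if (!any(m)) return(m)
  bridge <-
    (mat_shift(m, 1L, 0L) & mat_shift(m, -1L, 0L)) |
    (mat_shift(m, 0L, 1L) & mat_shift(m, 0L, -1L)) |
    (mat_shift(m, 1L, 1L) & mat_shift(m, -1L, -1L)) |
    (mat_shift(m, 1L, -1L) & mat_shift(m, -1L, 1L))
  m | bridge
}

#' Flood the accessible region from the apical border
#'
#' Digital flooding that starts at the apical ectocervical border and moves
#' toward the basal membrane, with the sealed net as the barrier: a
#' 4-connected flood fill over `interior` minus `sealed`, seeded from every
#' free pixel on or 4-adjacent to the apical border. The returned region is a
#' geometric proxy for how deep an external microorganism could penetrate.
#'
#' @param sealed Sealed strand mask from [seal_small_breaks()].
#' @param roi An [epithelium_roi()].
#' @return Logical mask of the accessible region.
#' @export
flood_accessible <- function(sealed, roi) {
  sealed <- as_mask(sealed)
  stopifnot(inherits(roi, "epithelium_roi"),
            all(dim(sealed) == dim(roi$interior)))
  free <- roi$interior & !sealed
  seeds <- adjacent4(free, roi$apical_border)
  out <- matrix(FALSE, nrow(free), ncol(free))
  if (!any(seeds)) {
    warning("no free pixel adjacent to the apical border; accessible region is empty")
    return(out)
  }
  lab <- label_components(free, connectivity = 4L)
  reach <- setdiff(unique(lab[seeds]), 0L)
  out[free] <- lab[free] %in% reach
  out
}

#' Partition the intermediate layer into intact and fragmented regions
#'
#' Because a hole of the net (a 4-connected free component of the
#' intermediate layer) floods entirely once it is reached, the breached free
#' space of the layer is exactly its intersection with the accessible region.
#' The fragmented region is that breached free space together with every
#' intermediate pixel within `margin_px` (Euclidean) of it, which attaches
#' the strand walls bounding each breached basin; everything else in the
#' layer is intact. The two masks always partition the intermediate layer,
#' and because the breached free space can only grow when further breaks are
#' added while the margin is fixed, the fragmented region grows monotonically
#' under nested break sequences.
#'
#' @param sealed Sealed strand mask.
#' @param accessible Accessible-region mask from [flood_accessible()].
#' @param layers A `layer_segmentation` from [segment_layers()].
#' @param margin_px Euclidean distance (px) within which intermediate pixels
#'   are attached to the breached free space; the default 2 covers the strand
#'   walls around a breached basin.
#' @return List with logical masks `intact_region` and `fragmented_region`.
#' @export
partition_intact_fragmented <- function(sealed, accessible, layers,
                                        margin_px = 2) {
  sealed <- as_mask(sealed)
  accessible <- as_mask(accessible)
  stopifnot(inherits(layers, "layer_segmentation"),
            all(dim(sealed) == dim(layers$intermediate)),
            all(dim(accessible) == dim(layers$intermediate)),
            margin_px >= 0)
  inter <- layers$intermediate
  if (!any(inter)) stop("intermediate layer is empty; nothing to partition")
  breached <- inter & !sealed & accessible
  if (any(breached)) {
    d <- imageData(distmap(matrix(as.numeric(!breached), nrow(inter))))
    fragmented <- inter & (breached | d <= margin_px)
  } else {
    fragmented <- matrix(FALSE, nrow(inter), ncol(inter))
  }
  intact <- inter & !fragmented
  list(intact_region = intact, fragmented_region = fragmented)
}

#' Percent coverage of a reference mask
#'
#' @param mask Logical mask.
#' @param reference Non-empty logical reference mask.
#' @return `100 * |mask AND reference| / |reference|`.
#' @export
coverage <- function(mask, reference) {
  mask <- as_mask(mask); reference <- as_mask(reference)
  stopifnot(all(dim(mask) == dim(reference)))
  if (!any(reference)) stop("reference mask is empty")
  100 * sum(mask & reference) / sum(reference)
}

#' Net integrity analysis of one ROI
#'
#' Runs sealing, apical flooding, and the intact/fragmented partition, and
#' computes the coverage percentages: accessible and intact regions as a
#' percent of the epithelial interior, fragmented region as a percent of the
#' intermediate layer. Pixel denominators are retained so any other ratio can
#' be recomputed downstream.
#'
#' @param strands A `strand_mask` or logical matrix.
#' @param roi An [epithelium_roi()].
#' @param layers A `layer_segmentation`.
#' @return Object of class `net_integrity` with masks `sealed_strands`,
#'   `accessible`, `intact_region`, `fragmented_region`, percentages
#'   `pct_accessible`, `pct_intact`, `pct_fragmented_intermediate`, and
#'   denominators `n_interior_px`, `n_intermediate_px`.
#' @export
net_integrity <- function(strands, roi, layers) {
  sealed <- seal_small_breaks(strands) & roi$interior
  accessible <- flood_accessible(sealed, roi)
  parts <- partition_intact_fragmented(sealed, accessible, layers)
  structure(list(
    sealed_strands = sealed,
    accessible = accessible,
    intact_region = parts$intact_region,
    fragmented_region = parts$fragmented_region,
    pct_accessible = coverage(accessible, roi$interior),
    pct_intact = coverage(parts$intact_region, roi$interior),
    pct_fragmented_intermediate = coverage(parts$fragmented_region,
                                           layers$intermediate),
    n_interior_px = sum(roi$interior),
    n_intermediate_px = sum(layers$intermediate)),
    class = "net_integrity")
}

#' @export
print.net_integrity <- function(x, ...) {
  cat(sprintf(paste0("<net_integrity> accessible %.1f%% of interior, ",
                     "intact %.1f%% of interior, fragmented %.1f%% of intermediate\n"),
              x$pct_accessible, x$pct_intact, x$pct_fragmented_intermediate))
  invisible(x)
}
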