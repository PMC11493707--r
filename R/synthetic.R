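# Synthetic epithelium and cohort generator. Produces band-shaped stratified
# epithelium images whose intermediate layer carries a Voronoi cell-boundary
# net, with controllable strand width/intensity, gap (fragmentation) rate and
# width, background and noise -- plus full ground truth, so every downstream
# stage can be tested against known answers.

#' Parameters for the synthetic epithelium generator
#'
#' The generated tissue is a horizontal band between an apical border (top)
#' and a basal border (bottom). The middle `intermediate_fraction` of the band
#' carries a honeycomb of junction-protein strands drawn along the boundaries
#' of a jittered-grid Voronoi tessellation; gaps are then punched into a
#' random subset of cell edges.
#'
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param pixel_size_um Pixel size in micrometres.
#' @param band_top,band_bottom Row index of the apical and basal border, either
#'   a scalar (flat border) or a function of the column index vector returning
#'   one row per column (curved epithelium).
#' @param intermediate_fraction Fraction (0, 1] of the band height occupied by
#'   the strand-bearing intermediate layer, centred within the band.
#' @param cell_diameter_px Mean Voronoi cell diameter (grid spacing) in px.
#' @param strand_width_px Drawn strand width in px.
#' @param strand_intensity,background_intensity Intensities in AU; strands are
#'   drawn additively on top of the compartment background.
#' @param gap_rate Probability that a cell edge receives one gap (capped at 1).
#' @param gap_width_px Integer gap width in px, measured along the strand.
#' @param noise_sd Standard deviation of additive Gaussian noise (clipped at
#'   zero); 0 disables noise.
#' @param seed RNG seed for reproducibility; `NULL` uses the global stream.
#' @return A validated list of class `epithelium_sim_params`.
#' @export
epithelium_sim_params <- function(image_shape = c(256L, 320L),
                                  pixel_size_um = 0.325,
                                  band_top = 20, band_bottom = 235,
                                  intermediate_fraction = 0.6,
                                  cell_diameter_px = 30,
                                  strand_width_px = 2,
                                  strand_intensity = 120,
                                  background_intensity = 20,
                                  gap_rate = 0.15,
                                  gap_width_px = 3L,
                                  noise_sd = 8,
                                  seed = NULL) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8),
            pixel_size_um > 0,
            intermediate_fraction > 0, intermediate_fraction <= 1,
            cell_diameter_px >= 3, strand_width_px >= 1,
            strand_intensity >= 0, background_intensity >= 0,
            gap_rate >= 0, gap_width_px >= 1, noise_sd >= 0)
  if (is.numeric(band_top) && is.numeric(band_bottom) &&
      any(band_top >= band_bottom)) {
    stop("band_top must lie above band_bottom")
  }
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um,
                 band_top = band_top, band_bottom = band_bottom,
                 intermediate_fraction = intermediate_fraction,
                 cell_diameter_px = cell_diameter_px,
                 strand_width_px = strand_width_px,
                 strand_intensity = strand_intensity,
                 background_intensity = background_intensity,
                 gap_rate = gap_rate,
                 gap_width_px = as.integer(gap_width_px),
                 noise_sd = noise_sd, seed = seed),
            class = "epithelium_sim_params")
}

resolve_boundary <- function(b, nc) {
  v <- if (is.function(b)) b(seq_len(nc)) else rep_len(b, nc)
  as.integer(round(v))
}

#' Generate a synthetic epithelium image with ground truth
#'
#' Draws the band-shaped compartment, rasterises the Voronoi cell-boundary
#' net in the intermediate layer at the requested strand width, punches gaps
#' into randomly selected cell edges, and adds clipped Gaussian noise. Ground
#' truth records the pre-gap and post-gap strand masks, the per-edge break
#' status, the true layer masks and the band height. Identical parameters and
#' seed give bit-identical output.
#'
#' @param params An [epithelium_sim_params()] object.
#' @return A list with elements `image` ([fluorescence_image()]), `roi`
#'   ([epithelium_roi()]) and `truth` (ground-truth list with
#'   `layer_masks`, `true_strand_mask`, `strand_mask`, `edges`,
#'   `edge_pixels`, `gap_locations`, `true_gap_fraction`, `true_height_um`).
#' @export
generate_epithelium <- function(params) {
  stopifnot(inherits(params, "epithelium_sim_params"))
  p <- params
  with_seed(p$seed, {
    nr <- p$image_shape[1L]; nc <- p$image_shape[2L]
    bt <- resolve_boundary(p$band_top, nc)
    bb <- resolve_boundary(p$band_bottom, nc)
    if (any(bt < 1L) || any(bb > nr) || any(bt >= bb)) {
      stop("band boundaries must satisfy 1 <= band_top < band_bottom <= rows")
    }
    h <- bb - bt + 1L
    if (min(h) < p$cell_diameter_px) {
      stop("degenerate band: height smaller than cell_diameter_px")
    }
    if (p$gap_width_px >= p$cell_diameter_px) {
      stop("gap_width_px must be smaller than cell_diameter_px")
    }

    rowm <- matrix(seq_len(nr), nr, nc)
    btm <- matrix(bt, nr, nc, byrow = TRUE)
    bbm <- matrix(bb, nr, nc, byrow = TRUE)
    compartment <- rowm >= btm & rowm <= bbm
    apical <- rowm == btm
    basal <- rowm == bbm

    int_h <- pmax(1L, as.integer(round(p$intermediate_fraction * h)))
    int_top <- bt + (h - int_h) %/% 2L
    int_bot <- int_top + int_h - 1L
    itm <- matrix(int_top, nr, nc, byrow = TRUE)
    ibm <- matrix(int_bot, nr, nc, byrow = TRUE)
    intermediate <- compartment & rowm >= itm & rowm <= ibm
    superficial <- compartment & rowm < itm
    basal_layer <- compartment & rowm > ibm

    # jittered-grid seed points inside the intermediate band
    s <- p$cell_diameter_px
    r_lo <- min(int_top); r_hi <- max(int_bot)
    gr <- seq(r_lo + s / 2, r_hi, by = s)
    gc <- seq(s / 2, nc, by = s)
    ngi <- length(gr); ngj <- length(gc)
    jit <- 0.35 * s
    sr <- matrix(gr, ngi, ngj) + matrix(stats::runif(ngi * ngj, -jit, jit), ngi, ngj)
    sc <- matrix(gc, ngi, ngj, byrow = TRUE) +
      matrix(stats::runif(ngi * ngj, -jit, jit), ngi, ngj)
    sr <- clamp(sr, r_lo, r_hi); sc <- clamp(sc, 1, nc)

    # mirror the outermost seed rows across the band boundaries so that the
    # apical- and basal-most cells are capped by their own membranes: the
    # Voronoi edges against the virtual seeds run along the band rim
    sr <- rbind(2 * r_lo - 1 - sr[1L, , drop = FALSE], sr,
                2 * r_hi + 1 - sr[ngi, , drop = FALSE])
    sc <- rbind(sc[1L, , drop = FALSE], sc, sc[ngi, , drop = FALSE])
    ngi <- ngi + 2L

    # nearest and second-nearest seed per intermediate pixel; seeds come from
    # a jittered grid, so candidates live in the surrounding 5x5 grid block
    pix <- which(intermediate)
    pr <- ((pix - 1L) %% nr) + 1L
    pc <- ((pix - 1L) %/% nr) + 1L
    gi <- clamp(as.integer(round((pr - gr[1L]) / s)) + 2L, 1L, ngi)
    gj <- clamp(as.integer(round((pc - gc[1L]) / s)) + 1L, 1L, ngj)
    n <- length(pix)
    d1 <- rep(Inf, n); d2 <- rep(Inf, n)
    l1 <- integer(n); l2 <- integer(n)
    for (di in -2:2) {
      ci <- gi + di
      oki <- ci >= 1L & ci <= ngi
      for (dj in -2:2) {
        cj <- gj + dj
        ok <- oki & cj >= 1L & cj <= ngj
        if (!any(ok)) next
        idx <- (cj[ok] - 1L) * ngi + ci[ok]
        d <- (pr[ok] - sr[idx])^2 + (pc[ok] - sc[idx])^2
        w <- which(ok)
        b1 <- d < d1[w]
        wb1 <- w[b1]
        d2[wb1] <- d1[wb1]; l2[wb1] <- l1[wb1]
        d1[wb1] <- d[b1]; l1[wb1] <- idx[b1]
        b2 <- !b1 & d < d2[w] & idx != l1[w]
        wb2 <- w[b2]
        d2[wb2] <- d[b2]; l2[wb2] <- idx[b2]
      }
    }

    on_strand <- is.finite(d2) & (sqrt(d2) - sqrt(d1)) <= p$strand_width_px
    true_strand <- matrix(FALSE, nr, nc)
    true_strand[pix[on_strand]] <- TRUE

    # per-edge bookkeeping: an edge is an unordered pair of adjacent cells
    ea <- pmin(l1[on_strand], l2[on_strand])
    eb <- pmax(l1[on_strand], l2[on_strand])
    key <- paste(ea, eb)
    edge_pixels <- split(pix[on_strand], key)
    ukey <- names(edge_pixels)
    n_edges <- length(ukey)
    pair <- do.call(rbind, lapply(strsplit(ukey, " "), as.integer))
    edges <- data.frame(edge_id = seq_len(n_edges),
                        cell_a = if (n_edges) pair[, 1L] else integer(0),
                        cell_b = if (n_edges) pair[, 2L] else integer(0),
                        n_px = vapply(edge_pixels, length, integer(1),
                                      USE.NAMES = FALSE))

    broken <- if (n_edges) stats::runif(n_edges) < min(p$gap_rate, 1) else logical(0)
    strand <- true_strand
    gap_locations <- list()
    for (e in which(broken)) {
      erase <- gap_pixels(edge_pixels[[e]], pair[e, ], sr, sc, nr,
                          p$gap_width_px)
      strand[erase] <- FALSE
      gap_locations[[length(gap_locations) + 1L]] <-
        list(pixels = erase, width_px = p$gap_width_px,
             edge_id = edges$edge_id[e])
    }
    edges$broken <- broken

    img <- p$background_intensity * compartment +
      p$strand_intensity * strand
    if (p$noise_sd > 0) {
      img <- pmax(img + stats::rnorm(nr * nc, sd = p$noise_sd), 0)
    }

    roi <- epithelium_roi(compartment, apical, basal)
    truth <- list(layer_masks = list(superficial = superficial,
                                     intermediate = intermediate,
                                     basal = basal_layer),
                  true_strand_mask = true_strand,
                  strand_mask = strand,
                  edges = edges,
                  edge_pixels = edge_pixels,
                  gap_locations = gap_locations,
                  true_gap_fraction = if (n_edges) mean(broken) else 0,
                  true_height_um = mean(h) * p$pixel_size_um,
                  params = p)
    list(image = fluorescence_image(img, p$pixel_size_um),
         roi = roi, truth = truth)
  })
}

# Pixels to erase for one gap: a run of gap_width_px along the edge tangent,
# centred on a uniformly chosen edge pixel. The caller supplies the seed
# coordinate matrices to derive the tangent direction.
gap_pixels <- function(pixels, cells, sr, sc, nr, gap_width_px) {
  dr <- sr[cells[2L]] - sr[cells[1L]]
  dc <- sc[cells[2L]] - sc[cells[1L]]
  nrm <- sqrt(dr^2 + dc^2)
  u <- if (nrm > 0) c(-dc, dr) / nrm else c(1, 0)  # tangent: perpendicular to the cell axis
  prr <- ((pixels - 1L) %% nr) + 1L
  pcc <- ((pixels - 1L) %/% nr) + 1L
  proj <- prr * u[1L] + pcc * u[2L]
  centre <- proj[sample.int(length(proj), 1L)]
  pixels[proj >= centre - gap_width_px / 2 & proj < centre + gap_width_px / 2]
}

#' Punch gaps into a ground-truth strand mask on chosen edges
#'
#' Erases one gap of `gap_width_px` on each listed edge of a generated
#' epithelium, using a per-edge RNG substream so that nested edge sets produce
#' nested erasures. Useful for controlled fragmentation experiments.
#'
#' @param truth Ground-truth list from [generate_epithelium()].
#' @param edge_ids Integer ids from `truth$edges$edge_id`.
#' @param gap_width_px Gap width in px; default from the generating params.
#' @param seed Base seed for the per-edge substreams.
#' @return Logical strand mask with the gaps applied to
#'   `truth$true_strand_mask`.
#' @export
break_edges <- function(truth, edge_ids, gap_width_px = NULL, seed = 1L) {
  if (is.null(gap_width_px)) gap_width_px <- truth$params$gap_width_px
  strand <- truth$true_strand_mask
  nr <- nrow(strand)
  for (e in edge_ids) {
    pixels <- truth$edge_pixels[[e]]
    erase <- with_seed(seed + e, {
      # tangent from the pixel cloud itself (principal axis), avoiding the
      # need to retain seed coordinates
      prr <- ((pixels - 1L) %% nr) + 1L
      pcc <- ((pixels - 1L) %/% nr) + 1L
      if (length(pixels) > 1L) {
        cv <- stats::cov(cbind(prr, pcc))
        u <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
      } else u <- c(1, 0)
      proj <- prr * u[1L] + pcc * u[2L]
      centre <- proj[sample.int(length(proj), 1L)]
      pixels[proj >= centre - gap_width_px / 2 & proj < centre + gap_width_px / 2]
    })
    strand[erase] <- FALSE
  }
  strand
}

#' Parameters for the synthetic cohort generator
#'
#' Hormone levels are drawn log-normally; per-sample image parameters are
#' linearly linked to standardised log-estradiol, so that a negative
#' `effect_gap` makes higher estradiol produce fewer strand gaps (a more
#' intact net) and a positive `effect_intensity` makes it produce brighter
#' strands. Defaults emulate a follicular-phase visit; `phase = "LUT"` flips
#' the hormone distribution and detection-limit defaults to luteal values.
#'
#' @param n_samples Number of study participants (>= 3).
#' @param rois_per_sample Annotated regions of interest per sample (2--6).
#' @param phase `"FOL"` or `"LUT"`.
#' @param estradiol_log_mean,estradiol_log_sd Log-scale (natural log) mean and
#'   sd of plasma estradiol in pg/mL.
#' @param progesterone_log_mean,progesterone_log_sd Same for progesterone in
#'   ng/mL.
#' @param lld_estradiol,lld_progesterone Assay lower limits of detection.
#' @param effect_gap Change in edge gap probability per SD of log-estradiol.
#' @param effect_intensity Change in strand intensity (AU) per SD of
#'   log-estradiol.
#' @param image_params [epithelium_sim_params()] template supplying the base
#'   `gap_rate` and `strand_intensity` and all tissue geometry.
#' @param seed RNG seed.
#' @return A validated list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_samples = 40L,
                              rois_per_sample = 2L,
                              phase = c("FOL", "LUT"),
                              estradiol_log_mean = NULL,
                              estradiol_log_sd = NULL,
                              progesterone_log_mean = NULL,
                              progesterone_log_sd = NULL,
                              lld_estradiol = NULL,
                              lld_progesterone = NULL,
                              effect_gap = -0.12,
                              effect_intensity = 15,
                              image_params = cohort_image_defaults(),
                              seed = NULL) {
  phase <- match.arg(phase)
  defaults <- if (phase == "FOL") {
    list(elm = log(94), els = 0.7, plm = log(0.05), pls = 1.5,
         lle = 22, llp = 0.05)
  } else {
    list(elm = log(180), els = 0.8, plm = log(3.4), pls = 1.3,
         lle = 20, llp = 0.09)
  }
  if (is.null(estradiol_log_mean)) estradiol_log_mean <- defaults$elm
  if (is.null(estradiol_log_sd)) estradiol_log_sd <- defaults$els
  if (is.null(progesterone_log_mean)) progesterone_log_mean <- defaults$plm
  if (is.null(progesterone_log_sd)) progesterone_log_sd <- defaults$pls
  if (is.null(lld_estradiol)) lld_estradiol <- defaults$lle
  if (is.null(lld_progesterone)) lld_progesterone <- defaults$llp
  stopifnot(n_samples >= 3L, rois_per_sample >= 1L, rois_per_sample <= 6L,
            estradiol_log_sd > 0, progesterone_log_sd > 0,
            lld_estradiol > 0, lld_progesterone > 0,
            inherits(image_params, "epithelium_sim_params"))
  structure(list(n_samples = as.integer(n_samples),
                 rois_per_sample = as.integer(rois_per_sample),
                 phase = phase,
                 estradiol_log_mean = estradiol_log_mean,
                 estradiol_log_sd = estradiol_log_sd,
                 progesterone_log_mean = progesterone_log_mean,
                 progesterone_log_sd = progesterone_log_sd,
                 lld_estradiol = lld_estradiol,
                 lld_progesterone = lld_progesterone,
                 effect_gap = effect_gap,
                 effect_intensity = effect_intensity,
                 image_params = image_params, seed = seed),
            class = "cohort_sim_params")
}

#' Default tissue geometry for simulated cohort images
#'
#' A compact epithelium (128 x 160 px, ~18 px cells, 2 px strands) sized so
#' that whole-cohort simulations stay tractable while each ROI still carries
#' tens of cells.
#'
#' @return An [epithelium_sim_params()] object.
#' @export
cohort_image_defaults <- function() {
  epithelium_sim_params(image_shape = c(128L, 160L),
                        band_top = 8, band_bottom = 120,
                        intermediate_fraction = 0.6,
                        cell_diameter_px = 18,
                        strand_width_px = 2,
                        strand_intensity = 100,
                        background_intensity = 20,
                        gap_rate = 0.3, gap_width_px = 3L,
                        noise_sd = 6)
}

#' Generate a synthetic cohort of epithelium image bundles
#'
#' Draws per-sample hormone levels, flags values below the lower limit of
#' detection (storing the censored value at the LLD while keeping the true
#' value in the `truth` attribute), derives per-sample image parameters from
#' the linear hormone links, and generates `rois_per_sample` epithelium image
#' bundles per sample from independent substreams.
#'
#' @param params A [cohort_sim_params()] object.
#' @return A list with `bundles` (list of [generate_epithelium()] results,
#'   each tagged with `sample_id`/`roi_id`) and `hormones` (data frame with
#'   columns `sample_id`, `phase`, `estradiol_pg_ml`, `estradiol_below_lld`,
#'   `progesterone_ng_ml`, `progesterone_below_lld`; true uncensored values
#'   and per-sample image parameters in `attr(, "truth")`).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_samples
    e_true <- stats::rlnorm(n, p$estradiol_log_mean, p$estradiol_log_sd)
    p_true <- stats::rlnorm(n, p$progesterone_log_mean, p$progesterone_log_sd)
    e_bl <- e_true < p$lld_estradiol
    p_bl <- p_true < p$lld_progesterone
    z <- (log(e_true) - p$estradiol_log_mean) / p$estradiol_log_sd
    gap_i <- clamp(p$image_params$gap_rate + p$effect_gap * z, 0, 0.95)
    int_i <- pmax(p$image_params$strand_intensity + p$effect_intensity * z, 1)
    sub_seeds <- sample.int(.Machine$integer.max,
                            n * p$rois_per_sample)
    sample_id <- sprintf("S%03d", seq_len(n))
    bundles <- vector("list", n * p$rois_per_sample)
    k <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(p$rois_per_sample)) {
        k <- k + 1L
        ip <- p$image_params
        ip$gap_rate <- gap_i[i]
        ip$strand_intensity <- int_i[i]
        ip$seed <- sub_seeds[k]
        b <- generate_epithelium(ip)
        b$roi$sample_id <- sample_id[i]
        b$roi$roi_id <- sprintf("R%d", j)
        bundles[[k]] <- b
      }
    }
    hormones <- data.frame(
      sample_id = sample_id,
      phase = p$phase,
      estradiol_pg_ml = ifelse(e_bl, p$lld_estradiol, e_true),
      estradiol_below_lld = e_bl,
      progesterone_ng_ml = ifelse(p_bl, p$lld_progesterone, p_true),
      progesterone_below_lld = p_bl)
    attr(hormones, "truth") <- data.frame(
      sample_id = sample_id,
      estradiol_true = e_true, progesterone_true = p_true,
      gap_rate = gap_i, strand_intensity = int_i)
    list(bundles = bundles, hormones = hormones)
  })
}
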