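test_that("sealing bridges one-pixel breaks and leaves wider breaks open", {
  s1 <- strand_with_gap(21L, 40L, 11L, gap_cols = 20L)
  sealed1 <- seal_small_breaks(s1)
  expect_true(all(sealed1[11, ]))
  expect_identical(max(ejpnet:::label_components(sealed1, 8L)), 1L)

  s2 <- strand_with_gap(21L, 40L, 11L, gap_cols = 20:21)
  sealed2 <- seal_small_breaks(s2)
  expect_false(any(sealed2[11, 20:21]))
  expect_identical(max(ejpnet:::label_components(sealed2, 8L)), 2L)

  # diagonal one-pixel break is bridged too
  d <- matrix(FALSE, 20, 20)
  d[cbind(1:20, 1:20)] <- TRUE
  d[10, 10] <- FALSE
  expect_true(seal_small_breaks(d)[10, 10])

  empty <- matrix(FALSE, 5, 5)
  expect_identical(seal_small_breaks(empty), empty)
})

test_that("flooding reaches everything when no net blocks it", {
  roi <- make_rect_roi(50L, 60L, 5, 45)
  acc <- flood_accessible(matrix(FALSE, 50, 60), roi)
  expect_identical(acc, roi$interior)
  expect_equal(coverage(acc, roi$interior), 100)
})

test_that("an unbroken strand stops the flood; a 3 px gap lets it through", {
  nr <- 100L; nc <- 80L
  roi <- make_rect_roi(nr, nc, 1, nr)
  s <- strand_with_gap(nr, nc, 30L)
  acc <- flood_accessible(seal_small_breaks(s), roi)
  want <- matrix(FALSE, nr, nc); want[1:29, ] <- TRUE
  expect_identical(acc, want)

  s3 <- strand_with_gap(nr, nc, 30L, gap_cols = 40:42)
  sealed3 <- seal_small_breaks(s3)
  acc3 <- flood_accessible(sealed3, roi)
  expect_identical(acc3, roi$interior & !sealed3)
})

test_that("flooding equals a brute-force breadth-first search", {
  for (seed in c(1L, 2L, 3L, 4L, 5L)) {
    g <- random_barrier_grid(96L, 96L, seed)
    acc <- flood_accessible(g$sealed, g$roi)
    free <- g$roi$interior & !g$sealed
    seeds <- ejpnet:::adjacent4(free, g$roi$apical_border)
    expect_identical(acc, bfs_flood(free, seeds))
  }
})

test_that("no accessible pixel leaks past the sealed net", {
  p <- epithelium_sim_params(image_shape = c(128L, 160L), band_top = 10,
                             band_bottom = 112, cell_diameter_px = 18,
                             gap_rate = 0.4, noise_sd = 0, seed = 17L)
  b <- generate_epithelium(p)
  sealed <- seal_small_breaks(b$truth$strand_mask) & b$roi$interior
  acc <- flood_accessible(sealed, b$roi)
  expect_false(any(acc & sealed))
  # every 4-neighbour of an accessible pixel is accessible, sealed, or outside
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- ejpnet:::mat_shift(acc, d[1], d[2])
    reached_free <- nb & b$roi$interior & !sealed
    expect_true(all(acc[reached_free]))
  }
})

test_that("a closed honeycomb is fully intact; one breached outer cell turns fragmented", {
  p <- epithelium_sim_params(gap_rate = 0, noise_sd = 0, seed = 23L)
  b <- generate_epithelium(p)
  layers <- segment_layers(b$truth$true_strand_mask, b$roi, 15L)
  ni0 <- net_integrity(b$truth$true_strand_mask, b$roi, layers)
  expect_equal(coverage(ni0$intact_region, layers$intermediate), 100)
  expect_false(any(ni0$fragmented_region))

  # break one rim edge (touching the top of the intermediate band)
  inter <- b$truth$layer_masks$intermediate
  top_rows <- apply(inter, 2, function(cc) which(cc)[1])
  rim <- which(vapply(b$truth$edge_pixels, function(px) {
    r <- ((px - 1L) %% nrow(inter)) + 1L
    cc <- ((px - 1L) %/% nrow(inter)) + 1L
    any(r <= top_rows[cc] + 1L)
  }, logical(1)))[1]
  m <- break_edges(b$truth, rim, gap_width_px = 3, seed = 3L)
  ni1 <- net_integrity(m, b$roi, layers)
  expect_gt(sum(ni1$fragmented_region), 0)
  # exactly one basin opened: fragmented area is about one cell
  cell_area <- pi * (b$truth$params$cell_diameter_px / 2)^2
  expect_lt(sum(ni1$fragmented_region), 3 * cell_area)
  expect_identical(ni1$intact_region | ni1$fragmented_region,
                   layers$intermediate)
  expect_false(any(ni1$intact_region & ni1$fragmented_region))
})

test_that("coverage is a literal pixel-count ratio", {
  ref <- matrix(FALSE, 20, 20); ref[3:18, 3:18] <- TRUE
  expect_equal(coverage(ref, ref), 100)
  expect_equal(coverage(matrix(FALSE, 20, 20), ref), 0)
  set.seed(5)
  m <- matrix(stats::runif(400) < 0.3, 20, 20)
  cnt <- 0
  for (i in 1:20) for (j in 1:20) if (m[i, j] && ref[i, j]) cnt <- cnt + 1
  expect_equal(coverage(m, ref), 100 * cnt / sum(ref))
  expect_error(coverage(m, matrix(FALSE, 20, 20)), "empty")
})

test_that("adding gaps never decreases accessibility nor increases intact coverage", {
  p <- epithelium_sim_params(image_shape = c(128L, 160L), band_top = 10,
                             band_bottom = 112, cell_diameter_px = 18,
                             gap_rate = 0, noise_sd = 0, seed = 29L)
  b <- generate_epithelium(p)
  layers <- segment_layers(b$truth$true_strand_mask, b$roi, 9L)
  set.seed(1)
  order_ids <- sample(b$truth$edges$edge_id)
  prev_acc <- -Inf; prev_int <- Inf
  for (k in c(0L, 4L, 8L, 12L)) {
    m <- if (k == 0L) b$truth$true_strand_mask else
      break_edges(b$truth, order_ids[seq_len(k)], gap_width_px = 3, seed = 55L)
    ni <- net_integrity(m, b$roi, layers)
    expect_gte(ni$pct_accessible, prev_acc)
    expect_lte(coverage(ni$intact_region, layers$intermediate), prev_int + 1e-9)
    prev_acc <- ni$pct_accessible
    prev_int <- coverage(ni$intact_region, layers$intermediate)
  }
})

test_that("end-to-end recovery: intact net stays intact, shattered net is accessible", {
  # gap-free tissue through the full pipeline (with noise)
  p0 <- epithelium_sim_params(gap_rate = 0, seed = 41L)
  b0 <- generate_epithelium(p0)
  row0 <- quantify_bundle(b0$image, b0$roi, pipeline_config())
  expect_gte(row0$pct_intact * row0$n_interior_px / row0$n_intermediate_px, 95)
  # every edge broken on a thin-strand, large-cell tissue: nearly everything
  # is reachable (the strands themselves are never accessible)
  p1 <- epithelium_sim_params(image_shape = c(256L, 320L), band_top = 12,
                              band_bottom = 244, cell_diameter_px = 40,
                              strand_width_px = 1, gap_rate = 0,
                              noise_sd = 0, seed = 43L)
  b1 <- generate_epithelium(p1)
  m <- break_edges(b1$truth, b1$truth$edges$edge_id, gap_width_px = 3,
                   seed = 5L)
  layers1 <- segment_layers(b1$truth$true_strand_mask, b1$roi, 20L)
  ni1 <- net_integrity(m, b1$roi, layers1)
  expect_gte(ni1$pct_accessible, 95)
})
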