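# Fixtures and independent oracles built in code at test time.

# Rectangular band ROI: full image width, apical border at row `top`, basal
# border at row `bottom`.
make_rect_roi <- function(nr, nc, top, bottom, roi_id = "roi1",
                          sample_id = "sample1") {
  interior <- matrix(FALSE, nr, nc)
  interior[top:bottom, ] <- TRUE
  apical <- matrix(FALSE, nr, nc); apical[top, ] <- TRUE
  basal <- matrix(FALSE, nr, nc); basal[bottom, ] <- TRUE
  epithelium_roi(interior, apical, basal, roi_id = roi_id,
                 sample_id = sample_id)
}

# Horizontal strand across the full width at `row`, with a break over
# `gap_cols` (possibly empty).
strand_with_gap <- function(nr, nc, row, gap_cols = integer(0)) {
  s <- matrix(FALSE, nr, nc)
  s[row, ] <- TRUE
  if (length(gap_cols)) s[row, gap_cols] <- FALSE
  s
}

# Brute-force breadth-first search flood oracle: level-synchronous frontier
# expansion over the 4-neighbour graph of `free`, starting at `seeds`.
# Independent of the component-labelling route used by the implementation.
bfs_flood <- function(free, seeds) {
  nr <- nrow(free); nc <- ncol(free)
  visited <- matrix(FALSE, nr, nc)
  frontier <- which(seeds & free)
  visited[frontier] <- TRUE
  while (length(frontier)) {
    r <- ((frontier - 1L) %% nr) + 1L
    cc <- ((frontier - 1L) %/% nr) + 1L
    nb <- c(frontier[r > 1L] - 1L,
            frontier[r < nr] + 1L,
            frontier[cc > 1L] - nr,
            frontier[cc < nc] + nr)
    nb <- unique(nb[free[nb] & !visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

# Exhaustive Spearman permutation p-value oracle for n = 5, enumerating
# permutations by filtering the full 5^5 grid (a deliberately different
# construction from the package's recursive generator) and computing rho with
# stats::cor(method = "spearman").
spearman_p_oracle_n5 <- function(x, y) {
  stopifnot(length(x) == 5L, length(y) == 5L)
  grid <- as.matrix(expand.grid(1:5, 1:5, 1:5, 1:5, 1:5))
  perms <- grid[apply(grid, 1L, function(r) length(unique(r)) == 5L), ]
  rho_obs <- stats::cor(x, y, method = "spearman")
  rho_perm <- apply(perms, 1L, function(pp) {
    stats::cor(x, y[pp], method = "spearman")
  })
  mean(abs(rho_perm) >= abs(rho_obs) - 1e-12)
}

# Loop-based single-scale Hessian ridge oracle with mirrored borders:
# explicit per-pixel kernel sums instead of the operator-matrix route.
ridge_oracle <- function(x, sigma, gamma = 1.5) {
  nr <- nrow(x); nc <- ncol(x)
  k <- max(1L, as.integer(ceiling(3.5 * sigma)))
  w <- stats::dnorm(-k:k, sd = sigma); w <- w / sum(w)
  refl <- function(j, n) {
    while (any(j < 1L | j > n)) {
      j[j < 1L] <- 2L - j[j < 1L]
      j[j > n] <- 2L * n - j[j > n]
    }
    j
  }
  s <- matrix(0, nr, nc)
  tmp <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    rows <- refl(i + (-k:k), nr)
    tmp[i, ] <- colSums(x[rows, , drop = FALSE] * w)
  }
  for (j in seq_len(nc)) {
    cols <- refl(j + (-k:k), nc)
    s[, j] <- as.vector(tmp[, cols, drop = FALSE] %*% w)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      iu <- refl(i - 1L, nr); id <- refl(i + 1L, nr)
      jl <- refl(j - 1L, nc); jr <- refl(j + 1L, nc)
      irr <- s[iu, j] - 2 * s[i, j] + s[id, j]
      icc <- s[i, jl] - 2 * s[i, j] + s[i, jr]
      irc <- ((s[id, jr] - s[iu, jr]) - (s[id, jl] - s[iu, jl])) / 4
      lam <- (irr + icc) / 2 - sqrt(((irr - icc) / 2)^2 + irc^2)
      out[i, j] <- sigma^gamma * max(0, -lam)
    }
  }
  out
}

# A random barrier grid for flood testing: smoothed noise thresholded into
# blobby walls inside a rectangular band ROI.
random_barrier_grid <- function(nr, nc, seed, wall_frac = 0.35) {
  set.seed(seed)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  z <- ejpnet:::gauss_smooth(z, 2)
  roi <- make_rect_roi(nr, nc, 2L, nr - 1L)
  sealed <- z > stats::quantile(z, 1 - wall_frac) & roi$interior
  list(roi = roi, sealed = sealed)
}
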