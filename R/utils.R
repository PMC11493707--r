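# Internal helpers shared across modules. All image data are plain R matrices
# indexed [row, col] with row 1 at the apical (lumen-facing) side.

#' @importFrom EBImage bwlabel distmap closing makeBrush imageData
NULL

# Shift a matrix by (dr, dc): out[i, j] = m[i - dr, j - dc], vacated cells
# filled with `fill`. Used for vectorised neighbourhood logic.
mat_shift <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(sr) && length(sc)) out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream; seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Connected-component labelling of a logical mask. connectivity = 4 delegates
# to EBImage::bwlabel (4-connected); connectivity = 8 additionally merges
# labels that touch diagonally (union-find over diagonal label pairs).
label_components <- function(mask, connectivity = 4L) {
  stopifnot(is.matrix(mask))
  lab <- imageData(bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask))))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 4L || max(lab) <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal pairs
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(max(lab))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  relab <- match(root, sort(unique(root)))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}

# Otsu threshold of a numeric vector via maximisation of the between-class
# variance over a fixed-width histogram. Returns a threshold on the value
# scale; values > threshold fall in the foreground class.
otsu_threshold <- function(v, levels = 256L) {
  r <- range(v)
  if (diff(r) == 0) return(r[1L])
  breaks <- seq(r[1L], r[2L], length.out = levels + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE),
                nbins = levels)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(h)
  w1 <- sum(h) - w0
  m0 <- cumsum(h * mids) / pmax(w0, 1)
  m1 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w1, 1)
  between <- w0 * w1 * (m0 - m1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  breaks[which.max(between) + 1L]
}

# Pixels of `mask` having a 4-neighbour in `target` (or lying in `target`).
adjacent4 <- function(mask, target) {
  nb <- mat_shift(target, 1L, 0L) | mat_shift(target, -1L, 0L) |
    mat_shift(target, 0L, 1L) | mat_shift(target, 0L, -1L)
  mask & (target | nb)
}

as_mask <- function(x) {
  if (inherits(x, "strand_mask")) x <- x$mask
  stopifnot(is.matrix(x))
  if (!is.logical(x)) x <- x > 0
  x
}
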