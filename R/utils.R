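# Internal numerical helpers shared across modules.
#
# Image convention: a frame is a numeric matrix indexed [row = y, col = x].
# Pixel centres sit at integer (col, row); physical coordinates are
# x_um = (col - 1) * pixel_size_um, y_um = (row - 1) * pixel_size_um.

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All generator randomness flows through this.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Counter-based substream derivation: cell k of a movie seeded with `seed`
# always sees the same stream, regardless of how many other cells exist.
# Linear congruential mix kept inside 2^31 (R integers are 32-bit).
substream_seed <- function(seed, key) {
  s <- (as.numeric(seed) %% 2147483563)
  as.integer((s * 40014 + as.numeric(key) * 40692 + 12211) %% 2147483563) + 1L
}

# Bilinear interpolation of matrix `img` at fractional (x = col, y = row)
# positions; outside pixels read as `pad`.
bilinear_sample <- function(img, x, y, pad = 0) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  gv <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- rep(pad, length(r))
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  v00 <- gv(y0, x0); v01 <- gv(y0, x0 + 1)
  v10 <- gv(y0 + 1, x0); v11 <- gv(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Rotate `img` by `angle` radians about `center` (x, y in pixels), output same
# size, bilinear, empty corners = pad. Positive angle rotates content
# counter-clockwise in standard x-right / y-down image axes.
rotate_image <- function(img, angle, center = NULL, pad = 0) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(center)) center <- c((nc + 1) / 2, (nr + 1) / 2)
  g <- expand.grid(y = seq_len(nr), x = seq_len(nc))  # row index fastest
  dx <- g$x - center[1]; dy <- g$y - center[2]
  ca <- cos(angle); sa <- sin(angle)
  xs <- center[1] + ca * dx - sa * dy
  ys <- center[2] + sa * dx + ca * dy
  matrix(bilinear_sample(img, xs, ys, pad = pad), nrow = nr, ncol = nc)
}

# Longest marching-squares contour of a binary mask at level 0.5.
# Returns a closed polygon as a two-column matrix (x = col, y = row).
mask_contour <- function(mask) {
  m <- matrix(as.numeric(mask), nrow = nrow(mask))
  # contourLines takes z[i, j] at (x[i], y[j]): feed rows as x, then swap.
  cl <- contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m,
                     levels = 0.5)
  if (length(cl) == 0) abort("mask has no contour (empty or full mask)")
  len <- vapply(cl, function(p) length(p$x), numeric(1))
  p <- cl[[which.max(len)]]
  cbind(x = p$y, y = p$x)
}

# Polygon arc length (closing the loop).
poly_perimeter <- function(poly) {
  d <- sqrt(diff(c(poly[, 1], poly[1, 1]))^2 + diff(c(poly[, 2], poly[1, 2]))^2)
  sum(d)
}

# Resample an (optionally closed) polyline to a uniform `step` spacing.
resample_polyline <- function(poly, step = 1, closed = FALSE) {
  if (closed) poly <- rbind(poly, poly[1, , drop = FALSE])
  seg <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) abort("degenerate polyline")
  si <- seq(0, total, by = step)
  cbind(x = approx(s, poly[, 1], xout = si, ties = "ordered")$y,
        y = approx(s, poly[, 2], xout = si, ties = "ordered")$y)
}

# Smooth a closed polygon: resample to ~1-px spacing and apply a circular
# running mean. Removes marching-squares staircase artefacts that inflate
# perimeter estimates on digitized shapes.
smooth_closed_poly <- function(poly, window = 3) {
  rs <- resample_polyline(poly, step = 1, closed = TRUE)
  rs <- rs[-nrow(rs), , drop = FALSE]
  n <- nrow(rs)
  if (n <= window) return(rs)
  k <- (window - 1) / 2
  idx <- function(i) ((i - 1) %% n) + 1
  out <- rs
  for (o in setdiff(-k:k, 0)) out <- out + rs[idx(seq_len(n) + o), ]
  out / window
}

# Three-point parabolic sub-sample refinement around discrete argmax `i` of
# values `v`; returns fractional index. Falls back to `i` at the ends.
parabolic_refine <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(i)
  y0 <- v[i - 1]; y1 <- v[i]; y2 <- v[i + 1]
  den <- y0 - 2 * y1 + y2
  if (!is.finite(den) || den == 0) return(i)
  delta <- 0.5 * (y0 - y2) / den
  i + max(-0.5, min(0.5, delta))
}

# Merge 4-connected labels that touch diagonally, yielding 8-connectivity.
labels_to_8conn <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  shifts <- list(c(1, 1), c(1, -1))
  for (sh in shifts) {
    a <- lab[seq_len(nr - 1), if (sh[2] == 1) seq_len(nc - 1) else 2:nc]
    b <- lab[2:nr, if (sh[2] == 1) 2:nc else seq_len(nc - 1)]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  k <- max(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(k), find, numeric(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}
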