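# Polygon and binary-morphology primitives shared by the region builders.
#
# Coordinate convention (package-wide): 0-based (row, col) addressing pixel
# centers, so the pixel stored at matrix position [i, j] has center
# (i - 1, j - 1). Polygons are closed implicitly.

# Even-odd rasterization of a closed polygon: TRUE for pixels whose centers
# lie strictly inside or exactly on the polygon boundary.
polygon_mask <- function(poly, shape) {
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  ys <- rep(0:(nr - 1L), times = nc)  # row coordinate of each pixel center
  xs <- rep(0:(nc - 1L), each = nr)   # col coordinate
  n <- nrow(poly)
  inside <- logical(nr * nc)
  on_boundary <- logical(nr * nc)
  j <- n
  for (i in seq_len(n)) {
    y1 <- poly[j, 1]; x1 <- poly[j, 2]
    y2 <- poly[i, 1]; x2 <- poly[i, 2]
    cross <- (x2 - x1) * (ys - y1) - (y2 - y1) * (xs - x1)
    on_seg <- abs(cross) < 1e-9 &
      xs >= pmin(x1, x2) - 1e-9 & xs <= pmax(x1, x2) + 1e-9 &
      ys >= pmin(y1, y2) - 1e-9 & ys <= pmax(y1, y2) + 1e-9
    on_boundary <- on_boundary | on_seg
    crosses <- (y1 > ys) != (y2 > ys)
    if (any(crosses)) {
      xint <- x1 + (ys - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (xs < xint))
    }
    j <- i
  }
  matrix(inside | on_boundary, nr, nc)
}

# Shoelace area of a closed polygon (vertex list, implicit closure).
shoelace_area <- function(poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(poly[j, 2] * poly[, 1] - poly[, 2] * poly[j, 1])) / 2
}

# Proper segment-crossing test used by the polygon simplicity check.
segments_cross <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    (b[2] - a[2]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[2] - a[2])
  }
  d1 <- orient(q1, q2, p1); d2 <- orient(q1, q2, p2)
  d3 <- orient(p1, p2, q1); d4 <- orient(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

# TRUE when the closed polygon has no properly crossing non-adjacent edges.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      # skip adjacent edges (they share a vertex)
      if (b == a || abs(a - b) == 1L || (a == 1L && b == n)) next
      if (segments_cross(poly[idx[a, 1], ], poly[idx[a, 2], ],
                         poly[idx[b, 1], ], poly[idx[b, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Disk structuring element offsets: {(dr, dc) : dr^2 + dc^2 <= r^2}.
disc_offsets <- function(r) {
  g <- expand.grid(dr = seq.int(-r, r), dc = seq.int(-r, r))
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

shift_mask <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Binary dilation by the radius-r disk (out-of-image treated as background).
dilate_mask <- function(m, r) {
  off <- disc_offsets(r)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mask(m, off$dr[i], off$dc[i], fill = FALSE)
  }
  out
}

# Binary erosion by the radius-r disk (out-of-image treated as background,
# so foreground touching the border erodes away).
erode_mask <- function(m, r) {
  off <- disc_offsets(r)
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_mask(m, off$dr[i], off$dc[i], fill = FALSE)
  }
  out
}
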