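# Fixture builders and independent brute-force oracles used across tests.

# Axis-aligned rectangular lesion annotation.
rect_annotation <- function(r0, r1, c0, c1, class = "benign",
                            shape = "regular", margin = "circumscribed",
                            echo = "uniform", calc = NULL) {
  lesion_annotation(
    boundary = rbind(c(r0, c0), c(r0, c1), c(r1, c1), c(r1, c0)),
    calcifications = calc, shape = shape, margin = margin, echo = echo,
    class = class)
}

# Random valid annotation with a convex polygon and calcifications inside
# its bounding box; coordinates on a quarter-pixel grid so that JSON
# round-trips are exact in decimal.
random_annotation <- function(img_size = 100) {
  n <- sample(3:12, 1)
  cx <- runif(1, 30, img_size - 30)
  cy <- runif(1, 30, img_size - 30)
  rad <- runif(1, 8, 22)
  th <- sort(runif(n, 0, 2 * pi))
  poly <- cbind(cy + rad * cos(th), cx + rad * sin(th))
  poly <- round(poly * 4) / 4
  if (!camlink:::polygon_is_simple(poly)) return(random_annotation(img_size))
  ncal <- sample(0:3, 1)
  calc <- if (ncal > 0) {
    # convex combinations of the (convex) boundary vertices lie inside it
    t(vapply(seq_len(ncal), function(i) {
      w <- runif(n); w <- w / sum(w)
      round(colSums(poly * w) * 4) / 4
    }, numeric(2)))
  } else NULL
  lesion_annotation(
    boundary = poly, calcifications = calc,
    shape = sample(c("regular", "irregular"), 1),
    margin = sample(c("circumscribed", "not_circumscribed"), 1),
    echo = sample(c("uniform", "non_uniform"), 1),
    class = sample(c("benign", "malignant"), 1),
    image = paste0("rand_", sample.int(1e6, 1)))
}

# Pixelwise brute-force morphology with the same disk element as the
# implementation, written independently (per-pixel neighborhood scan).
brute_dilate <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      hit <- FALSE
      for (di in -r:r) {
        for (dj in -r:r) {
          if (di^2 + dj^2 > r^2 + 1e-9) next
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && m[ii, jj]) {
            hit <- TRUE; break
          }
        }
        if (hit) break
      }
      out[i, j] <- hit
    }
  }
  out
}

brute_erode <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(TRUE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      keep <- TRUE
      for (di in -r:r) {
        for (dj in -r:r) {
          if (di^2 + dj^2 > r^2 + 1e-9) next
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > nr || jj < 1 || jj > nc || !m[ii, jj]) {
            keep <- FALSE; break
          }
        }
        if (!keep) break
      }
      out[i, j] <- keep
    }
  }
  out
}

# Random convex polygon (points on an ellipse) with shoelace area >= min_area.
random_convex_polygon <- function(min_area = 500, img = 80) {
  repeat {
    n <- sample(6:14, 1)
    a <- runif(1, 14, 25); b <- runif(1, 14, 25)
    th <- sort(runif(n, 0, 2 * pi))
    poly <- cbind(img / 2 + a * cos(th) + runif(1, -5, 5),
                  img / 2 + b * sin(th) + runif(1, -5, 5))
    if (camlink:::shoelace_area(poly) >= min_area) return(poly)
  }
}

# Independent classical Grad-CAM: spatial-mean gradient weights, rectified
# weighted sum, min-max normalized.
reference_gradcam <- function(maps, grads) {
  K <- dim(maps)[3]
  alpha <- vapply(seq_len(K), function(k) mean(grads[, , k]), numeric(1))
  m <- matrix(0, dim(maps)[1], dim(maps)[2])
  for (k in seq_len(K)) m <- m + alpha[k] * maps[, , k]
  m <- pmax(m, 0)
  if (max(m) > 0) m / max(m) else m
}

minmax01 <- function(m) {
  r <- max(m) - min(m)
  if (r == 0) m * 0 else (m - min(m)) / r
}

# Small deterministic RoI dataset for backend tests.
make_roi_dataset <- function(n, size = 32, seed = 7) {
  prepare_dataset(generate_dataset(n, seed = seed), size = size)
}
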