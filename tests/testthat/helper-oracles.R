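# Independent brute-force oracles used to freeze expected values.
# These deliberately re-derive each quantity from first principles and
# share no code with the implementation under test.

# exhaustive Otsu: scan all 256 candidate thresholds on the raw pixels
oracle_otsu <- function(img) {
  v <- as.vector(img)
  best_t <- NA_integer_
  best <- -Inf
  for (t in 0:255) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    crit <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (crit > best + 1e-12) {     # strictly greater: smallest argmax wins
      best <- crit
      best_t <- t
    }
  }
  best_t
}

# set-based dilation/erosion: direct definition over footprint offsets
oracle_morph <- function(mask, footprint, erode = FALSE) {
  r <- (nrow(footprint) - 1L) %/% 2L
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- logical(0)
    for (di in -r:r) for (dj in -r:r) {
      if (!footprint[di + r + 1, dj + r + 1]) next
      ii <- i + di; jj <- j + dj
      vals <- c(vals, ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
                  mask[ii, jj] == 255)
    }
    out[i, j] <- if (erode) {
      if (all(vals)) 255 else 0
    } else {
      if (any(vals)) 255 else 0
    }
  }
  out
}

# sliding-window mean with symmetric reflection, computed directly
oracle_blur <- function(img, k) {
  r <- (k - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0
    for (di in -r:r) for (dj in -r:r)
      s <- s + img[refl(i + di, h), refl(j + dj, w)]
    m <- s / k^2
    out[i, j] <- sign(m) * floor(abs(m) * 1 + 0.5)
  }
  out
}

# pixels adjacent (8-neighbourhood) to the opposite phase: the fg/bg boundary
boundary_set <- function(mask) {
  fg <- mask > 0
  h <- nrow(fg); w <- ncol(fg)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- fg
  bnd <- matrix(FALSE, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[2:(h + 1) + di, 2:(w + 1) + dj]
    bnd <- bnd | (fg & !nb) | (!fg & nb)
  }
  bnd
}

count_components <- function(mask, connectivity = 8) {
  woundsizer:::cc_label_cpp(mask > 0, as.integer(connectivity))$n
}

# random binary mask with a clear background margin around the border
random_margin_mask <- function(h, w, margin, p = 0.4) {
  m <- matrix(0, h, w)
  core <- matrix(ifelse(stats::runif((h - 2 * margin) * (w - 2 * margin)) < p,
                        255, 0), h - 2 * margin, w - 2 * margin)
  m[(margin + 1):(h - margin), (margin + 1):(w - margin)] <- core
  m
}

# draw k disjoint filled rectangles; returns mask and the per-rectangle
# traced-contour areas (w-1)(h-1)
random_rectangles <- function(k, h = 80, w = 100) {
  mask <- matrix(0, h, w)
  areas <- numeric(0)
  occupied <- matrix(FALSE, h, w)
  placed <- 0
  while (placed < k) {
    rw <- sample(4:15, 1); rh <- sample(4:15, 1)
    r0 <- sample(2:(h - rh - 1), 1); c0 <- sample(2:(w - rw - 1), 1)
    # 1-px clearance so rectangles stay 8-disconnected
    zone <- occupied[max(1, r0 - 1):min(h, r0 + rh), max(1, c0 - 1):min(w, c0 + rw)]
    if (any(zone)) next
    mask[r0:(r0 + rh - 1), c0:(c0 + rw - 1)] <- 255
    occupied[r0:(r0 + rh - 1), c0:(c0 + rw - 1)] <- TRUE
    areas <- c(areas, (rw - 1) * (rh - 1))
    placed <- placed + 1
  }
  list(mask = mask, areas = areas)
}
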