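# Internal image geometry: one bilinear sampler drives rotation, zoom,
# translation and resizing, with reflection at the borders so that rotated
# images show no black corners.

# mirror an out-of-range coordinate back into [1, n]
reflectCoord <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  p <- 2 * (n - 1)
  x <- (x - 1) %% p
  x <- ifelse(x > (n - 1), p - x, x)
  x + 1
}

# Sample a single-channel matrix at fractional (row, col) positions with
# bilinear interpolation and reflect padding.
bilinearAt <- function(img, rows, cols) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  r1 <- reflectCoord(r0, H); r2 <- reflectCoord(r0 + 1, H)
  c1 <- reflectCoord(c0, W); c2 <- reflectCoord(c0 + 1, W)
  v11 <- img[cbind(r1, c1)]; v21 <- img[cbind(r2, c1)]
  v12 <- img[cbind(r1, c2)]; v22 <- img[cbind(r2, c2)]
  (1 - fr) * (1 - fc) * v11 + fr * (1 - fc) * v21 +
    (1 - fr) * fc * v12 + fr * fc * v22
}

# Apply an affine map to an H x W x C image array. The map is defined in
# output space: output pixel p is sampled from A %*% (p - centre) + centre + t
# in the source image, i.e. `angle` rotates the *content* counter-clockwise,
# `zoom` > 1 magnifies, `translate` shifts the content by (dr, dc) pixels.
affineTransform <- function(img, angle = 0, zoom = 1, translate = c(0, 0)) {
  d <- dim(img)
  H <- d[1]; W <- d[2]; C <- if (length(d) >= 3) d[3] else 1L
  if (angle == 0 && zoom == 1 && all(translate == 0)) return(img)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  dr <- g$r - cr; dc <- g$c - cc
  ca <- cos(angle); sa <- sin(angle)
  # inverse map: rotate by -angle, scale by 1/zoom, then undo translation
  sr <- (ca * dr - sa * dc) / zoom + cr - translate[1]
  sc <- (sa * dr + ca * dc) / zoom + cc - translate[2]
  out <- array(0, dim = c(H, W, C))
  im3 <- array(img, dim = c(H, W, C))
  for (ch in seq_len(C)) {
    out[, , ch] <- matrix(bilinearAt(im3[, , ch], sr, sc), H, W)
  }
  if (length(d) == 2L) out[, , 1] else out
}

# Bilinear resize of an H x W x C image to newH x newW (centre-aligned).
resizeBilinear <- function(img, newH, newW) {
  d <- dim(img)
  H <- d[1]; W <- d[2]; C <- if (length(d) >= 3) d[3] else 1L
  if (H == newH && W == newW) return(img)
  rows <- (seq_len(newH) - 0.5) * H / newH + 0.5
  cols <- (seq_len(newW) - 0.5) * W / newW + 0.5
  g <- expand.grid(r = rows, c = cols)
  out <- array(0, dim = c(newH, newW, C))
  im3 <- array(img, dim = c(H, W, C))
  for (ch in seq_len(C)) {
    out[, , ch] <- matrix(bilinearAt(im3[, , ch], g$r, g$c), newH, newW)
  }
  if (length(d) == 2L) out[, , 1] else out
}

# horizontal flip (mirror columns) of an H x W x C array
flipHorizontal <- function(img) {
  d <- dim(img)
  if (length(d) == 2L) img[, rev(seq_len(d[2]))]
  else img[, rev(seq_len(d[2])), , drop = FALSE]
}
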