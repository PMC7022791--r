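# Independent oracles kept deliberately naive: they share no code with the
# implementation paths they check.

# Per-pixel double-loop sandbox mass count.
naive_masses <- function(mask, centers, radii) {
  out <- matrix(0L, nrow(centers), length(radii))
  for (i in seq_len(nrow(centers))) {
    for (r in seq_len(nrow(mask))) {
      for (c in seq_len(ncol(mask))) {
        if (mask[r, c]) {
          d <- sqrt((r - centers[i, 1])^2 + (c - centers[i, 2])^2)
          out[i, ] <- out[i, ] + as.integer(d <= radii)
        }
      }
    }
  }
  out
}

# Direct (non-separable) 2D Gaussian convolution with edge replication:
# shift-and-add over explicit kernel offsets.
brute_blur <- function(img, radius_px) {
  sigma <- radius_px / 3
  h <- ceiling(3 * sigma)
  k1 <- exp(-((-h:h)^2) / (2 * sigma^2))
  k2 <- outer(k1, k1)
  k2 <- k2 / sum(k2)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  rows <- seq_len(H); cols <- seq_len(W)
  for (dr in -h:h) {
    rr <- pmin(pmax(rows + dr, 1L), H)
    for (dc in -h:h) {
      cc <- pmin(pmax(cols + dc, 1L), W)
      out <- out + k2[dr + h + 1L, dc + h + 1L] * img[rr, cc]
    }
  }
  out
}
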