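# Fixtures built in code: hard-disk images with known geometry and small
# synthetic ROIs.

# marker image with disks of uniform extra amplitude over a flat base
disk_fixture <- function(n = 64, centers, radius, amplitude = 100, base = 0,
                         pixel_size = 0.1) {
  m <- matrix(base, n, n)
  xg <- (row(m) - 0.5) * pixel_size
  yg <- (col(m) - 0.5) * pixel_size
  for (k in seq_len(nrow(centers))) {
    inside <- (xg - centers[k, 1])^2 + (yg - centers[k, 2])^2 <= radius^2
    m[inside] <- m[inside] + amplitude
  }
  channel_image(m, pixel_size, "G3BP1")
}

# two touching disks with centres sep_factor * r apart (in um)
two_disk_fixture <- function(r_px = 6, sep_factor = 1.2, n = 64,
                             pixel_size = 0.1) {
  r <- r_px * pixel_size
  cx <- n * pixel_size / 2
  d <- sep_factor * r
  disk_fixture(n, rbind(c(cx - d / 2, cx), c(cx + d / 2, cx)),
               radius = r, amplitude = 100, base = 0,
               pixel_size = pixel_size)
}

# small, fast synthetic ROI
small_sim <- function(seed, pct = 15, hours = 2, width = 256, ...) {
  generate_roi(sg_preset(pct, hours), seed = seed, width = width, ...)
}

# brute-force pixel loop: per-label sums/counts without vectorised helpers
pixel_loop_sums <- function(pixels, labels) {
  n <- max(labels)
  sums <- numeric(n); counts <- numeric(n)
  for (i in seq_len(nrow(pixels))) {
    for (j in seq_len(ncol(pixels))) {
      l <- labels[i, j]
      if (l > 0) {
        sums[l] <- sums[l] + pixels[i, j]
        counts[l] <- counts[l] + 1
      }
    }
  }
  list(sums = sums, counts = counts)
}
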