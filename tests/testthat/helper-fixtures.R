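# Small in-code fixtures shared across test files.

# A three-compartment slice with hand-placed HU values: muscle 40 HU,
# fat -80 HU, bone 400 HU, air elsewhere.
make_block_slice <- function(spacing = 1) {
  hu <- matrix(-1000, 20, 20)
  hu[3:8, 3:8] <- 40      # 36 muscle px
  hu[12:15, 3:6] <- -80   # 16 fat px
  hu[12:14, 12:14] <- 400 # 9 bone px
  ct_slice(hu, spacing)
}

# Brute-force windowing oracle: per-pixel closed-interval test.
window_oracle <- function(slice, lo, hi) {
  m <- slice$hu >= lo & slice$hu <= hi
  if (!is.null(slice$roi)) m <- m & slice$roi
  m
}

# Brute-force sphere-mean oracle: loop over all voxels, centre-in-sphere.
voi_oracle <- function(volume, center, radius) {
  dims <- dim(volume$data)
  tot <- 0; n <- 0
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      p <- volume$origin + (c(i, j, k) - 1) * volume$spacing
      if (sum((p - center)^2) <= radius^2) {
        tot <- tot + volume$data[i, j, k]
        n <- n + 1
      }
    }
  list(mean = tot / n, n = n)
}
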