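# small geometric fixtures built in code

# logical mask of given dims with a filled ball (physical-mm radius) at ctr
ball_mask <- function(dims, spacing, ctr_mm, radius_mm) {
  cx <- (seq_len(dims[1]) - 0.5) * spacing[1] - ctr_mm[1]
  cy <- (seq_len(dims[2]) - 0.5) * spacing[2] - ctr_mm[2]
  cz <- (seq_len(dims[3]) - 0.5) * spacing[3] - ctr_mm[3]
  q <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  q <= radius_mm^2
}

# brute-force peritumoral ring: per-voxel scan of distances to every GTV voxel
ring_bruteforce <- function(gtv, spacing, thickness) {
  d <- dim(gtv)
  cc <- which(gtv, arr.ind = TRUE)
  ctr <- sweep(cc, 2, spacing, `*`)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (gtv[i, j, k]) next
    p <- c(i, j, k) * spacing
    dmin <- sqrt(min((ctr[, 1] - p[1])^2 + (ctr[, 2] - p[2])^2 +
                       (ctr[, 3] - p[3])^2))
    if (dmin <= thickness + 1e-9) out[i, j, k] <- TRUE
  }
  out
}

# tiny phantom spec for fast tests
small_phantom <- function(...) {
  phantom_spec(grid_shape = c(24L, 24L, 8L), spacing_mm = c(2, 2, 3),
               prostate_radius_mm = c(16, 14, 10), gtv_radius_mm = 5, ...)
}
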