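# Shared fixtures, built in code at test time.

rand_image <- function(nr, nc = nr, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc)
}

# disk of radius r pixels and value v, centred in an n x n grid; the edge is
# anti-aliased by 4x supersampling so the object is close to rotationally
# symmetric (a hard-rasterized disk is not)
disk_image <- function(n, r, v = 1, ss = 4) {
  ctr <- (n + 1) / 2
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  px <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sub <- outer((i + off - ctr)^2, (j + off - ctr)^2, `+`) <= r^2
      px[i, j] <- v * mean(sub)
    }
  }
  ct_image(px)
}

# Brute-force periodic 2D convolution with a separable 3-tap kernel
# (explicit index arithmetic; independent of the shift-based implementation):
# out[r, c] = sum_{a,b in -1:1} krow[a] kcol[b] x[(r - a) mod nr, (c - b) mod nc]
brute_conv2 <- function(x, krow, kcol) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      acc <- 0
      for (a in -1:1) {
        for (b in -1:1) {
          rr <- ((r - a - 1) %% nr) + 1
          cc <- ((c - b - 1) %% nc) + 1
          acc <- acc + krow[a + 2] * kcol[b + 2] * x[rr, cc]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# small geometry covering an n x n image
tiny_geometry <- function(range_deg, n_angles, n) {
  limited_angle_geometry(range_deg, n_angles, default_n_detectors(n))
}

# radially smooth "disk" (super-Gaussian profile): genuinely close to
# rotationally symmetric after rasterization, unlike a hard-edged disk
smooth_disk <- function(n, r, v = 1, p = 8) {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`))
  ct_image(v * exp(-(d / r)^p))
}
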