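# Small two-bone phantom used by the unit tests: fast to rasterise, with the
# same intensity regime as the full tarsal phantom. Bones start at a known
# slice so landmark detection can be checked against construction.
tiny_spec <- function(noise_sd = 0, rotation = NULL) {
  phantom_spec(
    grid_shape = c(80L, 80L, 100L),
    spacing = 0.018,
    bones = list(
      # both bodies on the same in-plane centre so the principal axis of the
      # stack is exactly +z (offsets correlated with z would tilt it)
      ellipsoid(c(0.72, 0.72, 0.60), c(0.12, 0.11, 0.09), 6700),
      ellipsoid(c(0.72, 0.72, 0.95), c(0.12, 0.11, 0.09), 6700)
    ),
    soft_envelope = ellipsoid(c(0.72, 0.72, 0.80), c(0.48, 0.45, 0.62), 300),
    air_intensity = -900,
    noise_sd = noise_sd,
    rotation = rotation
  )
}

# VOI length that fits the tiny phantom's bone stack
tiny_n_slices <- 30L

# Brute-force oracles (independent of the package's vectorised code paths)

brute_mask_volume <- function(mask, spacing) {
  d <- dim(mask)
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k]) n <- n + 1L
  }
  n * prod(spacing)
}

brute_sphere_count <- function(dims, spacing, center, radius) {
  n <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    p <- (c(i, j, k) - 0.5) * spacing
    if (sum(((p - center) / radius)^2) <= 1) n <- n + 1L
  }
  n
}

# Midrank Kruskal-Wallis H, written directly from the definition
kw_h_oracle <- function(values, groups) {
  N <- length(values)
  r <- rank(values) # midranks
  rbar <- tapply(r, groups, mean)
  ns <- table(groups)
  h <- 12 / (N * (N + 1)) * sum(ns * (rbar - (N + 1) / 2)^2)
  ties <- table(values)
  c_tie <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / c_tie
}

# Exhaustive permutation distribution of H for a small 3-group instance
kw_perm_distribution <- function(values, sizes) {
  N <- length(values)
  idx <- seq_len(N)
  out <- c()
  combs1 <- utils::combn(idx, sizes[1])
  for (a in seq_len(ncol(combs1))) {
    g1 <- combs1[, a]
    rest <- setdiff(idx, g1)
    combs2 <- utils::combn(rest, sizes[2])
    for (b in seq_len(ncol(combs2))) {
      g2 <- combs2[, b]
      g3 <- setdiff(rest, g2)
      lab <- integer(N)
      lab[g1] <- 1L; lab[g2] <- 2L; lab[g3] <- 3L
      out <- c(out, kw_h_oracle(values, lab))
    }
  }
  out
}
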