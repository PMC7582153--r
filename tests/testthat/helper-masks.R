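# Geometric fixtures built in code: digitized spheres/ellipsoids on physical
# grids, and label maps with prescribed class fractions.

coord_arrays <- function(d, spacing = c(1, 1, 1)) {
  g <- function(i) (seq_len(d[i]) - 0.5) * spacing[i]
  list(
    X = array(rep(g(1), times = d[2] * d[3]), d),
    Y = array(rep(rep(g(2), each = d[1]), times = d[3]), d),
    Z = array(rep(g(3), each = d[1] * d[2]), d))
}

sphere_mask <- function(d, center, radius, spacing = c(1, 1, 1)) {
  co <- coord_arrays(d, spacing)
  binary_mask((co$X - center[1])^2 + (co$Y - center[2])^2 +
                (co$Z - center[3])^2 <= radius^2, spacing = spacing)
}

ellipsoid_mask <- function(d, center, semi_axes, spacing = c(1, 1, 1)) {
  co <- coord_arrays(d, spacing)
  binary_mask(((co$X - center[1]) / semi_axes[1])^2 +
                ((co$Y - center[2]) / semi_axes[2])^2 +
                ((co$Z - center[3]) / semi_axes[3])^2 <= 1, spacing = spacing)
}

# A density label map over a cuboid tumor whose first n_low/n_mid/n_high
# voxels carry HU representative of each class; remainder background-level.
label_map_with_counts <- function(n_total, n_low, n_mid, n_high,
                                  thr = default_thresholds()) {
  stopifnot(n_low + n_mid + n_high <= n_total)
  d <- c(n_total, 1, 1)
  hu <- rep(50, n_total)
  i <- 1
  for (cl in list(c(n_low, 120), c(n_mid, 200), c(n_high, 300))) {
    if (cl[1] > 0) hu[i:(i + cl[1] - 1)] <- cl[2]
    i <- i + cl[1]
  }
  ct <- image_volume(array(hu, d))
  tumor <- binary_mask(array(TRUE, d))
  classify_density(ct, tumor, thr)
}

# Independent brute-force oracles for the bilevel operators: naive double
# loop, recomputing class statistics from scratch with mean().
oracle_variance <- function(v) {
  cands <- seq.int(floor(min(v)), ceiling(max(v)) - 1)
  best_t <- NA
  best <- -Inf
  for (t in cands) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    obj <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (obj > best + 1e-12) { best <- obj; best_t <- t }
  }
  best_t
}

oracle_cross_entropy <- function(v) {
  cands <- seq.int(floor(min(v)), ceiling(max(v)) - 1)
  best_t <- NA
  best <- Inf
  for (t in cands) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    obj <- -(sum(lo) * log(mean(lo)) + sum(hi) * log(mean(hi)))
    if (obj < best - 1e-12) { best <- obj; best_t <- t }
  }
  best_t
}

# assorted random histograms: mixtures, uniforms, skewed
random_histogram <- function(seed) {
  set.seed(seed)
  kind <- seed %% 3
  if (kind == 0) {
    c(rnorm(300, runif(1, 90, 150), runif(1, 5, 25)),
      rnorm(300, runif(1, 200, 320), runif(1, 5, 30)))
  } else if (kind == 1) {
    runif(400, 80, 350)
  } else {
    100 + rexp(500, 1 / runif(1, 20, 80))
  }
}
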