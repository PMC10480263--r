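# Shared fixtures, all generated in code. Sizes are desk-scale so the
# whole suite stays CPU-friendly.

fix_spec32 <- phantom_spec(image_size = 32)
fix_img32 <- make_thorax_phantom(fix_spec32)
fix_spec128 <- phantom_spec(image_size = 128)
fix_img128 <- make_thorax_phantom(fix_spec128)
fix_params32 <- desk_sim_params(32)
fix_params128 <- desk_sim_params(128)

# The clinical-scale generator layer listing, frozen as data: image
# input; 8 encoder stages (batch normalisation from stage 2); 8 decoder
# stages (dropout in the first four, each stage ending in a depth
# concatenation); terminal convolution. 61 entries.
table1_sequence <- c(
  "Image Input Layer",
  "Convolution 2D Layer", "Leaky ReLU Layer",
  rep(c("Convolution 2D Layer", "Batch Normalization Layer",
        "Leaky ReLU Layer"), 7),
  rep(c("Transposed Convolution 2D Layer", "Batch Normalization Layer",
        "Dropout Layer", "Leaky ReLU Layer",
        "Depth Concatenation Layer"), 4),
  rep(c("Transposed Convolution 2D Layer", "Batch Normalization Layer",
        "Leaky ReLU Layer", "Depth Concatenation Layer"), 4),
  "Convolution 2D Layer"
)

# analytic ellipse mask, independent of the package internals
oracle_ellipse_mask <- function(s, centre, axes) {
  r <- matrix(seq_len(s), s, s)
  c <- matrix(seq_len(s), s, s, byrow = TRUE)
  ((r - centre[1]) / axes[1])^2 + ((c - centre[2]) / axes[2])^2 <= 1
}

# brute-force windowed SSIM: explicit loop over all fully valid windows,
# Gaussian weights computed from first principles
oracle_ssim <- function(a, b, window = 5, sigma = 1.5,
                        K1 = 0.01, K2 = 0.03, L = 4095) {
  half <- (window - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  vals <- c()
  for (i in seq_len(nrow(a) - window + 1)) {
    for (j in seq_len(ncol(a) - window + 1)) {
      pa <- a[i:(i + window - 1), j:(j + window - 1)]
      pb <- b[i:(i + window - 1), j:(j + window - 1)]
      mu_a <- sum(w * pa); mu_b <- sum(w * pb)
      va <- sum(w * pa^2) - mu_a^2
      vb <- sum(w * pb^2) - mu_b^2
      cab <- sum(w * pa * pb) - mu_a * mu_b
      vals <- c(vals, (2 * mu_a * mu_b + C1) * (2 * cab + C2) /
                  ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2)))
    }
  }
  mean(vals)
}

# simulated training pairs (input -> full ground truth) for one volume
sim_full_pairs <- function(vol, params, seed) {
  sim <- simulate_scbct_volume(vol, params, seed = seed)
  lapply(seq_along(sim$pairs), function(i) {
    p <- sim$pairs[[i]]
    structure(list(input_img = p$scbct, target_img = p$full_gt,
                   patient_id = vol$patient_id, slice_index = i,
                   stage_tag = "fixture"),
              class = "paired_sample")
  })
}

# ground truth used for end-to-end evaluation: couch-removed CT
couchless <- function(vol) {
  ct_volume(lapply(vol$slices, function(s)
    remove_couch(s, detect_couch_surface(s))),
    vol$slice_thickness, vol$patient_id)
}
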