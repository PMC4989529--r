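# Shared fixtures, all generated in code.

# The default object/background spectrum pair of phantom_spec(): moderate
# object reflectance with three peaks, complementary bright background.
default_object_model <- function()
  spectrum_model(0.26, centers = c(0.52, 0.68, 0.86),
                 widths = rep(0.04, 3), amplitudes = c(0.09, 0.11, 0.08))

# Noiseless, artifact-free phantom whose object is a full-width stripe:
# straight edges (no exposed corners), so 3D median filtering and plane
# median smoothing leave the noiseless segmentation pixel-exact.
stripe_phantom <- function(rows = 48L, cols = 48L, bands = 16L) {
  render_phantom(phantom_spec(
    rows = rows, cols = cols, bands = bands,
    objects = list(list(shape = shape_rectangle(17L, 32L, 1L, cols),
                        spectrum = default_object_model())),
    noise_sigma_mid = 0, noise_edge_gain = 1, artifact_count = 0L))
}

# Noiseless two-object phantom of full-width stripes aligned to 4x4 blocks
# (for the hierarchical method at factor 4): object 1 carries the reference
# spectrum, object 2 a flat brighter curve.  Full-width stripes expose no
# convex corners, so every stage of the hierarchical chain is exact in the
# noiseless limit.
two_object_phantom <- function() {
  obj2 <- spectrum_model(0.55, centers = 0.75, widths = 0.06, amplitudes = 0.05)
  render_phantom(phantom_spec(
    rows = 48L, cols = 48L, bands = 16L,
    objects = list(
      list(shape = shape_rectangle(9L, 24L, 1L, 48L),
           spectrum = default_object_model()),
      list(shape = shape_rectangle(33L, 44L, 1L, 48L), spectrum = obj2)),
    noise_sigma_mid = 0, noise_edge_gain = 1, artifact_count = 0L))
}

# Moderate-noise phantom at test scale (SKE and S3D are scale-free).
small_noisy_phantom <- function(seed = 7L)
  render_phantom(phantom_spec(rows = 48L, cols = 48L, bands = 16L, seed = seed))

# The default-geometry phantom: the hierarchical method's 17x17 structuring
# element suits this frame size.
default_noisy_phantom <- function(seed = 1L)
  render_phantom(phantom_spec(seed = seed))

# Default geometry with strongly band-edge-amplified noise.
edge_noise_phantom <- function(seed = 11L)
  render_phantom(phantom_spec(noise_sigma_mid = 0.01, noise_edge_gain = 6,
                              seed = seed))

calibrated_of <- function(ph) calibrate(median3d(ph$raw), ph$dark, ph$white)

rand_cube_array <- function(d) array(runif(prod(d)), d)

# Gaussian blobs in (absolute-valued) mismatch-feature space, with the
# generating assignment for label-agreement scoring.
blob_features <- function(centers, n_per = 60, sd = 0.01, seed = 99) {
  set.seed(seed)
  f <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    matrix(rnorm(n_per * ncol(centers), mean = rep(centers[k, ], each = n_per),
                 sd = sd), n_per)))
  list(features = abs(f), truth = rep(seq_len(nrow(centers)), each = n_per))
}

# Best label agreement over all permutations of 2 or 3 class labels.
match_rate <- function(labels, truth) {
  K <- max(truth)
  perms <- if (K == 2) list(1:2, 2:1) else
    list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- 0
  for (p in perms) best <- max(best, mean(p[labels] == truth))
  best
}

acc_of <- function(pred, truth) unname(seg_scores(confusion(pred, truth))["ACC"])
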