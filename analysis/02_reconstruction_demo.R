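#!/usr/bin/env Rscript
# Tomographic reconstruction demonstration: forward-project a seed phantom
# with flat/dark frames and counting noise, correct, reconstruct with FBP,
# and segment the reconstructed volume. Writes summary numbers to
# results/reconstruction_summary.csv.

suppressPackageStartupMessages(library(charvoid))

dir.create("results", showWarnings = FALSE)
spec <- phantom_spec(40, 20, semi_axes = c(0.29, 0.25, 0.23),
                     voxel_size = 10,
                     rate_override = list(lambda_small = 0,
                                          lambda_medium = 0,
                                          lambda_large = 8),
                     hole_radius_um = list(Large = c(30, 60)),
                     rng_seed = 20260919L)
ph <- generate_seed_phantom(spec)
cat("Phantom grid:", paste(dim(ph$volume), collapse = " x "), "voxels;",
    sum(ph$ground_truth$holes$class == "hole"), "ground-truth holes\n")

angles <- seq(0, pi, length.out = 91)[1:90]
sino <- simulate_projections(ph$volume, angles, flux = 2e4,
                             rng_seed = 20260920L)
rec <- fbp_reconstruct(correct_projections(sino),
                       out_shape = dim(ph$volume)[2:3])
r <- cor(as.vector(rec), as.vector(ph$volume))
cat("Voxelwise correlation of FBP volume with ground truth:",
    round(r, 4), "\n")

mask <- segment_seed(rec, voxel_size = spec$voxel_size)
comp <- classify_components(extract_void_components(mask))
n_found <- sum(comp$klass == "hole")
cat("Holes recovered from the reconstructed (noisy) volume:", n_found,
    "of", sum(ph$ground_truth$holes$class == "hole"), "\n")

write.csv(data.frame(
  n_angles = length(angles), flux = 2e4,
  roundtrip_correlation = r,
  gt_holes = sum(ph$ground_truth$holes$class == "hole"),
  holes_recovered_from_recon = n_found
), "results/reconstruction_summary.csv", row.names = FALSE)
cat("Wrote results/reconstruction_summary.csv\n")
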