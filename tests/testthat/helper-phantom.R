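# Shared fixture builders: everything is generated in code at test time.

tiny_spec <- function(..., image_size = 64, noise_sd = 0, seed = 42) {
  phantom_spec(..., image_size = image_size, noise_sd = noise_sd, seed = seed)
}

tiny_case <- function(extremity = "hand", affected_side = "left", f = 1,
                      enhanced = NULL, noise_sd = 0, image_size = 64,
                      seed = 42, jitter = TRUE) {
  generate_phantom(phantom_spec(
    extremity, affected_side, image_size = image_size,
    enhancement_factor = f, enhanced_regions = enhanced,
    noise_sd = noise_sd, seed = seed, jitter = jitter))
}

# Random label matrix for mask-level tests.
random_mask <- function(nr = 32, nc = 32, n_class = 3, seed = 1) {
  set.seed(seed)
  matrix(sample(0:n_class, nr * nc, replace = TRUE), nr, nc)
}
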