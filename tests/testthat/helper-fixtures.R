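# shared small fixtures, built in code

tiny_phantom <- function(n_cases = 2, slices = 6, size = 32, seed = 7,
                         drift = 0.5, ...) {
  generate_phantom(phantom_config(n_cases = n_cases, slices_per_case = slices,
                                  height = size, width = size,
                                  inter_slice_drift = drift,
                                  rng_seed = seed, ...))
}

rect_mask <- function(H, W, r1, c1, r2, c2) {
  m <- matrix(0, H, W); m[r1:r2, c1:c2] <- 1; m
}

random_mask <- function(H, W, p = 0.3) matrix(rbinom(H * W, 1, p), H, W)
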