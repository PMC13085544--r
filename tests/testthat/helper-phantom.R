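# Shared fixtures: all phantoms are generated in code at test time.

# noise- and jitter-free phantom parameters
clean_params <- function(n_slices = 6, ...) {
  phantom_params(n_slices = n_slices, crack_probability = 0,
                 debris_density = 0, jitter_rotation_sd = 0,
                 jitter_translation_sd = 0, ...)
}

# a small random grayscale raster in [0, 1]
rand_img <- function(h = 20, w = 20) matrix(runif(h * w), h, w)

# a random mask guaranteed nonempty
rand_mask <- function(h = 20, w = 20, p = 0.5) {
  m <- matrix(runif(h * w) < p, h, w)
  if (!any(m)) m[1, 1] <- TRUE
  m
}
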