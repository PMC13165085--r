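# Small designs/scenarios shared across tests. Band counts are reduced where
# the property under test does not depend on spectral resolution.

tiny_design <- function(seed = 1L, n_plants = 2, n_stress = 1, days = 1:3,
                        px = 4) {
  trial_design(n_plants = n_plants, n_stress = n_stress, days = days,
               pixels_per_plant_day = px, seed = seed)
}

coarse_scenario <- function(n_bands = 60, ...) {
  spectral_scenario(wavelengths = seq(400, 1000, length.out = n_bands), ...)
}

# a deterministic little cube: values = row + 10*col + 100*band
index_cube <- function(nr = 4, nc = 5, nb = 6) {
  arr <- array(0, dim = c(nr, nc, nb))
  for (b in seq_len(nb)) arr[, , b] <- outer(seq_len(nr), 10 * seq_len(nc), `+`) + 100 * b
  hyper_cube(arr, seq(400, 1000, length.out = nb))
}
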