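# Small phantoms and idealised tissue sets shared across test files.
# Grids are kept small so the whole suite stays fast; the acceptance tests
# use the full default geometry.

small_spec <- function(fraction = 0.3, seed = 1L, noise_sd = 0,
                       composition = list(type = "blobs", fraction = fraction,
                                          scale_mm = 6)) {
  phantom_spec(grid_shape = c(48L, 36L, 32L),
               voxel_spacing_mm = c(1.3, 1.3, 1.0),
               breast_semi_axes_mm = c(13, 24, 13),
               breast_offset_mm = 14,
               chest_wall_plane_index = 27L,
               chest_wall_thickness_mm = 8,
               composition = composition,
               noise_sd = noise_sd,
               rng_seed = seed)
}

small_phantom <- function(...) generate_phantom(small_spec(...))

# single-peak fat, idealised for exact separation arithmetic
tissues_single <- function(...) {
  tissue_properties(fat_spectrum = fat_spectrum_single_peak(), ...)
}

tissues_multi <- function(...) tissue_properties(...)

# a raw echo pair without sequence metadata (no decay compensation applied)
raw_echo_pair <- function(ip, op, spacing = c(1, 1, 1)) {
  list(in_phase = volume_image(ip, spacing),
       out_of_phase = volume_image(op, spacing))
}

const_volume <- function(value, dim = c(6, 6, 6), spacing = c(1, 1, 1)) {
  volume_image(array(value, dim = dim), spacing)
}
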