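# desk-scale protocol: preset echo train / TR on a reduced grid so each vial
# still spans > 8 voxels and the 1.4 cm ROI fits inside the 2.4 cm vials
small_params <- function(preset = "3T") {
  p <- protocol_preset(preset)
  p$matrix <- c(48L, 48L)
  p$fov_cm <- c(14.4, 14.4)
  p
}

small_phantom <- function(params, ...) {
  make_pdff_t1_phantom(matrix = params$matrix, fov_cm = params$fov_cm,
                       vial_radius_cm = 1.2, ...)
}

phantom_spectrum <- function() default_fat_spectrum(phantom = TRUE)

# one-vial phantom on a tiny grid for brute-force oracles
tiny_phantom <- function(pdff = 0.2, t1w = 800, ...) {
  make_pdff_t1_phantom(matrix = c(24L, 24L), fov_cm = c(7.2, 7.2),
                       pdff_values = pdff, t1w_values_ms = t1w,
                       vial_radius_cm = 1.2, ...)
}

# single-voxel echo series (for per-voxel fitting and Monte-Carlo tests)
voxel_series <- function(voxel, spectrum, params) {
  s <- cse_signal(voxel, spectrum, echo_times_ms(params), params$b0_t)
  echo_series(lapply(s, function(v) matrix(v, 1, 1)),
              echo_times_ms(params), params, mode = "steady_state")
}
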