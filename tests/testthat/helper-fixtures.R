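# Small shared fixtures. Everything is generated in code; no stored data.

# short protocol: 20 bursts, injection after burst 10, flush at burst 12
quick_protocol <- function() {
  sonication_protocol(duration = 10, prf = 2, injection_time = 5,
                      flush_time = 6)
}

# single near-axis source with all three emission bands
quick_truth <- function(x = 0, z = 29.2, amps = c(1, 1, 0.5),
                        onset = 1L) {
  synthetic_truth(source_positions = matrix(c(x, 0, z), 1, 3),
                  source_band_amplitudes = matrix(amps, 1, 3),
                  onset_burst_index = onset)
}

# two-burst array RF for beamforming tests (burst 2 carries the emission)
quick_rf <- function(truth, geometry = array_geometry(), noise_sigma = 0,
                     seed = 3, n_samples = 1500) {
  p <- sonication_protocol(duration = 2, prf = 1, injection_time = 0,
                           flush_time = 0)
  gen_array_rf(geometry, truth, p, noise_sigma = noise_sigma, seed = seed,
               n_samples = n_samples)
}

# standard opening phantom on a 64 mm cube, 1 mm voxels
quick_mri <- function(volume_mm3 = 983, contrast = 70, noise_sigma = 10,
                      seed = 11, shape = c(64, 64, 64)) {
  traj <- trajectory(c(32, 32, 32), c(0, 0, 1))
  tr <- synthetic_truth(opening_volume_mm3 = volume_mm3,
                        opening_centroid = c(32, 32, 32))
  c(gen_mri_pair(shape = shape, trajectory = traj, truth = tr,
                 contrast = contrast, noise_sigma = noise_sigma, seed = seed),
    list(trajectory = traj))
}
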