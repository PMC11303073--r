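#!/usr/bin/env Rscript
# Generate the synthetic trial inputs for one subject: PCD burst recordings,
# 64-channel array RF, paired post-contrast T1 volumes, and a baseline /
# follow-up PET pair. Writes the acoustic containers, NIfTI volumes, and a
# JSON truth sidecar under results/synthetic/.

library(fusbbbo)

seed <- 1L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- default_config(seed = seed)
protocol <- do.call(sonication_protocol, cfg$protocol)
truth <- synthetic_truth(
  source_positions = rbind(cfg$truth$source_position),
  source_band_amplitudes = rbind(cfg$truth$band_amplitudes),
  onset_burst_index = cfg$truth$onset_burst_index,
  opening_volume_mm3 = cfg$truth$opening_volume_mm3,
  opening_centroid = cfg$truth$opening_centroid,
  asymmetry_factor = cfg$truth$asymmetry_factor)
traj <- trajectory(cfg$trajectory$focus_point, cfg$trajectory$direction)

message("PCD: ", protocol$n_bursts, " bursts at ", cfg$pcd$fs / 1e6, " MHz")
pcd <- gen_pcd_timeseries(protocol, truth, noise_sigma = cfg$pcd$noise_sigma,
                          seed = seed, fs = cfg$pcd$fs)
write_rf(pcd, file.path(out, "pcd"))

message("array RF: 64 channels x ", cfg$rf$n_samples, " samples per burst")
rf <- gen_array_rf(array_geometry(), truth, protocol,
                   noise_sigma = cfg$rf$noise_sigma, seed = seed + 3L,
                   n_samples = cfg$rf$n_samples)
write_rf(rf, file.path(out, "rf"))

message("MRI pair: ", paste(cfg$mri$shape, collapse = "x"), " voxels, CNR ",
        round(cfg$mri$contrast / (sqrt(2) * cfg$mri$noise_sigma), 1))
mri <- gen_mri_pair(cfg$mri$shape, cfg$mri$spacing, traj, truth,
                    contrast = cfg$mri$contrast,
                    noise_sigma = cfg$mri$noise_sigma,
                    background = cfg$mri$background,
                    axial_ratio = cfg$mri$axial_ratio, seed = seed + 1L)
write_volume(mri$day0, file.path(out, "t1_day0.nii.gz"))
write_volume(mri$day3, file.path(out, "t1_day3.nii.gz"))
write_volume(voxel_volume(mri$truth_mask + 0, mri$day0$affine),
             file.path(out, "truth_mask.nii.gz"))

message("PET pair: asymmetry factor ", truth$asymmetry_factor)
pet <- gen_pet_pair(cfg$pet$shape, cfg$pet$spacing,
                    asymmetry_factor = truth$asymmetry_factor,
                    reference_mean = cfg$pet$reference_mean,
                    region_suvr = cfg$pet$region_suvr,
                    noise_sigma = cfg$pet$noise_sigma, seed = seed + 2L)
write_volume(pet$baseline, file.path(out, "pet_baseline.nii.gz"))
write_volume(pet$followup, file.path(out, "pet_followup.nii.gz"))
for (nm in names(pet$masks))
  write_volume(voxel_volume(pet$masks[[nm]] + 0, pet$baseline$affine),
               file.path(out, paste0("mask_", nm, ".nii.gz")))

sidecar <- c(unclass(truth), list(seed = seed, config_hash = config_hash(cfg)))
jsonlite::write_json(sidecar, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("inputs written to ", out)
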