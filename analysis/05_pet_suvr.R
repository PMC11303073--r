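#!/usr/bin/env Rscript
# Amyloid-PET analysis: regional SUVR against the reference region,
# asymmetry SUVR against the mirrored contralateral region, percent changes
# from baseline to follow-up, and the Centiloid conversion.

library(fusbbbo)

cfg <- default_config(seed = 1L)
baseline <- read_volume("results/synthetic/pet_baseline.nii.gz")
followup <- read_volume("results/synthetic/pet_followup.nii.gz")
masks <- lapply(c(treated = "treated", contralateral = "contralateral",
                  reference = "reference"), function(nm)
  read_volume(file.path("results/synthetic",
                        paste0("mask_", nm, ".nii.gz")))$data > 0.5)

rep <- suvr_report(baseline, followup, masks$treated, masks$reference,
                   masks$contralateral, centiloid_cal = cfg$pet$centiloid)
message(sprintf("SUVR %.3f -> %.3f; asymmetry %.4f -> %.4f (%.2f%%)",
                rep$suvr_baseline, rep$suvr_followup, rep$asym_baseline,
                rep$asym_followup, rep$pct_change_asym))
message(sprintf("follow-up Centiloid: %.1f CL", rep$centiloid))

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(unclass(rep), "results/suvr_report.json",
                     auto_unbox = TRUE, digits = NA)
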