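#!/usr/bin/env Rscript
# Tilt-table arm: compound HEP in the 2 min before a spontaneous symptom
# report versus baseline (> 2 min before every report of that category),
# per-subject values from the 20x within-subject epoch bootstrap, paired
# t-tests at alpha 0.05/6.  Synthetic truth: functional syncope +2 uV/lead
# before bodily symptoms, vasovagal syncope -2 uV/lead, psychological
# reports carry no shift in either group.
#
# Outputs under results/tilt_arm/: subject_hep.csv, test_results.csv

library(hepline)

out_dir <- file.path("results", "tilt_arm")
seed <- 2026

cfg <- synth_cohort_config(n_subjects_per_cell = 19, cells = tilt_cells(),
                           seed = seed)
message("Running the tilt-table arm on ", 19 * 2, " synthetic subjects...")
rep <- run_cohort_study(cfg, prep = preprocess_config(), seed = seed,
                        out_dir = out_dir)
print(rep)

hep <- rep$subject_hep
hep$group <- sub("_(mot|non|[0-9]).*$", "", hep$subject_id)
agg <- aggregate(cbind(change_uv = hep_pre_uv - hep_base_uv,
                       n_epochs_pre = n_epochs_pre) ~
                   group + symptom_category, hep, mean)
message("\nMean pre-symptom minus baseline compound HEP (µV):")
print(agg, digits = 3)
write.csv(agg, file.path(out_dir, "category_changes.csv"), row.names = FALSE)
message("\nNote the attenuation of the recovered shift relative to the ",
        "injected 2x(+/-2) uV: at tilt-table heart rates the periodic ",
        "heartbeat-locked response overlaps the next beat's baseline ",
        "window, which absorbs part of the shift (see the methods vignette).")
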