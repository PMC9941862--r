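#!/usr/bin/env Rscript

# Step 4 — the group parameter-recovery study.
#
# Simulates and fits 8 synthetic subjects (GE and SE sessions each, two
# subjects on the alternative +3/+8 mmHg protocol) at temporal SNR 50,
# aggregates the selected-voxel maps into laminar depth profiles, forms
# GE/SE ratios, and scores recovery against the generating ground truth.
# This reproduces, on synthetic data, the study's qualitative pattern:
# CVR rises steeply toward the superficial bin for the all-venous (GE)
# contrast and only mildly for the micro-vascular (SE) contrast, the GE/SE
# CVR ratio grows with depth, the M-value rises toward the surface for
# both, and the relative venous CBV change is depth-constant.
#
# Tables written: results/group_profiles.tsv, results/group_ratios.tsv,
# results/group_recovery.tsv.

suppressPackageStartupMessages(library(laminarbold))

study <- recovery_study(n_subjects = 8, grid = c(24, 24, 22), tsnr = 50,
                        alt_subjects = c(7, 8), seed = 1L)

dir.create("results", showWarnings = FALSE)
prof <- do.call(rbind, lapply(names(study$profiles), function(sq) {
  p <- study$profiles[[sq]]
  p$sequence <- sq
  p
}))
write.table(prof, file.path("results", "group_profiles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(study$ratios, file.path("results", "group_ratios.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(study$recovery, file.path("results", "group_recovery.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

print(study)
cvr <- study$ratios[study$ratios$metric == "cvr", ]
cat(sprintf("\nGE/SE CVR ratio deep -> superficial: %.2f -> %.2f\n",
            cvr$ratio[cvr$bin == 1], cvr$ratio[cvr$bin == 3]))
cat(sprintf("max |group recovery error| = %.1f%%\n",
            100 * max(study$recovery$rel_error)))
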