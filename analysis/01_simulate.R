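#!/usr/bin/env Rscript

# Step 1 — generate the synthetic input bundle.
#
# Writes a small two-subject demonstration dataset (GE and SE sessions,
# default +5/+10 mmHg protocol with terminal hyperoxia) to scratch/demo:
# 4D NIfTI functional series, label volumes, gas/respiration/pulse/motion
# traces as TSV with JSON sidecars, and the ground-truth record each
# session was generated from. Everything is driven by one master seed, so
# rerunning this script reproduces the bundle byte for byte.

suppressPackageStartupMessages(library(laminarbold))

cfg <- default_config(out_dir = file.path("scratch", "demo"),
                      n_subjects = 2L, grid = c(14L, 14L, 22L), seed = 1L)
run_simulate(cfg)

cat("Simulated", cfg$n_subjects, "subjects x {GE, SE} at grid",
    paste(cfg$grid, collapse = "x"), "under", cfg$out_dir, "\n")
cat("Each series:", make_protocol()$n_volumes, "volumes,",
    make_protocol()$total_s, "s\n")
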