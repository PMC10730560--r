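#!/usr/bin/env Rscript
# Step 1 — simulate one experimental round of the vocal-fold replica bench.
#
# The synthetic bench reproduces the acquisition conditions of the real rig:
# a stepped airflow protocol (quasi-steady plateaus between ~0.3 and
# 3.5 L/s), subglottal pressure following the linear law Ps = Rd*phi + P0
# with an oscillation ripple at f0, and a calibrated microphone signal with
# prescribed f0 / SPL / HNR. Everything is written with its ground truth so
# the later reduction stages can be audited.

suppressMessages(library(phonobench))
dir.create("results", showWarnings = FALSE)

cfg <- bench_config(seed = 1L, audio_rate = 22050,
                    flow_steps = seq(0.4, 3.4, length.out = 10),
                    step_duration = 4)
print(cfg)

dir <- file.path("results", "bench_data")
write_bench_data(cfg, dir, n_frames = 25)
cat("wrote", dir, ":", paste(list.files(dir), collapse = ", "), "\n")

truth <- gen_flow_pressure(cfg)$truth
cat(sprintf("protocol: %d plateaus, Ps from %.0f to %.0f Pa (law %g*phi + %g)\n",
            nrow(truth), min(truth$ps_mean_Pa), max(truth$ps_mean_Pa),
            cfg$true_Rd, cfg$true_P0))
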