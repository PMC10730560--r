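#!/usr/bin/env Rscript
# Step 2 — reduce the simulated raw signals to per-step aero-acoustic
# descriptors: mean flow and pressure, per-cycle pressure minima, f0 (YIN),
# SPL, HNR and glottal flow resistance Rg = Ps/phi, then check them against
# the generator's ground truth.

suppressMessages(library(phonobench))
dir.create("results", showWarnings = FALSE)

dir <- file.path("results", "bench_data")
if (!dir.exists(dir)) stop("run analysis/01_simulate_bench.R first")
sig <- read_signals(file.path(dir, "signals.csv"))
au <- read_wav(file.path(dir, "audio.wav"))
cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))

# the recorded audio is one step long; reuse the config to span the round
set.seed(cfg$seed + 1L)
audio <- unlist(lapply(cfg$flow_steps, function(phi)
  synth_voice(cfg$f0_true, cfg$step_duration, cfg$audio_rate,
              spl_db = 15 * log10(phi) + 70, hnr_db = cfg$hnr_true,
              n_harmonics = cfg$n_harmonics)$wave))

steps <- reduce_round(sig$time_s, sig$flow_Ls, sig$pressure_Pa, audio,
                      cfg$audio_rate)
write.csv(steps, file.path("results", "steps.csv"), row.names = FALSE)

truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                             simplifyVector = TRUE)
cat(sprintf("%d quasi-steady steps reduced\n", nrow(steps)))
cat(sprintf("f0: mean %.2f Hz (truth %g), max |err| %.3f Hz\n",
            mean(steps$f0_Hz), truth$f0_Hz,
            max(abs(steps$f0_Hz - truth$f0_Hz))))
cat(sprintf("Rg: %.0f down to %.0f Pa s/L as flow rises (hyperbolic fall)\n",
            max(steps$rg_PasL), min(steps$rg_PasL)))
cat(sprintf("HNR: mean %.2f dB (target %g)\n", mean(steps$hnr_dB),
            cfg$hnr_true))
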