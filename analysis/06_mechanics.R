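#!/usr/bin/env Rscript
# Step 6 — mechanical post-processing: cyclic tensile records (4 load-unload
# cycles to eps = 0.7 at 1e-2 /s), tangent moduli Et = dP/deps on the last
# unloading path, and adhesion pull-off traces normalized by the relaxation
# force. Synthetic soft (hydrogel-like, Et ~ 0.02 MPa) and stiff
# (strain-hardening silicone-like) laws bracket the bench materials.

suppressMessages(library(phonobench))
dir.create("results", showWarnings = FALSE)

soft <- gen_tensile("linear", c(E = 0.02), n_cycles = 4, eps_max = 0.7)
stiff <- gen_tensile("exponential", c(a = 0.03, b = 2), n_cycles = 4,
                     eps_max = 0.7)
et_soft <- tangent_modulus(soft)
et_stiff <- tangent_modulus(stiff)
out <- data.frame(strain = et_soft$strain, et_soft_MPa = et_soft$Et,
                  et_stiff_MPa = et_stiff$Et)
write.csv(out, file.path("results", "tangent_moduli.csv"),
          row.names = FALSE)
cat(sprintf("soft law: Et %.3f-%.3f MPa (flat); stiff law: %.3f-%.3f MPa\n",
            min(et_soft$Et), max(et_soft$Et), min(et_stiff$Et),
            max(et_stiff$Et)))

sc <- segment_cycles(stiff$strain)
cat("cycle peaks:", paste(round(sc$peaks, 3), collapse = ", "), "\n")

# adhesion: a tacky surface separates later than a non-tacky one
tacky <- gen_adhesion(tack_tau = 3 + 10 / log(20))
plain <- gen_adhesion(tack_tau = 3)
an_t <- adhesion_normalize(tacky$force, tacky$time, tacky$relax_window)
an_p <- adhesion_normalize(plain$force, plain$time, plain$relax_window)
write.csv(data.frame(time_s = an_t$time, tacky = an_t$normalized_force,
                     plain = an_p$normalized_force),
          file.path("results", "adhesion_traces.csv"), row.names = FALSE)
cat(sprintf("separation: tacky %.1f s vs plain %.1f s (delay %.1f s)\n",
            an_t$separation_time, an_p$separation_time,
            an_t$separation_time - an_p$separation_time))
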