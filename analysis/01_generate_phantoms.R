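#!/usr/bin/env Rscript
# Generate the study's synthetic acquisitions: a control beating-heart
# phantom and an isoproterenol-like phantom with raised endocardial and
# trabecular-ridge deformation. Raw multi-page TIFF stacks go to scratch/
# (large, regenerable); the condition table goes to results/.

library(strain4d)
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

conditions <- list(
  control = phantom_spec(seed = 1001),
  iso = phantom_spec(seed = 1002, radial_ampl_endo = 0.18,
                     ridge_shortening = 0.12, ridge_thickening = 0.3))

for (nm in names(conditions)) {
  spec <- conditions[[nm]]
  message(sprintf("rendering %s phantom (%d slices x %d frames) ...", nm,
                  spec$nz, spec$n_frames))
  ph <- build_phantom(spec)
  export_phantom(ph$movie, file.path("scratch", paste0("phantom_", nm)),
                 force = TRUE)
}

tab <- do.call(rbind, lapply(names(conditions), function(nm) {
  s <- conditions[[nm]]
  data.frame(condition = nm, outer_radius_um = s$outer_axes[1],
             wall_um = s$outer_axes[1] - s$inner_axes[1],
             period_s = s$period,
             radial_ampl_epi = s$radial_ampl_epi,
             radial_ampl_endo = s$radial_ampl_endo,
             ridge_shortening = s$ridge_shortening,
             ridge_thickening = s$ridge_thickening,
             frames_per_slice = s$n_frames, frame_rate_hz = s$frame_rate,
             seed = s$seed)
}))
write.csv(tab, "results/phantom_conditions.csv", row.names = FALSE)
message("wrote results/phantom_conditions.csv")
print(tab)
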