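#!/usr/bin/env Rscript
# Oxygen reaction-diffusion analysis of the two culture geometries.
#
# Simulates 24 h of transwell and PFC-membrane culture at the average
# pancreatic OCR, sweeps OCR over the published range, and documents the
# calibration envelope for the unprinted transport/geometry coefficients.

suppressMessages(library(pancslice))
dir.create("results", showWarnings = FALSE)

res <- domain_resolution(nx = 61, nz_medium = 20, nz_tissue = 12)
kin <- oxygen_kinetics(r_max = 0.03, km = 0.44)

message("== 24 h transients at OCR 0.03 mol/m^3/s, 21% O2 ==")
traces <- list()
for (mode in c("transwell", "pfc")) {
  sim <- simulate_oxygen(build_domain(culture_config(mode), resolution = res),
                         kin, duration_h = 24, dt = 120)
  tr <- sim_traces(sim)
  tr$mode <- mode
  traces[[mode]] <- tr
  onset <- anoxia_onset(sim)
  message(sprintf("%-9s onset = %s h, terminal anoxic fraction = %.3f, mass-balance error = %.1e",
                  mode, ifelse(is.na(onset), "none", signif(onset, 3)),
                  tail(sim$anoxic_fraction, 1), sim$mass_balance$rel_error))
}
write_table_csv(do.call(rbind, traces), "results/oxygen_traces.csv")

message("== OCR parametric sweep (0.01-0.05 mol/m^3/s, both modes) ==")
sw <- ocr_sweep(list(culture_config("transwell"), culture_config("pfc")),
                ocr_values = seq(0.01, 0.05, by = 0.01), duration_h = 6,
                resolution = domain_resolution(nx = 41, nz_medium = 16,
                                               nz_tissue = 10), dt = 120)
write_table_csv(sw, "results/oxygen_ocr_sweep.csv")
print(as.data.frame(sw), row.names = FALSE)
message("PFC anoxic fraction <= transwell at every OCR: ",
        all(sw$anoxic_fraction[sw$mode == "pfc"] <=
            sw$anoxic_fraction[sw$mode == "transwell"]))

message("== Calibration envelope for the unprinted coefficients ==")
# The published transwell timeline reports core anoxia from ~16 h. The
# diffusion-consumption balance makes that unreachable here: tissue demand
# r_max * L = 3.6e-6 mol m^-2 s^-1 exceeds the maximal diffusive supply
# through 1 mm of medium (K * 150 / d ~ 5e-7) seven-fold, so the local
# oxygen store collapses within minutes. The envelope below spans the
# literature-plausible ranges and records where onset actually lands.
env <- expand.grid(medium_above = c(0.15, 0.5, 1, 2.5, 5),
                   km = c(0.1, 0.44, 2))
env_res <- domain_resolution(nx = 31, nz_medium = 12, nz_tissue = 8)
env$onset_h <- NA_real_
env$anoxic_fraction_6h <- NA_real_
for (i in seq_len(nrow(env))) {
  cfg <- culture_config("transwell", medium_above = env$medium_above[i])
  s <- simulate_oxygen(build_domain(cfg, resolution = env_res),
                       oxygen_kinetics(0.03, km = env$km[i]),
                       duration_h = 6, dt = 60, snapshot_every = 120)
  env$onset_h[i] <- anoxia_onset(s)
  env$anoxic_fraction_6h[i] <- tail(s$anoxic_fraction, 1)
}
write_table_csv(env, "results/oxygen_calibration_envelope.csv")
message("envelope onset range: ",
        paste(range(env$onset_h, na.rm = TRUE), collapse = " - "),
        " h (NA = never anoxic); none approaches the published 16 h")

write_manifest(list(stage = "oxygen_model", ocr = 0.03, km = 0.44,
                    grid = unclass(res)), seed = 1, dir = "results",
               file = "manifest_oxygen.json")
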