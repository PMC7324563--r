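#!/usr/bin/env Rscript
# Perifusion analysis: stimulation indices and windowed AUCs for synthetic
# insulin traces emulating three culture conditions.

suppressMessages(library(pancslice))
dir.create("results", showWarnings = FALSE)

print(as.data.frame(default_schedule()), row.names = FALSE)

# Response amplitudes emulate the qualitative condition ordering seen in
# long-term culture comparisons: well-oxygenated slices respond more
# strongly to high glucose and KCl than controls.
conditions <- list(
  acute = c("G16.7" = 1.5, "G3+KCl" = 2.0),
  day10_transwell = c("G16.7" = 1.0, "G3+KCl" = 1.5),
  day10_pfc = c("G16.7" = 3.0, "G3+KCl" = 4.0)
)

out <- list()
for (cond in names(conditions)) {
  tr <- synth_secretion_trace(amplitudes = conditions[[cond]],
                              noise_sd = 0.05, seed = 30 + match(cond, names(conditions)))
  # analysis clock: AUC windows mapped onto the stimulation sequence
  si <- stimulation_index(tr$trace$time_min, tr$trace$value,
                          baseline_window = c(1, 10))
  win <- list(baseline = c(1, 10), high_glucose = c(16, 36),
              low_glucose = c(36, 66), kcl = c(66, 71))
  auc <- vapply(win, function(w) window_auc(tr$trace$time_min, si, w), 1)
  out[[cond]] <- tibble::tibble(condition = cond, window = names(win),
                                auc = unname(auc))
  message(sprintf("%-16s high-glucose AUC = %6.1f, KCl AUC = %5.1f",
                  cond, auc[["high_glucose"]], auc[["kcl"]]))
}
write_table_csv(do.call(rbind, out), "results/secretion_auc.csv")
write_manifest(list(stage = "secretion", conditions = names(conditions)),
               seed = 30, dir = "results", file = "manifest_secretion.json")
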