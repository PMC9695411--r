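#!/usr/bin/env Rscript
# Simulate one synthetic nodule recording per preset and write it to disk.
#
# Each recording carries the three interictal patterns (where the nodule
# expresses them), a small population of gain-modulated units spanning the
# archetypes seen in the recorded data (phasic, sustained, periodic-modulated,
# suppressed), and -- for nodules 1 and 4 -- seizure epochs. Everything
# downstream (02-05) reads these files, so a re-run with the same seed
# reproduces the whole analysis bit for bit.

suppressPackageStartupMessages(library(pnhmicro))

seed <- 20260930L
outdir <- "results/recordings"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

duration_s <- 3000  # 50 min per nodule keeps every stage desk-sized

profiles_for <- function(nodule_id) {
  kinds <- if (nodule_id %in% c(1, 2, 4)) c("PD+F", "SD+F", "ES") else
    c("PD+F", "ES")
  gains_act <- function(peak_es, peak_sdf, peak_pdf) {
    g <- list("ES" = gain_phasic(peak = peak_es),
              "PD+F" = gain_periodic(peak = peak_pdf),
              "seizure" = gain_ictal(3))
    if ("SD+F" %in% kinds)
      g[["SD+F"]] <- gain_sustained(peak = peak_sdf, duration_s = 1)
    g
  }
  list(
    unit_gain_profile(sprintf("n%d_u1", nodule_id), 8,
                      gains_act(20, 12, 5)),
    unit_gain_profile(sprintf("n%d_u2", nodule_id), 20,
                      gains_act(8, 30, 3)),
    unit_gain_profile(sprintf("n%d_u3", nodule_id), 12,
                      list("ES" = gain_inverse(0, c(-0.2, 0.4)),
                           "PD+F" = gain_inverse(0.2, c(0, 1.5))),
                      inverse = TRUE))
}

for (nod in 1:4) {
  preset <- nodule_preset(nod)
  # heavy-tailed inter-event intervals (the recorded mode << mean
  # discrepancy): bursts of activity separated by quiet stretches, which is
  # what leaves event-free 10-s windows for the baseline firing statistics
  modes <- c("PD+F" = 10, "ES" = 3,
             if (!is.na(preset$sdf_fast_hz)) c("SD+F" = 8))
  rec <- generate_recording(
    preset, duration_s,
    profiles = profiles_for(nod),
    n_seizures = if (nod %in% c(1, 4)) 6 else 0,
    modes_s = modes, sigma_log = 1,
    seed = seed + nod)
  prefix <- file.path(outdir, sprintf("nodule%d", nod))
  write_raw_signal(rec$lfp, prefix)
  write_annotations(rec$annotations, paste0(prefix, "_annotations.tsv"))
  write_spike_times(rec$spikes, paste0(prefix, "_spikes.tsv"))
  # ground-truth deflection times of the periodic trains, for 03
  defl <- Filter(function(e) e$kind %in% c("PD+F", "PF"), rec$events)
  writeLines(vapply(defl, function(e)
    paste(signif(e$deflection_times_s, 10), collapse = "\t"), ""),
    paste0(prefix, "_deflections.tsv"))
  message(sprintf(
    "nodule %d: %d events (%s), %d units, %d seizures -> %s*",
    nod, nrow(rec$annotations),
    paste(names(table(rec$annotations$label)), collapse = "/"),
    length(rec$spikes),
    sum(rec$annotations$label == "seizure"), prefix))
}
message("done; recordings under ", outdir)
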