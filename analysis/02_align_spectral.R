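#!/usr/bin/env Rscript
# Align each pattern's events and characterize its time-frequency content.
#
# For every nodule recording from 01: epoch the LFP per pattern, refine
# onsets by cross-correlation alignment, compute the Hanning-taper TFR
# (% change vs baseline), and read out the 60-200 Hz peak frequency -- the
# narrow-band fast-activity signature of each pattern. Writes a summary
# table and the TFR maps; renders quick-look figures.

suppressPackageStartupMessages(library(pnhmicro))

indir <- "results/recordings"
outdir <- "results/spectral"
figdir <- "results/figures"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
dir.create(figdir, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (nod in 1:4) {
  prefix <- file.path(indir, sprintf("nodule%d", nod))
  sig <- read_raw_signal(prefix)[[1]]
  ann <- read_annotations(paste0(prefix, "_annotations.tsv"))
  for (lab in intersect(c("PD+F", "SD+F", "ES"), unique(ann$label))) {
    tm <- align_trials(epoch(sig, ann, lab))
    tfr <- baseline_normalize(compute_tfr(tm))
    pk <- peak_frequency(tfr)
    preset <- nodule_preset(nod)
    truth <- switch(lab, "PD+F" = preset$pdf_fast_hz,
                    "SD+F" = preset$sdf_fast_hz, "ES" = preset$es_fast_hz)
    rows[[length(rows) + 1L]] <- data.frame(
      nodule = nod, pattern = lab, n_trials = nrow(tm$data),
      aligned = tm$converged, f_peak_hz = pk$f_peak_hz,
      peak_pct_change = round(pk$peak_value),
      generator_hz = truth,
      bin_hz = diff(tfr$freqs_hz[1:2]))
    write_tfr(tfr, file.path(outdir, sprintf("nodule%d_%s", nod,
                                             gsub("[+]", "p", lab))))
    png(file.path(figdir, sprintf("tfr_nodule%d_%s.png", nod,
                                  gsub("[+]", "p", lab))),
        width = 900, height = 600)
    plot(tfr, main = sprintf("Nodule %d %s (n = %d)", nod, lab,
                             nrow(tm$data)))
    dev.off()
  }
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(outdir, "peak_frequencies.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
print(tab, row.names = FALSE)
off <- abs(tab$f_peak_hz - tab$generator_hz) > tab$bin_hz
message(sprintf("%d/%d pattern peaks within one frequency bin of the generator truth",
                sum(!off), nrow(tab)))
if (any(off)) message(
  "off-bin rows: ",
  paste(sprintf("nodule %d %s (%g vs %g Hz)", tab$nodule[off],
                tab$pattern[off], tab$f_peak_hz[off],
                tab$generator_hz[off]), collapse = "; "),
  "\n  in a mixed recording, events of one pattern inside another pattern's",
  " baseline window bias the percentage-change spectrum at shared",
  " frequencies (nodule 2's ES and PD+F fast activity sit 1 Hz apart);",
  " single-pattern series recover every preset within one bin (see tests)")
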