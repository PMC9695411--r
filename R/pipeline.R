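#' Default analysis parameters
#'
#' Bundles every tunable of the pipeline with its default: 200/400 ms taper
#' windows stepped 5 ms over 60-200 Hz, baselines of -1..-0.5 s (epileptic
#' spikes) and -2..-1 s (longer patterns), 10/50 ms rate kernels, 100 rate
#' bins, cluster statistics at first-level 0.01 / cluster-level 0.05 with
#' 10000 sign-flip permutations.
#'
#' @param n_perm permutations for the cluster test.
#' @param seed seed for the permutation draws.
#' @param min_events minimum events per pattern to analyze.
#' @param n_bins rate bins per trial.
#' @param modulation_measure `"peak"` or `"mean"` (see
#'   [modulation_percent]).
#' @return list of class `ip_params`.
#' @export
ip_params <- function(n_perm = 10000, seed = 1, min_events = 5,
                      n_bins = 100, modulation_measure = "peak") {
  structure(list(
    alpha_first = 0.01, alpha_cluster = 0.05, n_perm = n_perm,
    seed = seed, min_events = min_events, n_bins = n_bins,
    band_hz = c(60, 200), step_s = 0.005,
    modulation_measure = modulation_measure,
    kernel_sigma_s = function(label) if (label == "ES") 0.010 else 0.050,
    tfr_window_s = function(label) if (label == "ES") 0.2 else 0.4),
    class = "ip_params")
}

#' Run the interictal-pattern analysis
#'
#' End-to-end orchestration over one recording: per pattern label with enough
#' events it epochs and aligns the LFP, computes the baseline-normalized TFR
#' and its 60-200 Hz peak frequency, summarizes event statistics (count,
#' modal inter-event interval, periodicity of ground-truth deflection trains
#' when supplied); per unit x pattern it estimates Gaussian-kernel peri-event
#' rates on the aligned onsets, bins them, runs the cluster permutation test
#' against the pre-event baseline bins, and derives the maximal significant
#' up-/down-modulation and the rate-LFP correlation. Missing patterns are
#' skipped with a note; the run continues.
#'
#' @param signal a 1 kHz [sampled_signal].
#' @param annotations an [annotation_table].
#' @param trains list of [spike_train].
#' @param params an [ip_params] bundle.
#' @param deflection_times optional per-label list of per-train deflection
#'   times for the periodicity columns.
#' @param unit_meta optional data.frame (`unit_id`, `rpv_pct`,
#'   `amplitude_uV`, `unit_class`) merged into the unit table.
#' @return list of class `ip_report`: `pattern_table` (event statistics +
#'   TFR peak), `unit_table` (per unit x pattern up/down/rho + baseline
#'   FR/CV2), `tfrs`, `aligned`, `cluster_results`, `params`, `skipped`.
#' @export
run_ip_analysis <- function(signal, annotations, trains = list(),
                            params = ip_params(), deflection_times = NULL,
                            unit_meta = NULL) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (signal$fs_hz != 1000) signal <- downsample_to_1khz(signal)
  duration_s <- signal_duration(signal)
  labs <- intersect(IP_PATTERN_LABELS, unique(annotations$label))
  skipped <- character()
  aligned <- list(); tfrs <- list(); pattern_rows <- list()
  for (lab in labs) {
    nev <- sum(annotations$label == lab)
    if (nev < params$min_events) {
      skipped <- c(skipped, sprintf("%s: only %d events", lab, nev)); next
    }
    tm <- epoch(signal, annotations, lab)
    if (nrow(tm$data) < params$min_events) {
      skipped <- c(skipped, sprintf("%s: only %d usable trials", lab,
                                    nrow(tm$data))); next
    }
    tm <- align_trials(tm)
    tfr <- baseline_normalize(compute_tfr(tm,
                                          window_s = params$tfr_window_s(lab),
                                          step_s = params$step_s))
    pk <- peak_frequency(tfr)
    aligned[[lab]] <- tm
    tfrs[[lab]] <- tfr
    ev <- annotations_with_label(annotations, lab)
    lam <- if (nrow(ev) >= 2) interval_mode(ev$start_s)$lambda_mode_s
    else NA_real_
    mp <- pct <- NA_real_
    dt <- deflection_times[[lab]]
    if (!is.null(dt)) {
      reps <- lapply(dt[vapply(dt, length, 0L) >= 3], periodicity_fraction)
      if (length(reps)) {
        mp <- mean(vapply(reps, `[[`, 0, "mean_period_s"))
        pct <- periodicity_percent(
          sum(vapply(reps, `[[`, 0, "n_conforming")),
          sum(vapply(reps, function(r) r$n_deflections - 1L, 0L)))
      }
    }
    pattern_rows[[lab]] <- data.frame(
      label = lab, t_h = duration_s / 3600, n = nev,
      lambda_mode_s = lam, mean_period_s = mp, periodicity_pct = pct,
      f_peak_hz = pk$f_peak_hz, peak_pct_change = pk$peak_value)
  }
  pattern_table <- if (length(pattern_rows)) do.call(rbind, pattern_rows)
  else NULL
  unit_rows <- list(); cluster_results <- list()
  for (tr in trains) {
    bs <- baseline_stats(tr, annotations, duration_s)
    row <- data.frame(unit_id = tr$unit_id, fr_hz = bs$fr_hz, cv2 = bs$cv2)
    for (lab in names(aligned)) {
      tm <- aligned[[lab]]
      per <- kernel_rate(tr, tm$onsets_s, window_s = tm$window_s,
                         sigma_s = params$kernel_sigma_s(lab), label = lab)
      binned <- bin_rates(per, params$n_bins)
      centers <- attr(binned, "bin_centers_s")
      bl_win <- default_baseline(lab)
      bl_bins <- binned[, centers >= bl_win[1] & centers <= bl_win[2],
                        drop = FALSE]
      cres <- cluster_permutation_test(binned, bl_bins,
                                       alpha_first = params$alpha_first,
                                       alpha_cluster = params$alpha_cluster,
                                       n_perm = params$n_perm,
                                       seed = params$seed)
      cluster_results[[paste(tr$unit_id, lab, sep = "/")]] <-
        list(result = cres, bin_centers_s = centers)
      mod <- modulation_percent(binned, cres, label = lab,
                                measure = params$modulation_measure)
      rho <- rate_lfp_correlation(avg_rate(per),
                                  colMeans(tm_window_data(tm)))$rho
      add <- data.frame(up = mod$up_pct, down = mod$down_pct, rho = rho)
      names(add) <- paste0(c("up_", "down_", "rho_"), lab)
      row <- cbind(row, add)
    }
    unit_rows[[tr$unit_id]] <- row
  }
  unit_table <- if (length(unit_rows)) do.call(rbind, unit_rows) else NULL
  if (!is.null(unit_table) && !is.null(unit_meta))
    unit_table <- merge(unit_meta, unit_table, by = "unit_id", sort = FALSE)
  rownames(unit_table) <- NULL
  structure(list(pattern_table = pattern_table, unit_table = unit_table,
                 tfrs = tfrs, aligned = aligned,
                 cluster_results = cluster_results, params = params,
                 skipped = skipped, duration_s = duration_s),
            class = "ip_report")
}

#' @export
print.ip_report <- function(x, ...) {
  cat("<ip_report>\n-- patterns --\n")
  if (!is.null(x$pattern_table)) print(x$pattern_table, row.names = FALSE)
  cat("-- units --\n")
  if (!is.null(x$unit_table)) print(x$unit_table, row.names = FALSE)
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' Run the seizure-locked descriptive analysis
#'
#' Builds seizure-locked rasters and the pre/post rate table; by design no
#' inferential statistics are attached (too few seizures).
#'
#' @param annotations an [annotation_table] containing `seizure` rows.
#' @param trains list of [spike_train].
#' @param window_s raster window around onset.
#' @return a [seizure_raster], or a zero-seizure stub with
#'   `status = "no-seizures"`.
#' @export
run_seizure_analysis <- function(annotations, trains, window_s = c(-30, 60)) {
  sz <- annotations_with_label(annotations, "seizure")
  if (!nrow(sz))
    return(structure(list(raster = list(), summary = NULL,
                          window_s = window_s, n_seizures = 0L,
                          status = "no-seizures"),
                     class = "seizure_raster"))
  seizure_raster(trains, sz$start_s, window_s)
}

#' Write a report bundle to disk
#'
#' Emits the pattern and unit tables as TSV, significant-cluster windows as
#' TSV, every TFR map, and a JSON manifest (parameters + seed + package
#' version) sufficient to regenerate the bundle.
#'
#' @param report an `ip_report`.
#' @param outdir output directory (created if needed).
#' @param extra named list merged into the manifest (e.g. the synthesis
#'   scenario).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir, extra = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$pattern_table))
    utils::write.table(report$pattern_table,
                       file.path(outdir, "pattern_table.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(report$unit_table))
    utils::write.table(report$unit_table,
                       file.path(outdir, "unit_table.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  cw <- do.call(rbind, lapply(names(report$cluster_results), function(k) {
    cr <- report$cluster_results[[k]]
    w <- cluster_windows(cr$result, cr$bin_centers_s)
    if (nrow(w)) cbind(unit_pattern = k, w) else NULL
  }))
  if (!is.null(cw))
    utils::write.table(cw, file.path(outdir, "cluster_windows.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  for (lab in names(report$tfrs))
    write_tfr(report$tfrs[[lab]],
              file.path(outdir, paste0("tfr_", gsub("[+]", "p", lab))))
  p <- report$params
  manifest <- c(list(
    package = "pnhmicro",
    version = as.character(utils::packageVersion("pnhmicro")),
    alpha_first = p$alpha_first, alpha_cluster = p$alpha_cluster,
    n_perm = p$n_perm, seed = p$seed, n_bins = p$n_bins,
    band_hz = p$band_hz, step_s = p$step_s,
    modulation_measure = p$modulation_measure,
    duration_s = report$duration_s, skipped = report$skipped), extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
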