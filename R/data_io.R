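#' @importFrom signal butter filtfilt
NULL

# ---- raw float32 + JSON sidecar ------------------------------------------

#' Write / read signals as raw float32 with a JSON sidecar
#'
#' The lossless fast path: little-endian float32 samples in channel-contiguous
#' blocks (`<prefix>.f32`), with acquisition metadata in `<prefix>.json`.
#'
#' @param signals a [sampled_signal] or list of them (equal `fs_hz` and
#'   length).
#' @param prefix path prefix (without extension).
#' @return `write_raw_signal` returns the prefix invisibly; `read_raw_signal`
#'   returns a list of [sampled_signal].
#' @export
write_raw_signal <- function(signals, prefix) {
  if (inherits(signals, "sampled_signal")) signals <- list(signals)
  fs <- unique(vapply(signals, `[[`, 0, "fs_hz"))
  ns <- unique(vapply(signals, function(s) length(s$samples), 0L))
  if (length(fs) != 1L || length(ns) != 1L)
    stop("all channels must share one sampling rate and length")
  con <- file(paste0(prefix, ".f32"), "wb")
  on.exit(close(con))
  for (s in signals)
    writeBin(as.numeric(s$samples), con, size = 4L, endian = "little")
  meta <- list(fs_hz = fs, n_channels = length(signals), n_samples = ns,
               channel_ids = vapply(signals, `[[`, "", "channel_id"),
               t0_s = vapply(signals, `[[`, 0, "t0_s"),
               dtype = "float32-le", layout = "channel-blocks")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_raw_signal
#' @export
read_raw_signal <- function(prefix) {
  jpath <- paste0(prefix, ".json"); bpath <- paste0(prefix, ".f32")
  if (!file.exists(jpath)) stop("sidecar not found: ", jpath)
  if (!file.exists(bpath)) stop("binary payload not found: ", bpath)
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  for (f in c("fs_hz", "n_channels", "n_samples"))
    if (is.null(meta[[f]])) stop("sidecar is missing field: ", f)
  need <- meta$n_channels * meta$n_samples * 4
  if (file.info(bpath)$size != need)
    stop(sprintf("payload size %d != expected %d bytes (truncated?)",
                 file.info(bpath)$size, need))
  con <- file(bpath, "rb"); on.exit(close(con))
  lapply(seq_len(meta$n_channels), function(i) {
    x <- readBin(con, "numeric", n = meta$n_samples, size = 4L,
                 endian = "little")
    sampled_signal(x, meta$fs_hz,
                   channel_id = if (length(meta$channel_ids) >= i)
                     meta$channel_ids[i] else paste0("ch", i),
                   t0_s = if (length(meta$t0_s) >= i) meta$t0_s[i] else 0)
  })
}

# ---- EDF (16-bit) ---------------------------------------------------------

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)  # left-justified, padded
  if (nchar(s) > width) s <- substr(s, 1, width)
  s
}

#' Write signals to an EDF file
#'
#' European Data Format, 16-bit: the primary interchange format. All channels
#' must share one sampling rate and length; the whole recording is stored as a
#' single data record. Physical units are uV; amplitudes are quantized onto
#' the 16-bit digital range spanning each channel's amplitude extremes.
#'
#' @param signals a [sampled_signal] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, path) {
  if (inherits(signals, "sampled_signal")) signals <- list(signals)
  fs <- unique(vapply(signals, `[[`, 0, "fs_hz"))
  ns <- unique(vapply(signals, function(s) length(s$samples), 0L))
  if (length(fs) != 1L || length(ns) != 1L)
    stop("all channels must share one sampling rate and length")
  nsig <- length(signals)
  phys_min <- phys_max <- dig <- vector("list", nsig)
  for (i in seq_len(nsig)) {
    x <- signals[[i]]$samples
    r <- max(abs(range(x)), 1e-6)
    # quantize against the header value as printed, so scaling is exact
    r <- as.numeric(format(r, digits = 7))
    phys_min[[i]] <- -r; phys_max[[i]] <- r
    dig[[i]] <- as.integer(pmax(-32767, pmin(32767, round(x / r * 32767))))
  }
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8), edf_field("X X X X", 80), edf_field("Startdate X", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (nsig + 1), 8), edf_field("", 44),
    edf_field(1, 8), edf_field(format(ns / fs, digits = 8), 8),
    edf_field(nsig, 4))
  lab <- paste0(vapply(seq_len(nsig), function(i)
    edf_field(signals[[i]]$channel_id, 16), ""), collapse = "")
  tran <- strrep(edf_field("", 80), nsig)
  dim_ <- strrep(edf_field("uV", 8), nsig)
  pmin_ <- paste0(vapply(seq_len(nsig), function(i)
    edf_field(format(phys_min[[i]], digits = 7), 8), ""), collapse = "")
  pmax_ <- paste0(vapply(seq_len(nsig), function(i)
    edf_field(format(phys_max[[i]], digits = 7), 8), ""), collapse = "")
  dmin_ <- strrep(edf_field(-32767, 8), nsig)
  dmax_ <- strrep(edf_field(32767, 8), nsig)
  pref <- strrep(edf_field("", 80), nsig)
  spr <- strrep(edf_field(ns, 8), nsig)
  resv <- strrep(edf_field("", 32), nsig)
  writeChar(paste0(hdr, lab, tran, dim_, pmin_, pmax_, dmin_, dmax_, pref,
                   spr, resv),
            con, eos = NULL)
  for (i in seq_len(nsig))
    writeBin(dig[[i]], con, size = 2L, endian = "little")
  invisible(path)
}

read_edf_num <- function(s, field) {
  v <- suppressWarnings(as.numeric(trimws(s)))
  if (is.na(v)) stop("malformed EDF header field: ", field)
  v
}

#' Read an EDF file
#'
#' @param path EDF file written by [write_edf] or any single-record 16-bit EDF
#'   with equal per-channel rates.
#' @return list of [sampled_signal] (physical units).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  if (sz < 256) stop("truncated EDF: file shorter than the fixed header")
  con <- file(path, "rb"); on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  hdr_bytes <- read_edf_num(substr(fixed, 185, 192), "header bytes")
  n_rec <- read_edf_num(substr(fixed, 237, 244), "number of data records")
  rec_dur <- read_edf_num(substr(fixed, 245, 252), "record duration")
  nsig <- as.integer(read_edf_num(substr(fixed, 253, 256), "signal count"))
  if (nsig < 1) stop("malformed EDF header field: signal count")
  if (sz < hdr_bytes) stop("truncated EDF: header incomplete")
  sig_hdr <- readChar(con, hdr_bytes - 256, useBytes = TRUE)
  # field byte offsets within the per-signal header block
  pos <- cumsum(c(0, 16, 80, 8, 8, 8, 8, 8, 80, 8)) * nsig
  fld <- function(k, w) vapply(seq_len(nsig), function(i)
    substr(sig_hdr, pos[k] + (i - 1) * w + 1, pos[k] + i * w), "")
  labels <- trimws(fld(1, 16))
  phys_min <- vapply(fld(4, 8), read_edf_num, 0, field = "physical minimum")
  phys_max <- vapply(fld(5, 8), read_edf_num, 0, field = "physical maximum")
  dig_min <- vapply(fld(6, 8), read_edf_num, 0, field = "digital minimum")
  dig_max <- vapply(fld(7, 8), read_edf_num, 0, field = "digital maximum")
  spr <- vapply(fld(9, 8), read_edf_num, 0, field = "samples per record")
  expected <- hdr_bytes + 2 * n_rec * sum(spr)
  if (sz < expected)
    stop(sprintf("truncated EDF: %d bytes, header promises %d", sz, expected))
  out <- vector("list", nsig)
  raw_rec <- vector("list", nsig)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nsig)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(d) < spr[i]) stop("truncated EDF: data records incomplete")
      raw_rec[[i]] <- c(raw_rec[[i]], d)
    }
  }
  fs <- unname(spr / rec_dur)
  for (i in seq_len(nsig)) {
    scale <- unname((phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i]))
    x <- (raw_rec[[i]] - unname(dig_min[i])) * scale + unname(phys_min[i])
    out[[i]] <- sampled_signal(x, fs[i], channel_id = labels[i])
  }
  out
}

# ---- annotations & spike times (TSV) -------------------------------------

#' Read / write annotation tables as TSV
#'
#' Columns: `label`, `channel`, `start_s`, `end_s`. Unknown labels and rows
#' with `end_s < start_s` are rejected with the offending row reported.
#'
#' @param path TSV file.
#' @param table an [annotation_table].
#' @return `read_annotations` returns an [annotation_table].
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotations(df)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write spike-time tables as TSV
#'
#' Columns: `unit_id`, `time_s`. One [spike_train] per distinct unit.
#'
#' @param path TSV file.
#' @param trains a [spike_train] or list of them.
#' @return `read_spike_times` returns a named list of [spike_train].
#' @export
read_spike_times <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "time_s") %in% names(df)))
    stop("spike-time TSV requires columns unit_id, time_s")
  lapply(split(df$time_s, df$unit_id), function(ts)
    spike_train(sort(ts)))
}

#' @rdname read_spike_times
#' @export
write_spike_times <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr)
    data.frame(unit_id = tr$unit_id, time_s = tr$times_s)))
  if (is.null(df)) df <- data.frame(unit_id = character(), time_s = numeric())
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- resampling -----------------------------------------------------------

#' Downsample a signal to the common 1 kHz analysis rate
#'
#' Applies a zero-phase anti-aliasing low-pass (4th-order Butterworth at
#' 400 Hz, forward-backward) before integer decimation. A 1 kHz input is
#' returned unchanged. The decimation factor `fs_hz / 1000` must be an
#' integer.
#'
#' @param x a [sampled_signal] with `fs_hz >= 1000`.
#' @param cutoff_hz anti-aliasing cutoff (default 400 Hz, preserving the
#'   60-200 Hz analysis band).
#' @return A [sampled_signal] at 1000 Hz with `floor(n * 1000 / fs)` samples.
#' @export
downsample_to_1khz <- function(x, cutoff_hz = 400) {
  stopifnot(inherits(x, "sampled_signal"))
  if (x$fs_hz < 1000) stop("cannot downsample: fs_hz < 1000")
  if (x$fs_hz == 1000) return(x)
  fac <- x$fs_hz / 1000
  if (abs(fac - round(fac)) > 1e-9)
    stop("fs_hz must be an integer multiple of 1000 Hz")
  fac <- as.integer(round(fac))
  bf <- signal::butter(4, cutoff_hz / (x$fs_hz / 2), type = "low")
  y <- signal::filtfilt(bf, x$samples)
  n_out <- floor(length(x$samples) / fac)
  idx <- (seq_len(n_out) - 1L) * fac + 1L
  sampled_signal(y[idx], 1000, channel_id = x$channel_id, t0_s = x$t0_s)
}
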