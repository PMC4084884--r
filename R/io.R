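# Readers and writers for the interchange formats: EDF (the canonical
# sleep-EEG signal format; 16-bit integer encoding, one data record per
# second), delimited numeric text, tab-separated event tables, and flat
# key-value configuration files.

## ---- EDF -------------------------------------------------------------------

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' Minimal EDF writer: one data record per second, all channels at the
#' recording's sampling rate, 16-bit integer encoding with per-channel
#' physical scaling spanning the data range. Requires an integer `fs`; the
#' recording is zero-padded to a whole number of seconds (EDF data records
#' are fixed-length).
#'
#' @param recording An `so_recording`.
#' @param path Output path.
#' @param physical_dimension Unit string stored per channel (default "uV").
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_dimension = "uV") {
  stopifnot(inherits(recording, "so_recording"))
  fs <- recording$fs
  if (fs != round(fs))
    so_stop("parameter", "EDF with 1 s records requires an integer sampling rate")
  data <- recording$data
  ns <- ncol(data)
  n <- nrow(data)
  n_rec <- ceiling(n / fs)
  if (n_rec * fs > n)
    data <- rbind(data, matrix(0, n_rec * fs - n, ns))

  pmin_ <- apply(data, 2, min); pmax_ <- apply(data, 2, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) writeChar(paste0(vapply(vals, edf_pad, "", width),
                                                collapse = ""), con, eos = NULL)
  labels <- colnames(data)
  fld(labels, 16); fld(rep("", ns), 80); fld(rep(physical_dimension, ns), 8)
  fld(formatC(pmin_, format = "g", digits = 7), 8)
  fld(formatC(pmax_, format = "g", digits = 7), 8)
  fld(rep(dmin, ns), 8); fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80); fld(rep(fs, ns), 8); fld(rep("", ns), 32)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((data[idx, ch] - pmin_[ch]) * scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Counterpart of [write_edf()]; supports the plain EDF layout with equal
#' per-channel sampling rates. Header inconsistencies (truncation, field
#' mismatches) raise explicit parse errors.
#'
#' @param path Input path.
#' @return An `so_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256)
    so_stop("parse", "truncated EDF header")
  gf <- function(from, len) trimws(substr(fixed, from, from + len - 1))
  hdr_bytes <- suppressWarnings(as.integer(gf(185, 8)))
  n_rec <- suppressWarnings(as.integer(gf(237, 8)))
  rec_dur <- suppressWarnings(as.numeric(gf(245, 8)))
  ns <- suppressWarnings(as.integer(gf(253, 4)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, ns)) || ns < 1)
    so_stop("parse", "malformed EDF header fields")
  if (hdr_bytes != 256 * (1 + ns))
    so_stop("parse", "EDF header size inconsistent with signal count")
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  if (nchar(sig, type = "bytes") < 256 * ns)
    so_stop("parse", "truncated EDF signal header")
  ## byte offsets of the per-field blocks within the signal header: label 16,
  ## transducer 80, dim 8, phys min/max 8+8, dig min/max 8+8, prefilter 80,
  ## samples-per-record 8 (each block repeated ns times)
  off <- c(label = 0, transducer = 16, dim = 96, pmin = 104, pmax = 112,
           dmin = 120, dmax = 128, prefilter = 136, nsamp = 216)
  fld <- function(name, width) {
    start <- off[[name]] * ns
    vapply(seq_len(ns), function(i)
      trimws(substr(sig, start + (i - 1) * width + 1, start + i * width)), "")
  }
  labels <- fld("label", 16)
  pmin_ <- as.numeric(fld("pmin", 8)); pmax_ <- as.numeric(fld("pmax", 8))
  dmin <- as.numeric(fld("dmin", 8)); dmax <- as.numeric(fld("dmax", 8))
  nsamp <- as.integer(fld("nsamp", 8))
  if (anyNA(c(pmin_, pmax_, dmin, dmax, nsamp)))
    so_stop("parse", "malformed EDF signal header fields")
  if (length(unique(nsamp)) != 1)
    so_stop("parse", "per-channel sampling rates differ: not supported")
  fs <- nsamp[1] / rec_dur
  raw_vals <- readBin(con, "integer", n = n_rec * sum(nsamp), size = 2,
                      signed = TRUE, endian = "little")
  if (length(raw_vals) < n_rec * sum(nsamp))
    so_stop("parse", "EDF data shorter than the header promises")
  data <- matrix(0, n_rec * nsamp[1], ns)
  per_rec <- sum(nsamp)
  for (r in seq_len(n_rec)) {
    block <- raw_vals[((r - 1) * per_rec + 1):(r * per_rec)]
    for (ch in seq_len(ns)) {
      dig <- block[((ch - 1) * nsamp[ch] + 1):(ch * nsamp[ch])]
      phys <- pmin_[ch] + (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
        (dmax[ch] - dmin[ch])
      data[((r - 1) * nsamp[ch] + 1):(r * nsamp[ch]), ch] <- phys
    }
  }
  colnames(data) <- labels
  new_recording(data, fs)
}

## ---- delimited text --------------------------------------------------------

#' Read a signal from EDF or delimited text
#'
#' Delimited input is whitespace- or tab-separated numeric columns, one
#' column per channel, with an optional header line of channel names; the
#' sampling rate must then be supplied via `fs`.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"edf"` or `"delimited"`.
#' @param fs Sampling rate for delimited input, Hz.
#' @return An `so_recording`.
#' @export
read_signal <- function(path, format = c("auto", "edf", "delimited"),
                        fs = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  if (format == "edf") return(read_edf(path))
  if (is.null(fs))
    so_stop("parameter", "delimited input needs an explicit sampling rate (fs)")
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first),
                                                           "[\t ,]+")[[1]][1])))
  tab <- read.table(path, header = has_header)
  new_recording(as.matrix(tab), fs,
                channel_names = if (has_header) colnames(tab) else NULL)
}

#' Write a recording as delimited text
#'
#' Tab-separated columns (one per channel) with a header of channel names.
#'
#' @param recording An `so_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_text <- function(recording, path) {
  stopifnot(inherits(recording, "so_recording"))
  write.table(recording$data, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

## ---- event tables ----------------------------------------------------------

#' Read an event table
#'
#' Tab-separated file whose header starts with `sample`, `label`,
#' `condition` (extra columns are preserved). Samples must be sorted
#' non-decreasingly; the offending rows are listed otherwise. Duplicate
#' samples with differing labels are allowed but trigger a warning.
#'
#' @param path Input path.
#' @return Event table (data frame).
#' @export
read_events <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "label", "condition")
  if (!all(need %in% colnames(tab)[seq_len(min(3, ncol(tab)))]))
    so_stop("parse", 'event table must start with columns "sample", "label", "condition"')
  if (is.unsorted(tab$sample)) {
    bad <- which(diff(tab$sample) < 0) + 1L
    so_stop("validation", paste0("event samples not sorted; offending row(s): ",
                                 paste(bad, collapse = ", ")))
  }
  dup <- duplicated(tab$sample) & !duplicated(tab[, c("sample", "label")])
  if (any(dup))
    warning("duplicate event samples with differing labels at row(s): ",
            paste(which(dup), collapse = ", "))
  tab
}

#' Write an event table
#'
#' @param events Event table with columns `sample`, `label`, `condition`.
#' @param path Output path.
#' @param extra Optional data frame of additional columns to append.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, extra = NULL) {
  out <- events[, c("sample", "label", "condition")]
  if (!is.null(extra)) out <- cbind(out, extra)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "NA")
  invisible(path)
}

## ---- flat key-value configuration ------------------------------------------

#' Write a flat key-value configuration file
#'
#' One `key = value` line per entry; numeric vectors are comma-separated.
#' Round-trips losslessly through [read_config()] for numeric, logical and
#' character scalars and numeric vectors.
#'
#' @param config Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    val <- if (is.numeric(v)) paste(format(v, digits = 17), collapse = ",")
           else if (is.logical(v)) ifelse(v, "true", "false")
           else as.character(v)
    paste0(k, " = ", val)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' @param path Input path.
#' @param known_keys Optional character vector; unknown keys then raise a
#'   named error.
#' @return Named list with numerics, logicals and strings restored.
#' @export
read_config <- function(path, known_keys = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) so_stop("parse", paste0("malformed config line: ", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!is.null(known_keys) && !(key %in% known_keys))
      so_stop("parameter", paste0("unknown configuration key: ", key))
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (length(num) > 0 && !anyNA(num)) num
      else if (val %in% c("true", "false")) identical(val, "true")
      else val
  }
  out
}

#' Default run configuration with provenance
#'
#' The merged defaults of the predictor and analysis chain. Each field's
#' provenance records whether the value is a published constant of the
#' targeting protocol (`"protocol"`) or a package default (`"default"`).
#'
#' @return List with `values` (flat named list) and `provenance`
#'   (data frame).
#' @export
default_run_config <- function() {
  values <- list(
    fs = 512, buffer_len = 5000, so_band_lo = 0.6, so_band_hi = 1.2,
    filter_order = 1, filter_bandwidth_hz = 1.0,
    fit_window_lo = 0.80, fit_window_hi = 0.95,
    power_ratio_min = 0.6, fit_error_max = 0.1, horizon_max_s = 0.250,
    timeout_samples = 10000, target_up_deg = 90, target_down_deg = 270,
    playback_lead_s = 0.250,
    offline_band_lo = 0.5, offline_band_hi = 1.5,
    epoch_t0_s = -1.0, epoch_t1_s = 2.5,
    baseline_lo_s = -0.750, baseline_hi_s = 0,
    erp_lowpass_hz = 35,
    tf_n_freqs = 35, tf_freq_lo = 5, tf_freq_hi = 100,
    tf_cycles_lo = 4, tf_cycles_hi = 12,
    tf_fs_out = 100, tf_baseline_lo_s = -0.200, tf_baseline_hi_s = 0,
    cluster_alpha = 0.01, n_permutations = 1000, alpha_two_sided = 0.025,
    stats_window_lo_s = -0.200, stats_window_hi_s = 1.500,
    arousal_margin_s = 2.0, fake_lookback_s = 3.0, fake_tolerance_deg = 2,
    marker_offset_s = 0.250
  )
  protocol <- c("fs", "buffer_len", "so_band_lo", "so_band_hi", "filter_order",
                "filter_bandwidth_hz", "fit_window_lo", "fit_window_hi",
                "power_ratio_min", "fit_error_max", "horizon_max_s",
                "timeout_samples", "target_up_deg", "target_down_deg",
                "playback_lead_s", "offline_band_lo", "offline_band_hi",
                "epoch_t0_s", "epoch_t1_s", "baseline_lo_s", "baseline_hi_s",
                "erp_lowpass_hz", "tf_n_freqs", "tf_freq_lo", "tf_freq_hi",
                "tf_cycles_lo", "tf_cycles_hi", "tf_fs_out",
                "tf_baseline_lo_s", "tf_baseline_hi_s", "cluster_alpha",
                "n_permutations", "alpha_two_sided", "stats_window_lo_s",
                "stats_window_hi_s", "arousal_margin_s", "fake_lookback_s")
  list(values = values,
       provenance = data.frame(
         key = names(values),
         source = ifelse(names(values) %in% protocol, "protocol", "default")))
}
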