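#' Read a sensor stream from delimited text
#'
#' Expects a CSV with header columns `time_s, ax, ay, az`. Samples are
#' snapped onto the uniform `1/fs` grid spanned by the first and last
#' timestamps; grid points with no sample become missing-mask entries
#' (values undefined until [interpolate_missing()]).
#'
#' @param path file path.
#' @param fs_expected expected sampling rate in Hz; the rate implied by the
#'   time column must agree within 1%.
#' @return An [accel_ts()].
#' @export
read_sensor <- function(path, fs_expected) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("time_s", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop("sensor file must have columns: ", paste(need, collapse = ", "))
  tt <- df$time_s
  if (length(tt) < 2) stop("sensor file has fewer than 2 samples")
  if (any(diff(tt) <= 0))
    stop("non-monotone time column at row ",
         which(diff(tt) <= 0)[1] + 1L)
  # infer the rate from the modal spacing, so dropout gaps (integer
  # multiples of the true spacing) do not bias it
  dts <- round(diff(tt), 6)
  fs_obs <- 1 / as.numeric(names(which.max(table(dts))))
  if (abs(fs_obs - fs_expected) > 0.01 * fs_expected)
    stop(sprintf("sampling rate mismatch: file implies %.4f Hz, expected %g Hz",
                 fs_obs, fs_expected))
  fs <- fs_expected
  n <- round((tt[length(tt)] - tt[1]) * fs) + 1L
  grid <- tt[1] + (seq_len(n) - 1L) / fs
  idx <- round((tt - tt[1]) * fs) + 1L
  if (any(abs(tt - grid[idx]) > 0.05 / fs))
    stop("timestamps do not lie on a uniform 1/fs grid")
  if (anyDuplicated(idx)) stop("duplicate samples on the time grid")
  ax <- ay <- az <- rep(NA_real_, n)
  ax[idx] <- df$ax; ay[idx] <- df$ay; az[idx] <- df$az
  missing <- rep(TRUE, n); missing[idx] <- FALSE
  ax[missing] <- 0; ay[missing] <- 0; az[missing] <- 0
  accel_ts(grid, ax, ay, az, fs, missing)
}

#' Write a sensor stream as delimited text
#'
#' Inverse of [read_sensor()]: missing samples are omitted from the file and
#' reappear as mask entries on re-read. Values are written with full
#' precision so that read–write round-trips are lossless.
#'
#' @param s an [accel_ts()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sensor <- function(s, path) {
  stopifnot(inherits(s, "accel_ts"))
  keep <- !s$missing
  lines <- c("time_s,ax,ay,az",
             sprintf("%.17g,%.17g,%.17g,%.17g",
                     s$t[keep], s$ax[keep], s$ay[keep], s$az[keep]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a coder-exported annotation track
#'
#' Parses the tab-delimited export dialect of a video annotation tool: one
#' row per interval with columns `tier`, `onset_s`, `offset_s`, `label`.
#' Human-readable condition labels are mapped to the internal enum
#' ("Mother Not Providing Rhythm" -> `MOTHER_NOT_PROVIDING`,
#' "Mother Providing Rhythm" -> `MOTHER_PROVIDING`); rows may also carry the
#' enum values directly. Rows are returned sorted by onset; overlapping
#' same-tier intervals or unknown labels are errors.
#'
#' @param path file path to the tab-delimited export.
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("tier", "onset_s", "offset_s", "label")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  lab <- as.character(df$label)
  lab[lab %in% c("", "NA")] <- NA_character_
  lab[lab == "Mother Not Providing Rhythm"] <- "MOTHER_NOT_PROVIDING"
  lab[lab == "Mother Providing Rhythm"] <- "MOTHER_PROVIDING"
  annotation_track(df$tier, as.numeric(df$onset_s), as.numeric(df$offset_s), lab)
}

#' Write an annotation track as tab-delimited text
#'
#' @param track an [annotation_track()].
#' @param path output file path.
#' @param human_labels write the coder-facing condition strings instead of
#'   the internal enum values.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path, human_labels = FALSE) {
  stopifnot(inherits(track, "annotation_track"))
  lab <- track$label
  if (human_labels) {
    lab[lab == "MOTHER_NOT_PROVIDING"] <- "Mother Not Providing Rhythm"
    lab[lab == "MOTHER_PROVIDING"] <- "Mother Providing Rhythm"
  }
  lab[is.na(lab)] <- ""
  lines <- c("tier\tonset_s\toffset_s\tlabel",
             sprintf("%s\t%.17g\t%.17g\t%s",
                     track$tier, track$onset_s, track$offset_s, lab))
  writeLines(lines, path)
  invisible(path)
}

# CSV column names for the per-visit summary table; the descriptive names
# mirror the longitudinal descriptives table of the analysis.
VISIT_SUMMARY_COLS <- c(
  visit_id = "visit_id",
  condition = "condition",
  n_episodes = "Number of rattling episodes during play",
  mean_episode_dur_s = "Mean duration of rattling episode [s]",
  n_movements = "Number of rattling movements during play",
  rattling_freq_hz = "Rattling frequency [Hz]",
  wavelet_coherence = "Wavelet coherence",
  excluded = "excluded")

#' Write per-visit summary rows
#'
#' One row per visit x condition with episode counts, mean episode duration,
#' movement counts, rattling frequency, band-averaged wavelet coherence and
#' the >2.5 Hz exclusion flag. [read_visit_summary()] round-trips the table.
#'
#' @param rows data frame with columns `visit_id`, `condition`,
#'   `n_episodes`, `mean_episode_dur_s`, `n_movements`, `rattling_freq_hz`,
#'   `wavelet_coherence` (optional, `NA` allowed), `excluded`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_visit_summary <- function(rows, path) {
  internal <- names(VISIT_SUMMARY_COLS)
  if (nrow(rows) == 0 && !all(internal %in% names(rows))) {
    for (cc in setdiff(internal, names(rows))) rows[[cc]] <- logical(0)
  }
  if (!"wavelet_coherence" %in% names(rows))
    rows$wavelet_coherence <- NA_real_
  missing_cols <- setdiff(internal, names(rows))
  if (length(missing_cols))
    stop("summary rows lack columns: ", paste(missing_cols, collapse = ", "))
  out <- rows[, internal, drop = FALSE]
  names(out) <- unname(VISIT_SUMMARY_COLS)
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a per-visit summary table written by [write_visit_summary()]
#'
#' @param path CSV path.
#' @return Data frame with the internal column names.
#' @export
read_visit_summary <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(VISIT_SUMMARY_COLS %in% names(df)))
    stop("not a visit summary file: ", path)
  out <- df[, unname(VISIT_SUMMARY_COLS), drop = FALSE]
  names(out) <- names(VISIT_SUMMARY_COLS)
  for (cc in c("n_episodes", "mean_episode_dur_s", "n_movements",
               "rattling_freq_hz", "wavelet_coherence"))
    out[[cc]] <- as.numeric(out[[cc]])
  out$excluded <- as.logical(out$excluded)
  out$visit_id <- as.character(out$visit_id)
  out$condition <- as.character(out$condition)
  out
}
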