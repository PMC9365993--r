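#' Multichannel recording container
#'
#' A `tremor_recording` bundles an aligned multichannel time series with its
#' sampling rate and per-channel role labels.  Channels are columns of a
#' numeric matrix; roles are one of `"eeg"`, `"lfp"`, `"emg"`, `"accel"`
#' (plus free-form labels such as `"kinematic"` for derived series).
#'
#' @param samples numeric matrix, one column per channel (column names are
#'   channel names).
#' @param rate sampling rate in Hz.
#' @param roles character vector of channel roles, one per column.
#' @param condition condition tag (e.g. `"control"`, `"harmaline"`).
#' @param subject subject identifier.
#' @return An object of class `tremor_recording`.
#' @export
new_recording <- function(samples, rate, roles,
                          condition = NA_character_, subject = NA_character_) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (is.null(colnames(samples)))
    colnames(samples) <- paste0("ch", seq_len(ncol(samples)))
  if (length(roles) != ncol(samples))
    stop("one role per channel required")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  structure(
    list(samples = samples, rate = rate,
         roles = stats::setNames(as.character(roles), colnames(samples)),
         condition = condition, subject = subject),
    class = "tremor_recording")
}

#' @export
print.tremor_recording <- function(x, ...) {
  cat(sprintf("<tremor_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$rate,
              nrow(x$samples) / x$rate))
  cat("  channels:", paste(sprintf("%s[%s]", colnames(x$samples), x$roles),
                           collapse = ", "), "\n")
  if (!is.na(x$condition)) cat("  condition:", x$condition, "\n")
  if (!is.na(x$subject)) cat("  subject:", x$subject, "\n")
  invisible(x)
}

#' Extract a single channel as a numeric vector
#'
#' @param rec a [new_recording()] object.
#' @param channel channel name.
#' @return Numeric vector of samples.
#' @export
channel <- function(rec, channel) {
  stopifnot(inherits(rec, "tremor_recording"))
  if (!channel %in% colnames(rec$samples))
    stop("no such channel: ", channel)
  rec$samples[, channel]
}

#' Read / write a recording as wide CSV
#'
#' Columns are channels; the header encodes `name:role`.  Sampling rate,
#' condition and subject travel in `#`-prefixed comment lines so a session
#' round-trips through a single plain-text file.
#'
#' @param rec recording to write.
#' @param path file path.
#' @return `read_recording_csv` returns a [new_recording()];
#'   `write_recording_csv` returns `path` invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "tremor_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate=%.10g", rec$rate),
               sprintf("# condition=%s", rec$condition),
               sprintf("# subject=%s", rec$subject)), con)
  hdr <- paste(colnames(rec$samples), rec$roles, sep = ":")
  writeLines(paste(hdr, collapse = ","), con)
  utils::write.table(rec$samples, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  lines <- readLines(path, n = 10L)
  meta <- grep("^#", lines, value = TRUE)
  getm <- function(key) {
    hit <- grep(paste0("^# *", key, "="), meta, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^# *", key, "="), "", hit[1])
  }
  rate <- as.numeric(getm("rate"))
  if (!is.finite(rate)) stop("missing '# rate=' header in ", path)
  dat <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  parts <- strsplit(colnames(dat), ":", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1L)
  role <- vapply(parts, function(p) if (length(p) > 1) p[2] else "unknown", "")
  m <- as.matrix(dat)
  colnames(m) <- nm
  new_recording(m, rate, role, condition = getm("condition"),
                subject = getm("subject"))
}
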