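#' Gamma-ray pulse-height spectrum
#'
#' Container for a measured or synthesised spectrum: per-channel counts with
#' an affine channel-to-energy calibration and live/real acquisition times.
#'
#' @param counts Non-negative integer vector of per-channel counts
#'   (channel 0 is the first element).
#' @param offset Calibration offset (keV).
#' @param gain Calibration gain (keV per channel), > 0.
#' @param live_time Live time (s), > 0.
#' @param real_time Real time (s), >= live_time; defaults to `live_time`.
#' @param label Metadata label (source nuclide, sample id or "open").
#' @return Object of class `gamma_spectrum`.
#' @export
spectrum <- function(counts, offset, gain, live_time, real_time = live_time,
                     label = "") {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  if (live_time <= 0) stop("live_time must be > 0", call. = FALSE)
  if (real_time < live_time) stop("real_time must be >= live_time", call. = FALSE)
  structure(list(counts = counts, offset = offset, gain = gain,
                 live_time = live_time, real_time = real_time, label = label),
            class = "gamma_spectrum")
}

#' @export
print.gamma_spectrum <- function(x, ...) {
  cat("<gamma_spectrum>", x$label, "\n")
  cat(sprintf("  %d channels, %.4g total counts, live %.6g s (real %.6g s)\n",
              length(x$counts), sum(x$counts), x$live_time, x$real_time))
  cat(sprintf("  energy %.6g keV + %.6g keV/channel\n", x$offset, x$gain))
  invisible(x)
}

#' Channel centre energies of a spectrum
#' @param spec A [spectrum()].
#' @return Numeric vector of energies (keV).
#' @export
channel_energies <- function(spec) {
  spec$offset + spec$gain * (seq_along(spec$counts) - 1)
}

#' Read / write a spectrum in the package CSV dialect
#'
#' The format is a plain CSV `channel,counts` table preceded by `#`-prefixed
#' header lines `live_time_s`, `real_time_s`, `cal_offset_keV`,
#' `cal_gain_keV_per_ch` and `label`.
#'
#' @param path File path.
#' @return `read_spectrum_csv` returns a [spectrum()];
#'   `write_spectrum_csv` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (!length(m)) stop("spectrum file missing header '", key, "'", call. = FALSE)
    sub(paste0("^#\\s*", key, "="), "", m[1])
  }
  d <- read.csv(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  counts <- numeric(max(d$channel) + 1)
  counts[d$channel + 1] <- d$counts
  spectrum(counts,
           offset = as.numeric(get("cal_offset_keV")),
           gain = as.numeric(get("cal_gain_keV_per_ch")),
           live_time = as.numeric(get("live_time_s")),
           real_time = as.numeric(get("real_time_s")),
           label = get("label"))
}

#' @rdname read_spectrum_csv
#' @param spec A [spectrum()].
#' @export
write_spectrum_csv <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# live_time_s=%.10g", spec$live_time),
               sprintf("# real_time_s=%.10g", spec$real_time),
               sprintf("# cal_offset_keV=%.10g", spec$offset),
               sprintf("# cal_gain_keV_per_ch=%.10g", spec$gain),
               paste0("# label=", spec$label)), con)
  writeLines("channel,counts", con)
  writeLines(sprintf("%d,%d", seq_along(spec$counts) - 1,
                     as.integer(spec$counts)), con)
  invisible(path)
}
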