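#' Read a single-column signal file
#'
#' Reads the plain-text dialect used for public single-channel EEG segments:
#' one numeric sample per line (single-column headerless CSV is the same
#' thing). Blank lines and surrounding whitespace are tolerated; any
#' unparseable line raises an error naming its (1-based) line number in the
#' file.
#'
#' @param path path to an existing file.
#' @param label free-text label attached to the signal (defaults to the file
#'   name).
#' @return a numeric vector with attributes `label` and `source`.
#' @examples
#' seg <- read_segment(system.file("extdata", "synthetic_eeg_segment.txt",
#'                                 package = "rangeen"))
#' length(seg)
#' @export
read_segment <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  # a lone trailing comma (sloppy CSV) is tolerated
  trimmed <- sub(",$", "", trimmed)
  keep <- nzchar(trimmed)
  vals <- suppressWarnings(as.numeric(trimmed[keep]))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop(sprintf("cannot parse '%s' as a number at line %d of %s",
                 lines[bad], bad, path), call. = FALSE)
  }
  if (length(vals) == 0L) stop(sprintf("no samples found in %s", path), call. = FALSE)
  x <- check_signal(vals)
  attr(x, "label") <- label
  attr(x, "source") <- path
  x
}

#' Write a signal as a single-column text file
#'
#' One sample per line, at full double precision (`%.17g`), so that
#' write-then-read is lossless.
#'
#' @param x numeric signal.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path) {
  x <- check_signal(x)
  writeLines(sprintf("%.17g", x), path)
  invisible(path)
}
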