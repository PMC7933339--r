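#' Construct a validated chromatogram
#'
#' A chromatogram is one detector trace for one sample at one detection
#' wavelength: a strictly increasing, uniformly spaced time grid (minutes)
#' and a detector response of the same length (arbitrary absorbance units).
#'
#' @param sample_id Character scalar identifying the sample (batch).
#' @param wavelength Detection wavelength in nanometres, or the string
#'   `"fused"` for a multi-wavelength fusion profile.
#' @param time Numeric vector of retention times in minutes. Must be strictly
#'   increasing with a constant step (relative tolerance `1e-6`) and have
#'   length at least 2.
#' @param intensity Numeric vector of detector response, same length as
#'   `time`; all values must be finite.
#'
#' @return An object of class `chromatogram`: a list with elements
#'   `sample_id`, `wavelength`, `time` and `intensity`.
#' @seealso [read_chromatogram()], [write_chromatogram()], [fuse()]
#' @export
chromatogram <- function(sample_id, wavelength, time, intensity) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (length(time) < 2L)
    stop("chromatogram must have at least 2 points, got ", length(time))
  if (length(intensity) != length(time))
    stop("time and intensity lengths differ (", length(time), " vs ",
         length(intensity), ")")
  if (!all(is.finite(time)))
    stop("non-finite retention time at row ", which(!is.finite(time))[1L])
  if (!all(is.finite(intensity)))
    stop("non-finite intensity at row ", which(!is.finite(intensity))[1L])
  d <- diff(time)
  bad <- which(d <= 0)
  if (length(bad))
    stop("retention times not strictly increasing at row ", bad[1L] + 1L,
         " (", time[bad[1L]], " -> ", time[bad[1L] + 1L], ")")
  step <- stats::median(d)
  off <- which(abs(d - step) > 1e-6 * step)
  if (length(off))
    stop("non-uniform time grid at row ", off[1L] + 1L,
         ": step ", format(d[off[1L]]), " vs median step ", format(step))
  structure(
    list(sample_id = sample_id, wavelength = wavelength,
         time = as.numeric(time), intensity = as.numeric(intensity)),
    class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("<chromatogram> sample", x$sample_id, "at",
      if (identical(x$wavelength, "fused")) "fused channel"
      else paste0(x$wavelength, " nm"),
      "\n  ", length(x$time), "points,",
      format(min(x$time)), "-", format(max(x$time)), "min, step",
      format(signif(chrom_step(x), 6)), "min\n")
  invisible(x)
}

#' Grid step of a chromatogram in minutes
#' @param chrom A [chromatogram()].
#' @return Numeric scalar, the (uniform) sampling step.
#' @export
chrom_step <- function(chrom) {
  stats::median(diff(chrom$time))
}

# Split delimited lines on an auto-detected separator (comma or tab).
detect_sep <- function(line) {
  if (grepl(",", line, fixed = TRUE)) "," else "\t"
}

#' Read a chromatogram from two-column delimited text
#'
#' The file must contain two columns (time in minutes, intensity), separated
#' by a comma or a tab (auto-detected); a single header line is allowed and
#' skipped when its first field is not numeric.
#'
#' @param path Path to the file.
#' @inheritParams chromatogram
#' @return A validated [chromatogram()].
#' @export
read_chromatogram <- function(path, sample_id, wavelength) {
  if (!file.exists(path)) stop("no such chromatogram file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty chromatogram file: ", path)
  sep <- detect_sep(lines[[1L]])
  parts <- strsplit(lines, sep, fixed = TRUE)
  first <- suppressWarnings(as.numeric(trimws(parts[[1L]][1L])))
  skip <- if (is.na(first)) 1L else 0L
  n <- length(lines) - skip
  if (n < 2L) stop("chromatogram file ", path, " has fewer than 2 data rows")
  ncols <- lengths(parts[(skip + 1L):length(parts)])
  if (any(ncols < 2L))
    stop("row ", which(ncols < 2L)[1L] + skip, " of ", path,
         " has fewer than 2 fields")
  m <- matrix(suppressWarnings(as.numeric(trimws(
    unlist(lapply(parts[(skip + 1L):length(parts)], `[`, 1:2))))),
    ncol = 2L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(is.na(m[, 1L]) | is.na(m[, 2L]))[1L]
    stop("non-numeric value at line ", bad + skip, " of ", path)
  }
  chromatogram(sample_id, wavelength, m[, 1L], m[, 2L])
}

#' Write a chromatogram as two-column delimited text
#'
#' Values are written at full double precision so that a write/read
#' round trip reproduces the trace exactly.
#'
#' @param chrom A [chromatogram()].
#' @param path Output path (comma-separated, one header line).
#' @return Invisibly, `path`.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  ok <- tryCatch({
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("time_min,intensity", con)
    writeLines(sprintf("%.17g,%.17g", chrom$time, chrom$intensity), con)
    TRUE
  }, error = function(e) stop("cannot write chromatogram to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
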