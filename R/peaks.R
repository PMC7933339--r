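# Centred rolling minimum, window k points (odd), edges replicated.
# O(n) sliding-window minimum via per-block prefix/suffix cumulative minima.
roll_min <- function(x, k) {
  h <- k %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  n <- length(xp)
  pad <- (k - n %% k) %% k
  xb <- c(xp, rep(Inf, pad))
  m <- matrix(xb, nrow = k)
  pre <- apply(m, 2, cummin)
  suf <- apply(m[k:1, , drop = FALSE], 2, cummin)[k:1, , drop = FALSE]
  pre <- as.vector(pre); suf <- as.vector(suf)
  i <- seq_len(n - k + 1L)
  pmin(suf[i], pre[i + k - 1L])
}

# Centred moving average, window k points (odd), edges replicated.
roll_mean <- function(x, k) {
  h <- k %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2L))[(h + 1L):(h + length(x))]
}

#' Subtract a rolling-minimum baseline
#'
#' The baseline is estimated as the rolling minimum over a `window`-minute
#' wide window, smoothed by a moving average of the same width, and
#' subtracted from the trace. Output intensities may dip slightly below zero
#' at the noise level; peaks much narrower than the window are preserved.
#'
#' @param chrom A [chromatogram()].
#' @param window Baseline window in minutes; must span at least 3 grid steps.
#' @return A baseline-corrected [chromatogram()].
#' @export
subtract_baseline <- function(chrom, window = 2) {
  stopifnot(inherits(chrom, "chromatogram"))
  step <- chrom_step(chrom)
  if (window <= 0 || window < 3 * step)
    stop("baseline window (", window, " min) must span at least 3 grid steps (",
         format(3 * step), " min)")
  k <- min(round(window / step), length(chrom$time))
  if (k %% 2L == 0L) k <- k - 1L
  k <- max(k, 3L)
  base <- roll_mean(roll_min(chrom$intensity, k), k)
  chromatogram(chrom$sample_id, chrom$wavelength, chrom$time,
               chrom$intensity - base)
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two minima separating it from the nearest taller point (or
# trace end) on each side.
peak_prominence <- function(x, i) {
  h <- x[i]
  left <- if (i > 1L) {
    seg <- x[seq_len(i - 1L)]
    taller <- which(seg > h)
    lo <- if (length(taller)) max(taller) + 1L else 1L
    min(x[lo:(i - 1L)])
  } else h
  right <- if (i < length(x)) {
    seg <- x[(i + 1L):length(x)]
    taller <- which(seg > h)
    hi <- if (length(taller)) i + min(taller) - 1L else length(x)
    min(x[(i + 1L):hi])
  } else h
  h - max(left, right)
}

#' Detect and integrate chromatographic peaks
#'
#' Local maxima exceeding `min_height` whose topographic prominence is at
#' least `min_prominence` are reported. Peak boundaries are the nearest
#' flanking local minima (or the trace ends) and the area is the trapezoidal
#' integral of the trace between them, so integration is valley-to-valley on
#' the (ideally baseline-corrected) signal.
#'
#' @param chrom A [chromatogram()], normally after [subtract_baseline()].
#' @param min_height Minimum apex response.
#' @param min_prominence Minimum topographic prominence.
#' @return A data frame with columns `apex_rt`, `start_rt`, `end_rt`, `area`,
#'   `height`, ordered by retention time. Zero rows is a valid result.
#' @export
detect_peaks <- function(chrom, min_height = 1, min_prominence = 1) {
  stopifnot(inherits(chrom, "chromatogram"),
            min_height >= 0, min_prominence >= 0)
  x <- chrom$intensity
  t <- chrom$time
  n <- length(x)
  s <- diff(sign(diff(x)))
  maxima <- which(s < 0) + 1L
  minima <- which(s > 0) + 1L
  empty <- data.frame(apex_rt = numeric(0), start_rt = numeric(0),
                      end_rt = numeric(0), area = numeric(0),
                      height = numeric(0))
  if (!length(maxima)) return(empty)
  maxima <- maxima[x[maxima] >= min_height]
  if (!length(maxima)) return(empty)
  prom <- vapply(maxima, function(i) peak_prominence(x, i), numeric(1))
  maxima <- maxima[prom >= min_prominence]
  if (!length(maxima)) return(empty)
  out <- lapply(maxima, function(i) {
    lo <- minima[minima < i]
    lo <- if (length(lo)) max(lo) else 1L
    hi <- minima[minima > i]
    hi <- if (length(hi)) min(hi) else n
    idx <- lo:hi
    area <- sum(diff(t[idx]) * (x[idx][-1L] + x[idx][-length(idx)]) / 2)
    c(apex_rt = t[i], start_rt = t[lo], end_rt = t[hi],
      area = area, height = x[i])
  })
  out <- as.data.frame(do.call(rbind, out))
  out <- out[out$area > 0 & out$height > 0, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$apex_rt), , drop = FALSE]
}

#' Match peaks across samples into a fingerprint matrix
#'
#' Peaks from all samples are pooled, sorted by apex retention time, and
#' clustered greedily: a candidate joins the current group when its apex lies
#' within `rt_tolerance` of the group's running mean (computed with the
#' candidate included), otherwise a new group starts. Groups detected in at
#' least `presence_fraction` of the samples are retained; when a sample
#' contributes several peaks to one group their areas are summed, so matching
#' never creates or destroys area.
#'
#' @param peak_lists Named list (one element per sample) of peak tables from
#'   [detect_peaks()].
#' @param rt_tolerance Retention-time tolerance in minutes.
#' @param presence_fraction Minimum fraction of samples a peak group must be
#'   detected in; the default 1 keeps only co-possessing peaks (present in
#'   every sample).
#' @param channel Channel tag stored on the result (a wavelength or
#'   `"fused"`).
#' @return A `fingerprint_matrix`: list with `sample_ids`, `peak_rts` (group
#'   mean apex retention times, strictly increasing), `areas` (samples x
#'   peaks), and `channel`.
#' @export
match_peaks <- function(peak_lists, rt_tolerance = 0.2,
                        presence_fraction = 1, channel = NA) {
  if (length(peak_lists) < 2L) stop("need peak lists from at least 2 samples")
  if (is.null(names(peak_lists)) || any(!nzchar(names(peak_lists))))
    stop("peak_lists must be named by sample_id")
  stopifnot(rt_tolerance > 0,
            presence_fraction > 0, presence_fraction <= 1)
  samples <- names(peak_lists)
  pool <- do.call(rbind, lapply(samples, function(s) {
    pk <- peak_lists[[s]]
    if (!nrow(pk)) return(NULL)
    data.frame(sample = s, apex_rt = pk$apex_rt, area = pk$area)
  }))
  if (is.null(pool) || !nrow(pool))
    stop("no peaks detected in any sample; nothing to match")
  pool <- pool[order(pool$apex_rt), ]
  grp <- integer(nrow(pool))
  g <- 1L
  gsum <- pool$apex_rt[1L]
  gn <- 1L
  grp[1L] <- 1L
  for (i in seq_len(nrow(pool))[-1L]) {
    a <- pool$apex_rt[i]
    # running mean with the candidate provisionally included
    if (abs(a - (gsum + a) / (gn + 1L)) <= rt_tolerance) {
      gsum <- gsum + a; gn <- gn + 1L
    } else {
      g <- g + 1L; gsum <- a; gn <- 1L
    }
    grp[i] <- g
  }
  keep <- integer(0)
  rts <- numeric(0)
  for (k in seq_len(g)) {
    members <- pool[grp == k, ]
    if (length(unique(members$sample)) / length(samples) >=
        presence_fraction - 1e-12) {
      keep <- c(keep, k)
      rts <- c(rts, mean(members$apex_rt))
    }
  }
  if (!length(keep))
    stop("no peak group present in >= ", presence_fraction,
         " of samples; consider increasing rt_tolerance")
  areas <- matrix(0, nrow = length(samples), ncol = length(keep),
                  dimnames = list(samples, sprintf("P%02d", seq_along(keep))))
  for (j in seq_along(keep)) {
    members <- pool[grp == keep[j], ]
    sums <- tapply(members$area, members$sample, sum)
    areas[names(sums), j] <- sums
  }
  fingerprint_matrix(samples, rts, areas, channel)
}

#' Construct a fingerprint matrix
#'
#' @param sample_ids Character vector of sample ids (row order).
#' @param peak_rts Strictly increasing mean apex retention times (minutes).
#' @param areas Numeric matrix, samples x peaks, non-negative.
#' @param channel Channel tag (wavelength in nm or `"fused"`).
#' @return An object of class `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(sample_ids, peak_rts, areas, channel = NA) {
  areas <- as.matrix(areas)
  stopifnot(length(sample_ids) == nrow(areas),
            length(peak_rts) == ncol(areas))
  if (is.unsorted(peak_rts, strictly = TRUE))
    stop("peak_rts must be strictly increasing")
  if (any(areas < 0)) stop("peak areas must be non-negative")
  rownames(areas) <- sample_ids
  structure(list(sample_ids = as.character(sample_ids),
                 peak_rts = as.numeric(peak_rts),
                 areas = areas, channel = channel),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat("<fingerprint_matrix>", length(x$sample_ids), "samples x",
      length(x$peak_rts), "peaks, channel",
      as.character(x$channel), "\n  RT range",
      format(signif(min(x$peak_rts), 4)), "-",
      format(signif(max(x$peak_rts), 4)), "min\n")
  invisible(x)
}

#' Write / read a fingerprint matrix as delimited text
#'
#' Samples are rows; the header carries the group mean retention times.
#'
#' @param fm A [fingerprint_matrix()].
#' @param path File path.
#' @return `write_fingerprint_matrix` returns `path` invisibly;
#'   `read_fingerprint_matrix` returns a [fingerprint_matrix()].
#' @export
write_fingerprint_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  df <- data.frame(sample_id = fm$sample_ids, fm$areas, check.names = FALSE)
  colnames(df)[-1L] <- sprintf("rt_%.4f", fm$peak_rts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_matrix
#' @param channel Channel tag to attach on read.
#' @export
read_fingerprint_matrix <- function(path, channel = NA) {
  df <- utils::read.csv(path, check.names = FALSE)
  rts <- as.numeric(sub("^rt_", "", colnames(df)[-1L]))
  fingerprint_matrix(df$sample_id, rts,
                     as.matrix(df[, -1L, drop = FALSE]), channel)
}
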