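#' Fuse single-wavelength chromatograms into a multi-wavelength profile
#'
#' The fusion profile is the projection of a sample's time x wavelength
#' response surface along the wavelength axis: a point-wise (optionally
#' weighted) sum of the single-channel traces. Fusion is linear - additive
#' and homogeneous in every channel - and requires identical time grids; no
#' implicit resampling is performed.
#'
#' @param channels List of [chromatogram()]s for one sample, one per
#'   detection wavelength (at least 2).
#' @param weights Optional numeric vector of per-channel weights (default:
#'   all 1, the unweighted projection).
#' @return A [chromatogram()] with `wavelength = "fused"` and an attribute
#'   `source_wavelengths`.
#' @export
fuse <- function(channels, weights = NULL) {
  if (length(channels) < 2L) stop("fusion needs at least 2 channels")
  if (!all(vapply(channels, inherits, logical(1), "chromatogram")))
    stop("all channels must be chromatogram objects")
  ids <- unique(vapply(channels, `[[`, character(1), "sample_id"))
  if (length(ids) != 1L)
    stop("cannot fuse traces from different samples: ",
         paste(ids, collapse = ", "))
  if (is.null(weights)) weights <- rep(1, length(channels))
  if (length(weights) != length(channels) || any(weights < 0))
    stop("weights must be non-negative, one per channel")
  ref <- channels[[1L]]$time
  for (ch in channels[-1L]) {
    if (length(ch$time) != length(ref) ||
        any(abs(ch$time - ref) > 1e-6 * max(abs(ref), 1)))
      stop("channel time grids differ for sample ", ids,
           "; fusion requires identical grids (no resampling is performed)")
  }
  total <- Reduce(`+`, Map(function(ch, w) w * ch$intensity,
                           channels, as.list(weights)))
  out <- chromatogram(ids, "fused", ref, total)
  attr(out, "source_wavelengths") <-
    vapply(channels, function(ch) as.numeric(ch$wavelength), numeric(1))
  out
}

#' Build per-channel and fused fingerprint matrices for a study
#'
#' For every detection wavelength, and for the fused profile of each sample,
#' the pipeline is baseline subtraction, peak detection and cross-sample
#' peak matching, yielding one co-possessing-peak area matrix per channel
#' plus one for the fused channel. Fusion happens at the signal level,
#' before peak detection, so a compound invisible at one wavelength still
#' forms a single coherent fused peak.
#'
#' @param study An `mwfp_study` from [load_study()] or [generate_study()].
#' @param baseline_window Baseline window in minutes ([subtract_baseline()]).
#' @param min_height,min_prominence Detection thresholds ([detect_peaks()]).
#' @param rt_tolerance,presence_fraction Matching parameters
#'   ([match_peaks()]).
#' @param weights Optional per-channel fusion weights ([fuse()]).
#' @param include_fused Set `FALSE` to skip the fused channel.
#' @return Named list of [fingerprint_matrix()] objects, one per wavelength
#'   plus `"fused"`.
#' @export
build_fingerprints <- function(study, baseline_window = 2,
                               min_height = 2, min_prominence = 2,
                               rt_tolerance = 0.2, presence_fraction = 1,
                               weights = NULL, include_fused = TRUE) {
  stopifnot(inherits(study, "mwfp_study"))
  samples <- study$manifest$sample_id
  corrected <- lapply(samples, function(sid) {
    lapply(study$chromatograms[[sid]],
           subtract_baseline, window = baseline_window)
  })
  names(corrected) <- samples
  out <- list()
  for (ch in as.character(study$channels)) {
    pk <- lapply(corrected, function(per)
      detect_peaks(per[[ch]], min_height, min_prominence))
    out[[ch]] <- match_peaks(pk, rt_tolerance, presence_fraction,
                             channel = as.numeric(ch))
  }
  if (include_fused && length(study$channels) >= 2L) {
    pk <- lapply(samples, function(sid) {
      fused <- fuse(study$chromatograms[[sid]], weights = weights)
      detect_peaks(subtract_baseline(fused, baseline_window),
                   min_height, min_prominence)
    })
    names(pk) <- samples
    out[["fused"]] <- match_peaks(pk, rt_tolerance, presence_fraction,
                                  channel = "fused")
  } else if (include_fused) {
    warning("only one channel present; fusion skipped")
  }
  out
}
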