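#' Load a multi-wavelength fingerprint study from a manifest
#'
#' The manifest is a delimited text table (comma or tab) with columns
#' `sample_id`, `origin`, and one `path_<wavelength>` column per detection
#' channel (e.g. `path_203`, `path_270`, `path_325`). Paths are resolved
#' relative to the manifest's directory. Every sample must provide a trace
#' for every channel and sample ids must be unique.
#'
#' @param manifest_path Path to the manifest file.
#' @return An object of class `mwfp_study`: a list with `manifest`
#'   (data frame of `sample_id`, `origin`), `channels` (numeric wavelengths),
#'   and `chromatograms`, a list indexed as
#'   `chromatograms[[sample_id]][[as.character(wavelength)]]`.
#' @export
load_study <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("no such manifest: ", manifest_path)
  sep <- detect_sep(readLines(manifest_path, n = 1L))
  man <- utils::read.table(manifest_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  req <- c("sample_id", "origin")
  miss <- setdiff(req, names(man))
  if (length(miss)) stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  pcols <- grep("^path_", names(man), value = TRUE)
  if (!length(pcols)) stop("manifest has no path_<wavelength> columns")
  channels <- as.numeric(sub("^path_", "", pcols))
  if (anyNA(channels)) stop("malformed path column name among: ",
                            paste(pcols, collapse = ", "))
  dup <- man$sample_id[duplicated(man$sample_id)]
  if (length(dup)) stop("duplicate sample_id in manifest: ",
                        paste(unique(dup), collapse = ", "))
  base <- dirname(manifest_path)
  for (j in seq_along(pcols)) {
    p <- man[[pcols[j]]]
    bad <- is.na(p) | !nzchar(p)
    if (any(bad))
      stop("sample ", man$sample_id[which(bad)[1L]], " has no trace for ",
           channels[j], " nm")
  }
  chroms <- vector("list", nrow(man))
  names(chroms) <- man$sample_id
  for (i in seq_len(nrow(man))) {
    per <- vector("list", length(channels))
    names(per) <- as.character(channels)
    for (j in seq_along(channels)) {
      p <- file.path(base, man[[pcols[j]]][i])
      if (!file.exists(p))
        stop("sample ", man$sample_id[i], " is missing its ", channels[j],
             " nm trace (", p, ")")
      per[[j]] <- read_chromatogram(p, man$sample_id[i], channels[j])
    }
    chroms[[i]] <- per
  }
  structure(list(manifest = man[, c("sample_id", "origin")],
                 channels = channels, chromatograms = chroms),
            class = "mwfp_study")
}

#' @export
print.mwfp_study <- function(x, ...) {
  cat("<mwfp_study>", nrow(x$manifest), "samples x",
      length(x$channels), "channels (",
      paste(x$channels, collapse = ", "), "nm )\n")
  cat("  origins:", paste(sprintf("%s (%d)", names(table(x$manifest$origin)),
                                  table(x$manifest$origin)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a study (manifest plus chromatogram files) to a directory
#'
#' Writes one chromatogram file per (sample, wavelength), a `manifest.csv`
#' consumable by [load_study()], and, when the study carries a synthetic
#' ground truth, a `ground_truth.csv` with the true contents.
#'
#' @param study An `mwfp_study`, e.g. from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mwfp_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- study$manifest
  for (ch in study$channels) man[[paste0("path_", ch)]] <- NA_character_
  for (sid in man$sample_id) {
    for (ch in study$channels) {
      fn <- sprintf("%s_%snm.csv", sid, ch)
      write_chromatogram(study$chromatograms[[sid]][[as.character(ch)]],
                         file.path(dir, fn))
      man[[paste0("path_", ch)]][man$sample_id == sid] <- fn
    }
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE, quote = FALSE)
  if (!is.null(study$truth)) {
    gt <- data.frame(sample_id = rownames(study$truth$contents),
                     origin = study$truth$origins,
                     study$truth$contents, check.names = FALSE)
    utils::write.csv(gt, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(mp)
}
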