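#' The eight-level similarity grade criteria
#'
#' Grades 1-7 tighten jointly in three nested thresholds: a minimum average
#' linear qualitative similarity `Sm`, an inclusive interval for the average
#' linear quantitative similarity `Pm` (in percent), and a maximum
#' fingerprint variation coefficient `alpha`. Grade 8 is "otherwise"
#' (`Sm < 0.50`, `Pm` outside 50-150, or `alpha > 0.50`).
#'
#' @return A data frame with columns `grade`, `sm_min`, `pm_lo`, `pm_hi`,
#'   `alpha_max` for grades 1-7.
#' @export
default_grade_criteria <- function() {
  data.frame(
    grade = 1:7,
    sm_min = c(0.95, 0.90, 0.85, 0.80, 0.70, 0.60, 0.50),
    pm_lo = c(95, 90, 80, 75, 70, 60, 50),
    pm_hi = c(105, 110, 120, 125, 130, 140, 150),
    alpha_max = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50))
}

validate_criteria <- function(criteria) {
  stopifnot(is.data.frame(criteria),
            all(c("grade", "sm_min", "pm_lo", "pm_hi", "alpha_max") %in%
                  names(criteria)))
  if (any(diff(criteria$sm_min) >= 0))
    stop("sm_min must be strictly decreasing over grades")
  if (any(diff(criteria$pm_lo) > 0) || any(diff(criteria$pm_hi) < 0))
    stop("pm intervals must be nested")
  if (any(diff(criteria$alpha_max) <= 0))
    stop("alpha_max must be strictly increasing over grades")
  criteria
}

#' Build a reference fingerprint from a fingerprint matrix
#'
#' @param fm A [fingerprint_matrix()].
#' @param mode `"mean"` (column means over all samples, the default),
#'   `"sample:<id>"` (a designated reference batch), `"max_total"` (the
#'   batch with the largest total fingerprint area), or `"scaled_mean"`
#'   (the consensus mean pattern rescaled to the total area of the
#'   largest-total batch: qualitative reference = consensus profile,
#'   quantitative benchmark = the most content-rich batch, so quantitative
#'   similarities of ordinary batches centre below 100 percent).
#' @param benchmark Optional sample id fixing the benchmark batch for
#'   `"scaled_mean"`; by default the batch with the largest total area of
#'   `fm` itself. Passing the study-wide benchmark (chosen once, e.g. on
#'   the fused matrix) keeps the quantitative scale of all channels
#'   anchored to the same batch.
#' @return An object of class `reference_fingerprint`: list with `peak_rts`,
#'   `areas` (strictly positive) and `provenance`.
#' @export
reference_fingerprint <- function(fm, mode = "mean", benchmark = NULL) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  if (!length(fm$sample_ids)) stop("empty fingerprint matrix")
  if (identical(mode, "mean")) {
    y <- colMeans(fm$areas)
    prov <- "mean of all samples"
  } else if (identical(mode, "scaled_mean")) {
    tot <- rowSums(fm$areas)
    i <- if (is.null(benchmark)) which.max(tot)
         else match(benchmark, fm$sample_ids)
    if (is.na(i)) stop("unknown benchmark sample id: ", benchmark)
    y <- colMeans(fm$areas) * tot[i] / mean(tot)
    prov <- paste0("mean pattern scaled to benchmark batch ",
                   fm$sample_ids[i])
  } else if (identical(mode, "max_total")) {
    i <- which.max(rowSums(fm$areas))
    y <- fm$areas[i, ]
    prov <- paste0("sample ", fm$sample_ids[i], " (largest total area)")
  } else if (grepl("^sample:", mode)) {
    id <- sub("^sample:", "", mode)
    i <- match(id, fm$sample_ids)
    if (is.na(i)) stop("unknown reference sample id: ", id)
    y <- fm$areas[i, ]
    prov <- paste0("sample ", id)
  } else stop("unknown reference mode: ", mode)
  if (any(y <= 0))
    stop("reference fingerprint has non-positive entries; ",
         "build it from co-possessing peaks")
  structure(list(peak_rts = fm$peak_rts, areas = as.numeric(y),
                 provenance = prov),
            class = "reference_fingerprint")
}

#' Average linear qualitative and quantitative similarity of a fingerprint
#'
#' Against a reference fingerprint `y`, with peak-area ratios
#' `r_i = x_i / y_i` over the n co-possessing peaks:
#' \describe{
#'   \item{Sm}{`(S_cos + S_prof) / 2`, the mean of the cosine similarity of
#'     `x` and `y` and the overlap `sum(pmin(p, q))` of the area-fraction
#'     profiles `p = x/sum(x)`, `q = y/sum(y)`. Scale-free in `[0, 1]`,
#'     equal to 1 iff `x` is proportional to `y`.}
#'   \item{Pm}{`100 * mean(r)`, the average linear quantitative similarity
#'     in percent; linear in the scale of `x`.}
#'   \item{alpha}{`sd(r) / mean(r)`, the fingerprint variation coefficient
#'     (coefficient of variation of the ratios, n-1 denominator);
#'     scale-free.}
#' }
#'
#' @param x Non-negative peak-area vector of the sample (`sum(x) > 0`).
#' @param y Reference areas: a [reference_fingerprint()] or a strictly
#'   positive numeric vector of the same length as `x` (length >= 2).
#' @return A list with elements `Sm`, `Pm`, `alpha`.
#' @export
similarity_parameters <- function(x, y) {
  if (inherits(y, "reference_fingerprint")) y <- y$areas
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("sample and reference fingerprints differ in length (",
         length(x), " vs ", length(y), ")")
  if (length(x) < 2L) stop("need at least 2 co-possessing peaks")
  if (any(x < 0)) stop("sample areas must be non-negative")
  if (sum(x) <= 0) stop("sample fingerprint is all zero")
  if (any(y <= 0)) stop("reference areas must be strictly positive")
  r <- x / y
  s_cos <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  s_prof <- sum(pmin(x / sum(x), y / sum(y)))
  list(Sm = (s_cos + s_prof) / 2,
       Pm = 100 * mean(r),
       alpha = stats::sd(r) / mean(r))
}

#' Assign the eight-level similarity grade
#'
#' Each parameter is rated separately - `gS` is the smallest grade whose
#' `sm_min` the sample meets, `gP` the smallest grade whose `Pm` interval
#' (boundaries inclusive) contains the sample, `gA` the smallest grade whose
#' `alpha_max` the sample stays under - and the returned grade is the worst
#' of the three, so any degradation in any parameter can only raise the
#' grade.
#'
#' @param Sm Qualitative similarity in `[0, 1]`.
#' @param Pm Quantitative similarity in percent (>= 0).
#' @param alpha Fingerprint variation coefficient (>= 0).
#' @param criteria Grade criteria table ([default_grade_criteria()]).
#' @return Integer grade in 1-8.
#' @export
assign_grade <- function(Sm, Pm, alpha, criteria = default_grade_criteria()) {
  criteria <- validate_criteria(criteria)
  if (any(c(Sm, Pm, alpha) < 0)) stop("Sm, Pm and alpha must be non-negative")
  if (Sm > 1 + 1e-9) stop("Sm must lie in [0, 1], got ", Sm)
  first <- function(hit) if (any(hit)) criteria$grade[which(hit)[1L]] else 8L
  gS <- first(Sm >= criteria$sm_min)
  gP <- first(Pm >= criteria$pm_lo & Pm <= criteria$pm_hi)
  gA <- first(alpha <= criteria$alpha_max)
  as.integer(max(gS, gP, gA))
}

#' Grade every sample of a study on every channel
#'
#' For each channel a reference fingerprint is built from that channel's
#' matrix and every sample is scored against it. Under the `"scaled_mean"`
#' mode the benchmark batch is designated once for the whole study - the
#' batch with the largest total area on the fused matrix (or the first
#' matrix when no fused channel is present) - so that all channels are
#' quantitatively anchored to the same batch.
#'
#' @param matrices Named list of [fingerprint_matrix()] objects sharing the
#'   same sample order (e.g. from [build_fingerprints()]).
#' @param criteria Grade criteria table.
#' @param reference_mode Reference construction per channel; see
#'   [reference_fingerprint()].
#' @return A data frame of class `alqfm_results` with one row per
#'   (sample, channel): `sample_id`, `channel`, `Sm`, `Pm`, `alpha`, `grade`.
#' @export
evaluate_study <- function(matrices, criteria = default_grade_criteria(),
                           reference_mode = "mean") {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  ids <- matrices[[1L]]$sample_ids
  for (fm in matrices)
    if (!identical(fm$sample_ids, ids))
      stop("fingerprint matrices do not share sample ordering")
  benchmark <- NULL
  if (identical(reference_mode, "scaled_mean")) {
    anchor <- matrices[["fused"]] %||% matrices[[1L]]
    benchmark <- anchor$sample_ids[which.max(rowSums(anchor$areas))]
  }
  rows <- lapply(names(matrices), function(ch) {
    fm <- matrices[[ch]]
    ref <- reference_fingerprint(fm, mode = reference_mode,
                                 benchmark = benchmark)
    per <- lapply(seq_along(ids), function(i) {
      p <- similarity_parameters(fm$areas[i, ], ref)
      data.frame(sample_id = ids[i], channel = ch, Sm = p$Sm, Pm = p$Pm,
                 alpha = p$alpha,
                 grade = assign_grade(p$Sm, p$Pm, p$alpha, criteria))
    })
    do.call(rbind, per)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("alqfm_results", "data.frame")
  out
}

#' Two-origin discrimination by similarity grade
#'
#' Samples of the first group are called correctly when their grade is at
#' most `cutoff` (similar to the reference) and samples of the second group
#' when their grade exceeds it.
#'
#' @param grades Integer grades, or an `alqfm_results` slice for one channel.
#' @param labels Origin labels (exactly two groups), aligned with `grades`;
#'   the first group is the one labelled like `labels[1]`.
#' @param cutoff Grade cutoff (default 4).
#' @return List with the group names and sizes, `group1_within` (group-1
#'   samples at grade <= cutoff), `group2_beyond` (group-2 samples at grade >
#'   cutoff), and `errors`, the total misclassified.
#' @export
grade_discrimination <- function(grades, labels, cutoff = 4) {
  if (is.data.frame(grades)) {
    if (length(unique(grades$channel)) != 1L)
      stop("pass results for a single channel")
    grades <- grades$grade
  }
  groups <- if (is.factor(labels)) levels(droplevels(labels))
            else unique(as.character(labels))
  labels <- as.character(labels)
  if (length(grades) != length(labels))
    stop("grades and labels differ in length")
  if (length(groups) != 2L)
    stop("need exactly two origin groups, got ", length(groups))
  g1 <- grades[labels == groups[1L]]
  g2 <- grades[labels == groups[2L]]
  w1 <- sum(g1 <= cutoff)
  b2 <- sum(g2 > cutoff)
  list(group1 = groups[1L], group2 = groups[2L],
       n1 = length(g1), n2 = length(g2),
       group1_within = w1, group2_beyond = b2,
       errors = (length(g1) - w1) + (length(g2) - b2))
}

#' Write similarity results as a wide per-channel report
#'
#' One row per sample; for each channel the four columns `Sm`, `Pm`,
#' `alpha`, `grade`.
#'
#' @param results An `alqfm_results` data frame from [evaluate_study()].
#' @param path Output path (CSV).
#' @return Invisibly, the wide data frame written.
#' @export
write_alqfm_results <- function(results, path) {
  channels <- unique(results$channel)
  ids <- unique(results$sample_id)
  wide <- data.frame(sample_id = ids)
  for (ch in channels) {
    sl <- results[results$channel == ch, ]
    sl <- sl[match(ids, sl$sample_id), ]
    for (v in c("Sm", "Pm", "alpha", "grade"))
      wide[[paste(v, ch, sep = "_")]] <- sl[[v]]
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(wide)
}
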