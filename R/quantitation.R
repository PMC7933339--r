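#' Fit a linear calibration curve
#'
#' Ordinary least squares of detector response on standard concentration,
#' with the coefficient of determination and the limit of detection by the
#' 3.3 sigma/slope convention (sigma = residual standard deviation).
#'
#' @param conc Standard concentrations in mg/mL (>= 3 distinct values).
#' @param response Peak areas at those concentrations.
#' @param compound Optional compound name.
#' @return Object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared`, `lod` (mg/mL) and `compound`.
#' @export
fit_calibration <- function(conc, response, compound = NA_character_) {
  stopifnot(length(conc) == length(response))
  if (length(conc) < 3L) stop("calibration needs at least 3 points")
  if (length(unique(conc)) < 2L || stats::sd(conc) == 0)
    stop("calibration concentrations have no spread")
  fit <- stats::lm(response ~ conc)
  slope <- unname(stats::coef(fit)[2L])
  if (slope <= 0) stop("calibration slope is not positive (", signif(slope, 4),
                       "); curve rejected")
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((response - mean(response))^2)
  sigma <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
  structure(list(compound = compound, slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, lod = 3.3 * sigma / slope),
            class = "calibration_curve")
}

#' Solution concentration from a calibration curve
#'
#' @param curve A [fit_calibration()] result.
#' @param response Peak area(s).
#' @return Concentration(s) in mg/mL.
#' @export
predict_concentration <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  (response - curve$intercept) / curve$slope
}

#' Convert solution concentration to content of the raw material
#'
#' With the standard extraction of about 0.500 g of powdered sample into
#' 20 mL of solvent, content (mg/g) = solution concentration (mg/mL) x
#' extract volume / sample mass.
#'
#' @param solution_conc Concentration in the sample solution, mg/mL.
#' @param sample_mass Mass of raw material extracted, g (default 0.5).
#' @param extract_volume Extraction volume, mL (default 20).
#' @return Content in mg per g of raw material.
#' @export
to_content <- function(solution_conc, sample_mass = 0.5, extract_volume = 20) {
  if (sample_mass <= 0 || extract_volume <= 0)
    stop("sample mass and extract volume must be positive")
  solution_conc * extract_volume / sample_mass
}

#' Per-compound mean and relative standard deviation
#'
#' @param table Concentration table (samples x compounds), matrix or data
#'   frame of numeric columns.
#' @return Data frame with `compound`, `mean`, `rsd_percent`
#'   (`100 * sd / mean`, n-1 denominator).
#' @export
summary_stats <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  mu <- colMeans(m)
  if (any(mu == 0)) stop("RSD undefined for zero-mean compound: ",
                         paste(colnames(m)[mu == 0], collapse = ", "))
  data.frame(compound = colnames(m) %||% as.character(seq_len(ncol(m))),
             mean = unname(mu),
             rsd_percent = unname(100 * apply(m, 2, stats::sd) / mu),
             row.names = NULL)
}

#' Per-compound two-origin difference test
#'
#' Welch's two-sample t-test of each compound's content between the two
#' origin groups (robust to unequal group sizes and variances).
#'
#' @param table Concentration table (samples x compounds).
#' @param labels Two-group origin labels aligned with rows.
#' @return Data frame with `compound`, group means and `p_value`.
#' @export
group_difference <- function(table, labels) {
  m <- as.matrix(table)
  labels <- as.character(labels)
  if (length(labels) != nrow(m)) stop("labels and rows differ in length")
  groups <- unique(labels)
  if (length(groups) != 2L) stop("need exactly two groups")
  if (any(table(labels) < 2L)) stop("each group needs at least 2 samples")
  a <- m[labels == groups[1L], , drop = FALSE]
  b <- m[labels == groups[2L], , drop = FALSE]
  p <- vapply(seq_len(ncol(m)), function(j) {
    if (stats::sd(a[, j]) == 0 && stats::sd(b[, j]) == 0)
      return(if (mean(a[, j]) == mean(b[, j])) 1 else 0)
    stats::t.test(a[, j], b[, j])$p.value
  }, numeric(1))
  out <- data.frame(compound = colnames(m) %||% as.character(seq_len(ncol(m))),
                    row.names = NULL)
  out[[paste0("mean_", groups[1L])]] <- unname(colMeans(a))
  out[[paste0("mean_", groups[2L])]] <- unname(colMeans(b))
  out$p_value <- p
  out
}
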