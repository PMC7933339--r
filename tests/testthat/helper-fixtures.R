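# Shared fixtures: everything is generated in code at test time.

# A chromatogram made of Gaussian peaks on a uniform grid.
gaussian_chrom <- function(rts, areas, sigma = 0.05, step = 0.002,
                           t_max = max(rts) + 1, sample_id = "S1",
                           wavelength = 203, baseline = 0) {
  t <- seq(0, t_max, by = step)
  y <- rep(baseline, length(t))
  for (k in seq_along(rts)) y <- y + areas[k] * dnorm(t, rts[k], sigma)
  chromatogram(sample_id, wavelength, t, y)
}

# A compact compound library for fast end-to-end tests.
tiny_library <- function(n_sap = 3, n_flav = 1, n_aa = 1) {
  n <- n_sap + n_flav + n_aa
  cls <- rep(c("saponin", "flavonoid", "amino_acid"),
             c(n_sap, n_flav, n_aa))
  rf <- list(saponin = c(1, 0, 0), flavonoid = c(0, 1.2, 1),
             amino_acid = c(0, 0.9, 0))
  m <- do.call(rbind, rf[cls])
  data.frame(name = sprintf("C%02d", seq_len(n)), class = cls,
             rt = seq(3, by = 1.5, length.out = n), sigma = 0.05,
             rf_203 = m[, 1], rf_270 = m[, 2], rf_325 = m[, 3],
             mean_sichuan = seq(4, by = 2, length.out = n) * 1.2,
             mean_yunnan = seq(4, by = 2, length.out = n) / 1.2,
             cv_sichuan = 0.12, cv_yunnan = 0.12,
             discriminating = rep(c(TRUE, FALSE), length.out = n))
}

# A small, quick synthetic configuration (coarser grid, short window).
tiny_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_sichuan = 3, n_yunnan = 3,
                   library = tiny_library(), grid_step = 0.01, t_max = 12,
                   noise_sd = 0, drift_amplitude = 0, rt_jitter_sd = 0,
                   shared_scale_cv = 0.05)
  extra <- list(...)
  args <- defaults
  for (nm in names(extra)) args[[nm]] <- extra[[nm]]
  do.call(synthetic_study_config, args)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
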