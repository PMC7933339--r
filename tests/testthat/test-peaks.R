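test_that("baseline subtraction removes flat and drifting baselines", {
  const <- chromatogram("S1", 203, seq(0, 10, 0.01), rep(5, 1001))
  out <- subtract_baseline(const, window = 1)
  expect_equal(out$intensity, rep(0, 1001), tolerance = 1e-12)

  # Gaussian peak on zero baseline: window much wider than the peak keeps
  # the apex height within 2%
  pk <- gaussian_chrom(5, 10, sigma = 0.05, step = 0.01, t_max = 10)
  corr <- subtract_baseline(pk, window = 2)
  expect_equal(max(corr$intensity), max(pk$intensity), tolerance = 0.02)

  # pure linear drift, window = full range: residual bounded by the drift
  # accumulated over one window
  t <- seq(0, 10, 0.01)
  drift <- chromatogram("S1", 203, t, 3 * t)
  resid <- subtract_baseline(drift, window = 10)$intensity
  expect_lt(max(abs(resid)), 3 * 10)

  expect_error(subtract_baseline(const, window = 0.01),
               "at least 3 grid steps")
})

test_that("detect_peaks finds, bounds and integrates isolated peaks", {
  flat <- chromatogram("S1", 203, seq(0, 5, 0.01), rep(0, 501))
  expect_equal(nrow(detect_peaks(flat, 0.1, 0.1)), 0L)

  # closed form: area of unit-amplitude Gaussian = A * sigma * sqrt(2*pi)
  t <- seq(0, 4, 0.002)
  g <- chromatogram("S1", 203, t, dnorm(t, 2, 0.05) * 0.05 * sqrt(2 * pi))
  pk <- detect_peaks(g, min_height = 0.1, min_prominence = 0.1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$area, 0.05 * sqrt(2 * pi), tolerance = 0.01)
  expect_true(pk$start_rt < pk$apex_rt && pk$apex_rt < pk$end_rt)

  # two fully resolved Gaussians: both apexes within one grid step
  two <- gaussian_chrom(c(2, 3), c(0.1253, 0.1253), sigma = 0.05,
                        step = 0.002, t_max = 5)
  pk2 <- detect_peaks(two, 0.1, 0.1)
  expect_equal(nrow(pk2), 2L)
  expect_equal(pk2$apex_rt, c(2, 3), tolerance = 0.002)

  # thresholds drop sub-threshold maxima
  expect_equal(nrow(detect_peaks(g, min_height = 2, min_prominence = 0.1)),
               0L)
})

test_that("prominence separates shoulders from independent peaks", {
  # a small bump riding on the flank of a big peak has low prominence
  t <- seq(0, 6, 0.002)
  y <- 10 * dnorm(t, 3, 0.3) + 0.3 * dnorm(t, 3.45, 0.04)
  ch <- chromatogram("S1", 203, t, y)
  big_only <- detect_peaks(ch, min_height = 1, min_prominence = 3)
  expect_equal(nrow(big_only), 1L)
  both <- detect_peaks(ch, min_height = 1, min_prominence = 0.5)
  expect_equal(nrow(both), 2L)
})

make_peaks <- function(rts, areas = rep(1, length(rts))) {
  data.frame(apex_rt = rts, start_rt = rts - 0.1, end_rt = rts + 0.1,
             area = areas, height = areas * 8)
}

test_that("match_peaks builds co-possessing matrices", {
  pls <- list(A = make_peaks(c(5.00, 10.00)),
              B = make_peaks(c(5.02, 9.98)),
              C = make_peaks(c(4.99, 10.02)))
  fm <- match_peaks(pls, rt_tolerance = 0.2, presence_fraction = 1)
  expect_equal(ncol(fm$areas), 2L)
  expect_true(all(fm$areas > 0))
  expect_true(!is.unsorted(fm$peak_rts, strictly = TRUE))

  # co-possession excludes a peak absent from one sample; a lower
  # presence fraction re-admits it
  pls2 <- list(A = make_peaks(c(5, 7)), B = make_peaks(c(5, 7)),
               C = make_peaks(5))
  expect_equal(ncol(match_peaks(pls2, 0.2, 1)$areas), 1L)
  expect_equal(ncol(match_peaks(pls2, 0.2, 0.6)$areas), 2L)
})

test_that("greedy clustering follows the running-mean rule", {
  # {5.00, 5.15, 5.31} chains into one group at tolerance 0.2: each apex is
  # within 0.2 of the group mean computed with it included
  pls <- list(A = make_peaks(5.00), B = make_peaks(5.15),
              C = make_peaks(5.31))
  fm <- match_peaks(pls, rt_tolerance = 0.2, presence_fraction = 1)
  expect_equal(ncol(fm$areas), 1L)
  expect_equal(fm$peak_rts, mean(c(5, 5.15, 5.31)))

  # a clearly separated apex starts a new group
  pls2 <- list(A = make_peaks(c(5.0, 5.6)), B = make_peaks(c(5.02, 5.62)))
  expect_equal(ncol(match_peaks(pls2, 0.2, 1)$areas), 2L)
})

test_that("matching conserves area and sums same-sample duplicates", {
  pls <- list(A = make_peaks(c(5.00, 5.05), areas = c(1, 2)),
              B = make_peaks(5.02, areas = 3))
  fm <- match_peaks(pls, rt_tolerance = 0.2, presence_fraction = 1)
  expect_equal(ncol(fm$areas), 1L)
  expect_equal(unname(fm$areas["A", 1]), 3)      # duplicates summed
  total_in <- sapply(pls, function(p) sum(p$area))
  expect_true(all(rowSums(fm$areas) <= total_in + 1e-12))

  expect_error(match_peaks(list(A = make_peaks(1), B = make_peaks(9)),
                           rt_tolerance = 0.2, presence_fraction = 1),
               "increasing rt_tolerance")
})

test_that("fingerprint matrices round-trip through delimited text", {
  fm <- fingerprint_matrix(c("A", "B"), c(1.5, 3.2),
                           matrix(c(1, 2, 3, 4), 2), channel = "fused")
  path <- withr::local_tempfile(fileext = ".csv")
  write_fingerprint_matrix(fm, path)
  back <- read_fingerprint_matrix(path, channel = "fused")
  expect_equal(back$areas, fm$areas, ignore_attr = TRUE)
  expect_equal(back$peak_rts, fm$peak_rts)
})
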