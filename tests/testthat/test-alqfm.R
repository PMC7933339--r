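rand_fm <- function(n, p, seed = 1, channel = "fused") {
  set.seed(seed)
  fingerprint_matrix(sprintf("S%d", seq_len(n)), seq_len(p),
                     matrix(rlnorm(n * p, 1, 0.3), n), channel)
}

test_that("reference fingerprints follow the requested mode", {
  fm <- fingerprint_matrix(c("A", "B"), c(1, 2), rbind(c(1, 2), c(3, 4)))
  expect_equal(reference_fingerprint(fm, "mean")$areas, c(2, 3))
  expect_equal(reference_fingerprint(fm, "sample:B")$areas, c(3, 4))
  expect_error(reference_fingerprint(fm, "sample:Z"), "unknown")

  one <- fingerprint_matrix("A", c(1, 2), rbind(c(1.5, 2.5)))
  expect_equal(reference_fingerprint(one, "mean")$areas, c(1.5, 2.5))

  big <- rand_fm(32, 10, seed = 4)
  brute <- apply(big$areas, 2, function(col) sum(col) / length(col))
  expect_equal(reference_fingerprint(big, "mean")$areas, unname(brute),
               tolerance = 1e-12)

  # benchmark scaling: mean pattern at the largest batch's total level
  ref <- reference_fingerprint(big, "scaled_mean")
  expect_equal(sum(ref$areas), max(rowSums(big$areas)), tolerance = 1e-9)
  expect_equal(reference_fingerprint(big, "max_total")$areas,
               unname(big$areas[which.max(rowSums(big$areas)), ]))
})

test_that("similarity parameters satisfy their defining identities", {
  y <- c(3, 1, 4, 1.5, 9)
  p0 <- similarity_parameters(y, y)
  expect_equal(p0$Sm, 1)
  expect_equal(p0$Pm, 100)
  expect_equal(p0$alpha, 0)

  ph <- similarity_parameters(0.5 * y, y)
  expect_equal(ph$Sm, 1)
  expect_equal(ph$Pm, 50)
  expect_equal(ph$alpha, 0)

  # hand-evaluated case: x = (1, 0), y = (1, 1)
  pe <- similarity_parameters(c(1, 0), c(1, 1))
  expect_equal(pe$Sm, (1 / sqrt(2) + 0.5) / 2, tolerance = 1e-9)
  expect_equal(pe$Pm, 50)
  expect_equal(pe$alpha, sqrt(2) * 0.5 / 0.5, tolerance = 1e-9)

  expect_error(similarity_parameters(c(1, 2, 3), c(1, 2)), "length")
  expect_error(similarity_parameters(c(1, 2), c(1, 0)), "positive")
  expect_error(similarity_parameters(c(0, 0), c(1, 1)), "all zero")
})

test_that("Sm and alpha are scale-free, Pm is linear in scale", {
  set.seed(11)
  for (i in 1:20) {
    x <- rlnorm(8); y <- rlnorm(8)
    c0 <- runif(1, 0.1, 10)
    a <- similarity_parameters(x, y)
    b <- similarity_parameters(c0 * x, y)
    expect_equal(b$Sm, a$Sm, tolerance = 1e-12)
    expect_equal(b$alpha, a$alpha, tolerance = 1e-12)
    expect_equal(b$Pm, c0 * a$Pm, tolerance = 1e-9)
    # Sm = 1 and alpha = 0 exactly when x is proportional to y
    expect_lt(a$Sm, 1)
    expect_gt(a$alpha, 0)
  }
})

test_that("grade assignment is worst-of-three with inclusive bounds", {
  expect_equal(assign_grade(1, 100, 0), 1L)
  expect_equal(assign_grade(0.45, 100, 0.01), 8L)       # Sm below grade 7
  # reported per-sample values reproduce their published grades
  expect_equal(assign_grade(0.883, 94.3, 0.047), 3L)
  expect_equal(assign_grade(0.848, 59.4, 0.07), 7L)
  # boundary inclusivity
  expect_equal(assign_grade(1, 70, 0), 5L)              # Pm = 70 -> band 5
  expect_equal(assign_grade(0.95, 100, 0), 1L)          # Sm = 0.95 -> 1
  expect_equal(assign_grade(1, 100, 0.05), 1L)          # alpha = 0.05 -> 1
  # alpha above 0.5 is grade 8 (grades 2-7 remain reachable in between)
  expect_equal(assign_grade(1, 100, 0.30), 5L)
  expect_equal(assign_grade(1, 100, 0.35), 6L)
  expect_equal(assign_grade(1, 100, 0.55), 8L)
  expect_error(assign_grade(-0.1, 100, 0), "non-negative")
})

test_that("worsening any parameter never lowers the grade", {
  set.seed(21)
  for (i in 1:50) {
    Sm <- runif(1, 0.4, 1); Pm <- runif(1, 40, 160); a <- runif(1, 0, 0.6)
    g <- assign_grade(Sm, Pm, a)
    expect_gte(assign_grade(max(Sm - runif(1, 0, 0.2), 0), Pm, a), g)
    worse_pm <- 100 + (Pm - 100) * (1 + runif(1, 0, 0.5))
    expect_gte(assign_grade(Sm, worse_pm, a), g)
    expect_gte(assign_grade(Sm, Pm, a + runif(1, 0, 0.2)), g)
  }
})

test_that("the grade rule reproduces the reported fused grades", {
  rg <- regrade_reported_results("fused")
  agree <- rg$recomputed_grade == rg$reported_grade
  expect_true(all(agree[!rg$known_discrepant]))
  expect_equal(sum(agree), 26L)
  expect_setequal(rg$sample_id[!agree],
                  c("S4", "S8", "S9", "S13", "S17", "S18"))
  # the six discrepant rows are printed exactly one grade worse
  expect_true(all(rg$reported_grade[!agree] -
                    rg$recomputed_grade[!agree] == 1L))
})

test_that("evaluate_study grades all samples on all channels", {
  # identical samples: every grade is 1 on every channel
  areas <- matrix(rep(c(2, 5, 1), each = 4), 4)
  fm <- fingerprint_matrix(sprintf("S%d", 1:4), 1:3, areas, "203")
  res <- evaluate_study(list(`203` = fm))
  expect_true(all(res$grade == 1L))
  expect_true(all(abs(res$Pm - 100) < 1e-9))

  mats <- list(`203` = rand_fm(6, 5, 1, "203"), fused = rand_fm(6, 5, 2))
  res2 <- evaluate_study(mats)
  expect_equal(nrow(res2), 12L)
  expect_s3_class(res2, "alqfm_results")

  # a half-scaled sample is graded through its Pm band
  areas2 <- areas; areas2[2, ] <- areas2[2, ] / 2
  res3 <- evaluate_study(list(`203` = fingerprint_matrix(
    sprintf("S%d", 1:4), 1:3, areas2, "203")))
  r_mean <- mean(areas2[2, ] / colMeans(areas2))
  expect_equal(res3$Pm[2], 100 * r_mean, tolerance = 1e-9)
  expect_gte(res3$grade[2], 6L)   # Pm ~ 57% falls in the 50-150 band
})

test_that("grade discrimination counts match the published split", {
  rep_tab <- reported_similarity_results()
  d <- grade_discrimination(rep_tab$grade_fused, rep_tab$origin, cutoff = 4)
  expect_equal(d$group1_within, 12L)   # Sichuan in grades 1-4
  expect_equal(d$group2_beyond, 15L)   # Yunnan in grades 5-8
  expect_equal(d$errors, 5L)

  # swapping the group roles complements the error count
  d2 <- grade_discrimination(rep_tab$grade_fused,
                             factor(rep_tab$origin,
                                    levels = c("Yunnan", "Sichuan")),
                             cutoff = 4)
  expect_equal(d2$errors, 32L - 5L)

  perfect <- grade_discrimination(rep(c(1L, 8L), c(5, 7)),
                                  rep(c("A", "B"), c(5, 7)))
  expect_equal(perfect$errors, 0L)
  expect_error(grade_discrimination(1:3, c("A", "B", "C")), "two origin")
})

test_that("alqfm results serialise to a wide per-channel report", {
  mats <- list(`203` = rand_fm(4, 3, 1, "203"), fused = rand_fm(4, 3, 2))
  res <- evaluate_study(mats)
  path <- withr::local_tempfile(fileext = ".csv")
  wide <- write_alqfm_results(res, path)
  expect_equal(nrow(wide), 4L)
  expect_true(all(c("Sm_203", "grade_fused") %in% names(wide)))
  expect_true(file.exists(path))
})
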