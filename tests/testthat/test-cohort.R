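test_that("schema validity enforces the 6 MRI / 9 cognitive contract", {
  s <- defaultFeatureSchema()
  expect_s4_class(s, "FeatureSchema")
  expect_length(schemaFeatures(s, "mri"), 6)
  expect_length(schemaFeatures(s, "cognitive"), 9)
  expect_length(attendedFeatures(s), 17)
  expect_length(demographicFeatures(s), 3)
  bad <- s
  bad@roles[1] <- "cognitive"   # 5 mri / 10 cognitive
  expect_error(validObject(bad), "mri")
})

test_that("complete cohort file round-trips with mask all ones", {
  f <- withr::local_tempfile(fileext = ".csv")
  handCohortCSV(f)
  co <- loadCohort(f)
  expect_true(all(cohortMask(co) == 1))
  expect_identical(dim(cohortValues(co)), c(20L, 2L, 3L))
  # write then reload reproduces values and mask
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeCohort(co, f2)
  co2 <- loadCohort(f2)
  expect_equal(cohortValues(co2), cohortValues(co), tolerance = 1e-12)
  expect_equal(cohortMask(co2), cohortMask(co))
  expect_equal(abetaGroup(co2), abetaGroup(co))
})

test_that("a blank cell yields mask 0 and the delta recurrence advances", {
  f <- withr::local_tempfile(fileext = ".csv")
  handCohortCSV(f, blank_kmmse_at_visit2 = TRUE)
  co <- loadCohort(f)
  expect_equal(unname(cohortMask(co)["kmmse", , 2]), c(0, 0))
  # annual visits: unobserved at visit 2 -> delta at visit 3 spans 2 years
  expect_equal(unname(cohortDelta(co)["kmmse", , 3]), c(2, 2))
  expect_equal(unname(cohortDelta(co)["kmmse", , 2]), c(1, 1))
})

test_that("demographics are duplicated from baseline with mask 1 and age advances", {
  f <- withr::local_tempfile(fileext = ".csv")
  handCohortCSV(f, blank_edu_after_baseline = TRUE)
  co <- loadCohort(f)
  expect_true(all(cohortMask(co)["education", , ] == 1))
  expect_true(all(cohortValues(co)["education", , ] == 12))
  expect_equal(unname(cohortValues(co)["age", 1, ]), c(70, 71, 72))
})

test_that("malformed files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- handCohortCSV(f)
  df$bogus <- 1
  write.csv(df, f, row.names = FALSE, na = "")
  expect_error(loadCohort(f), "unknown column")
  df$bogus <- NULL
  dup <- rbind(df, df[1, ])
  write.csv(dup, f, row.names = FALSE, na = "")
  expect_error(loadCohort(f), "duplicate")
  nobase <- df[df$visit_year > 0 | df$subject_id == "A01", ]
  write.csv(nobase, f, row.names = FALSE, na = "")
  expect_error(loadCohort(f), "baseline")
})

test_that("delta recurrence matches hand-unrolled cases", {
  mk <- function(mask, times) {
    m <- array(rep(mask, each = 1), c(1, 1, length(mask)))
    buildDelta(m, matrix(times, 1))
  }
  expect_equal(drop(mk(c(1, 1, 1), 0:2)), c(0, 1, 1))
  expect_equal(drop(mk(c(1, 0, 0, 1), 0:3)), c(0, 1, 2, 3))
  expect_equal(drop(mk(c(1, 0, 1), c(0, 1.5, 2.0))), c(0, 1.5, 2.0))
  expect_error(mk(c(1, 1), c(1, 0)), "nondecreasing")
})

test_that("delta recurrence equals a per-cell loop oracle on random masks", {
  set.seed(101)
  for (rep_i in 1:20) {
    B <- sample(2:4, 1); N <- sample(2:10, 1); T <- sample(2:6, 1)
    mask <- array(rbinom(B * N * T, 1, 0.6), c(B, N, T))
    mask[, , 1] <- 1
    vt <- t(apply(matrix(runif(N * T), N), 1, function(r) cumsum(c(0, r[-1]))))
    got <- buildDelta(mask, vt)
    # oracle: literal per-cell recurrence
    want <- array(0, c(B, N, T))
    for (b in seq_len(B)) for (i in seq_len(N)) for (t in 2:T) {
      gap <- vt[i, t] - vt[i, t - 1]
      want[b, i, t] <- if (mask[b, i, t - 1] == 1) gap
                       else gap + want[b, i, t - 1]
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("min-max normalization maps train range to [0,1] and round-trips", {
  co <- tinyCohort(n_per_group = 5, T = 3, seed = 9)
  ids <- colnames(co)
  st <- fitNormalizer(co, ids)
  n <- applyNormalizer(co, st)
  v <- cohortValues(n); m <- cohortMask(n)
  expect_true(all(v[m == 1] >= -1e-12 & v[m == 1] <= 1 + 1e-12))
  back <- invertNormalizer(n, st)
  expect_equal(cohortValues(back), cohortValues(co), tolerance = 1e-10)
  # direct arithmetic: observed {2,4,6} -> {0, .5, 1}
  expect_equal(normalizeArray(c(2, 4, 6),
                              new("NormalizationState", minimum = c(x = 2),
                                  maximum = c(x = 6), method = "minmax"),
                              "x"),
               c(0, 0.5, 1))
})

test_that("normalizer is fit on the training split only and admits out-of-range", {
  co <- tinyCohort(n_per_group = 6, T = 3, seed = 10)
  ids <- colnames(co)
  train <- ids[1:8]
  st <- fitNormalizer(co, train)
  # mutating non-train values does not change the state
  v <- cohortValues(co)
  v[, 9:12, ] <- v[, 9:12, ] * 10
  co2 <- makeCohort(v, cohortMask(co), visitTimes(co), abetaGroup(co),
                    cohortSchema(co))
  st2 <- fitNormalizer(co2, train)
  expect_equal(st@minimum, st2@minimum)
  expect_equal(st@maximum, st2@maximum)
  # test-split value beyond the train range maps outside [0,1]
  expect_equal(unname(normalizeArray(8, new("NormalizationState",
    minimum = c(x = 2), maximum = c(x = 6), method = "minmax"), "x")), 1.5)
  # constant feature is a named degenerate error
  vv <- cohortValues(co)
  vv["gender", , ] <- 1
  co3 <- makeCohort(vv, cohortMask(co), visitTimes(co), abetaGroup(co),
                    cohortSchema(co))
  expect_error(fitNormalizer(co3, ids), "gender")
})

test_that("normalization state serializes to JSON and back", {
  co <- tinyCohort(n_per_group = 4, T = 3, seed = 11)
  st <- fitNormalizer(co, colnames(co))
  f <- withr::local_tempfile(fileext = ".json")
  writeNormalizer(st, f)
  st2 <- readNormalizer(f)
  expect_equal(st@minimum, st2@minimum)
  expect_equal(st@maximum, st2@maximum)
})

test_that("mask/value consistency survives subsetting and normalization", {
  co <- tinyCohort(n_per_group = 6, T = 4, seed = 12, p_miss = 0.3)
  st <- fitNormalizer(co, colnames(co))
  n <- applyNormalizer(co, st)
  sub <- subsetSubjects(n, colnames(n)[c(2, 5, 9)])
  for (x in list(co, n, sub)) {
    v <- cohortValues(x); m <- cohortMask(x)
    expect_true(all(is.finite(v[m == 1])))
    expect_true(validObject(x))
  }
})
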