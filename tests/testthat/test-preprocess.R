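test_that("replicate averaging follows the absent-as-zero convention", {
  raw <- make_raw(data.frame(
    s = c("A", "A", "A", "A", "A"),
    r = c(1, 2, 1, 2, 1),
    p = c("P1", "P1", "P2", "P2", "P3"),
    n = c(2, 4, 5, 5, 6)))
  m <- average_replicates(raw)
  expect_equal(unname(m["A", c("P1", "P2", "P3")]), c(3, 5, 3))
})

test_that("averaging is idempotent on single-replicate tables and rejects bad input", {
  raw1 <- make_raw(data.frame(s = c("A", "B"), r = 1, p = "P1", n = c(4, 7)))
  m <- average_replicates(raw1)
  expect_equal(unname(m[, "P1"]), c(4, 7))
  expect_error(average_replicates(raw1[0, ]), "empty")
  dup <- rbind(raw1, raw1[1, ])
  expect_error(average_replicates(dup), "duplicate")
  expect_warning(
    average_replicates(make_raw(data.frame(
      s = c("A", "A", "B"), r = c(1, 2, 1), p = "P1", n = c(2, 4, 5)))),
    "unbalanced")
})

test_that("normalization equalizes row totals and conserves the grand total", {
  m <- matrix(c(60, 40, 100, 200), 2, 2,
              dimnames = list(c("A", "B"), c("P1", "P2")))
  nm <- normalize_profiles(m)
  expect_equal(unname(rowSums(nm)), c(200, 200))
  expect_equal(sum(nm), sum(m))
  # equal totals: unchanged; single subject: unchanged
  eq <- matrix(c(1, 2, 3, 2), 2, 2, dimnames = list(c("A", "B"), c("P1", "P2")))
  expect_equal(normalize_profiles(eq), eq)
  one <- m[1, , drop = FALSE]
  expect_equal(normalize_profiles(one), one)
  bad <- m; bad[1, ] <- 0
  expect_error(normalize_profiles(bad), "all-zero")
})

test_that("prevalence filter is boundary-inclusive and monotone", {
  set.seed(42)
  m <- matrix(rpois(17 * 5, 3) + 1, 17, 5,
              dimnames = list(sprintf("S%02d", 1:17), sprintf("P%d", 1:5)))
  m[1:6, "P1"] <- 0   # nonzero in 11 subjects -> removed at 12
  m[1:5, "P2"] <- 0   # nonzero in exactly 12 -> retained
  f <- filter_proteins(m, 12)
  expect_false("P1" %in% colnames(f))
  expect_true("P2" %in% colnames(f))
  expect_equal(colnames(filter_proteins(m, 1)), colnames(m))
  # monotone: raising the threshold never adds columns
  cols <- lapply(c(1, 5, 12, 17), function(k)
    tryCatch(colnames(filter_proteins(m, k)), error = function(e) character(0)))
  for (k in seq_along(cols)[-1])
    expect_true(all(cols[[k]] %in% cols[[k - 1]]))
  m0 <- m; m0[] <- 0; m0[1, ] <- 1
  expect_error(filter_proteins(m0, 12), "survive")
})

test_that("covariates append after proteins and bypass normalization and filtering", {
  set.seed(7)
  m <- matrix(rpois(6 * 4, 5) + 1, 6, 4,
              dimnames = list(sprintf("S%d", 1:6), sprintf("P%d", 1:4)))
  meta <- data.frame(subject_id = sprintf("S%d", 1:6),
                     age = 40:45, bmi = seq(22, 42, 4))
  a <- augment_covariates(m, meta, c("age", "bmi"))
  expect_equal(ncol(a), 6)
  expect_equal(colnames(a)[5:6], c("age", "bmi"))
  expect_identical(augment_covariates(m, meta, character(0)), m)
  expect_error(augment_covariates(m, meta, "height"), "height")
  # normalization leaves covariates untouched even when they dominate totals
  nn <- normalize_profiles(a)
  expect_equal(unname(nn[, "age"]), meta$age)
  # filtering never drops a covariate
  a2 <- a; a2[, "bmi"] <- 0
  f <- filter_proteins(a2, 3)
  expect_true(all(c("age", "bmi") %in% colnames(f)))
})

test_that("filtering commutes with normalization on the zero pattern", {
  set.seed(11)
  m <- matrix(rpois(17 * 20, 2), 17, 20,
              dimnames = list(sprintf("S%02d", 1:17), sprintf("P%02d", 1:20)))
  m[, 1] <- m[, 1] + 1  # guarantee positive row totals
  surv_after <- colnames(filter_proteins(normalize_profiles(m), 12))
  surv_before <- colnames(filter_proteins(m, 12))
  expect_identical(surv_after, surv_before)
})
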