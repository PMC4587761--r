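test_that("fold sizes are deterministic and form a partition", {
  f17 <- make_folds(17, 10, seed = 1)
  expect_equal(sort(lengths(f17)), c(1, 1, 1, rep(2, 7)))
  f20 <- make_folds(20, 10, seed = 1)
  expect_true(all(lengths(f20) == 2))
  for (s in c(2, 77, 1234)) {
    f <- make_folds(17, 10, seed = s)
    expect_equal(sort(unlist(f)), 1:17)
  }
  expect_error(make_folds(5, 10), "exceeds")
  expect_identical(make_folds(17, 10, seed = 5), make_folds(17, 10, seed = 5))
})

test_that("stratified folds spread both classes", {
  y <- rep(1:2, c(9, 8))
  f <- make_folds(17, 4, seed = 3, y = y)
  expect_equal(sort(unlist(f)), 1:17)
  cls2 <- vapply(f, function(ix) sum(y[ix] == 2), integer(1))
  expect_true(max(cls2) - min(cls2) <= 1)
})

test_that("performance indices use classified-only denominators and flag undefined", {
  idx <- performance_indices(c(tp = 6, fp = 3, tn = 6, fn = 2))
  expect_equal(round(idx, 3),
               c(acc = 0.706, sen = 0.750, spc = 0.667, ppv = 0.667,
                 npv = 0.750))
  perfect <- performance_indices(c(tp = 8, fp = 0, tn = 9, fn = 0))
  expect_true(all(perfect == 1))
  none_pos <- performance_indices(c(tp = 0, fp = 0, tn = 5, fn = 2))
  expect_true(is.na(none_pos["ppv"]))
  expect_false(is.na(none_pos["npv"]))
})

test_that("run summaries use the t-based margin of error", {
  runs <- data.frame(acc = rep(0.75, 20))
  s <- summarize_runs(runs)
  expect_equal(s$sd, 0)
  expect_equal(s$moe, 0)
  expect_equal(c(s$ci_low, s$ci_high), c(0.75, 0.75))
  set.seed(8)
  v <- data.frame(acc = runif(20, 0.5, 0.9))
  s2 <- summarize_runs(v)
  expect_equal(s2$moe, qt(0.975, 19) * sd(v$acc) / sqrt(20), tolerance = 1e-12)
  expect_warning(summarize_runs(data.frame(acc = c(0.5, 0.6, NA))), "undefined")
  expect_error(suppressWarnings(summarize_runs(data.frame(acc = c(0.5, NA)))),
               "fewer than 2")
})

test_that("repeated CV is deterministic and accounts for every subject", {
  d <- make_separable(n1 = 9, n2 = 8, p = 6, gap = 1.2, seed = 21)
  cv <- cv_config(repetitions = 2, base_seed = 42)
  cfg <- ensemble_config(m = 20)
  r1 <- run_repeated_cv(d$x, d$y, cv, cfg)
  r2 <- run_repeated_cv(d$x, d$y, cv, cfg)
  expect_identical(cv_index_table(r1), cv_index_table(r2))
  expect_identical(r1$runs[[1]]$predictions, r2$runs[[1]]$predictions)
  for (run in r1$runs) {
    cf <- run$confusion
    expect_equal(sum(cf), nrow(d$x))   # tp+fp+tn+fn+abstained = n
    expect_equal(length(run$fold_pairs), 10)
  }
})

test_that("fold models are trained without the held-out subjects", {
  d <- make_separable(n1 = 9, n2 = 8, p = 6, gap = 1.2, seed = 22)
  cv <- cv_config(repetitions = 1, base_seed = 7)
  cfg <- ensemble_config(m = 10)
  res <- run_repeated_cv(d$x, d$y, cv, cfg, keep_top = 10)
  folds <- make_folds(17, 10, seed = cv$base_seed + 1)
  for (fi in seq_along(folds)) {
    test <- folds[[fi]]
    ens <- train_ensemble(d$x[-test, , drop = FALSE], d$y[-test], cfg)
    expect_equal(res$runs[[1]]$fold_pairs[[fi]],
                 utils::head(ens$ranked_pairs, 10))
  }
})

test_that("strong class separation yields high cross-validated accuracy", {
  # quadrupled signature effects: per-cohort mean ACC averaged ~0.92 over
  # ten pilot draws (range 0.80-1.00); threshold set from those pilots
  accs <- vapply(1:3, function(s) {
    co <- suppressMessages(generate_cohort(cohort_spec(effect_scale = 4),
                                           seed = 30 + s))
    pm <- preprocess_cohort(co$counts, co$meta)
    y <- class_labels(co$meta)
    res <- run_repeated_cv(pm, y, cv_config(repetitions = 3,
                                            base_seed = 300 + 10 * s))
    mean(cv_index_table(res)$acc)
  }, numeric(1))
  expect_gte(mean(accs), 0.85)
  expect_true(all(accs > 0.7))
})

test_that("permutation control preserves label counts and reports coincidences", {
  d <- make_separable(n1 = 9, n2 = 8, p = 5, gap = 2, seed = 33)
  pc <- permutation_control(d$x, d$y, cv_config(repetitions = 2, base_seed = 5),
                            ensemble_config(m = 10), perm_seed = 99)
  expect_equal(sort(pc$permuted_labels), sort(d$y))
  n1 <- sum(d$y == 1)
  expect_gte(pc$n_coincident, max(0, 2 * n1 - 17))
  expect_lte(pc$n_coincident, 17)
  expect_equal(pc$n_coincident, sum(pc$permuted_labels == d$y))
})
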