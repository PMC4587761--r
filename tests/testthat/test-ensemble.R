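test_that("pair ranking matches exhaustive per-pair OLS", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(10 * 8), 10, 8)
    y <- rep(1:2, each = 5)
    rk <- rank_predictor_pairs(x, y, m = choose(8, 2))
    or <- oracle_pair_r2(x, y)
    key <- paste(rk$i, rk$j)
    expect_equal(rk$r2, or$r2[match(key, paste(or$i, or$j))],
                 tolerance = 1e-10)
    # descending order with lexicographic tie-break
    expect_true(all(diff(rk$r2) <= 1e-12))
  }
})

test_that("ranking is invariant to affine label recoding and handles exact fits", {
  set.seed(3)
  x <- matrix(rnorm(12 * 6), 12, 6)
  y12 <- rep(1:2, 6)
  x[, 2] <- (y12 - x[, 1])        # pair (1,2) reconstructs y exactly
  rk12 <- rank_predictor_pairs(x, y12, m = 15)
  rk01 <- rank_predictor_pairs(x, y12 - 1, m = 15)
  expect_equal(rk12, rk01, tolerance = 1e-12)
  expect_equal(c(rk12$i[1], rk12$j[1]), c(1, 2))
  expect_equal(rk12$r2[1], 1, tolerance = 1e-9)
})

test_that("constant predictors score zero and contracts are enforced", {
  set.seed(4)
  x <- cbind(const = rep(2, 9), matrix(rnorm(18), 9, 2))
  y <- rep(1:2, c(4, 5))
  rk <- rank_predictor_pairs(x, y, m = 3)
  expect_equal(rk$r2[rk$i == 1 & rk$j == 2],
               summary(lm(y ~ x[, 2]))$r.squared, tolerance = 1e-10)
  xc <- cbind(rep(1, 9), rep(3, 9))
  expect_equal(rank_predictor_pairs(xc, y, m = 1)$r2, 0)
  expect_error(rank_predictor_pairs(x[, 1, drop = FALSE], y, 1), "2 predictors")
  expect_error(rank_predictor_pairs(x, rep(1, 9), 1), "both classes")
})

test_that("member votes follow hull containment with abstention", {
  cfg <- ensemble_config()
  model <- list(i = 1L, j = 2L,
                hull_1 = build_hull(cbind(c(0, 2, 1), c(0, 0, 2))),
                hull_2 = build_hull(cbind(c(10, 12, 11), c(0, 0, 2))))
  expect_equal(member_vote(model, c(1, 0.7), cfg), "class1")   # centroid
  expect_equal(member_vote(model, c(50, 50), cfg), "abstain")
  expect_equal(member_vote(model, c(10, 0), cfg), "class2")    # hull_2 vertex
  excl <- ensemble_config(boundary_inclusive = FALSE)
  expect_equal(member_vote(model, c(10, 0), excl), "abstain")
  # vote exclusivity over random points and members
  for (s in 1:50) {
    set.seed(s)
    f <- fit_trimmed_hulls(matrix(rnorm(16), 8), matrix(rnorm(16, 1), 8))
    m <- list(hull_1 = f$hull_1, hull_2 = f$hull_2)
    p <- rnorm(2)
    v <- member_vote(m, p, cfg)
    expect_true(v %in% c("class1", "class2", "abstain"))
    expect_false(hull_contains(m$hull_1, p) && hull_contains(m$hull_2, p))
  }
})

test_that("training caps members at available pairs and needs two classes", {
  d <- make_separable(p = 4)
  ens <- train_ensemble(d$x, d$y, ensemble_config(m = 1000))
  expect_lte(length(ens$members), choose(4, 2))
  expect_error(train_ensemble(d$x, rep(1, nrow(d$x))), "two classes")
})

test_that("on separable data every voting member classifies training samples correctly", {
  d <- make_separable(n1 = 7, n2 = 7, p = 6, gap = 6, seed = 2)
  ens <- train_ensemble(d$x, d$y, ensemble_config(m = 15))
  pred <- predict(ens, d$x)
  voted <- pred$votes1 + pred$votes2 > 0
  expect_true(any(voted))
  expect_equal(pred$class[voted], d$y[voted])
})

test_that("majority vote with ties and empty votes abstains", {
  d <- make_separable(seed = 5)
  ens <- train_ensemble(d$x, d$y, ensemble_config(m = 10))
  out <- ensemble_classify(ens, d$x[1, ])
  expect_true(out$votes1 + out$votes2 + out$abstentions == length(ens$members))
  # synthetic tallies through a stub ensemble of four members
  stub_hull <- function(cx) build_hull(cbind(cx + c(0, 1, 0.5), c(0, 0, 1)))
  mk <- function(h1x, h2x) list(i = 1L, j = 2L,
                                hull_1 = stub_hull(h1x), hull_2 = stub_hull(h2x))
  ens2 <- structure(list(members = list(mk(0, 10), mk(0, 10),
                                        mk(10, 0), mk(20, 30)),
                         predictor_ids = c("a", "b"),
                         config = ensemble_config()),
                    class = "hull_ensemble")
  tied <- ensemble_classify(ens2, c(50, 50))       # nobody votes
  expect_true(is.na(tied$class))
  expect_equal(tied$abstentions, 4)
  two_two <- structure(ens2, class = "hull_ensemble")
  two_two$members <- list(mk(0, 10), mk(10, 0))    # 1 vs 1 at x ~ 0.5
  res <- ensemble_classify(two_two, c(0.5, 0.3))
  expect_true(is.na(res$class))
  expect_equal(c(res$votes1, res$votes2), c(1, 1))
  maj <- structure(ens2, class = "hull_ensemble")
  maj$members <- list(mk(0, 10), mk(0, 10), mk(0, 10), mk(10, 0))
  expect_equal(ensemble_classify(maj, c(0.5, 0.3))$class, 1L)
})

test_that("training is deterministic and ensembles round-trip through JSON", {
  d <- make_separable(n1 = 6, n2 = 6, p = 5, gap = 2, seed = 9)
  e1 <- train_ensemble(d$x, d$y, ensemble_config(m = 8))
  e2 <- train_ensemble(d$x, d$y, ensemble_config(m = 8))
  expect_identical(ensemble_to_json(e1), ensemble_to_json(e2))
  e3 <- ensemble_from_json(ensemble_to_json(e1))
  expect_equal(predict(e3, d$x), predict(e1, d$x))
})

test_that("removing one member changes tallies by at most one", {
  d <- make_separable(n1 = 7, n2 = 7, p = 5, gap = 3, seed = 11)
  ens <- train_ensemble(d$x, d$y, ensemble_config(m = 9))
  full <- ensemble_classify(ens, d$x[3, ])
  for (k in seq_along(ens$members)) {
    sub <- ens; sub$members <- ens$members[-k]
    part <- ensemble_classify(sub, d$x[3, ])
    expect_lte(abs(full$votes1 - part$votes1), 1)
    expect_lte(abs(full$votes2 - part$votes2), 1)
  }
})
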