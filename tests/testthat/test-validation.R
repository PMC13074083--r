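# The OECD statistics suite: cross-validation, concordance, rm2, external
# regression, Y-randomization, applicability domain.

test_that("training statistics match closed forms and a double-loop oracle", {
  withr::with_seed(21, {
    # noiseless planted data: perfect fit
    X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    y0 <- 2 + drop(X %*% c(1, -1, 0.5))
    m0 <- fit_mlr(X, y0)
    s0 <- training_stats(m0, X, y0)
    expect_equal(s0$r2, 1, tolerance = 1e-12)
    expect_equal(s0$rmse, 0, tolerance = 1e-10)
    expect_equal(s0$ccc, 1, tolerance = 1e-12)

    # noisy data: every statistic equals its naive recomputation
    y <- y0 + rnorm(20, sd = 0.5)
    m <- fit_mlr(X, y)
    s <- training_stats(m, X, y)
    yhat <- m$fitted
    n <- 20; p <- 3
    rss <- sum((y - yhat)^2); tss <- sum((y - mean(y))^2)
    expect_equal(s$r2, 1 - rss / tss, tolerance = 1e-10)
    expect_equal(s$r2_adj, 1 - (1 - s$r2) * (n - 1) / (n - p - 1),
                 tolerance = 1e-10)
    expect_equal(s$rmse, sqrt(rss / n), tolerance = 1e-10)
    expect_equal(s$mae, mean(abs(y - yhat)), tolerance = 1e-10)
    expect_error(training_stats(m, X, rep(1, 20)), "zero-variance")
  })
})

test_that("Lin's CCC follows its closed forms", {
  withr::with_seed(33, {
    o <- rnorm(50)
    expect_equal(ccc(o, o), 1, tolerance = 1e-12)
    # constant shift c: CCC = 2 s2 / (2 s2 + c^2), population moments
    s2 <- mean((o - mean(o))^2)
    expect_equal(ccc(o, o + 2), 2 * s2 / (2 * s2 + 4), tolerance = 1e-12)
    expect_equal(ccc(o, -o), -2 * s2 / (2 * s2 + (2 * mean(o))^2),
                 tolerance = 1e-12)
  })
})

test_that("hat-shortcut Q2(LOO) equals explicit refits and behaves under nulls", {
  withr::with_seed(55, {
    X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    y0 <- 2 + drop(X %*% c(1, -1, 0.5))
    expect_equal(q2_loo(X, y0), 1, tolerance = 1e-10)  # noiseless
  })
  for (s in 1:5) {
    rr <- random_regression(100 + s)
    expect_equal(q2_loo(rr$X, rr$y), oracle_q2_loo(rr$X, rr$y),
                 tolerance = 1e-10)
  }
  # permuted response against informative X at study scale (n = 81,
  # p' = 5): Q2 <= 0 in at least 95 of 100 seeded scrambles
  withr::with_seed(77, {
    rr <- random_regression(200, n = 81, p = 5, sigma = 0.3)
    bad <- sum(vapply(1:100, function(k) {
      q2_loo(rr$X, sample(rr$y)) > 0
    }, TRUE))
    expect_lte(bad, 5)
  })
})

test_that("Q2(LMO) reduces to Q2(LOO) in the limit and is seed-stable", {
  rr <- random_regression(9, n = 24)
  expect_equal(q2_lmo(rr$X, rr$y, leave_frac = 1 / 24, repeats = 24),
               q2_loo(rr$X, rr$y), tolerance = 1e-10)
  v1 <- q2_lmo(rr$X, rr$y, leave_frac = 0.2, repeats = 50, seed = 4)
  v2 <- q2_lmo(rr$X, rr$y, leave_frac = 0.2, repeats = 50, seed = 4)
  expect_identical(v1, v2)
  # noiseless: 1 at any fraction
  withr::with_seed(2, {
    X <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
    y0 <- drop(X %*% c(2, 1, -1))
    expect_equal(q2_lmo(X, y0, leave_frac = 0.3, repeats = 40), 1,
                 tolerance = 1e-8)
  })
  expect_error(q2_lmo(rr$X, rr$y, leave_frac = 0.8), "leave_frac")
})

test_that("predictive R2 matches its defining sum", {
  rr <- random_regression(3, n = 40)
  tr <- 1:30; te <- 31:40
  m <- fit_mlr(rr$X[tr, ], rr$y[tr])
  yhat <- predict(m, rr$X[te, ])
  direct <- 1 - sum((rr$y[te] - yhat)^2) /
    sum((rr$y[te] - mean(rr$y[tr]))^2)
  expect_equal(r2_pred(m, rr$X[te, ], rr$y[te], mean(rr$y[tr])), direct,
               tolerance = 1e-12)
  # perfect predictions give exactly 1
  expect_equal(r2_pred(m, rr$X[tr, ], m$fitted, mean(rr$y[tr])), 1,
               tolerance = 1e-12)
  expect_error(r2_pred(m, rr$X[0, ], numeric(0), 5), "empty")
})

test_that("rm2 metrics: identity, symmetry, and independent evaluation", {
  withr::with_seed(44, {
    o <- rnorm(30, mean = 6)
    r <- rm2_metrics(o, o)
    expect_equal(r$rm2_avg, 1, tolerance = 1e-12)
    expect_equal(r$delta_rm2, 0, tolerance = 1e-12)

    p <- o + rnorm(30, sd = 0.4)
    r1 <- rm2_metrics(o, p)
    # independent formula evaluation
    r2v <- cor(o, p)^2
    k1 <- sum(o * p) / sum(o^2)
    r01 <- 1 - sum((p - k1 * o)^2) / sum((p - mean(p))^2)
    k2 <- sum(o * p) / sum(p^2)
    r02 <- 1 - sum((o - k2 * p)^2) / sum((o - mean(o))^2)
    rm_f <- r2v * (1 - sqrt(max(r2v - r01, 0)))
    rm_r <- r2v * (1 - sqrt(max(r2v - r02, 0)))
    expect_equal(r1$rm2_avg, (rm_f + rm_r) / 2, tolerance = 1e-10)
    expect_equal(r1$delta_rm2, abs(rm_f - rm_r), tolerance = 1e-10)
    # swapping obs and pred leaves both metrics unchanged
    r2 <- rm2_metrics(p, o)
    expect_equal(r1$rm2_avg, r2$rm2_avg, tolerance = 1e-12)
    expect_equal(r1$delta_rm2, r2$delta_rm2, tolerance = 1e-12)
  })
})

test_that("external regression reproduces the published validation numbers", {
  t2 <- external_validation_pairs()
  er <- external_regression(t2$experimental, t2$calculated)
  expect_equal(er$r2, 0.862, tolerance = 0.001)
  expect_equal(er$slope, 0.616, tolerance = 0.001)
  expect_equal(er$intercept, 2.320, tolerance = 0.001)
  expect_equal(er$n, 8)
  # identity pairs
  ident <- external_regression(t2$experimental, t2$experimental)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-10)
  expect_equal(ident$r2, 1, tolerance = 1e-12)
  # closed-form least squares on seeded pairs
  withr::with_seed(8, {
    x <- rnorm(12); yv <- 0.5 * x + rnorm(12, sd = 0.2)
    er2 <- external_regression(x, yv)
    b <- cov(x, yv) / var(x)
    expect_equal(er2$slope, b, tolerance = 1e-10)
    expect_equal(er2$intercept, mean(yv) - b * mean(x), tolerance = 1e-10)
  })
  expect_error(external_regression(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("Y-randomization separates planted signal from chance correlation", {
  d <- gen_qsar_dataset(81, 10, qsar_truth(seed = 11))
  Xp <- d$X[, d$truth$planted]
  yr <- y_randomize(Xp, d$y, iterations = 400, seed = 3)
  expect_length(yr$r2_scr, 400)
  expect_gt(yr$r2_orig, yr$r2_scr_max)
  expect_gt(yr$q2_orig, max(yr$q2_scr))
  # scrambled R2 mean near the p'/(n-1) chance level
  se <- sd(yr$r2_scr) / sqrt(yr$iterations)
  expect_lt(abs(yr$r2_scr_mean - 5 / 80), 3 * se + 0.005)
  # determinism
  yr2 <- y_randomize(Xp, d$y, iterations = 400, seed = 3)
  expect_identical(yr$r2_scr, yr2$r2_scr)
})

test_that("Williams AD leverages obey the hat identities and threshold", {
  expect_equal(hstar(5, 81), 0.2222222, tolerance = 1e-6)
  rr <- random_regression(61, n = 40, p = 4)
  m <- fit_mlr(rr$X, rr$y)
  ad <- williams_ad(m, rr$X)
  tr <- ad$table[ad$table$set == "training", ]
  expect_equal(sum(tr$leverage), 5, tolerance = 1e-8)
  expect_true(all(tr$leverage >= 0))
  expect_equal(ad$h_star, 3 * 5 / 40, tolerance = 1e-12)
  # leverages agree with the fit's hat diagonal
  expect_equal(tr$leverage, m$hat, tolerance = 1e-10)
  # query at the training centroid has the minimum leverage 1/n
  centroid <- matrix(colMeans(rr$X), 1,
                     dimnames = list("q", colnames(rr$X)))
  adq <- williams_ad(m, rr$X, centroid)
  expect_equal(adq$table$leverage[adq$table$set == "query"], 1 / 40,
               tolerance = 1e-10)
  # high-leverage fraction bounded by Markov: (p'+1)/(n h*)
  expect_lte(mean(tr$high_leverage), (4 + 1) / (40 * ad$h_star))
})

test_that("validate_all composes the individual statistics consistently", {
  d <- gen_qsar_dataset(80, 8, qsar_truth(seed = 17))
  Xp <- d$X[, d$truth$planted]
  tr <- 1:56; te <- 57:80
  m <- fit_mlr(Xp[tr, ], d$y[tr])
  rep <- validate_all(m, Xp[tr, ], d$y[tr], Xp[te, ], d$y[te],
                      lmo_repeats = 100, seed = 2)
  ts <- training_stats(m, Xp[tr, ], d$y[tr])
  expect_equal(rep$r2, ts$r2, tolerance = 1e-12)
  expect_equal(rep$rmse, ts$rmse, tolerance = 1e-12)
  expect_equal(rep$q2_loo, q2_loo(Xp[tr, ], d$y[tr]), tolerance = 1e-12)
  expect_equal(rep$r2_pred,
               r2_pred(m, Xp[te, ], d$y[te], mean(d$y[tr])),
               tolerance = 1e-12)
  yhat_te <- predict(m, Xp[te, ])
  expect_equal(rep$ccc_external, ccc(d$y[te], yhat_te), tolerance = 1e-12)
  expect_equal(rep$n_train, 56)
  expect_equal(rep$n_test, 24)
  # JSON round-trip preserves every entry
  tf <- withr::local_tempfile(fileext = ".json")
  report_to_json(rep, tf)
  back <- report_from_json(tf)
  for (f in setdiff(names(rep), NULL)) {
    expect_equal(back[[f]], rep[[f]], tolerance = 1e-12)
  }
  expect_error(validate_all(m, NULL, NULL, Xp[te, ], d$y[te]), "training")
})
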