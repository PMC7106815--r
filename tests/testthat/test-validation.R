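test_that("r2, adjusted r2, F and standard error match hand values", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 2)), 0.5)
  expect_error(r_squared(c(1, 1), c(1, 2)), "constant")

  expect_equal(adjusted_r2(1, 10, 3), 1)
  expect_equal(adjusted_r2(0.5, 10, 2), (4.5 - 2) / 7, tolerance = 1e-12)
  expect_equal(adjusted_r2(0.3182, 20, 3), (19 * 0.3182 - 3) / 16,
               tolerance = 1e-12)
  expect_error(adjusted_r2(0.5, 4, 3), "degrees of freedom")

  obs <- c(0, 1, 2, 3); pred <- c(0.1, 0.9, 2.1, 2.9)
  expect_equal(f_statistic(obs, pred, 1), f_oracle(obs, pred, 1),
               tolerance = 1e-12)
  expect_equal(f_statistic(c(1, 2, 3), rep(2, 3), 1), 0)
  expect_identical(f_statistic(c(1, 2, 3), c(1, 2, 3), 1), Inf)

  res <- c(0.2, -0.2, 0.2, -0.2)
  expect_equal(std_error(res, rep(0, 4), 1, "n_minus_p_minus_1"),
               sqrt(0.16 / 2))
  expect_equal(std_error(res, rep(0, 4), 1, "n_minus_p"), sqrt(0.16 / 3))
  expect_equal(std_error(c(1, 2), c(1, 2), 0, "n_minus_p"), 0)
})

test_that("loo_cv matches hand-computed holdouts and explicit refits", {
  # mean-only model on Y = (0, 1, 2): three hand-computed folds
  d <- tibble::tibble(y = c(0, 1, 2))
  res <- loo_cv(d, "y", mean_fit_fn("y"))
  expect_equal(res$press, 4.5)
  expect_equal(res$sdep, sqrt(1.5), tolerance = 1e-12)
  expect_equal(res$q2, -1.25)

  # exactly collinear data with a linear model
  d2 <- tibble::tibble(x = 1:6, y = 2 * (1:6) + 1)
  res2 <- loo_cv(d2, "y", ols_fit_fn("y", "x"))
  expect_equal(res2$press, 0, tolerance = 1e-18)
  expect_equal(res2$q2, 1)

  # least-squares LOO equals n explicit refits; PRESS >= RSS
  for (seed in 1:10) {
    n <- 12
    d3 <- withr::with_seed(seed, tibble::tibble(
      x1 = rnorm(n), x2 = rnorm(n)))
    d3$y <- withr::with_seed(seed + 500,
                             1 + d3$x1 - 0.5 * d3$x2 + rnorm(n, sd = 0.4))
    res3 <- loo_cv(d3, "y", ols_fit_fn("y", c("x1", "x2")))
    manual <- vapply(seq_len(n), function(i) {
      beta <- ols_oracle(as.matrix(d3[-i, c("x1", "x2")]), d3$y[-i])
      drop(c(1, d3$x1[i], d3$x2[i]) %*% beta)
    }, numeric(1))
    expect_equal(res3$predictions$predicted, manual, tolerance = 1e-10)
    rss <- sum((d3$y - drop(cbind(1, as.matrix(d3[, c("x1", "x2")])) %*%
                              ols_oracle(as.matrix(d3[, c("x1", "x2")]),
                                         d3$y)))^2)
    expect_gte(res3$press, rss)
  }
})

test_that("rm2 family matches its formula and stays below r2", {
  obs <- c(1, 2, 3, 4, 5)
  res <- rm2_metrics(obs, obs)
  expect_equal(res$rm2, 1)          # pred = obs: r0^2 = r^2 = 1
  expect_equal(res$delta_rm2, 0)
  expect_equal(res$rm2_avg, 1)

  # trivial averaging arithmetic
  expect_equal((0.6 + 0.5) / 2, 0.55)
  expect_equal(abs(0.6 - 0.5), 0.1)
  # formula shape: r2 = 0.9, r0 = 0.8 gives 0.9 (1 - sqrt(0.1))
  expect_equal(0.9 * (1 - sqrt(0.9 - 0.8)), 0.61544, tolerance = 1e-4)

  for (seed in 1:10) {
    v <- withr::with_seed(seed, list(o = rnorm(8, 5), p = rnorm(8, 5)))
    got <- rm2_metrics(v$o, v$p)
    want <- rm2_oracle(v$o, v$p)
    expect_equal(got$rm2, unname(want["rm2"]), tolerance = 1e-12)
    expect_equal(got$rm2_prime, unname(want["rm2_prime"]), tolerance = 1e-12)
    expect_equal(got$delta_rm2, abs(got$rm2 - got$rm2_prime))
    r2 <- cor(v$o, v$p)^2
    expect_lte(got$rm2, r2 + 1e-12)
    expect_gte(got$delta_rm2, 0)
  }
})

test_that("external metrics match hand values", {
  expect_equal(r2_pred(c(1, 2), c(1, 2), 5), 1)
  expect_equal(r2_pred(c(1, 2), c(1, 1), 0), 0.8)
  expect_error(r2_pred(c(1, 1), c(0, 0), 1), "denominator")
  expect_equal(rmsep(c(1, 2), c(1, 2)), 0)
  expect_equal(rmsep(c(1, -1), c(0, 0)), 1)
})

test_that("k-subset external validation covers rows once and nests LOO", {
  n <- 24
  d <- withr::with_seed(13, tibble::tibble(x = rnorm(n)))
  d$y <- withr::with_seed(14, 2 * d$x + rnorm(n, sd = 0.2))

  folds6 <- kfold_external(d, "y", ols_fit_fn("y", "x"),
                           subset_size = 4, seed = 3)
  expect_equal(nrow(folds6), 6)
  expect_equal(folds6$n_test, rep(4, 6))
  preds <- attr(folds6, "predictions")
  expect_setequal(preds$row, 1:n)  # every row held out exactly once

  expect_error(kfold_external(d[1:23, ], "y", ols_fit_fn("y", "x"),
                              subset_size = 4, seed = 3), "multiple")

  # k = n reduces to leave-one-out PRESS
  foldsn <- kfold_external(d, "y", ols_fit_fn("y", "x"), k = n, seed = 5)
  pn <- attr(foldsn, "predictions")
  loo <- loo_cv(d, "y", ols_fit_fn("y", "x"))
  expect_equal(sum((pn$observed - pn$predicted)^2), loo$press,
               tolerance = 1e-10)

  # noise-free linear data: all folds perfectly predictive
  d0 <- tibble::tibble(x = 1:24, y = 3 * (1:24) - 2)
  f0 <- kfold_external(d0, "y", ols_fit_fn("y", "x"), subset_size = 4,
                       seed = 1)
  expect_equal(f0$r2_pred, rep(1, 6))
})

test_that("all metrics agree with direct formula transliterations", {
  for (seed in 1:20) {
    v <- withr::with_seed(seed, list(
      o = rnorm(15, 2), p = rnorm(15, 2, 0.8), ot = rnorm(5, 2),
      pt = rnorm(5, 2)))
    expect_equal(r_squared(v$o, v$p), r2_oracle(v$o, v$p), tolerance = 1e-12)
    expect_equal(adjusted_r2(r_squared(v$o, v$p), 15, 3),
                 r2a_oracle(r2_oracle(v$o, v$p), 15, 3), tolerance = 1e-12)
    expect_equal(f_statistic(v$o, v$p, 3), f_oracle(v$o, v$p, 3),
                 tolerance = 1e-12)
    expect_equal(std_error(v$o, v$p, 3, "n_minus_p_minus_1"),
                 se_oracle(v$o, v$p, 11), tolerance = 1e-12)
    expect_equal(r2_pred(v$ot, v$pt, mean(v$o)),
                 r2pred_oracle(v$ot, v$pt, mean(v$o)), tolerance = 1e-12)
    expect_equal(rmsep(v$ot, v$pt), rmsep_oracle(v$ot, v$pt),
                 tolerance = 1e-12)
  }
})

test_that("r2 is invariant to a joint constant shift of obs and pred", {
  for (seed in 1:5) {
    v <- withr::with_seed(seed, list(o = rnorm(10), p = rnorm(10)))
    expect_equal(r_squared(v$o + 7, v$p + 7), r_squared(v$o, v$p),
                 tolerance = 1e-10)
  }
})

test_that("validation reports bundle the metric suite", {
  d <- gen_qsar_dataset(synthetic_spec(seed = 33))
  tr <- d[d$split == "train", ]
  te <- d[d$split == "test", ]
  fit <- fit_pcr(tr, "activity", descriptors = paste0("X", 1:6),
                 p_prime = "auto")
  loo <- loo_cv(tr, "activity", function(dd)
    fit_pcr(dd, "activity", descriptors = paste0("X", 1:6),
            p_prime = fit$p_prime))
  rep <- validation_report(tr$activity, fit$fitted, p = fit$p_prime,
                           obs_test = te$activity,
                           pred_test = predict(fit, te), loo = loo)
  expect_s3_class(rep, "validation_report")
  expect_lte(rep$r2, 1)
  expect_gte(rep$press, 0)
  expect_equal(rep$delta_rm2, abs(rep$rm2 - rep$rm2_prime))
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$r2, rep$r2, tolerance = 1e-12)
  expect_equal(back$n, 20)
})
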