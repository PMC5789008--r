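test_that("mean_center removes the mean and preserves differences", {
  expect_equal(mean_center(c(1, 2, 3)), c(-1, 0, 1))
  v <- c(-1.5, 0.5, 1)
  expect_equal(mean_center(v), v)
  expect_equal(mean_center(c(4, 4, 4)), c(0, 0, 0))
  set.seed(1)
  x <- rnorm(20)
  expect_equal(mean(mean_center(x)), 0, tolerance = 1e-12)
  expect_equal(diff(mean_center(x)), diff(x))
})

test_that("noiseless moderated data is recovered exactly", {
  d <- make_interaction_data(n = 30, beta = c(2, 0.5, 0.3, 0.25), sd_e = 0)
  f <- fit_moderated(d, "y", "x", "z")
  co <- setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(unname(co["(Intercept)"]), 2, tolerance = 1e-8)
  expect_equal(unname(co["x"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(co["z"]), 0.3, tolerance = 1e-8)
  expect_equal(unname(co["x_x_z"]), 0.25, tolerance = 1e-8)
  expect_equal(f$r2_full, 1, tolerance = 1e-10)
})

test_that("model degrees of freedom follow the n = 38, 3-predictor layout", {
  d <- make_interaction_data(n = 38, sd_e = 1)
  f <- fit_moderated(d, "y", "x", "z")
  expect_equal(f$F_full$df1, 3)
  expect_equal(f$F_full$df2, 34)
  expect_equal(f$delta_F$df1, 1)
  expect_equal(f$delta_F$df2, 34)
  expect_equal(f$r2_full, f$r2_main + f$delta_r2, tolerance = 1e-10)
})

test_that("incremental F matches the published self-consistent triples", {
  expect_equal(delta_f(0.2420, 0.4561, 32, 4)$statistic, 11.02,
               tolerance = 0.005 / 11.02)
  expect_equal(delta_f(0.0583, 0.2587, 38, 4)$statistic, 9.19,
               tolerance = 0.005 / 9.19)
  expect_equal(delta_f(0.5, 0.5, 30, 4)$statistic, 0)
  expect_error(delta_f(0.2, 1.0, 30, 4), "r2_full")
  expect_error(delta_f(0.6, 0.4, 30, 4), "r2_reduced")
  expect_error(delta_f(0.1, 0.2, 4, 4), "n > p_full")
})

test_that("delta-F of the single added term equals its squared t statistic", {
  for (s in 1:5) {
    d <- make_interaction_data(n = 25 + 3 * s, beta = c(1, 0.3, 0.2, 0.1),
                               sd_e = 2, seed = s)
    f <- fit_moderated(d, "y", "x", "z")
    t3 <- f$coefficients$t[f$coefficients$term == "x_x_z"]
    expect_equal(f$delta_F$statistic, t3^2, tolerance = 1e-8)
  }
})

test_that("one-sided p halves the two-sided p in the hypothesised direction", {
  d <- make_interaction_data(n = 40, beta = c(1, 0.3, 0.2, 0.15), sd_e = 1)
  fp <- fit_moderated(d, "y", "x", "z", direction = "positive")
  fn <- fit_moderated(d, "y", "x", "z", direction = "negative")
  i <- which(fp$coefficients$term == "x_x_z")
  expect_gt(fp$coefficients$estimate[i], 0)
  expect_equal(fp$coefficients$p_one[i], fp$coefficients$p_two[i] / 2)
  expect_equal(fn$coefficients$p_one[i], 1 - fp$coefficients$p_two[i] / 2)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  d <- make_interaction_data(n = 20, sd_e = 1)
  d$w <- 2 * d$x
  expect_error(fit_moderated(d, "y", "x", "z", covariates = "w"),
               "collinear.*w")
})

test_that("simple slopes follow slope = b1 + b3 z0 with the delta-method SE", {
  # hand value on a mock fit: b1 = 0.5, b3 = 0.42, probed at sd_z = 2
  mock <- structure(list(
    coefficients = data.frame(term = c("(Intercept)", "x", "z", "x_x_z"),
                              estimate = c(1, 0.5, 0.2, 0.42)),
    x = "x", z = "z", int = "x_x_z",
    vcov = matrix(diag(1e-4, 4), 4, 4,
                  dimnames = list(c("(Intercept)", "x", "z", "x_x_z"),
                                  c("(Intercept)", "x", "z", "x_x_z"))),
    df_residual = 30, direction = "positive"), class = "moderated_fit")
  ss <- simple_slopes(mock, sd_z = 2)
  expect_equal(ss$slope[ss$at == "+1 SD"], 0.5 + 0.42 * 2)
  expect_equal(ss$slope[ss$at == "-1 SD"], 0.5 - 0.42 * 2)
  # with b3 = 0 the slope is b1 everywhere
  mock$coefficients$estimate[4] <- 0
  ss0 <- simple_slopes(mock, sd_z = 2)
  expect_equal(ss0$slope, c(0.5, 0.5))
})

test_that("simple-slope SEs equal the recentring-refit SEs", {
  d <- make_interaction_data(n = 35, beta = c(1, 0.4, 0.2, 0.3), sd_e = 1.5,
                             seed = 7)
  f <- fit_moderated(d, "y", "x", "z")
  ss <- simple_slopes(f)
  xc <- d$x - mean(d$x)
  zc <- d$z - mean(d$z)
  for (k in 1:2) {
    z0 <- ss$z0[k]
    zs <- zc - z0
    ref <- summary(lm(d$y ~ xc + zs + I(xc * zs)))$coefficients
    expect_equal(ss$slope[k], unname(ref["xc", "Estimate"]),
                 tolerance = 1e-10)
    expect_equal(ss$se[k], unname(ref["xc", "Std. Error"]),
                 tolerance = 1e-10)
  }
})

test_that("bootstrap is seed-deterministic and sign-stable on strong data", {
  d <- make_interaction_data(n = 30, beta = c(1, 0.4, 0.2, 0.5), sd_e = 0,
                             seed = 3)
  b1 <- bootstrap_interaction(d, "y", "x", "z", B = 200, seed = 11)
  b2 <- bootstrap_interaction(d, "y", "x", "z", B = 200, seed = 11)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$estimates, b2$estimates)
  expect_true(all(b1$estimates > 0))  # noiseless positive interaction
  expect_equal(b1$p, 0)
  expect_lt(b1$ci[1], b1$ci[2])
  b3 <- bootstrap_interaction(d, "y", "x", "z", B = 200, seed = 12)
  expect_false(identical(b1$estimates, b3$estimates))
  expect_error(bootstrap_interaction(d, "y", "x", "z", B = 50), "at least 100")
})

test_that("null-interaction data rejects at about the nominal bootstrap rate", {
  # 200 replicate generator datasets with beta3 = 0: the 95% percentile CI
  # should exclude 0 in about 5% of replicates (99% binomial band)
  rej <- vapply(1:200, function(i) {
    ds <- simulate_dataset(synthetic_config(seed = 20000 + i, beta3 = 0,
                                            instruments = "T"))
    d <- merge(ds$truth, ds$trait_table, by = "population_id")
    b <- bootstrap_interaction(d, "T", "dopamine", "demand", B = 400,
                               seed = i)
    b$ci[1] > 0 || b$ci[2] < 0
  }, logical(1))
  half <- 2.576 * sqrt(0.05 * 0.95 / 200)
  expect_gt(mean(rej), 0.05 - half)
  expect_lt(mean(rej), 0.05 + half)
})

test_that("outlier screen matches the quadratic-form oracle", {
  set.seed(5)
  d <- data.frame(a = rnorm(30), b = rnorm(30))
  d <- rbind(d, data.frame(a = 8, b = -8))   # planted extreme row
  d$population_id <- sprintf("P%02d", seq_len(nrow(d)))
  # row at the centroid has distance 0
  d2 <- rbind(d, data.frame(a = mean(d$a), b = mean(d$b),
                            population_id = "CTR"))
  out2 <- outlier_screen(d2, c("a", "b"))
  expect_equal(out2$dist2[out2$row == "CTR"], 0, tolerance = 1e-20)
  out <- outlier_screen(d, c("a", "b"))
  expect_identical(out$row[out$outlier], "P31")
  # direct quadratic-form oracle for the planted row
  X <- as.matrix(d[, c("a", "b")])
  dd <- X[31, ] - colMeans(X)
  expect_equal(out$dist2[31], drop(t(dd) %*% solve(cov(X)) %*% dd))
  # univariate: squared Mahalanobis distance is the squared z-score
  u <- data.frame(v = c(rnorm(20), 5))
  ou <- outlier_screen(u, "v")
  expect_equal(ou$dist2, ((u$v - mean(u$v)) / sd(u$v))^2)
  # singular covariance rejected
  d$c <- d$a
  expect_error(outlier_screen(d, c("a", "c")), "singular")
})

test_that("hierarchical blocks partition R2 exactly and test increments", {
  d <- make_interaction_data(n = 40, beta = c(1, 0.4, 0.3, 0.2), sd_e = 2,
                             seed = 2)
  d$w <- rnorm(40)
  h <- hierarchical_controls(d, "y", list("w", c("x", "z"), "x:z"))
  expect_equal(sum(h$delta_r2), h$r2[nrow(h)], tolerance = 1e-10)
  expect_true(all(h$df1 == c(1, 2, 1)))
  # the final single-term increment agrees with the focused delta-F
  f <- fit_moderated(d, "y", "x", "z", covariates = "w")
  expect_equal(h$F[3], f$delta_F$statistic, tolerance = 1e-8)
  # an all-zero predictor adds nothing
  d$zero <- 0
  h0 <- hierarchical_controls(d, "y", list(c("x", "z"), "zero"))
  expect_equal(h0$delta_r2[2], 0)
  # categorical blocks expand to dummies
  hc <- hierarchical_controls(d, "y", list("continent", c("x", "z"), "x:z"))
  expect_equal(hc$df1[1], 3)
  expect_equal(sum(hc$delta_r2), hc$r2[3], tolerance = 1e-10)
})

test_that("controlling correlated covariates shrinks the GxE increment", {
  ds <- simulate_dataset(synthetic_config(seed = 11))
  d <- Reduce(function(a, b) merge(a, b, by = "population_id"),
              list(ds$truth, ds$trait_table, ds$covariate_table))
  un <- hierarchical_controls(d, "NEO", list(c("dopamine", "demand"),
                                             "dopamine:demand"))
  co <- hierarchical_controls(d, "NEO",
                              list(c("wealth", "parasite_stress"),
                                   c("dopamine", "demand"),
                                   "dopamine:demand"))
  expect_gt(abs(cor(d$wealth, d$demand)), 0.2)  # generator builds them linked
  expect_lt(co$delta_r2[3], un$delta_r2[2])
})

test_that("Bonferroni adjustment caps at 1 and scales by m", {
  expect_equal(adjust_pvalues(0.01, m = 5), 0.05)
  expect_equal(adjust_pvalues(0.5, m = 5), 1.0)
  expect_equal(adjust_pvalues(c(0.001, 0.02, 0.4)), c(0.003, 0.06, 1.0))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("continent dummies never flip the interaction sign on clean data", {
  for (s in 1:4) {
    d <- make_interaction_data(n = 32, beta = c(1, 0.4, 0.2, 0.3), sd_e = 0,
                               seed = s)
    f0 <- fit_moderated(d, "y", "x", "z")
    f1 <- fit_moderated(d, "y", "x", "z", dummies = "continent")
    b0 <- f0$coefficients$estimate[f0$coefficients$term == "x_x_z"]
    b1 <- f1$coefficients$estimate[f1$coefficients$term == "x_x_z"]
    expect_equal(sign(b0), sign(b1))
    expect_equal(b1, 0.3, tolerance = 1e-8)
  }
})
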