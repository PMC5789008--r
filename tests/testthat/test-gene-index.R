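test_that("pairwise correlation matches the Pearson formula and records pairs", {
  x <- cbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4) + 1,
             c = -c(1, 2, 3, 4), d = c(1, 3, 2, 4))
  ce <- pairwise_correlation(x)
  expect_equal(ce$matrix["a", "b"], 1)
  expect_equal(ce$matrix["a", "c"], -1)
  expect_equal(ce$matrix["a", "d"], 0.8)  # hand Pearson on (1,2,3,4)/(1,3,2,4)
  expect_equal(diag(ce$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(ce$pair_counts == 4))
  # missing cells reduce pair counts
  x[1, "d"] <- NA
  expect_equal(pairwise_correlation(x)$pair_counts["a", "d"], 3)
  x[2, "d"] <- NA
  expect_error(pairwise_correlation(x), "fewer than 3 complete pairs")
  y <- cbind(a = 1:5, b = rep(2, 5))
  expect_error(pairwise_correlation(y), "zero-variance")
})

test_that("PSD smoothing fixes indefinite matrices and is idempotent", {
  # identity passes through
  expect_equal(smooth_to_psd(diag(4)), diag(4))
  # an already-PSD correlation matrix is unchanged
  set.seed(1)
  r <- cor(matrix(rnorm(200), 40, 5))
  expect_lt(max(abs(smooth_to_psd(r) - r)), 1e-10)
  # indefinite 3x3 repaired, matching the independent eigen-clip oracle
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_lt(min(eigen(bad)$values), 0)
  sm <- smooth_to_psd(bad)
  expect_gte(min(eigen(sm)$values), 0)
  expect_equal(diag(sm), rep(1, 3))
  expect_equal(sm, eigen_clip_oracle(bad), tolerance = 1e-6)
  # idempotence on randomly perturbed correlation matrices
  for (s in 1:5) {
    set.seed(s)
    r <- cor(matrix(rnorm(60), 12, 5))
    r[upper.tri(r)] <- r[upper.tri(r)] + runif(10, -0.3, 0.3)
    r[lower.tri(r)] <- t(r)[lower.tri(r)]
    r <- pmin(pmax(r, -1), 1)
    diag(r) <- 1
    once <- smooth_to_psd(r)
    expect_lt(max(abs(smooth_to_psd(once) - once)), 1e-6)
  }
  expect_error(smooth_to_psd(matrix(c(1, 0.2, 0.4, 1), 2, 2)), "symmetric")
})

test_that("PCA of a correlation matrix has closed-form spectra", {
  p9 <- pca_correlation(diag(9))
  expect_equal(p9$eigenvalues, rep(1, 9))
  expect_equal(p9$variance_fractions, rep(1 / 9, 9))
  r2 <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  p2 <- pca_correlation(r2)
  expect_equal(p2$eigenvalues, c(1.6, 0.4))
  expect_equal(abs(p2$loadings[, 1]), rep(sqrt(0.8), 2))
  expect_error(pca_correlation(matrix(c(1, 2, 2, 1), 2, 2)),
               "smooth_to_psd")
})

test_that("eigenvalues of a k-variable correlation matrix sum to k", {
  for (s in 1:5) {
    set.seed(s)
    k <- sample(3:9, 1)
    r <- cor(matrix(rnorm(30 * k), 30, k))
    p <- pca_correlation(r)
    expect_equal(sum(p$eigenvalues), k, tolerance = 1e-8)
    expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-8)
    expect_true(all(diff(p$eigenvalues) <= 1e-12))
  }
})

test_that("orientation flips the component iff the anchor sign disagrees", {
  l <- c(rs28363170 = -0.75, rs1800497 = 0.89, rs6280 = -0.5)
  expect_equal(orient_component(l), -l)
  expect_equal(orient_component(-l), -l)
  expect_equal(orient_component(l, anchor = "rs1800497", anchor_sign = 1), l)
  expect_error(orient_component(c(rs28363170 = 0, rs6280 = 1)), "zero")
  # the published orientation keeps mixed signs: DAT1 positive alongside a
  # negative Taq1A loading
  or <- orient_component(c(rs28363170 = -0.75, rs1800497 = 0.89))
  expect_gt(or["rs28363170"], 0)
  expect_lt(or["rs1800497"], 0)
})

test_that("Tucker phi matches hand values and its bounds", {
  expect_equal(tucker_phi(c(1, 2), c(2, 4)), 1)
  expect_equal(tucker_phi(c(1, 0), c(0, 1)), 0)
  expect_equal(tucker_phi(c(0.8, 0.6), c(0.6, 0.8)), 0.96)
  expect_error(tucker_phi(c(0, 0), c(1, 1)), "zero")
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(9)
    y <- rnorm(9)
    expect_equal(tucker_phi(x, x), 1)
    expect_lte(abs(tucker_phi(x, y)), 1)
    expect_equal(tucker_phi(x, -y), -tucker_phi(x, y))
  }
})

test_that("standardized alpha follows the Spearman-Brown composite formula", {
  expect_equal(standardized_alpha(9, 0.39), 9 * 0.39 / (1 + 8 * 0.39))
  expect_equal(standardized_alpha(5, 0), 0)
  expect_equal(standardized_alpha(5, 1), 1)
  expect_error(standardized_alpha(9, -0.2), "mean_r")
  expect_error(standardized_alpha(1, 0.5), "k")
})

test_that("mean inter-item r reflects items by their orientation sign", {
  expect_equal(mean_interitem_r(diag(4), rep(1, 4)), 0)
  r <- matrix(0.39, 3, 3)
  diag(r) <- 1
  expect_equal(mean_interitem_r(r, c(1, 1, 1)), 0.39)
  r3 <- matrix(c(1, 0.5, -0.5, 0.5, 1, -0.5, -0.5, -0.5, 1), 3, 3)
  expect_equal(mean_interitem_r(r3, c(1, 1, -1)), 0.5)
})

test_that("population scoring is a renormalised loading-weighted z composite", {
  x <- one_factor_matrix(n = 25, seed = 3)
  lam <- setNames(dopamine_polymorphisms()$loading,
                  dopamine_polymorphisms()$id)
  s <- score_populations(x, lam)
  # a population sitting at every column mean scores 0
  x2 <- rbind(x, AtMean = colMeans(x))
  s2 <- score_populations(x2, lam)
  means2 <- colMeans(x2)
  sds2 <- apply(x2, 2, sd)
  expect_equal(unname(s2["AtMean"]),
               sum(lam * (colMeans(x2) - means2) / sds2) / sum(abs(lam)))
  # a population exactly +1 SD on every positively loaded item and -1 SD on
  # every negatively loaded one scores exactly 1: build 4-row columns with
  # mean 0, sd 1 whose last entry is sign(lambda)
  cols <- lapply(sign(lam), function(s) {
    t <- (-4 * s + sqrt(40)) / 12
    c(t, t, -s - 2 * t, s)
  })
  m1 <- do.call(cbind, cols)
  rownames(m1) <- c("a", "b", "c", "Extreme")
  expect_equal(colMeans(m1), setNames(rep(0, 9), names(lam)),
               tolerance = 1e-12)
  expect_equal(apply(m1, 2, sd), setNames(rep(1, 9), names(lam)))
  sE <- score_populations(m1, lam)
  expect_equal(unname(sE["Extreme"]), 1)
  # missing one item equals the subset-weight recomputation
  x4 <- x
  x4[3, 2] <- NA
  s4 <- score_populations(x4, lam)
  z4 <- scale(x4)
  j <- !is.na(z4[3, ])
  expect_equal(unname(s4[3]), sum(lam[j] * z4[3, j]) / sum(abs(lam[j])))
  # below the item floor -> excluded with a warning
  x5 <- x
  x5[2, 1:5] <- NA
  expect_warning(s5 <- score_populations(x5, lam), "fewer than 5")
  expect_false(rownames(x)[2] %in% names(s5))
})

test_that("scores strictly increase in a positively loaded frequency", {
  x <- one_factor_matrix(n = 20, seed = 9)
  lam <- setNames(dopamine_polymorphisms()$loading,
                  dopamine_polymorphisms()$id)
  pos <- names(lam)[lam > 0][1]
  for (s in 1:5) {
    set.seed(s)
    i <- sample(nrow(x), 1)
    x2 <- x
    x2[i, pos] <- min(1, x2[i, pos] + 0.05)
    s1 <- score_populations(x, lam)
    s2 <- score_populations(x2, lam)
    expect_gt(s2[i], s1[i])
  }
})

test_that("0-100 scaling anchors the extremes", {
  expect_equal(scale_0_100(c(1, 2, 3)), c(0, 50, 100))
  set.seed(4)
  v <- rnorm(30)
  sc <- scale_0_100(v)
  expect_equal(min(sc), 0)
  expect_equal(max(sc), 100)
  expect_equal(sc[which.min(v)], 0)
  expect_equal(sc[which.max(v)], 100)
  expect_error(scale_0_100(c(5, 5, 5)), "constant")
})

test_that("the assembled index is coherent and congruent across levels", {
  x <- one_factor_matrix(n = 40, seed = 2)
  # sample level: three noisy replicates of each population row
  set.seed(2)
  xs <- x[rep(seq_len(nrow(x)), each = 3), ] +
    matrix(rnorm(3 * length(x), 0, 0.01), nrow = 3 * nrow(x))
  xs <- pmin(pmax(xs, 0), 1)
  rownames(xs) <- paste0("s", seq_len(nrow(xs)))
  gi <- build_gene_index(x, sample_matrix = xs)
  expect_equal(min(gi$scaled_scores), 0)
  expect_equal(max(gi$scaled_scores), 100)
  expect_lte(gi$alpha, 1)
  expect_equal(gi$alpha,
               standardized_alpha(9, gi$mean_r))
  expect_gt(gi$oriented_loadings[["rs28363170"]], 0)
  # one latent factor -> first components congruent across analysis levels
  expect_gte(gi$phi[["PC1"]], 0.95)
})
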