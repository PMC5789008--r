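# Population-by-polymorphism frequency matrix with the one-factor latent
# structure the index construction assumes (no sampling noise).
one_factor_matrix <- function(n = 30, seed = 1,
                              loadings = dopamine_polymorphisms()$loading,
                              base_freqs = dopamine_polymorphisms()$base_freq) {
  set.seed(seed)
  u <- rnorm(n)
  p <- plogis(outer(u, loadings) +
                matrix(qlogis(base_freqs), n, length(loadings), byrow = TRUE))
  dimnames(p) <- list(sprintf("P%03d", seq_len(n)),
                      dopamine_polymorphisms()$id)
  p
}

# Small interaction dataset built directly from known coefficients on
# mean-centred predictors (independent of the package's generator).
make_interaction_data <- function(n = 40, beta = c(2, 0.5, 0.3, 0.25),
                                  sd_e = 0, seed = 1) {
  set.seed(seed)
  x <- rnorm(n, 10, 2)
  z <- rnorm(n, 5, 3)
  xc <- x - mean(x)
  zc <- z - mean(z)
  y <- beta[1] + beta[2] * xc + beta[3] * zc + beta[4] * xc * zc +
    rnorm(n, 0, sd_e)
  data.frame(population_id = sprintf("P%02d", seq_len(n)), y = y, x = x,
             z = z, continent = rep(c("a", "b", "c", "d"), length.out = n))
}

# Independent eigenvalue-clipping oracle for PSD smoothing tests.
eigen_clip_oracle <- function(r, floor = 1e-6) {
  e <- eigen(r, symmetric = TRUE)
  m <- e$vectors %*% diag(pmax(e$values, floor)) %*% t(e$vectors)
  d <- diag(1 / sqrt(diag(m)))
  out <- d %*% m %*% d
  (out + t(out)) / 2
}
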