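#' Pairwise-complete Pearson correlations between polymorphism frequencies
#'
#' Correlates polymorphism frequency columns across populations (or samples),
#' using all rows where both columns are observed. With missing cells the
#' resulting matrix need not be positive semidefinite; pass it through
#' [smooth_to_psd()] before [pca_correlation()].
#'
#' @param x Numeric matrix (rows = populations or samples, columns =
#'   polymorphisms) or a `pop_freq_matrix` from [aggregate_population()].
#' @param min_pairs Minimum number of complete pairs required for every
#'   column pair (default 3).
#' @return An object of class `corr_estimate`: list with `matrix` (unit
#'   diagonal, symmetric) and `pair_counts` (complete pairs per cell).
#' @export
pairwise_correlation <- function(x, min_pairs = 3L) {
  if (inherits(x, "pop_freq_matrix")) x <- x$freq
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  pair_counts <- crossprod(!is.na(x))
  off <- pair_counts[upper.tri(pair_counts)]
  if (any(off < min_pairs)) {
    idx <- which(pair_counts < min_pairs & upper.tri(pair_counts), arr.ind = TRUE)
    pairs <- apply(idx, 1L, function(i)
      paste0(colnames(x)[i[1L]], "/", colnames(x)[i[2L]]))
    stop("fewer than ", min_pairs, " complete pairs for: ",
         paste(pairs, collapse = ", "), call. = FALSE)
  }
  sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[!is.finite(sds) | sds == 0], collapse = ", "),
         call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  if (anyNA(r)) {
    stop("correlation undefined for some pair (constant within overlap)",
         call. = FALSE)
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(matrix = r, pair_counts = pair_counts),
            class = "corr_estimate")
}

.corr_mat <- function(corr) {
  if (inherits(corr, "corr_estimate")) corr$matrix else as.matrix(corr)
}

#' Smooth a correlation matrix to positive semidefiniteness
#'
#' Pairwise-complete correlation matrices are frequently indefinite. The
#' conventional repair is applied: eigenvalues are clipped at a small
#' positive floor, the matrix is reconstructed from the clipped spectrum and
#' rescaled back to unit diagonal. Already-PSD matrices pass through
#' (numerically) unchanged, and the operation is idempotent up to rescaling
#' tolerance.
#'
#' @param corr A `corr_estimate` or plain symmetric correlation matrix.
#' @param floor Eigenvalue floor (default `1e-6`).
#' @return Object of the same kind as the input with a PSD, unit-diagonal
#'   matrix.
#' @export
smooth_to_psd <- function(corr, floor = 1e-6) {
  r <- .corr_mat(corr)
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-8) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  e <- eigen((r + t(r)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, floor)
  m <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(m))
  m <- m / tcrossprod(d)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- dimnames(r)
  if (inherits(corr, "corr_estimate")) {
    corr$matrix <- m
    corr
  } else {
    m
  }
}

#' Principal components of a correlation matrix
#'
#' Eigendecomposition of a PSD correlation matrix. Loadings for component c
#' are `eigenvector_c * sqrt(eigenvalue_c)`; the variance fraction of a
#' component is its eigenvalue divided by the number of variables (the trace
#' of a correlation matrix).
#'
#' @param corr A `corr_estimate` or PSD correlation matrix.
#' @return Object of class `corr_pca`: list with `eigenvalues`
#'   (nonincreasing), `loadings` (k x k matrix, rows named by variable) and
#'   `variance_fractions` (sums to 1).
#' @export
pca_correlation <- function(corr) {
  r <- .corr_mat(corr)
  e <- eigen((r + t(r)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop("correlation matrix is not positive semidefinite; ",
         "apply smooth_to_psd() first", call. = FALSE)
  }
  k <- ncol(r)
  lam <- pmax(e$values, 0)
  loadings <- sweep(e$vectors, 2L, sqrt(lam), `*`)
  rownames(loadings) <- colnames(r)
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(eigenvalues = lam,
                 loadings = loadings,
                 variance_fractions = lam / k),
            class = "corr_pca")
}

#' Fix the sign of a principal component with an anchor variable
#'
#' Eigenvector signs are arbitrary; the index convention is that the DAT1
#' 9-repeat carrier frequency loads positively (higher index = higher
#' dopaminergic function). The whole loading vector is negated iff the
#' anchor's loading disagrees with the requested sign.
#'
#' @param loadings Named numeric loading vector (names = polymorphism ids).
#' @param anchor Polymorphism id (or alias) whose sign is fixed. Default
#'   DAT1 (`rs28363170`).
#' @param anchor_sign `+1` or `-1` (default `+1`).
#' @return Oriented loading vector.
#' @export
orient_component <- function(loadings, anchor = "rs28363170", anchor_sign = 1) {
  if (is.null(names(loadings))) {
    stop("loadings must be named by polymorphism id", call. = FALSE)
  }
  anchor <- resolve_polymorphism(anchor)
  if (!anchor %in% names(loadings)) {
    stop("anchor ", anchor, " not among loading names", call. = FALSE)
  }
  a <- loadings[[anchor]]
  if (a == 0) {
    stop("anchor loading is exactly zero; orientation undefined",
         call. = FALSE)
  }
  if (sign(a) != sign(anchor_sign)) -loadings else loadings
}

#' Tucker's congruence coefficient between two loading vectors
#'
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))` — the cosine between two factor
#' loading vectors, in `[-1, 1]`; 1 for proportional vectors.
#'
#' @param x,y Numeric vectors of equal length (>= 2), neither all zero.
#' @return The congruence coefficient.
#' @export
#' @examples
#' tucker_phi(c(1, 2), c(2, 4))        # 1
#' tucker_phi(c(0.8, 0.6), c(0.6, 0.8)) # 0.96
tucker_phi <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("x and y must have equal length >= 2", call. = FALSE)
  }
  sx <- sum(x^2)
  sy <- sum(y^2)
  if (sx == 0 || sy == 0) stop("zero loading vector", call. = FALSE)
  phi <- sum(x * y) / sqrt(sx * sy)
  max(-1, min(1, phi))
}

#' Standardized Cronbach's alpha from the mean inter-item correlation
#'
#' The Spearman-Brown composite reliability of k items with average
#' inter-item correlation `mean_r`: `k * mean_r / (1 + (k - 1) * mean_r)`.
#'
#' @param k Number of items (>= 2).
#' @param mean_r Average inter-item correlation, must exceed `-1/(k-1)` and
#'   not exceed 1.
#' @return Alpha (<= 1).
#' @export
#' @examples
#' standardized_alpha(9, 0.39)  # ~0.85
standardized_alpha <- function(k, mean_r) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (!is.finite(mean_r) || mean_r <= -1 / (k - 1) || mean_r > 1) {
    stop("mean_r must lie in (-1/(k-1), 1]", call. = FALSE)
  }
  k * mean_r / (1 + (k - 1) * mean_r)
}

#' Mean inter-item correlation after reflecting items to a common direction
#'
#' Items with negative oriented loadings are reflected (their rows/columns
#' sign-flipped) so that all items point in the index direction; the mean of
#' the off-diagonal correlations of the reflected matrix is returned. This
#' is the `mean_r` that feeds [standardized_alpha()].
#'
#' @param corr A `corr_estimate` or correlation matrix.
#' @param orientation Numeric vector of signs (or oriented loadings; only
#'   signs are used), one per item.
#' @return Mean off-diagonal correlation.
#' @export
mean_interitem_r <- function(corr, orientation) {
  r <- .corr_mat(corr)
  s <- sign(orientation)
  if (length(s) != ncol(r)) {
    stop("orientation length must match the number of items", call. = FALSE)
  }
  if (any(s == 0)) stop("orientation signs must be nonzero", call. = FALSE)
  rr <- r * tcrossprod(s)
  mean(rr[upper.tri(rr)])
}

#' Score populations on the oriented first component
#'
#' Each polymorphism column is z-scored over the available populations; a
#' population's raw score is the loading-weighted sum of its available
#' z-scores with the weights renormalised over the available items,
#' `sum(lambda_j * z_pj) / sum(|lambda_j|)` over present j. Populations with
#' fewer than `min_items` observed polymorphisms are excluded with a
#' warning. This loading-weighted composite (rather than regression-method
#' factor scores) is robust to missing cells, monotone in each oriented
#' frequency, and reproducible without a covariance inverse.
#'
#' @param x Frequency matrix (rows = populations) or `pop_freq_matrix`.
#' @param oriented_loadings Named oriented loading vector from
#'   [orient_component()].
#' @param min_items Minimum observed items per population (default 5, the
#'   floor used with the nine-polymorphism panel; capped at the number of
#'   columns for smaller panels).
#' @return Named numeric vector of raw scores (excluded populations absent).
#' @export
score_populations <- function(x, oriented_loadings, min_items = 5L) {
  if (inherits(x, "pop_freq_matrix")) x <- x$freq
  x <- as.matrix(x)
  if (is.null(names(oriented_loadings)) ||
      !all(colnames(x) %in% names(oriented_loadings))) {
    stop("oriented_loadings must be named and cover every column of x",
         call. = FALSE)
  }
  lam <- oriented_loadings[colnames(x)]
  min_items <- min(min_items, ncol(x))
  z <- scale(x)  # per-column mean/sd over available rows
  present <- !is.na(z)
  n_items <- rowSums(present)
  keep <- n_items >= min_items
  if (any(!keep)) {
    warning("excluding population(s) with fewer than ", min_items,
            " observed polymorphisms: ",
            paste(rownames(x)[!keep], collapse = ", "), call. = FALSE)
  }
  z0 <- z
  z0[!present] <- 0
  num <- drop(z0 %*% lam)
  den <- drop(present %*% abs(lam))
  out <- (num / den)[keep]
  names(out) <- rownames(x)[keep]
  out
}

#' Rescale scores linearly to the 0-100 range
#'
#' `100 * (x - min) / (max - min)`: the lowest-scoring population maps to 0,
#' the highest to 100.
#'
#' @param raw_scores Numeric vector with at least two distinct values.
#' @return Vector in `[0, 100]` with minimum 0 and maximum 100.
#' @export
scale_0_100 <- function(raw_scores) {
  rng <- range(raw_scores, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    stop("scale undefined: scores are constant", call. = FALSE)
  }
  100 * (raw_scores - rng[1]) / (rng[2] - rng[1])
}

#' Build the dopaminergic gene-system index
#'
#' Full index construction: pairwise correlation of the population frequency
#' matrix, PSD smoothing, principal components, orientation of the first
#' component on the anchor polymorphism, loading-weighted population scores,
#' 0-100 rescaling, composite reliability (standardized alpha from the mean
#' reflected inter-item correlation of the smoothed matrix), and — when a
#' sample-level frequency matrix is supplied — Tucker congruence between the
#' sample-level and population-level components.
#'
#' @param x Population frequency matrix or `pop_freq_matrix`.
#' @param anchor,anchor_sign Orientation convention (see
#'   [orient_component()]); default: DAT1 9R loads positive.
#' @param sample_matrix Optional sample-by-polymorphism matrix (from
#'   [sample_frequency_matrix()]) for cross-level congruence.
#' @param n_phi Number of components compared across levels (default 3).
#' @param min_items Scoring floor passed to [score_populations()].
#' @return Object of class `gene_index`: list with `correlation` (raw),
#'   `smoothed`, `pca`, `oriented_loadings`, `raw_scores`, `scaled_scores`,
#'   `mean_r`, `alpha`, `phi` (cross-level congruence per component, `NULL`
#'   without `sample_matrix`).
#' @export
build_gene_index <- function(x, anchor = "rs28363170", anchor_sign = 1,
                             sample_matrix = NULL, n_phi = 3L,
                             min_items = 5L) {
  if (inherits(x, "pop_freq_matrix")) x <- x$freq
  corr <- pairwise_correlation(x)
  sm <- smooth_to_psd(corr)
  pca <- pca_correlation(sm)
  l1 <- pca$loadings[, 1L]
  oriented <- orient_component(l1, anchor = anchor, anchor_sign = anchor_sign)
  raw <- score_populations(x, oriented, min_items = min_items)
  scaled <- scale_0_100(raw)
  mr <- mean_interitem_r(sm, sign(oriented))
  alpha <- standardized_alpha(ncol(x), mr)

  phi <- NULL
  if (!is.null(sample_matrix)) {
    s_pca <- pca_correlation(smooth_to_psd(pairwise_correlation(sample_matrix)))
    k <- min(n_phi, ncol(pca$loadings), ncol(s_pca$loadings))
    phi <- vapply(seq_len(k), function(cc) {
      # component signs are arbitrary: align before comparing
      abs(tucker_phi(s_pca$loadings[, cc], pca$loadings[, cc]))
    }, numeric(1))
    names(phi) <- paste0("PC", seq_len(k))
  }

  structure(list(correlation = corr, smoothed = sm, pca = pca,
                 oriented_loadings = oriented, raw_scores = raw,
                 scaled_scores = scaled, mean_r = mr, alpha = alpha,
                 phi = phi),
            class = "gene_index")
}

#' @export
print.gene_index <- function(x, ...) {
  k <- length(x$oriented_loadings)
  vf <- x$pca$variance_fractions
  cat("Gene-system index over", k, "polymorphisms,",
      length(x$scaled_scores), "populations scored\n")
  cat(sprintf("  PC1 eigenvalue %.2f (%.0f%% of variance); PC1-3 together %.0f%%\n",
              x$pca$eigenvalues[1], 100 * vf[1], 100 * sum(vf[1:min(3, k)])))
  cat(sprintf("  reliability: alpha = %.2f (mean inter-item r = %.2f)\n",
              x$alpha, x$mean_r))
  if (!is.null(x$phi)) {
    cat("  cross-level Tucker phi:",
        paste(sprintf("%.2f", x$phi), collapse = ", "), "\n")
  }
  cat("  oriented PC1 loadings:\n")
  print(round(x$oriented_loadings, 2))
  invisible(x)
}
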