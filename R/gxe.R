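#' Mean-centre a numeric vector
#'
#' @param values Numeric vector of length >= 2.
#' @return The vector with mean exactly removed (differences preserved).
#' @export
mean_center <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  values - mean(values)
}

# Shared design construction for the moderated model: complete cases,
# centred (or standardized) focal predictors and covariates, treatment-coded
# dummies with the alphabetically first level as reference, and the product
# term formed from the centred variables. Returned as a plain matrix so the
# bootstrap can refit cheaply.
.gxe_design <- function(data, y, x, z, covariates = NULL, dummies = NULL,
                        standardize = FALSE) {
  vars <- c(y, x, z, covariates, dummies)
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  cc <- stats::complete.cases(data[vars])
  d <- data[cc, vars, drop = FALSE]
  n <- nrow(d)
  if (n < 8L) {
    stop("need at least 8 complete cases; have ", n, call. = FALSE)
  }
  ctr <- function(v) {
    v <- mean_center(as.numeric(v))
    if (standardize) v / stats::sd(v) else v
  }
  xc <- ctr(d[[x]])
  zc <- ctr(d[[z]])
  cols <- list()
  cols[[x]] <- xc
  cols[[z]] <- zc
  for (cv in covariates) cols[[cv]] <- ctr(d[[cv]])
  if (!is.null(dummies)) {
    f <- factor(as.character(d[[dummies]]),
                levels = sort(unique(as.character(d[[dummies]]))))
    if (nlevels(f) > 1L) {
      mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(dummies, "_", levels(f)[-1L])
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    }
  }
  int_name <- paste0(x, "_x_", z)
  cols[[int_name]] <- xc * zc
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  list(y = as.numeric(d[[y]]), X = X, int = int_name, n = n,
       sd_z = stats::sd(zc), rows = which(cc),
       x = x, z = z)
}

.ols_summary <- function(X, yv) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    keep <- q$pivot[seq_len(q$rank)]
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)], collapse = ", "),
         call. = FALSE)
  }
  beta <- qr.coef(q, yv)
  res <- yv - drop(X %*% beta)
  n <- length(yv)
  p <- ncol(X)
  df <- n - p
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  vc <- s2 * XtXinv
  dimnames(vc) <- list(colnames(X), colnames(X))
  tss <- sum((yv - mean(yv))^2)
  r2 <- 1 - sum(res^2) / tss
  list(coef = beta, vcov = vc, sigma2 = s2, df = df, r2 = r2, n = n, p = p)
}

#' Incremental F for one added term
#'
#' F statistic for the change in R-squared when a single term is added to a
#' nested OLS model: `F = (r2_full - r2_reduced) / ((1 - r2_full) / (n -
#' p_full))` on `(1, n - p_full)` degrees of freedom, where `p_full` counts
#' all estimated coefficients of the full model including the intercept.
#'
#' @param r2_reduced,r2_full R-squared of the nested and the full model.
#' @param n Number of observations.
#' @param p_full Number of coefficients in the full model (intercept
#'   included).
#' @return List with `statistic`, `df1`, `df2`, `p` (upper tail).
#' @export
#' @examples
#' delta_f(0.2420, 0.4561, 32, 4)$statistic  # ~11.02
delta_f <- function(r2_reduced, r2_full, n, p_full) {
  if (r2_full >= 1) stop("r2_full must be < 1", call. = FALSE)
  if (r2_reduced < 0 || r2_reduced > r2_full) {
    stop("need 0 <= r2_reduced <= r2_full < 1", call. = FALSE)
  }
  if (n <= p_full) stop("need n > p_full", call. = FALSE)
  df2 <- n - p_full
  f <- (r2_full - r2_reduced) / ((1 - r2_full) / df2)
  list(statistic = f, df1 = 1L, df2 = df2,
       p = stats::pf(f, 1, df2, lower.tail = FALSE))
}

#' Full-model F from R-squared
#'
#' @inheritParams delta_f
#' @return List with `statistic`, `df1 = p_full - 1`, `df2 = n - p_full`, `p`.
#' @export
model_f <- function(r2_full, n, p_full) {
  if (r2_full < 0 || r2_full >= 1) stop("r2_full must be in [0, 1)",
                                        call. = FALSE)
  if (n <= p_full) stop("need n > p_full", call. = FALSE)
  df1 <- p_full - 1L
  df2 <- n - p_full
  f <- (r2_full / df1) / ((1 - r2_full) / df2)
  list(statistic = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

.one_sided <- function(t, df, direction) {
  stats::pt(t, df, lower.tail = (direction == "negative"))
}

#' Moderated regression with incremental F and one-sided tests
#'
#' Fits the gene-by-environment model by OLS on mean-centred variables: the
#' reduced model regresses the trait on the centred focal predictor `x`
#' (gene index), the centred moderator `z` (climatic demand) and any centred
#' covariates / treatment-coded dummies; the full model adds the product
#' `x*z` formed from the centred variables. Reported are the coefficient
#' table with two-sided and one-sided p values (one-sided under the a priori
#' direction of the hypothesis: half the two-sided p when the estimate's
#' sign matches the direction, its complement otherwise), the variance
#' partition `r2_full = r2_main + delta_r2`, the incremental F of the
#' product term, the full-model F, and simple slopes at plus/minus one SD of
#' the centred moderator.
#'
#' @param data Data frame of populations.
#' @param y,x,z Column names: outcome (trait mean), focal predictor (gene
#'   index) and moderator (climatic demand).
#' @param covariates Optional character vector of covariate column names
#'   (entered, centred, in both reduced and full models).
#' @param dummies Optional name of a categorical column (e.g. continent)
#'   expanded to treatment dummies; reference level = alphabetically first.
#' @param direction `"positive"` or `"negative"`: the hypothesised sign of
#'   the interaction (and of the high-moderator simple slope).
#' @param standardize If `TRUE`, `x`, `z` and covariates are z-scored rather
#'   than merely centred, giving coefficients per SD of predictor; the
#'   outcome is left on its own scale.
#' @return Object of class `moderated_fit`; see Details. Contains
#'   `coefficients` (data frame: estimate, se, t, p_two, p_one), `n`,
#'   `r2_main`, `r2_full`, `delta_r2`, `delta_F`, `F_full`, `sd_z`,
#'   `simple_slopes`, `vcov`, `df_residual`, `direction`.
#' @export
fit_moderated <- function(data, y, x, z, covariates = NULL, dummies = NULL,
                          direction = c("positive", "negative"),
                          standardize = FALSE) {
  direction <- match.arg(direction)
  des <- .gxe_design(data, y, x, z, covariates = covariates,
                     dummies = dummies, standardize = standardize)
  X_full <- des$X
  X_red <- X_full[, setdiff(colnames(X_full), des$int), drop = FALSE]
  full <- .ols_summary(X_full, des$y)
  red <- .ols_summary(X_red, des$y)

  se <- sqrt(diag(full$vcov))
  tval <- full$coef / se
  p_two <- 2 * stats::pt(abs(tval), full$df, lower.tail = FALSE)
  p_one <- .one_sided(tval, full$df, direction)
  coefs <- data.frame(term = colnames(X_full), estimate = unname(full$coef),
                      se = unname(se), t = unname(tval),
                      p_two = unname(p_two), p_one = unname(p_one),
                      stringsAsFactors = FALSE, row.names = NULL)

  if (full$r2 > 1 - 1e-12) {
    # perfect fit (noiseless data): incremental and model F diverge
    dF <- list(statistic = Inf, df1 = 1L, df2 = full$df, p = 0)
    Ff <- list(statistic = Inf, df1 = full$p - 1L, df2 = full$df, p = 0)
  } else {
    dF <- delta_f(red$r2, full$r2, full$n, full$p)
    Ff <- model_f(full$r2, full$n, full$p)
  }

  fit <- structure(list(
    coefficients = coefs, n = full$n, p_full = full$p,
    x = des$x, z = des$z, int = des$int,
    r2_main = red$r2, r2_full = full$r2, delta_r2 = full$r2 - red$r2,
    delta_F = dF, F_full = Ff,
    sd_z = des$sd_z, vcov = full$vcov, df_residual = full$df,
    direction = direction, standardize = standardize,
    rows = des$rows), class = "moderated_fit")
  fit$simple_slopes <- simple_slopes(fit)
  fit
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("Moderated regression (n = %d, direction = %s%s)\n", x$n,
              x$direction, if (x$standardize) ", standardized predictors" else ""))
  co <- x$coefficients
  co[, -1] <- round(co[, -1], 4)
  print(co, row.names = FALSE)
  cat(sprintf("R2: main %.4f + interaction %.4f = full %.4f\n",
              x$r2_main, x$delta_r2, x$r2_full))
  cat(sprintf("Delta-F(%d, %d) = %.2f, p = %.4f; model F(%d, %d) = %.2f\n",
              x$delta_F$df1, x$delta_F$df2, x$delta_F$statistic, x$delta_F$p,
              x$F_full$df1, x$F_full$df2, x$F_full$statistic))
  cat("Simple slopes:\n")
  ss <- x$simple_slopes
  ss[, -1] <- round(ss[, -1], 4)
  print(ss, row.names = FALSE)
  invisible(x)
}

#' Simple slopes of the focal predictor at low and high moderator values
#'
#' The conditional slope of `x` at moderator value `z0` is `b_x + b_xz * z0`
#' with standard error `sqrt(var(b_x) + z0^2 var(b_xz) + 2 z0 cov(b_x,
#' b_xz))`, tested on the full model's residual df. Evaluated at `z0 =
#' -sd_z` and `+sd_z` (one SD below/above the centred moderator's mean).
#'
#' @param fit A `moderated_fit`.
#' @param sd_z Moderator SD at which to probe (default: the SD of the
#'   centred moderator over the fitted cases, stored in the fit).
#' @return Data frame with columns `at`, `z0`, `slope`, `se`, `t`, `df`,
#'   `p_one`, `p_two`.
#' @export
simple_slopes <- function(fit, sd_z = fit$sd_z) {
  co <- fit$coefficients
  b1 <- co$estimate[co$term == fit$x]
  b3 <- co$estimate[co$term == fit$int]
  vc <- fit$vcov
  if (is.null(vc)) stop("fit lacks a coefficient covariance", call. = FALSE)
  v1 <- vc[fit$x, fit$x]
  v3 <- vc[fit$int, fit$int]
  c13 <- vc[fit$x, fit$int]
  z0 <- c(-sd_z, sd_z)
  slope <- b1 + b3 * z0
  se <- sqrt(v1 + z0^2 * v3 + 2 * z0 * c13)
  tval <- slope / se
  data.frame(at = c("-1 SD", "+1 SD"), z0 = z0, slope = slope, se = se,
             t = tval, df = fit$df_residual,
             p_one = .one_sided(tval, fit$df_residual, fit$direction),
             p_two = 2 * stats::pt(abs(tval), fit$df_residual,
                                   lower.tail = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percentile bootstrap for the interaction coefficient
#'
#' Resamples populations (rows) with replacement, refits the full moderated
#' model on each resample, and summarises the interaction coefficient with a
#' percentile confidence interval and a sign-based two-tailed bootstrap p
#' value `2 * min(frac <= 0, frac >= 0)`. Centring/standardization and dummy
#' coding are done once on the original data; resamples that produce a
#' rank-deficient design are redrawn (counted), up to `10 * B` attempts.
#'
#' @inheritParams fit_moderated
#' @param B Number of bootstrap resamples (>= 100; default 1000).
#' @param seed Integer seed; the resampling is fully reproducible given it.
#' @param level Confidence level (default 0.95).
#' @return Object of class `gxe_bootstrap`: list with `estimates` (length
#'   B), `ci` (percentile bounds), `p`, `B`, `seed`, `level`, `n_redrawn`
#'   and the observed-data estimate `b3`.
#' @export
bootstrap_interaction <- function(data, y, x, z, covariates = NULL,
                                  dummies = NULL, B = 1000L, seed = 1L,
                                  level = 0.95, standardize = FALSE) {
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  des <- .gxe_design(data, y, x, z, covariates = covariates,
                     dummies = dummies, standardize = standardize)
  X <- des$X
  yv <- des$y
  n <- des$n
  j <- match(des$int, colnames(X))
  p <- ncol(X)
  obs <- stats::lm.fit(X, yv)$coefficients[[j]]

  est <- numeric(B)
  n_redrawn <- 0L
  attempts <- 0L
  with_local_seed(seed, {
    b <- 1L
    while (b <= B) {
      attempts <- attempts + 1L
      if (attempts > 10L * B) {
        stop("too many rank-deficient resamples (", n_redrawn, " redraws)",
             call. = FALSE)
      }
      idx <- sample.int(n, n, replace = TRUE)
      f <- stats::lm.fit(X[idx, , drop = FALSE], yv[idx])
      if (f$rank < p || is.na(f$coefficients[[j]])) {
        n_redrawn <- n_redrawn + 1L
        next
      }
      est[b] <- f$coefficients[[j]]
      b <- b + 1L
    }
  })
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(est, c(a, 1 - a)))
  p_boot <- min(1, 2 * min(mean(est <= 0), mean(est >= 0)))
  structure(list(estimates = est, ci = ci, p = p_boot, B = B, seed = seed,
                 level = level, n_redrawn = n_redrawn, b3 = obs),
            class = "gxe_bootstrap")
}

#' @export
print.gxe_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Percentile bootstrap (B = %d, seed = %d): b3 = %.4f, %d%% CI [%.4f, %.4f], p = %.4f\n",
    x$B, x$seed, x$b3, round(100 * x$level), x$ci[1], x$ci[2], x$p))
  if (x$n_redrawn > 0) cat("  resamples redrawn (rank-deficient):",
                           x$n_redrawn, "\n")
  invisible(x)
}

#' Multivariate outlier screen via Mahalanobis distance
#'
#' Squared Mahalanobis distance of each complete row from the multivariate
#' centroid, referred to a chi-square distribution with as many df as
#' variables; rows are flagged when the Bonferroni-adjusted p value falls
#' below `alpha`.
#'
#' @param data Data frame.
#' @param variables Character vector of numeric column names to screen on.
#' @param alpha Flagging level after Bonferroni adjustment (default 0.05).
#' @return Data frame with `row` (id or index), `dist2`, `p`, `p_adj`,
#'   `outlier`.
#' @export
outlier_screen <- function(data, variables, alpha = 0.05) {
  miss <- setdiff(variables, names(data))
  if (length(miss)) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  cc <- stats::complete.cases(data[variables])
  X <- as.matrix(data[cc, variables, drop = FALSE])
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2L) stop("need at least p + 2 complete rows", call. = FALSE)
  S <- stats::cov(X)
  ok <- tryCatch({solve(S); TRUE}, error = function(e) FALSE)
  if (!ok) stop("singular covariance matrix; drop collinear variables",
                call. = FALSE)
  d2 <- stats::mahalanobis(X, colMeans(X), S)
  pv <- stats::pchisq(d2, df = p, lower.tail = FALSE)
  p_adj <- pmin(1, pv * n)
  id <- if ("population_id" %in% names(data)) {
    as.character(data$population_id[cc])
  } else {
    rownames(data)[cc]
  }
  data.frame(row = id, dist2 = d2, p = pv, p_adj = p_adj,
             outlier = p_adj < alpha, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Hierarchical (blockwise) regression with incremental R-squared
#'
#' Enters ordered blocks of predictors and reports, at each block boundary,
#' the cumulative R-squared, the increment, and the incremental F test of
#' the added terms (via [stats::anova()] on the nested fits). Numeric terms
#' are mean-centred; a term written `"a:b"` is the product of the centred
#' `a` and `b`; a categorical term is expanded to treatment dummies. The
#' block increments sum exactly to the final model's R-squared. Supports the
#' control orders used for competitive tests, e.g.
#' `list(c("wealth", "parasite_stress"), c("dopamine", "demand"),
#' "dopamine:demand")` and
#' `list(c("demand", "wealth", "demand:wealth"), "dopamine",
#' "dopamine:demand")`.
#'
#' @param data Data frame.
#' @param y Outcome column name.
#' @param blocks List of character vectors; each element is one block of
#'   term labels entered together.
#' @return Data frame with one row per block: `block`, `terms`, `r2`,
#'   `delta_r2`, `F`, `df1`, `df2`, `p`.
#' @export
hierarchical_controls <- function(data, y, blocks) {
  if (!length(blocks)) stop("no blocks supplied", call. = FALSE)
  terms <- unique(unlist(blocks))
  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  miss <- setdiff(c(y, base_vars), names(data))
  if (length(miss)) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  cc <- stats::complete.cases(data[c(y, base_vars)])
  d <- data[cc, , drop = FALSE]
  n <- nrow(d)
  if (n < 8L) stop("need at least 8 complete cases; have ", n, call. = FALSE)

  cols <- list()
  add_var <- function(v) {
    if (is.numeric(d[[v]])) {
      cols[[v]] <<- mean_center(d[[v]])
    } else {
      f <- factor(as.character(d[[v]]),
                  levels = sort(unique(as.character(d[[v]]))))
      mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(v, "_", levels(f)[-1L])
      for (jj in colnames(mm)) cols[[jj]] <<- mm[, jj]
      names(cols)[names(cols) %in% colnames(mm)]
    }
  }
  term_cols <- list()
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) {
      if (is.numeric(d[[tm]])) {
        add_var(tm)
        term_cols[[tm]] <- tm
      } else {
        term_cols[[tm]] <- add_var(tm)
      }
    } else {
      for (pp in parts) if (is.null(cols[[pp]])) {
        if (!is.numeric(d[[pp]])) {
          stop("product terms require numeric variables: ", tm, call. = FALSE)
        }
        add_var(pp)
      }
      nm <- paste(parts, collapse = "_x_")
      cols[[nm]] <- Reduce(`*`, cols[parts])
      term_cols[[tm]] <- nm
    }
  }
  dd <- as.data.frame(cols, check.names = FALSE)
  dd[[".y"]] <- as.numeric(d[[y]])

  fits <- list(stats::lm(.y ~ 1, data = dd))
  used <- character(0)
  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    used <- c(used, unlist(term_cols[blocks[[b]]]))
    fml <- stats::as.formula(paste(".y ~",
                                   paste(sprintf("`%s`", used), collapse = "+")))
    fit <- stats::lm(fml, data = dd)
    prev <- fits[[length(fits)]]
    r2 <- summary(fit)$r.squared
    r2_prev <- summary(prev)$r.squared
    q <- prev$df.residual - fit$df.residual
    if (q > 0) {
      an <- stats::anova(prev, fit)
      Fv <- an$F[2L]
      pv <- an$`Pr(>F)`[2L]
      df1 <- an$Df[2L]
    } else {
      Fv <- NA_real_; pv <- NA_real_; df1 <- 0L
    }
    out[[b]] <- data.frame(block = b,
                           terms = paste(blocks[[b]], collapse = " + "),
                           r2 = r2, delta_r2 = r2 - r2_prev, F = Fv,
                           df1 = df1, df2 = fit$df.residual, p = pv,
                           stringsAsFactors = FALSE)
    fits[[length(fits) + 1L]] <- fit
  }
  do.call(rbind, out)
}

#' Adjust p values for multiple testing
#'
#' Bonferroni by default: `min(1, m * p)`. Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @param method Adjustment method (default `"bonferroni"`).
#' @param m Number of comparisons (default `length(pvals)`).
#' @return Adjusted p values.
#' @export
#' @examples
#' adjust_pvalues(0.01, m = 5)  # 0.05
adjust_pvalues <- function(pvals, method = "bonferroni", m = length(pvals)) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = method, n = max(m, length(pvals)))
}
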