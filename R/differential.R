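#' Filter a ScoreMatrix by coverage and sample completeness
#'
#' Cells with fewer than `min_coverage` reads become missing, and positions
#' observed in fewer than `min_sample_frac` of the samples are dropped
#' (order preserved). The defaults keep cells with more than 5 reads and
#' positions covered in at least 80% of samples.
#'
#' @param se ScoreMatrix.
#' @param min_coverage minimum reads for a cell to be kept (default 6,
#'   i.e. coverage must exceed 5).
#' @param min_sample_frac minimum fraction of non-missing samples per
#'   position (default 0.8).
#' @return filtered ScoreMatrix.
#' @export
filter_positions <- function(se, min_coverage = 6L, min_sample_frac = 0.8) {
  sc <- asm_scores(se)
  cv <- asm_coverage(se)
  low <- is.na(cv) | cv < min_coverage
  sc[low] <- NA_real_
  cv[low] <- NA_real_
  frac <- rowMeans(!is.na(sc))
  keep <- frac >= min_sample_frac
  SummarizedExperiment::assay(se, "asm") <- sc
  SummarizedExperiment::assay(se, "cov") <- cv
  se[keep, ]
}

#' Transform ASM scores before linear modelling
#'
#' `sqrt` (`sqrt(|score|)`) stabilizes the mean-variance relationship of the
#' unbounded tuple score; `arcsine` (`asin(sqrt(score))`) is the
#' variance-stabilizing transform for the proportion-scale SNP score;
#' `none` leaves scores untouched (the default choice for SNP scores
#' entering the linear model).
#'
#' @param se ScoreMatrix.
#' @param mode one of `"sqrt"`, `"arcsine"`, `"none"`.
#' @return ScoreMatrix with transformed `asm` assay.
#' @export
transform_scores <- function(se, mode = c("sqrt", "arcsine", "none")) {
  mode <- match.arg(mode)
  sc <- asm_scores(se)
  if (mode == "sqrt") {
    sc <- sqrt(abs(sc))
  } else if (mode == "arcsine") {
    if (any(sc > 1 | sc < 0, na.rm = TRUE))
      stop("arcsine transform requires scores in [0, 1]")
    sc <- asin(sqrt(sc))
  }
  SummarizedExperiment::assay(se, "asm") <- sc
  se
}

#' Per-position ordinary least squares with a contrast
#'
#' Fits `E(y_i) = X beta_i` for every position i (scores across samples as
#' response), by complete-case OLS, and returns the contrast estimate
#' `C beta_i` with its unscaled standard error and residual variance.
#' Positions left with non-positive residual degrees of freedom or a
#' rank-deficient design after missingness are dropped (count reported).
#'
#' @param se ScoreMatrix (filtered/transformed).
#' @param design numeric design matrix, samples x coefficients, full column
#'   rank; rows in the sample order of `se`.
#' @param contrast numeric contrast vector over coefficients; default picks
#'   out the last coefficient.
#' @return data.frame with columns `index` (row in `se`), `chrom`, `pos`,
#'   `beta`, `stdev_unscaled`, `sigma2`, `df_residual`, `se`.
#' @export
fit_linear_models <- function(se, design, contrast = NULL) {
  Y <- asm_scores(se)
  n <- ncol(Y); p <- ncol(design)
  stopifnot(nrow(design) == n)
  if (is.null(contrast)) contrast <- c(rep(0, p - 1), 1)
  stopifnot(length(contrast) == p)
  if (qr(design)$rank < p) stop("design matrix is not full column rank")
  key <- score_positions(se)

  ols_one <- function(y, X) {
    fit <- stats::lm.fit(X, y)
    if (fit$rank < ncol(X)) return(NULL)
    df <- length(y) - fit$rank
    if (df < 1) return(NULL)
    XtXinv <- chol2inv(chol(crossprod(X)))
    list(beta = sum(contrast * fit$coefficients),
         unscaled = sqrt(drop(t(contrast) %*% XtXinv %*% contrast)),
         sigma2 = sum(fit$residuals^2) / df,
         df = df)
  }

  if (!anyNA(Y)) {
    # one solve serves all positions when no cells are missing
    XtXinv <- chol2inv(chol(crossprod(design)))
    H <- XtXinv %*% t(design)                 # p x n
    B <- Y %*% t(H)                           # positions x p
    resid <- Y - B %*% t(design)
    df <- n - p
    sigma2 <- rowSums(resid^2) / df
    beta <- drop(B %*% contrast)
    unscaled <- sqrt(drop(t(contrast) %*% XtXinv %*% contrast))
    out <- data.frame(index = seq_len(nrow(Y)),
                      chrom = key$chrom, pos = key$pos,
                      beta = beta, stdev_unscaled = unscaled,
                      sigma2 = sigma2, df_residual = df,
                      se = unscaled * sqrt(sigma2))
    rownames(out) <- NULL
    return(out)
  }

  res <- vector("list", nrow(Y))
  n_drop <- 0L
  for (i in seq_len(nrow(Y))) {
    ok <- !is.na(Y[i, ])
    f <- ols_one(Y[i, ok], design[ok, , drop = FALSE])
    if (is.null(f)) { n_drop <- n_drop + 1L; next }
    res[[i]] <- data.frame(index = i, chrom = key$chrom[i], pos = key$pos[i],
                           beta = f$beta, stdev_unscaled = f$unscaled,
                           sigma2 = f$sigma2, df_residual = f$df,
                           se = f$unscaled * sqrt(f$sigma2))
  }
  if (n_drop) message(n_drop, " position(s) dropped (insufficient df or rank)")
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(index = integer(0), chrom = character(0),
                      pos = integer(0), beta = numeric(0),
                      stdev_unscaled = numeric(0), sigma2 = numeric(0),
                      df_residual = numeric(0), se = numeric(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Solve trigamma(y) = x by Newton iteration on 1/y (monotone, well behaved),
# as used for moment-matching the log-variance distribution.
trigamma_inverse <- function(x) {
  if (!length(x)) return(x)
  y <- 0.5 + 1 / x
  for (iter in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(-dif / y) < 1e-8) break
  }
  y
}

# Moment-match a scaled-F prior to the observed residual variances:
# log s^2 has mean log(s0^2) + digamma(df/2) - log(df/2) and variance
# trigamma(df/2) + trigamma(d0/2) under the hierarchical model, giving the
# prior df d0 via trigamma inversion and s0^2 from the mean.
estimate_var_prior <- function(sigma2, df) {
  ok <- is.finite(sigma2) & df > 0
  x <- pmax(sigma2[ok], 0)
  dfo <- df[ok]
  m <- stats::median(x)
  if (m == 0) {
    warning("more than half of the residual variances are exactly zero")
    m <- 1
  }
  # exact zeros (e.g. constant scores across samples) are offset, not
  # dropped: they carry real information about the variance spread
  x <- pmax(x, 1e-5 * m)
  z <- log(x)
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(dfo / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- mean(x)
  }
  list(df_prior = d0, s2_prior = s0)
}

#' Moderated t-statistics by empirical-Bayes variance shrinkage
#'
#' Shrinks each position's residual variance toward a common prior
#' estimated by moment-matching the distribution of log residual variances
#' across positions: posterior variance
#' `s2_post = (d0 s0^2 + df s^2) / (d0 + df)`, moderated t
#' `beta / (stdev_unscaled * sqrt(s2_post))`, two-sided p-value from a t
#' distribution on `d0 + df` degrees of freedom.
#'
#' @param fits data.frame from [fit_linear_models()] (needs >= 10 positions
#'   to estimate the prior, unless `prior_df` is supplied).
#' @param prior_df optional fixed prior degrees of freedom `d0` (0 recovers
#'   the ordinary t-statistic; `Inf` fully shrinks every variance to the
#'   prior).
#' @return the input with added columns `s2_post`, `t_mod`, `df_total`,
#'   `p`; attributes `df_prior`, `s2_prior`.
#' @export
moderate_t <- function(fits, prior_df = NULL) {
  if (all(fits$sigma2 == 0)) {
    warning("all residual variances are zero; falling back to ordinary t")
    prior_df <- 0
  }
  if (is.null(prior_df)) {
    if (nrow(fits) < 10L)
      stop("need >= 10 positions to estimate the variance prior")
    prior <- estimate_var_prior(fits$sigma2, fits$df_residual)
  } else {
    prior <- list(df_prior = prior_df,
                  s2_prior = if (prior_df > 0)
                    estimate_var_prior(fits$sigma2, fits$df_residual)$s2_prior
                  else NA_real_)
  }
  d0 <- prior$df_prior; s0 <- prior$s2_prior
  if (is.finite(d0) && d0 > 0) {
    s2_post <- (d0 * s0 + fits$df_residual * fits$sigma2) / (d0 + fits$df_residual)
  } else if (is.infinite(d0)) {
    s2_post <- rep(s0, nrow(fits))
  } else {
    s2_post <- fits$sigma2
  }
  t_mod <- fits$beta / (fits$stdev_unscaled * sqrt(s2_post))
  df_total <- fits$df_residual + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- fits
  out$s2_post <- s2_post
  out$t_mod <- t_mod
  out$df_total <- df_total
  out$p <- p
  attr(out, "df_prior") <- d0
  attr(out, "s2_prior") <- s0
  out
}

#' Smooth coefficients along the genome within clusters
#'
#' Local polynomial (loess) regression of the per-position coefficient on
#' genomic position, fitted separately within each cluster. The span is
#' expressed as a number of positions (`span_points`, converted to the
#' loess span fraction and capped at 1). Clusters with fewer than
#' `degree + 2` positions pass through unchanged.
#'
#' @param beta numeric coefficients.
#' @param pos integer genomic positions.
#' @param cluster cluster ids (from [make_clusters()]).
#' @param span_points window size in positions (default 11).
#' @param degree local polynomial degree (default 2).
#' @return numeric vector of smoothed coefficients, same order as input.
#' @export
smooth_by_cluster <- function(beta, pos, cluster, span_points = 11L, degree = 2L) {
  out <- beta
  for (idx in split(seq_along(beta), cluster)) {
    n <- length(idx)
    if (n < degree + 2L) next
    deg <- min(degree, n - 2L)
    span <- min(1, span_points / n)
    # make sure each local window holds enough points for the polynomial
    span <- max(span, min(1, (deg + 2L) / n))
    sm <- tryCatch(
      stats::predict(stats::loess(beta[idx] ~ pos[idx], span = span,
                                  degree = deg, family = "gaussian",
                                  surface = "direct")),
      error = function(e) beta[idx]
    )
    out[idx] <- sm
  }
  out
}

#' Per-position statistics for DAME detection
#'
#' Convenience pipeline: OLS fits ([fit_linear_models()]), moderated t
#' ([moderate_t()]), genomic clustering ([make_clusters()]) and
#' within-cluster smoothing ([smooth_by_cluster()]).
#'
#' @inheritParams fit_linear_models
#' @inheritParams moderate_t
#' @param maxgap cluster gap in bp (default 100).
#' @param span_points,degree see [smooth_by_cluster()].
#' @return SiteStats data.frame with `cluster` and `beta_smooth` columns
#'   added to the [moderate_t()] output.
#' @export
site_stats <- function(se, design, contrast = NULL, maxgap = 100L,
                       span_points = 11L, degree = 2L, prior_df = NULL) {
  fits <- fit_linear_models(se, design, contrast)
  stats <- moderate_t(fits, prior_df = prior_df)
  stats$cluster <- make_clusters(stats$chrom, stats$pos, maxgap = maxgap)
  stats$beta_smooth <- smooth_by_cluster(stats$beta, stats$pos, stats$cluster,
                                         span_points = span_points,
                                         degree = degree)
  stats
}
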