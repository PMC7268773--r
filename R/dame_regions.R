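#' Group genomic positions into clusters
#'
#' Adjacent positions at most `maxgap` bp apart share a cluster; clusters
#' never span chromosomes. Positions must be non-decreasing within each
#' chromosome block (ties allowed: distinct tuples can share a median
#' position).
#'
#' @param chrom chromosome per position.
#' @param pos integer positions, sorted within chromosome.
#' @param maxgap maximum gap in bp (default 100).
#' @return integer cluster ids, increasing along the input.
#' @export
make_clusters <- function(chrom, pos, maxgap = 100L) {
  stopifnot(length(chrom) == length(pos))
  if (!length(pos)) return(integer(0))
  same_chrom <- chrom[-1] == chrom[-length(chrom)]
  if (any(same_chrom & diff(pos) < 0))
    stop("positions must be sorted within each chromosome")
  if (anyDuplicated(rle(chrom)$values))
    stop("chromosome blocks must be contiguous")
  breaks <- c(TRUE, !same_chrom | diff(pos) > maxgap)
  cumsum(breaks)
}

#' Find candidate DAMEs as runs of extreme smoothed coefficients
#'
#' The threshold is the `K_quantile` quantile of `|beta_smooth|` over all
#' positions. Within each cluster, maximal runs of consecutive positions
#' whose smoothed coefficient strictly exceeds the threshold (all positive,
#' or all below the negated threshold) become candidate regions, each with
#' area `A = sum(|beta_smooth|)` over its members, the mean statistic, and
#' a direction: `"gain"` when the group of interest has higher ASM than the
#' reference (positive contrast), `"loss"` otherwise.
#'
#' @param stats data.frame with columns `chrom`, `pos`, `cluster`,
#'   `beta_smooth` (e.g. from [site_stats()]).
#' @param K_quantile quantile in \[0, 1\] defining the threshold
#'   (default 0.7).
#' @return data.frame of candidate regions: `chrom`, `start`, `end`,
#'   `n_positions`, `area`, `mean_stat`, `direction`, `cluster`.
#' @export
find_regions <- function(stats, K_quantile = 0.7) {
  bs <- stats$beta_smooth
  stopifnot(all(is.finite(bs)))
  thr <- stats::quantile(abs(bs), K_quantile, names = FALSE)
  sgn <- ifelse(bs > thr, 1L, ifelse(bs < -thr, -1L, 0L))
  out <- list()
  for (idx in split(seq_along(bs), stats$cluster)) {
    r <- rle(sgn[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0L) next
      mem <- idx[starts[k]:ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = stats$chrom[mem[1]],
        start = min(stats$pos[mem]),
        end = max(stats$pos[mem]),
        n_positions = length(mem),
        area = sum(abs(bs[mem])),
        mean_stat = mean(bs[mem]),
        direction = if (r$values[k] > 0L) "gain" else "loss",
        cluster = stats$cluster[mem[1]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_positions = integer(0),
                      area = numeric(0), mean_stat = numeric(0),
                      direction = character(0), cluster = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Enumerate non-redundant reassignments of a binary group labelling:
# distinct assignments of the group sizes over samples, identified up to a
# global label swap, excluding the observed labelling (and its mirror).
# Returns a list of logical vectors (TRUE = group of interest).
enumerate_label_permutations <- function(observed) {
  n <- length(observed)
  n1 <- sum(observed)
  sets <- utils::combn(n, n1, simplify = FALSE)
  assigns <- lapply(sets, function(s) {
    v <- rep(FALSE, n); v[s] <- TRUE; v
  })
  if (n1 * 2L == n) {
    # complement pairs are equivalent; keep the member containing sample 1
    assigns <- Filter(function(v) v[1], assigns)
    obs_canon <- if (observed[1]) observed else !observed
  } else {
    obs_canon <- observed
  }
  Filter(function(v) !identical(v, obs_canon), assigns)
}

# Fit + smooth for one design, returning the inputs find_regions needs.
smoothed_stats <- function(se, design, contrast, maxgap, span_points, degree) {
  fits <- fit_linear_models(se, design, contrast)
  fits$cluster <- make_clusters(fits$chrom, fits$pos, maxgap = maxgap)
  fits$beta_smooth <- smooth_by_cluster(fits$beta, fits$pos, fits$cluster,
                                        span_points = span_points,
                                        degree = degree)
  fits
}

#' Permutation p-values for candidate DAMEs
#'
#' Candidate regions are found on the observed fit; then, for every
#' non-redundant reassignment of the two-group label column of the design
#' (distinct assignments up to a global swap, excluding the observed one;
#' covariate columns held fixed), the fit-smooth-scan pipeline is re-run
#' with the quantile threshold recomputed within each permutation, and all
#' null region areas are pooled. Each observed region R gets
#' `p = (#\{null areas >= A_R\} + 1) / (N_null + 1)` and a
#' Benjamini-Hochberg adjusted p-value.
#'
#' @param se filtered/transformed ScoreMatrix.
#' @param design design matrix; the column selected by `contrast` must be a
#'   two-level group indicator with at least 2 samples per group.
#' @param contrast contrast vector with a single non-zero entry selecting
#'   the group column; default last column.
#' @param K_quantile threshold quantile(s); a vector yields a named list of
#'   result tables, one per K.
#' @param maxgap,span_points,degree see [site_stats()].
#' @return data.frame of DAMEs (`method = "permutation"`) sorted by
#'   `adj_p` then decreasing area, with attributes `n_permutations` and
#'   `n_null_areas`; or a named list of such tables for vector
#'   `K_quantile`.
#' @export
permutation_pvalues <- function(se, design, contrast = NULL,
                                K_quantile = 0.7, maxgap = 100L,
                                span_points = 11L, degree = 2L) {
  p <- ncol(design)
  if (is.null(contrast)) contrast <- c(rep(0, p - 1), 1)
  j <- which(contrast != 0)
  if (length(j) != 1L)
    stop("permutation method needs a contrast selecting a single group column")
  col <- design[, j]
  lev <- sort(unique(col))
  if (length(lev) != 2L) stop("group column must have exactly two levels")
  if (min(table(col)) < 2L) stop("need at least 2 samples per group")
  observed <- col == lev[2]
  perms <- enumerate_label_permutations(observed)
  if (length(perms) < 3L) {
    stop("only ", length(perms), " non-redundant permutation(s) available; ",
         "use the Simes method instead")
  }

  obs <- smoothed_stats(se, design, contrast, maxgap, span_points, degree)
  perm_stats <- lapply(perms, function(v) {
    d <- design
    d[, j] <- ifelse(v, lev[2], lev[1])
    smoothed_stats(se, d, contrast, maxgap, span_points, degree)
  })

  one_K <- function(K) {
    regions <- find_regions(obs, K_quantile = K)
    null_areas <- unlist(lapply(perm_stats, function(st) {
      find_regions(st, K_quantile = K)$area
    }))
    if (nrow(regions)) {
      n_null <- length(null_areas)
      regions$p <- vapply(regions$area, function(a) {
        (sum(null_areas >= a) + 1) / (n_null + 1)
      }, numeric(1))
      regions$adj_p <- bh_adjust(regions$p)
    } else {
      regions$p <- numeric(0)
      regions$adj_p <- numeric(0)
    }
    regions$method <- rep("permutation", nrow(regions))
    regions <- regions[order(regions$adj_p, -regions$area), , drop = FALSE]
    rownames(regions) <- NULL
    attr(regions, "n_permutations") <- length(perms)
    attr(regions, "n_null_areas") <- length(null_areas)
    regions
  }

  if (length(K_quantile) == 1L) return(one_K(K_quantile))
  out <- lapply(K_quantile, one_K)
  names(out) <- as.character(K_quantile)
  out
}

#' Simes cluster-wise p-values for DAMEs
#'
#' Combines the per-position moderated-t p-values of each cluster with the
#' Simes rule `p_c = min_i { n p_(i) / i }` over the ascending ordered
#' p-values (valid under positive dependence of the position-level tests).
#' Each cluster becomes one DAME spanning its positions; adjusted p-values
#' are Benjamini-Hochberg over clusters.
#'
#' @param stats SiteStats data.frame from [site_stats()] (needs `p`,
#'   `cluster`, `chrom`, `pos` and `beta_smooth` for area/direction).
#' @return data.frame of DAMEs (`method = "simes"`) sorted by `adj_p` then
#'   decreasing area.
#' @export
simes_pvalues <- function(stats) {
  stopifnot(all(c("p", "cluster", "chrom", "pos") %in% names(stats)))
  stat_col <- if ("beta_smooth" %in% names(stats)) "beta_smooth" else "beta"
  rows <- lapply(split(seq_len(nrow(stats)), stats$cluster), function(idx) {
    pv <- sort(stats$p[idx])
    n <- length(pv)
    p_c <- min(n * pv / seq_len(n))
    ms <- mean(stats[[stat_col]][idx])
    data.frame(chrom = stats$chrom[idx[1]],
               start = min(stats$pos[idx]),
               end = max(stats$pos[idx]),
               n_positions = n,
               area = sum(abs(stats[[stat_col]][idx])),
               mean_stat = ms,
               direction = if (ms >= 0) "gain" else "loss",
               cluster = stats$cluster[idx[1]],
               p = p_c,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out$method <- "simes"
  out <- out[order(out$adj_p, -out$area), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect DAMEs from a score matrix
#'
#' End-to-end differential pipeline: coverage/completeness filtering,
#' score transformation, per-position modelling, and region-level p-values
#' by either the permutation or the Simes strategy.
#'
#' @param se ScoreMatrix.
#' @param design,contrast see [fit_linear_models()].
#' @param method `"simes"` or `"permutation"`.
#' @param transform score transform; default `"sqrt"` for tuple scores,
#'   `"none"` for SNP scores.
#' @param min_coverage,min_sample_frac see [filter_positions()].
#' @param K_quantile,maxgap,span_points,degree see [permutation_pvalues()].
#' @return data.frame of DAMEs sorted by `adj_p` then decreasing area.
#' @export
find_dames <- function(se, design, contrast = NULL,
                       method = c("simes", "permutation"),
                       transform = NULL,
                       min_coverage = 6L, min_sample_frac = 0.8,
                       K_quantile = 0.7, maxgap = 100L,
                       span_points = 11L, degree = 2L) {
  method <- match.arg(method)
  if (is.null(transform))
    transform <- if (identical(score_kind(se), "tuple")) "sqrt" else "none"
  se <- filter_positions(se, min_coverage, min_sample_frac)
  se <- transform_scores(se, transform)
  if (method == "simes") {
    st <- site_stats(se, design, contrast, maxgap = maxgap,
                     span_points = span_points, degree = degree)
    simes_pvalues(st)
  } else {
    permutation_pvalues(se, design, contrast, K_quantile = K_quantile,
                        maxgap = maxgap, span_points = span_points,
                        degree = degree)
  }
}
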