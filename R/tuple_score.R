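#' Parameters for the tuple ASM score
#'
#' @param c pseudo-count added to each of the four tuple counts before the
#'   log-odds ratio, to avoid division by zero. Default 1 (a unit
#'   pseudo-count keeps the log-odds a standard smoothed estimator).
#' @param gamma Beta hyperparameter penalizing fully methylated or fully
#'   unmethylated tuples. Default 0.5.
#' @param epsilon allowed departure of the MM:(MM+UU) proportion from 0.5,
#'   in (0, 0.5]. Default 0.2.
#' @param max_tuple_distance maximum bp between the two CpGs of a tuple.
#' @return list of validated parameters, class `"tuple_params"`.
#' @export
tuple_params <- function(c = 1, gamma = 0.5, epsilon = 0.2,
                         max_tuple_distance = 150L) {
  if (!is.numeric(c) || c <= 0) stop("pseudo-count c must be > 0")
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon > 0.5)
    stop("epsilon must be in (0, 0.5]")
  structure(list(c = c, gamma = gamma, epsilon = epsilon,
                 max_tuple_distance = as.integer(max_tuple_distance)),
            class = "tuple_params")
}

#' Beta-probability weight of a CpG tuple
#'
#' The weight is the posterior probability that the moderated MM:(MM+UU)
#' proportion theta ~ Beta(gamma + X_MM, gamma + X_UU) lies within
#' `epsilon` of 0.5, i.e. the regularized incomplete Beta difference
#' I_{0.5+eps}(a, b) - I_{0.5-eps}(a, b). Tuples dominated by MM or by UU
#' reads (no allele specificity) receive weights near 0; balanced tuples
#' near 1. Vectorized over the counts.
#'
#' @param x_mm,x_uu reads with both CpGs methylated / both unmethylated.
#' @param gamma,epsilon see [tuple_params()].
#' @return weight in \[0, 1\].
#' @export
tuple_weight <- function(x_mm, x_uu, gamma = 0.5, epsilon = 0.2) {
  if (any(x_mm < 0) || any(x_uu < 0)) stop("counts must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")
  if (epsilon <= 0 || epsilon > 0.5) stop("epsilon must be in (0, 0.5]")
  a <- gamma + x_mm
  b <- gamma + x_uu
  w <- stats::pbeta(0.5 + epsilon, a, b) - stats::pbeta(0.5 - epsilon, a, b)
  pmin(pmax(w, 0), 1)
}

#' Tuple-based ASM score
#'
#' Weighted absolute log-odds ratio of concordant versus discordant
#' methylation in a CpG pair:
#' `| log10( (MM+c)(UU+c) / ((MU+c)(UM+c)) ) * w |`
#' with `w = tuple_weight(MM, UU, gamma, epsilon)`. High values indicate a
#' balanced mixture of fully methylated and fully unmethylated reads, the
#' read-level signature of allele-specific methylation. Vectorized.
#'
#' @param mm,mu,um,uu the four tuple read counts.
#' @param params a [tuple_params()] object.
#' @return score `>= 0`.
#' @export
tuple_asm <- function(mm, mu, um, uu, params = tuple_params()) {
  if (any(c(mm, mu, um, uu) < 0)) stop("counts must be >= 0")
  lo <- log10(((mm + params$c) * (uu + params$c)) /
              ((mu + params$c) * (um + params$c)))
  w <- tuple_weight(mm, uu, params$gamma, params$epsilon)
  abs(lo * w)
}

#' Score CpG tuples across samples
#'
#' Computes [tuple_asm()] for every tuple of every sample and assembles a
#' ScoreMatrix by outer join over the `(chrom, pos1, pos2)` key (the strand
#' column is carried upstream but ignored here). A tuple absent from a
#' sample is missing (`NA`), not zero. The reported genomic position of a
#' tuple is the floored median `floor((pos1 + pos2) / 2)`; coverage is the
#' tuple read total `MM + MU + UM + UU`.
#'
#' @param tuples named list of per-sample data.frames as returned by
#'   [read_methtuple()]; names are the sample ids.
#' @param params a [tuple_params()] object.
#' @return ScoreMatrix (`score_kind = "tuple"`) with `rowData` columns
#'   `pos1`, `pos2`.
#' @export
score_tuples <- function(tuples, params = tuple_params()) {
  stopifnot(length(tuples) >= 1L)
  if (is.null(names(tuples)) || any(names(tuples) == ""))
    stop("'tuples' must be a named list (sample ids)")
  per_sample <- lapply(names(tuples), function(s) {
    df <- tuples[[s]]
    key <- paste(df$chrom, df$pos1, df$pos2, sep = ":")
    if (anyDuplicated(key))
      stop("duplicate (chrom,pos1,pos2) rows in sample '", s, "'")
    data.table::data.table(
      chrom = df$chrom, pos1 = df$pos1, pos2 = df$pos2,
      asm = tuple_asm(df$MM, df$MU, df$UM, df$UU, params),
      cov = df$MM + df$MU + df$UM + df$UU,
      sample = s
    )
  })
  long <- data.table::rbindlist(per_sample)
  wide_s <- data.table::dcast(long, chrom + pos1 + pos2 ~ sample,
                              value.var = "asm")
  wide_c <- data.table::dcast(long, chrom + pos1 + pos2 ~ sample,
                              value.var = "cov")
  data.table::setorder(wide_s, chrom, pos1, pos2)
  data.table::setorder(wide_c, chrom, pos1, pos2)
  samples <- names(tuples)
  key <- data.frame(chrom = wide_s$chrom,
                    pos = as.integer(floor((wide_s$pos1 + wide_s$pos2) / 2)),
                    pos1 = wide_s$pos1, pos2 = wide_s$pos2)
  # re-sort by chrom then median position so downstream clustering sees
  # non-decreasing coordinates
  ord <- order(key$chrom, key$pos, key$pos1, key$pos2)
  score_matrix(key[ord, , drop = FALSE],
               as.matrix(wide_s[, samples, with = FALSE])[ord, , drop = FALSE],
               as.matrix(wide_c[, samples, with = FALSE])[ord, , drop = FALSE],
               score_kind = "tuple")
}
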