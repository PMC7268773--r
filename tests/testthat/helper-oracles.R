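# Independent brute-force oracles used across test files. These are kept
# deliberately naive (per-element loops, direct definitions) so they share
# no code path with the implementation they check.

# Per-base CIGAR walker: returns the reference position of every query base.
bf_cigar_walk <- function(cigar, start) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  q <- integer(0)
  rpos <- start
  for (op in ops) {
    n <- as.integer(sub("[A-Z=]$", "", op))
    type <- sub("^\\d+", "", op)
    if (type %in% c("M", "=", "X")) {
      q <- c(q, rpos:(rpos + n - 1L))
      rpos <- rpos + n
    } else if (type %in% c("I", "S")) {
      q <- c(q, rep(NA_integer_, n))
    } else if (type %in% c("D", "N")) {
      rpos <- rpos + n
    }
  }
  q
}

# Random valid CIGAR over M/I/D/S ops with total query length <= 30.
random_cigar <- function() {
  n_ops <- sample(1:5, 1)
  ops <- character(0)
  for (k in seq_len(n_ops)) {
    type <- if (k == 1 || k == n_ops) sample(c("M", "S"), 1)
            else sample(c("M", "I", "D"), 1)
    ops <- c(ops, paste0(sample(1:6, 1), type))
  }
  if (!grepl("M", paste(ops, collapse = ""))) ops <- c(ops, "3M")
  # merge illegal adjacent identical ops is unnecessary for the walker
  paste(ops, collapse = "")
}

# Step-up BH from the definition.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, n * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Simes combination from the definition.
bf_simes <- function(p) {
  ps <- sort(p)
  min(length(p) * ps / seq_along(ps))
}

# Cluster assignment by pairwise scan.
bf_clusters <- function(chrom, pos, maxgap) {
  id <- integer(length(pos))
  cur <- 0L
  for (i in seq_along(pos)) {
    if (i == 1 || chrom[i] != chrom[i - 1] || pos[i] - pos[i - 1] > maxgap) {
      cur <- cur + 1L
    }
    id[i] <- cur
  }
  id
}

# Exhaustive scan for sign-consistent runs above a threshold.
bf_find_regions <- function(beta, cluster, thr) {
  out <- list()
  i <- 1
  n <- length(beta)
  while (i <= n) {
    s <- if (beta[i] > thr) 1L else if (beta[i] < -thr) -1L else 0L
    if (s == 0L) { i <- i + 1; next }
    j <- i
    while (j < n && cluster[j + 1] == cluster[i] &&
           (if (s > 0) beta[j + 1] > thr else beta[j + 1] < -thr)) {
      j <- j + 1
    }
    out[[length(out) + 1]] <- data.frame(
      from = i, to = j, area = sum(abs(beta[i:j])), sign = s)
    i <- j + 1
  }
  if (!length(out)) {
    return(data.frame(from = integer(0), to = integer(0),
                      area = numeric(0), sign = integer(0)))
  }
  do.call(rbind, out)
}

# OLS contrast by explicit normal equations via stats::lm.
bf_ols_contrast <- function(y, X, contrast) {
  fit <- stats::lm(y ~ X - 1)
  beta <- sum(contrast * coef(fit))
  se <- sqrt(drop(t(contrast) %*% vcov(fit) %*% contrast))
  list(beta = beta, se = se, sigma2 = summary(fit)$sigma^2,
       df = fit$df.residual)
}

# Small toy ScoreMatrix: 2 groups x n_per samples, one chromosome.
toy_score_matrix <- function(scores, coverage = NULL, pos = NULL,
                             kind = "snp") {
  if (is.null(coverage)) {
    coverage <- matrix(10L, nrow(scores), ncol(scores))
  }
  if (is.null(pos)) pos <- seq_len(nrow(scores)) * 10L
  colnames(scores) <- colnames(coverage) <-
    paste0("s", seq_len(ncol(scores)))
  score_matrix(data.frame(chrom = "chr1", pos = pos),
               scores, coverage, score_kind = kind)
}

two_group_design <- function(n_per_group) {
  cbind(intercept = 1, group = rep(0:1, each = n_per_group))
}
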