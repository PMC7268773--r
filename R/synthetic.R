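# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the score-level semi-simulation
#'
#' Defines the study conditions for evaluating FDR control: clustered CpG
#' positions, a baseline ASM score distribution, and spiked group-specific
#' effects in a fraction of clusters. Effect sizes come from
#' inverse-transform sampling of the Beta(1, 2.5) CDF at
#' Unif(0.35, 0.75) quantiles, identical for every affected position of a
#' cluster, with random sign and a randomly chosen affected group.
#'
#' @param n_samples_per_group samples per group (two groups; default 3).
#' @param n_clusters number of CpG clusters (default 200).
#' @param prop_differential fraction of clusters truly differential
#'   (default 0.2).
#' @param effect_u_range quantile range for effect sampling
#'   (default `c(0.35, 0.75)`).
#' @param effect_beta_shape Beta shape parameters of the effect CDF
#'   (default `c(1, 2.5)`).
#' @param cluster_size_range positions per cluster, sampled uniformly
#'   (default `c(5, 30)`).
#' @param intra_gap_range bp gaps between positions within a cluster
#'   (default `c(2, 100)`).
#' @param baseline_mix baseline score mixture: probability and Beta
#'   parameters of the low- and high-ASM components.
#' @param coverage_lambda Poisson mean of simulated read coverage
#'   (default 30).
#' @param maxgap clustering gap; inter-cluster spacing always exceeds it.
#' @param seed RNG seed governing all draws.
#' @return list of validated settings, class `"sim_config"`.
#' @export
sim_config <- function(n_samples_per_group = 3L, n_clusters = 200L,
                       prop_differential = 0.2,
                       effect_u_range = c(0.35, 0.75),
                       effect_beta_shape = c(1, 2.5),
                       cluster_size_range = c(5L, 30L),
                       intra_gap_range = c(2L, 100L),
                       baseline_mix = list(p_low = 0.9,
                                           low = c(1, 8), high = c(5, 2)),
                       coverage_lambda = 30,
                       maxgap = 100L, seed = 1L) {
  stopifnot(prop_differential >= 0, prop_differential < 1,
            effect_u_range[1] > 0, effect_u_range[2] < 1,
            n_samples_per_group >= 2L)
  structure(list(n_samples_per_group = as.integer(n_samples_per_group),
                 n_clusters = as.integer(n_clusters),
                 prop_differential = prop_differential,
                 effect_u_range = effect_u_range,
                 effect_beta_shape = effect_beta_shape,
                 cluster_size_range = as.integer(cluster_size_range),
                 intra_gap_range = as.integer(intra_gap_range),
                 baseline_mix = baseline_mix,
                 coverage_lambda = coverage_lambda,
                 maxgap = as.integer(maxgap),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample effect sizes by inverse-transform sampling
#'
#' Draws `u ~ Unif(u_range)` and returns the Beta(`shape`) quantile at u;
#' for Beta(1, b) this is the closed form `1 - (1-u)^(1/b)`.
#'
#' @param n number of draws.
#' @param u_range uniform range of the quantile (default `c(0.35, 0.75)`).
#' @param shape Beta shape parameters (default `c(1, 2.5)`).
#' @return numeric effect sizes in (0, 1).
#' @export
sample_effect_size <- function(n = 1L, u_range = c(0.35, 0.75),
                               shape = c(1, 2.5)) {
  u <- stats::runif(n, u_range[1], u_range[2])
  stats::qbeta(u, shape[1], shape[2])
}

#' Simulate a score matrix with planted differential clusters
#'
#' Lays out `n_clusters` clusters of CpG positions on one chromosome
#' (intra-cluster gaps within `intra_gap_range`, inter-cluster gaps above
#' `maxgap`) and emulates the sampling process behind the SNP ASM score:
#' each position has a true allele methylation differential drawn from a
#' two-component Beta mixture (mostly low-ASM methylome, occasional
#' high-ASM tail); each cell realizes the score as the absolute difference
#' of two binomial methylation proportions at the simulated per-allele
#' coverage, so positions carry locus-level signal shared across samples
#' plus read-sampling noise. Effects are then planted: in
#' `prop_differential` of the clusters, a contiguous block of positions
#' (uniform random start and length >= 1) receives one signed effect size
#' added to one randomly chosen group's scores; scores are truncated to
#' \[0, 1\]. Coverage is Poisson (shifted to be at least 2).
#'
#' @param cfg a [sim_config()].
#' @return list with `se` (ScoreMatrix, `score_kind = "snp"`, samples
#'   `g1_*`/`g2_*`, `rowData` column `cluster`) and `truth` (list with
#'   per-cluster data.frame `clusters` and per-position data.frame
#'   `positions` flagging affected positions).
#' @export
simulate_score_matrix <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    sizes <- sample(seq(cfg$cluster_size_range[1], cfg$cluster_size_range[2]),
                    cfg$n_clusters, replace = TRUE)
    n_pos <- sum(sizes)
    cluster <- rep(seq_len(cfg$n_clusters), sizes)
    gaps <- sample(seq(cfg$intra_gap_range[1], cfg$intra_gap_range[2]),
                   n_pos, replace = TRUE)
    inter <- sample(seq(cfg$maxgap + 51L, cfg$maxgap + 900L),
                    cfg$n_clusters, replace = TRUE)
    step <- gaps
    first <- !duplicated(cluster)
    step[first] <- inter
    pos <- cumsum(step)

    n <- cfg$n_samples_per_group
    samples <- c(paste0("g1_", seq_len(n)), paste0("g2_", seq_len(n)))
    n_cells <- n_pos * 2L * n
    # true per-locus allele differential, shared across samples
    comp <- stats::runif(n_pos) < cfg$baseline_mix$p_low
    delta <- ifelse(comp,
                    stats::rbeta(n_pos, cfg$baseline_mix$low[1],
                                 cfg$baseline_mix$low[2]),
                    stats::rbeta(n_pos, cfg$baseline_mix$high[1],
                                 cfg$baseline_mix$high[2]))
    p_lo <- stats::runif(n_pos) * (1 - delta)
    p_hi <- p_lo + delta
    coverage <- matrix(stats::rpois(n_cells, cfg$coverage_lambda - 2) + 2L,
                       nrow = n_pos, ncol = 2L * n,
                       dimnames = list(NULL, samples))
    # realized score per cell: |binomial proportion difference| between the
    # two alleles at the cell's per-allele coverage
    cov_ref <- matrix(pmax(1L, pmin(coverage - 1L,
                                    stats::rbinom(n_cells, coverage, 0.5))),
                      nrow = n_pos)
    cov_alt <- coverage - cov_ref
    m_ref <- matrix(stats::rbinom(n_cells, cov_ref, rep(p_hi, 2L * n)),
                    nrow = n_pos)
    m_alt <- matrix(stats::rbinom(n_cells, cov_alt, rep(p_lo, 2L * n)),
                    nrow = n_pos)
    scores <- abs(m_ref / cov_ref - m_alt / cov_alt)
    dimnames(scores) <- list(NULL, samples)

    n_diff <- round(cfg$prop_differential * cfg$n_clusters)
    diff_clusters <- if (n_diff > 0) sort(sample(cfg$n_clusters, n_diff)) else integer(0)
    affected <- rep(FALSE, n_pos)
    truth_rows <- vector("list", cfg$n_clusters)
    for (cl in seq_len(cfg$n_clusters)) {
      idx <- which(cluster == cl)
      is_diff <- cl %in% diff_clusters
      eff <- sgn <- NA_real_; grp <- NA_integer_
      a_start <- a_end <- NA_integer_
      if (is_diff) {
        len <- sample.int(length(idx), 1L)
        start_at <- sample.int(length(idx) - len + 1L, 1L)
        block <- idx[start_at:(start_at + len - 1L)]
        eff <- sample_effect_size(1L, cfg$effect_u_range, cfg$effect_beta_shape)
        sgn <- sample(c(-1, 1), 1L)
        grp <- sample(1:2, 1L)
        cols <- if (grp == 1L) seq_len(n) else n + seq_len(n)
        scores[block, cols] <- pmin(1, pmax(0, scores[block, cols] + sgn * eff))
        affected[block] <- TRUE
        a_start <- pos[block[1]]; a_end <- pos[block[length(block)]]
      }
      truth_rows[[cl]] <- data.frame(
        cluster = cl, chrom = "chr1",
        start = pos[idx[1]], end = pos[idx[length(idx)]],
        n_positions = length(idx), differential = is_diff,
        effect = eff, sign = sgn, group = grp,
        affected_start = a_start, affected_end = a_end
      )
    }
    se <- score_matrix(
      data.frame(chrom = "chr1", pos = pos, cluster = cluster),
      scores, coverage, score_kind = "snp"
    )
    truth <- list(
      clusters = do.call(rbind, truth_rows),
      positions = data.frame(chrom = "chr1", pos = pos, cluster = cluster,
                             affected = affected)
    )
    list(se = se, truth = truth)
  })
}

#' Evaluate DAME calls against simulation truth
#'
#' A call is a true positive when it overlaps at least one truly affected
#' position; a differential cluster counts as detected when at least one
#' call overlaps its affected positions. TPR = detected differential
#' clusters / all differential clusters; FDR = false calls / all calls
#' (0 when nothing is called).
#'
#' @param dames DAME data.frame (needs `chrom`, `start`, `end`, `adj_p`).
#' @param truth truth list from [simulate_score_matrix()].
#' @param adj_p_thresholds adjusted-p cutoffs (default 0.01, 0.05, 0.1).
#' @return data.frame with one row per threshold: `threshold`, `n_called`,
#'   `n_true_calls`, `TPR`, `FDR`.
#' @export
evaluate_detection <- function(dames, truth,
                               adj_p_thresholds = c(0.01, 0.05, 0.1)) {
  aff <- truth$positions[truth$positions$affected, , drop = FALSE]
  n_diff <- sum(truth$clusters$differential)
  res <- lapply(adj_p_thresholds, function(thr) {
    calls <- dames[!is.na(dames$adj_p) & dames$adj_p <= thr, , drop = FALSE]
    if (!nrow(calls)) {
      return(data.frame(threshold = thr, n_called = 0L, n_true_calls = 0L,
                        TPR = 0, FDR = 0))
    }
    hit <- vapply(seq_len(nrow(calls)), function(i) {
      any(aff$chrom == calls$chrom[i] &
            aff$pos >= calls$start[i] & aff$pos <= calls$end[i])
    }, logical(1))
    detected <- vapply(which(truth$clusters$differential), function(cl) {
      a <- aff[aff$cluster == truth$clusters$cluster[cl], , drop = FALSE]
      any(vapply(seq_len(nrow(calls)), function(i) {
        any(a$chrom == calls$chrom[i] &
              a$pos >= calls$start[i] & a$pos <= calls$end[i])
      }, logical(1)))
    }, logical(1))
    data.frame(threshold = thr, n_called = nrow(calls),
               n_true_calls = sum(hit),
               TPR = if (n_diff) sum(detected) / n_diff else 0,
               FDR = (nrow(calls) - sum(hit)) / nrow(calls))
  })
  do.call(rbind, res)
}

#' Simulate read-level biallelic methylation
#'
#' Generates per-sample read records (the [extract_read_meth()] format)
#' for a list of region specifications, each with two alleles: every read
#' picks an allele with probability 0.5, then every CpG call is Bernoulli
#' with that allele's methylation probability. Region kinds encode the
#' biology being emulated: `imprinted` / `xci_female` (one allele
#' methylated, one not; no SNP), `sd_asm` (same, with an allele-tagging
#' SNP base written into the read), `null_methylated` /
#' `null_unmethylated` (both alleles alike), `heterogeneous` (bimodal
#' reads without any allele tag).
#'
#' @param specs list of region specs; each a list with `chrom`,
#'   `cpg_pos` (integer vector), `coverage`, `probs` (length-2 per-allele
#'   methylation probabilities, or a named list of such vectors per
#'   sample), and optionally `snp_pos`, `snp_ref` (default `"A"`),
#'   `snp_alt` (default `"G"`).
#' @param sample_ids character vector of samples to simulate.
#' @param seed RNG seed.
#' @return list with `reads` (named list of read-record lists per sample)
#'   and `snps` (named list of het-SNP data.frames per sample, possibly
#'   empty).
#' @export
simulate_reads <- function(specs, sample_ids, seed = 1L) {
  with_seed(seed, {
    reads <- stats::setNames(vector("list", length(sample_ids)), sample_ids)
    snps <- stats::setNames(vector("list", length(sample_ids)), sample_ids)
    for (s in sample_ids) {
      recs <- list()
      snp_rows <- list()
      for (ri in seq_along(specs)) {
        spec <- specs[[ri]]
        probs <- if (is.list(spec$probs)) spec$probs[[s]] else spec$probs
        stopifnot(length(probs) == 2L)
        snp_ref <- if (is.null(spec$snp_ref)) "A" else spec$snp_ref
        snp_alt <- if (is.null(spec$snp_alt)) "G" else spec$snp_alt
        has_snp <- !is.null(spec$snp_pos)
        span <- range(c(spec$cpg_pos, if (has_snp) spec$snp_pos))
        start <- span[1] - 2L
        len <- span[2] + 2L - start + 1L
        for (k in seq_len(spec$coverage)) {
          allele <- sample(1:2, 1L)
          meth <- stats::runif(length(spec$cpg_pos)) < probs[allele]
          seq_chars <- rep("T", len)
          xm_chars <- rep(".", len)
          off <- spec$cpg_pos - start + 1L
          seq_chars[off] <- "C"
          xm_chars[off] <- ifelse(meth, "Z", "z")
          if (has_snp) {
            soff <- spec$snp_pos - start + 1L
            seq_chars[soff] <- if (allele == 1L) snp_ref else snp_alt
          }
          calls <- data.frame(pos = spec$cpg_pos,
                              state = ifelse(meth, "methylated", "unmethylated"),
                              stringsAsFactors = FALSE)
          recs[[length(recs) + 1L]] <- list(
            read_id = sprintf("%s_r%d_%d", s, ri, k),
            chrom = spec$chrom, start = start, mapq = 60L,
            seq = paste(seq_chars, collapse = ""),
            qual = strrep("I", len),
            ref_pos = start:(start + len - 1L),
            calls = calls
          )
        }
        if (has_snp) {
          snp_rows[[length(snp_rows) + 1L]] <- data.frame(
            chrom = spec$chrom, pos = spec$snp_pos,
            ref = snp_ref, alt = snp_alt, sample_id = s,
            stringsAsFactors = FALSE
          )
        }
      }
      reads[[s]] <- recs
      snps[[s]] <- if (length(snp_rows)) do.call(rbind, snp_rows)
                   else data.frame(chrom = character(0), pos = integer(0),
                                   ref = character(0), alt = character(0),
                                   sample_id = character(0))
    }
    list(reads = reads, snps = snps)
  })
}

#' Count CpG-pair tuples from read records
#'
#' Emulates the CpG-pair counting step: for every read, consecutive CpG
#' calls form tuples and contribute one of MM/MU/UM/UU; overlapping mate
#' pairs are de-duplicated per (read id, pair). Pairs farther apart than
#' `max_tuple_distance` are skipped.
#'
#' @param records list of read records.
#' @param max_tuple_distance maximum bp between the two CpGs.
#' @return data.frame in the [read_methtuple()] layout.
#' @export
tuple_counts_from_reads <- function(records, max_tuple_distance = 150L) {
  counts <- new.env(hash = TRUE, parent = emptyenv())
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (r in records) {
    cc <- r$calls
    if (nrow(cc) < 2L) next
    for (k in seq_len(nrow(cc) - 1L)) {
      p1 <- cc$pos[k]; p2 <- cc$pos[k + 1L]
      if (p2 - p1 > max_tuple_distance) next
      dkey <- paste0(r$read_id, "#", r$chrom, ":", p1, ":", p2)
      if (!is.null(seen[[dkey]])) next
      seen[[dkey]] <- TRUE
      state <- paste0(ifelse(cc$state[k] == "methylated", "M", "U"),
                      ifelse(cc$state[k + 1L] == "methylated", "M", "U"))
      key <- paste(r$chrom, p1, p2, sep = ":")
      cur <- counts[[key]]
      if (is.null(cur)) cur <- c(MM = 0L, MU = 0L, UM = 0L, UU = 0L)
      cur[state] <- cur[state] + 1L
      counts[[key]] <- cur
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    return(data.frame(chrom = character(0), strand = character(0),
                      pos1 = integer(0), pos2 = integer(0),
                      MM = integer(0), MU = integer(0),
                      UM = integer(0), UU = integer(0)))
  }
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  tab <- do.call(rbind, lapply(keys, function(k) counts[[k]]))
  out <- data.frame(chrom = parts[, 1], strand = "*",
                    pos1 = as.integer(parts[, 2]),
                    pos2 = as.integer(parts[, 3]),
                    MM = tab[, "MM"], MU = tab[, "MU"],
                    UM = tab[, "UM"], UU = tab[, "UU"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos1, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize simulated reads as SAM
#'
#' Writes a minimal single-end SAM file with the bismark-style
#' methylation-call string in the `XM` tag, so simulated reads can be run
#' through the BAM-reading path.
#'
#' @param records list of read records.
#' @param path output SAM path.
#' @param chrom_lengths named integer vector for the header; defaults to
#'   generous lengths covering the records.
#' @export
write_sam <- function(records, path, chrom_lengths = NULL) {
  chroms <- unique(vapply(records, `[[`, character(1), "chrom"))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) {
      max(vapply(records, function(r) {
        if (r$chrom == ch) max(r$ref_pos, na.rm = TRUE) else 0L
      }, integer(1))) + 1000L
    }, integer(1))
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), chrom_lengths))
  lines <- vapply(records, function(r) {
    len <- nchar(r$seq)
    xm <- rep(".", len)
    off <- r$calls$pos - r$start + 1L
    xm[off] <- ifelse(r$calls$state == "methylated", "Z", "z")
    paste(r$read_id, 0L, r$chrom, r$start, r$mapq,
          paste0(len, "M"), "*", 0L, 0L, r$seq, r$qual,
          paste0("XM:Z:", paste(xm, collapse = "")),
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Serialize heterozygous SNPs as a minimal VCF
#'
#' Writes a VCF v4.2 with a single sample column carrying genotype 0/1 for
#' every record.
#'
#' @param snps data.frame with `chrom`, `pos`, `ref`, `alt`, `sample_id`
#'   (one sample).
#' @param path output path.
#' @export
write_vcf <- function(snps, path) {
  sample_id <- if (nrow(snps)) snps$sample_id[1] else "sample1"
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_id, sep = "\t"))
  body <- if (nrow(snps)) {
    paste(snps$chrom, snps$pos, ".", snps$ref, snps$alt, ".", "PASS", ".",
          "GT", "0/1", sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
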