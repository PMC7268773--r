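#' SNP-based ASM score for one CpG site
#'
#' Absolute difference in methylation proportion between the reads carrying
#' the reference allele and those carrying the alternative allele at a
#' linked heterozygous SNP: `| ref_M/ref_tot - alt_M/alt_tot |`. 1 means one
#' allele fully methylated and the other fully unmethylated; 0 means equal
#' proportions. Symmetric in the two alleles. Sites uncovered on either
#' allele are missing (`NA`), not zero. Vectorized.
#'
#' @param ref_m,ref_tot methylated / total reads carrying the ref allele.
#' @param alt_m,alt_tot same for the alternative allele.
#' @return score in \[0, 1\] or `NA`.
#' @export
snp_asm <- function(ref_m, ref_tot, alt_m, alt_tot) {
  if (any(ref_m > ref_tot, na.rm = TRUE) || any(alt_m > alt_tot, na.rm = TRUE))
    stop("methylated counts cannot exceed totals")
  if (any(c(ref_m, ref_tot, alt_m, alt_tot) < 0, na.rm = TRUE))
    stop("counts must be >= 0")
  out <- abs(ref_m / ref_tot - alt_m / alt_tot)
  out[ref_tot == 0 | alt_tot == 0] <- NA_real_
  out
}

#' Tuple-converted SNP ASM score
#'
#' Pools the allele-split counts of the two CpG sites of a tuple before
#' taking the proportion difference; used as the ground-truth ASM value
#' when benchmarking the tuple score against SNP-linked evidence.
#'
#' @param a1,a2 lists/rows with fields `ref_m`, `ref_tot`, `alt_m`,
#'   `alt_tot` for the two CpG sites linked to the same SNP.
#' @return score in \[0, 1\] or `NA` if a pooled allele is uncovered.
#' @export
snp_asm_tuple <- function(a1, a2) {
  snp_asm(a1$ref_m + a2$ref_m, a1$ref_tot + a2$ref_tot,
          a1$alt_m + a2$alt_m, a1$alt_tot + a2$alt_tot)
}

#' Methylation-deviation score
#'
#' Comparator score using only the overall methylation proportion:
#' `1 - 2 |meth/total - 0.5|`, i.e. 1 at 50% methylation (the level
#' intermediate methylation consistent with ASM would show) and 0 at fully
#' methylated or unmethylated sites. Vectorized.
#'
#' @param methylated,total methylated and total read counts.
#' @return score in \[0, 1\] or `NA` when `total == 0`.
#' @export
meth_deviation_score <- function(methylated, total) {
  if (any(methylated > total, na.rm = TRUE)) stop("methylated > total")
  out <- 1 - 2 * abs(methylated / total - 0.5)
  out[total == 0] <- NA_real_
  out
}

# Base (and its Phred quality) of a read record at a reference position;
# NA if the read does not align a base there.
base_at_read <- function(record, pos) {
  i <- which(record$ref_pos == pos)
  if (length(i) != 1L) return(list(base = NA_character_, qual = NA_integer_))
  list(base = substr(record$seq, i, i),
       qual = utf8ToInt(substr(record$qual, i, i)) - 33L)
}

#' Partition reads by allele at a heterozygous SNP
#'
#' Assigns each read overlapping the SNP to the reference or alternative
#' allele by its base at the SNP position; reads with any other base, an N,
#' or base quality below `min_base_qual` are discarded (count reported).
#' Reads not covering the position are ignored.
#'
#' @param reads list of read records from [extract_read_meth()].
#' @param snp one-row data.frame (or list) with `chrom`, `pos`, `ref`, `alt`.
#' @param min_base_qual minimum Phred base quality at the SNP (default 20).
#' @return list with elements `ref` and `alt` (lists of read records) and
#'   `n_discarded`.
#' @export
partition_reads_by_allele <- function(reads, snp, min_base_qual = 20L) {
  ref_reads <- list(); alt_reads <- list(); n_disc <- 0L
  for (r in reads) {
    if (!identical(r$chrom, snp$chrom)) next
    ba <- base_at_read(r, snp$pos)
    if (is.na(ba$base)) next
    if (!is.na(ba$qual) && ba$qual < min_base_qual) { n_disc <- n_disc + 1L; next }
    if (ba$base == snp$ref) ref_reads[[length(ref_reads) + 1L]] <- r
    else if (ba$base == snp$alt) alt_reads[[length(alt_reads) + 1L]] <- r
    else n_disc <- n_disc + 1L
  }
  list(ref = ref_reads, alt = alt_reads, n_discarded = n_disc)
}

# Count methylated/total reads per CpG position over a set of read records,
# de-duplicating overlapping mate pairs: for a given read_id and CpG
# position only the first record's call counts (one molecule, one vote).
count_allele_calls <- function(reads) {
  if (!length(reads)) {
    return(data.frame(pos = integer(0), m = integer(0), tot = integer(0)))
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  pos <- integer(0); meth <- integer(0)
  for (r in reads) {
    if (!nrow(r$calls)) next
    for (k in seq_len(nrow(r$calls))) {
      key <- paste0(r$read_id, "@", r$calls$pos[k])
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      pos <- c(pos, r$calls$pos[k])
      meth <- c(meth, as.integer(r$calls$state[k] == "methylated"))
    }
  }
  agg <- stats::aggregate(meth, by = list(pos = pos),
                          FUN = function(x) c(m = sum(x), tot = length(x)))
  data.frame(pos = agg$pos, m = agg$x[, "m"], tot = agg$x[, "tot"])
}

#' SNP-based ASM scores across samples
#'
#' For every heterozygous SNP of every sample, partitions the overlapping
#' reads by allele and scores each CpG site covered on both alleles with
#' [snp_asm()]. A CpG linked to several SNPs is keyed per (CpG, SNP) pair;
#' with `collapse = TRUE` the matrix is reduced to one row per CpG, keeping
#' the SNP with the highest combined allele coverage across samples.
#'
#' @param reads_by_sample named list: per sample, a list of read records
#'   ([extract_read_meth()]).
#' @param snps_by_sample named list (same names): per sample, a data.frame
#'   from [read_het_snps()].
#' @param min_base_qual passed to [partition_reads_by_allele()].
#' @param collapse collapse multi-SNP CpGs to one row per CpG?
#' @return ScoreMatrix (`score_kind = "snp"`) with `rowData` column
#'   `snp_pos`; coverage is the combined ref+alt read total.
#' @export
score_snp_sites <- function(reads_by_sample, snps_by_sample,
                            min_base_qual = 20L, collapse = TRUE) {
  stopifnot(identical(sort(names(reads_by_sample)), sort(names(snps_by_sample))))
  samples <- names(reads_by_sample)
  rows <- list()
  for (s in samples) {
    snps <- snps_by_sample[[s]]
    if (is.null(snps) || nrow(snps) == 0L) next
    for (j in seq_len(nrow(snps))) {
      snp <- snps[j, ]
      part <- partition_reads_by_allele(reads_by_sample[[s]], snp,
                                        min_base_qual = min_base_qual)
      refc <- count_allele_calls(part$ref)
      altc <- count_allele_calls(part$alt)
      both <- merge(refc, altc, by = "pos", suffixes = c("_ref", "_alt"))
      if (!nrow(both)) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = snp$chrom, pos = both$pos, snp_pos = snp$pos,
        asm = snp_asm(both$m_ref, both$tot_ref, both$m_alt, both$tot_alt),
        cov = both$tot_ref + both$tot_alt,
        sample = s
      )
    }
  }
  if (!length(rows)) {
    empty <- matrix(numeric(0), nrow = 0, ncol = length(samples),
                    dimnames = list(NULL, samples))
    return(score_matrix(data.frame(chrom = character(0), pos = integer(0),
                                   snp_pos = integer(0)),
                        empty, empty, score_kind = "snp"))
  }
  long <- data.table::rbindlist(rows)
  wide_s <- data.table::dcast(long, chrom + pos + snp_pos ~ sample,
                              value.var = "asm")
  wide_c <- data.table::dcast(long, chrom + pos + snp_pos ~ sample,
                              value.var = "cov")
  for (s in setdiff(samples, names(wide_s))) {
    wide_s[[s]] <- NA_real_
    wide_c[[s]] <- NA_real_
  }
  data.table::setorder(wide_s, chrom, pos, snp_pos)
  data.table::setorder(wide_c, chrom, pos, snp_pos)
  scores <- as.matrix(wide_s[, samples, with = FALSE])
  covs <- as.matrix(wide_c[, samples, with = FALSE])
  if (collapse) {
    total_cov <- rowSums(covs, na.rm = TRUE)
    cpg_key <- paste(wide_s$chrom, wide_s$pos, sep = ":")
    keep <- unlist(lapply(split(seq_along(cpg_key), cpg_key), function(idx) {
      idx[which.max(total_cov[idx])]
    }), use.names = FALSE)
    keep <- sort(keep)
    wide_s <- wide_s[keep, ]
    scores <- scores[keep, , drop = FALSE]
    covs <- covs[keep, , drop = FALSE]
  }
  score_matrix(data.frame(chrom = wide_s$chrom, pos = wide_s$pos,
                          snp_pos = wide_s$snp_pos),
               scores, covs, score_kind = "snp")
}
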