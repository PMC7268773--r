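#' Read a methtuple-style CpG-pair count table
#'
#' Parses the tab-separated dialect produced by CpG-pair counting tools:
#' columns `chr`, `strand`, `pos1`, `pos2` (1-based C positions of the two
#' CpGs, `pos2 > pos1`) and the read counts `MM`, `MU`, `UM`, `UU` (both
#' CpGs methylated, first-only, second-only, neither). Pairs farther apart
#' than `max_tuple_distance` are dropped (distant pairs are more likely to
#' span allele switches unrelated to ASM); the number dropped is reported
#' via `message()`.
#'
#' @param path path to the TSV file.
#' @param sample_id sample label attached to the returned table.
#' @param max_tuple_distance maximum `pos2 - pos1` to keep, in bp.
#' @return data.frame with columns `chrom`, `strand`, `pos1`, `pos2`,
#'   `MM`, `MU`, `UM`, `UU` and attribute `sample_id`.
#' @export
read_methtuple <- function(path, sample_id, max_tuple_distance = 150L) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character")
  required <- c("chr", "strand", "pos1", "pos2", "MM", "MU", "UM", "UU")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("methtuple file '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("pos1", "pos2", "MM", "MU", "UM", "UU")) {
    v <- suppressWarnings(as.integer(dt[[col]]))
    bad <- which(is.na(v) & !is.na(dt[[col]]))
    if (length(bad)) {
      stop("non-integer value in column '", col, "' of '", path,
           "' at line ", bad[1] + 1L)  # +1 for header
    }
    data.table::set(dt, j = col, value = v)
  }
  out <- data.frame(chrom = dt$chr, strand = dt$strand,
                    pos1 = dt$pos1, pos2 = dt$pos2,
                    MM = dt$MM, MU = dt$MU, UM = dt$UM, UU = dt$UU,
                    stringsAsFactors = FALSE)
  if (any(out$pos2 <= out$pos1)) stop("pos2 must exceed pos1 in '", path, "'")
  if (any(out$MM < 0 | out$MU < 0 | out$UM < 0 | out$UU < 0))
    stop("negative counts in '", path, "'")
  far <- out$pos2 - out$pos1 > max_tuple_distance
  if (any(far)) {
    message(sum(far), " tuple(s) beyond ", max_tuple_distance,
            " bp dropped from '", basename(path), "'")
    out <- out[!far, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  out
}

#' Write a CpG-pair count table in the methtuple dialect
#'
#' Inverse of [read_methtuple()]; round-trips counts exactly.
#'
#' @param tuples data.frame as returned by [read_methtuple()].
#' @param path output path.
#' @export
write_methtuple <- function(tuples, path) {
  out <- data.frame(chr = tuples$chrom, strand = tuples$strand,
                    pos1 = tuples$pos1, pos2 = tuples$pos2,
                    MM = tuples$MM, MU = tuples$MU,
                    UM = tuples$UM, UU = tuples$UU)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read heterozygous SNPs for one sample from a VCF
#'
#' Keeps only biallelic SNV records whose genotype for `sample_id` is
#' heterozygous (0/1, 0|1, 1/0 or 1|0). Indels and multiallelic records are
#' skipped with a reported count.
#'
#' @param path VCF (v4.x) file path.
#' @param sample_id sample name as it appears in the VCF header.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`.
#' @export
read_het_snps <- function(path, sample_id) {
  vcf <- VariantAnnotation::readVcf(path)
  avail <- colnames(vcf)
  if (!sample_id %in% avail) {
    stop("sample '", sample_id, "' not in VCF; available: ",
         paste(avail, collapse = ", "))
  }
  n_total <- nrow(vcf)
  snv <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  if (sum(!snv)) message(sum(!snv), " non-SNV/multiallelic record(s) skipped")
  vcf <- vcf[snv, ]
  gt <- VariantAnnotation::geno(vcf)$GT[, sample_id]
  het <- gt %in% c("0/1", "0|1", "1/0", "1|0")
  vcf <- vcf[het, ]
  rr <- SummarizedExperiment::rowRanges(vcf)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(VariantAnnotation::alt(vcf))),
    sample_id = rep(sample_id, sum(het)),
    stringsAsFactors = FALSE
  )
}

# Map each query (read) base to its 1-based reference position through the
# CIGAR. Returns an integer vector along the query; NA for inserted or
# soft-clipped bases. Only M/=/X consume both spaces, so the per-op ranges
# along the two spaces pair up block by block.
query_to_ref_map <- function(cigar, start) {
  ops <- c("M", "=", "X")
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar, ops = ops)[[1]]
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, pos = start, ops = ops)[[1]]
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  map <- rep(NA_integer_, qlen)
  for (k in seq_along(qr)) {
    if (IRanges::width(qr)[k] > 0)
      map[IRanges::start(qr)[k]:IRanges::end(qr)[k]] <-
        IRanges::start(rr)[k]:IRanges::end(rr)[k]
  }
  map
}

#' Extract per-read CpG methylation calls from aligned bisulfite reads
#'
#' Reads alignments carrying a bismark-style methylation-call string tag
#' (one character per read base; `Z` = methylated CpG, `z` = unmethylated
#' CpG, anything else ignored) and resolves each call to its reference
#' coordinate through the CIGAR. Reads below `min_mapq`, without the tag, or
#' aligned with zero reference width are skipped (counts reported).
#' Mate pairs appear as two records; overlap de-duplication happens when
#' records are counted (first mate wins).
#'
#' @param bam path to an indexed BAM file.
#' @param region optional `GRanges` restricting extraction.
#' @param min_mapq minimum mapping quality (default 30).
#' @param xm_tag name of the methylation-call string tag (default `"XM"`).
#' @return list of read records; each a list with `read_id`, `chrom`,
#'   `start`, `mapq`, `seq`, `qual`, `ref_pos` (reference position of every
#'   query base, NA for insertions) and `calls` (data.frame `pos`, `state`
#'   with state `"methylated"`/`"unmethylated"`, positions strictly
#'   increasing).
#' @export
extract_read_meth <- function(bam, region = NULL, min_mapq = 30L, xm_tag = "XM") {
  what <- c("qname", "rname", "pos", "mapq", "cigar", "seq", "qual")
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what, tag = xm_tag, flag = flag)
  } else {
    Rsamtools::ScanBamParam(what = what, tag = xm_tag, flag = flag, which = region)
  }
  chunks <- Rsamtools::scanBam(bam, param = param)
  records <- list()
  n_lowmapq <- n_notag <- n_clipped <- 0L
  for (ch in chunks) {
    xm <- ch$tag[[xm_tag]]
    n <- length(ch$qname)
    if (!n) next
    seqs <- as.character(ch$seq)
    quals <- as.character(ch$qual)
    for (i in seq_len(n)) {
      if (!is.na(ch$mapq[i]) && ch$mapq[i] < min_mapq) { n_lowmapq <- n_lowmapq + 1L; next }
      if (is.null(xm) || is.na(xm[i])) { n_notag <- n_notag + 1L; next }
      cig <- ch$cigar[i]
      if (GenomicAlignments::cigarWidthAlongReferenceSpace(cig) == 0L) {
        n_clipped <- n_clipped + 1L; next
      }
      map <- query_to_ref_map(cig, ch$pos[i])
      xmc <- strsplit(xm[i], "", fixed = TRUE)[[1]]
      idx <- which(xmc %in% c("Z", "z"))
      pos <- map[idx]
      keep <- !is.na(pos)
      calls <- data.frame(pos = pos[keep],
                          state = ifelse(xmc[idx][keep] == "Z",
                                         "methylated", "unmethylated"),
                          stringsAsFactors = FALSE)
      calls <- calls[order(calls$pos), , drop = FALSE]
      rownames(calls) <- NULL
      records[[length(records) + 1L]] <- list(
        read_id = ch$qname[i],
        chrom = as.character(ch$rname[i]),
        start = ch$pos[i],
        mapq = ch$mapq[i],
        seq = seqs[i],
        qual = quals[i],
        ref_pos = map,
        calls = calls
      )
    }
  }
  if (n_lowmapq + n_notag + n_clipped > 0L) {
    message("skipped reads: ", n_lowmapq, " low MAPQ, ", n_notag,
            " missing ", xm_tag, " tag, ", n_clipped, " fully clipped")
  }
  records
}

#' Write detected DAMEs as BED6+
#'
#' Intervals are converted from the internal 1-based inclusive coordinates
#' to BED's 0-based half-open convention. The BED score column is
#' `min(1000, round(-10 log10(adj_p)))`; extra columns are `n_positions`,
#' `mean_stat`, `direction`, `p`, `adj_p`.
#'
#' @param dames data.frame of DAMEs (from [permutation_pvalues()] or
#'   [simes_pvalues()]).
#' @param path output path.
#' @export
write_dames_bed <- function(dames, path) {
  if (nrow(dames) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed_score <- pmin(1000, round(-10 * log10(pmax(dames$adj_p, 1e-300))))
  out <- data.frame(
    chrom = dames$chrom,
    start = dames$start - 1L,
    end = dames$end,
    name = paste0("DAME_", seq_len(nrow(dames))),
    score = bed_score,
    strand = ".",
    n_positions = dames$n_positions,
    mean_stat = dames$mean_stat,
    direction = dames$direction,
    p = dames$p,
    adj_p = dames$adj_p
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
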