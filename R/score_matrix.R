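#' Build a ScoreMatrix container
#'
#' A ScoreMatrix is a [SummarizedExperiment::RangedSummarizedExperiment]
#' holding one ASM score and one coverage value per genomic position and
#' sample. For tuple scores the position is the (floored) median of the two
#' CpG C positions, carried in `rowData` as `pos1`/`pos2`; for SNP scores the
#' position is the CpG site and `rowData` carries the linked `snp_pos`.
#' Missing cells (position not observed in a sample, or removed by the
#' coverage filter) are `NA`, never zero.
#'
#' @param positions data.frame with columns `chrom`, `pos` and any extra
#'   per-position metadata columns (e.g. `pos1`, `pos2`, `snp_pos`).
#' @param scores numeric matrix, positions x samples; `NA` = missing.
#' @param coverage numeric matrix of read totals, same shape as `scores`.
#' @param score_kind `"tuple"` or `"snp"`.
#' @return A `RangedSummarizedExperiment` with assays `asm` and `cov`.
#' @export
score_matrix <- function(positions, scores, coverage, score_kind = c("tuple", "snp")) {
  score_kind <- match.arg(score_kind)
  stopifnot(is.data.frame(positions),
            all(c("chrom", "pos") %in% names(positions)),
            nrow(positions) == nrow(scores),
            identical(dim(scores), dim(coverage)))
  extra <- positions[setdiff(names(positions), c("chrom", "pos"))]
  rr <- GenomicRanges::GRanges(
    seqnames = positions$chrom,
    ranges = IRanges::IRanges(start = positions$pos, width = 1L)
  )
  if (ncol(extra)) S4Vectors::mcols(rr) <- S4Vectors::DataFrame(extra)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(asm = scores, cov = coverage),
    rowRanges = rr
  )
  S4Vectors::metadata(se)$score_kind <- score_kind
  se
}

#' Accessors for ScoreMatrix objects
#'
#' @param se a ScoreMatrix (`RangedSummarizedExperiment` built by
#'   [score_matrix()], [score_tuples()] or [score_snp_sites()]).
#' @return `asm_scores`/`asm_coverage` return the positions x samples
#'   matrices; `score_kind` the `"tuple"`/`"snp"` label; `score_positions` a
#'   data.frame of per-position metadata (chrom, pos, extras).
#' @export
asm_scores <- function(se) SummarizedExperiment::assay(se, "asm")

#' @rdname asm_scores
#' @export
asm_coverage <- function(se) SummarizedExperiment::assay(se, "cov")

#' @rdname asm_scores
#' @export
score_kind <- function(se) S4Vectors::metadata(se)$score_kind

#' @rdname asm_scores
#' @export
score_positions <- function(se) {
  rr <- SummarizedExperiment::rowRanges(se)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr))
  mc <- as.data.frame(S4Vectors::mcols(rr))
  if (ncol(mc)) out <- cbind(out, mc)
  out
}

#' Serialize / deserialize a ScoreMatrix as TSV
#'
#' Writes two tab-separated files, `<prefix>_scores.tsv` and
#' `<prefix>_coverage.tsv`, each with the position-key columns followed by
#' one column per sample. Coordinates are 1-based as everywhere internally.
#'
#' @param se ScoreMatrix.
#' @param prefix output path prefix.
#' @return `write_score_tsv` returns the two paths invisibly;
#'   `read_score_tsv` rebuilds the ScoreMatrix.
#' @export
write_score_tsv <- function(se, prefix) {
  key <- score_positions(se)
  sc <- cbind(key, as.data.frame(asm_scores(se)))
  cv <- cbind(key, as.data.frame(asm_coverage(se)))
  paths <- paste0(prefix, c("_scores.tsv", "_coverage.tsv"))
  utils::write.table(sc, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cv, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @rdname write_score_tsv
#' @param score_kind kind label to restore.
#' @export
read_score_tsv <- function(prefix, score_kind = c("tuple", "snp")) {
  score_kind <- match.arg(score_kind)
  paths <- paste0(prefix, c("_scores.tsv", "_coverage.tsv"))
  sc <- utils::read.delim(paths[1], check.names = FALSE)
  cv <- utils::read.delim(paths[2], check.names = FALSE)
  keycols <- intersect(c("chrom", "pos", "pos1", "pos2", "snp_pos", "cluster"),
                       names(sc))
  samples <- setdiff(names(sc), keycols)
  score_matrix(sc[keycols],
               as.matrix(sc[samples]),
               as.matrix(cv[samples]),
               score_kind = score_kind)
}
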