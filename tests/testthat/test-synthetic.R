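test_that("effect sizes follow the closed-form Beta(1, 2.5) quantile", {
  # closed form for Beta(1, b): F^{-1}(u) = 1 - (1-u)^(1/b)
  u <- seq(0.35, 0.75, by = 0.05)
  expect_equal(qbeta(u, 1, 2.5), 1 - (1 - u)^(1 / 2.5))
  set.seed(2)
  eff <- sample_effect_size(5000)
  lo <- 1 - (1 - 0.35)^(1 / 2.5)
  hi <- 1 - (1 - 0.75)^(1 / 2.5)
  expect_true(all(eff >= lo & eff <= hi))
  # monotone in the quantile: shifting the u-range up raises every draw
  set.seed(3); low <- sample_effect_size(100, u_range = c(0.35, 0.4))
  set.seed(3); high <- sample_effect_size(100, u_range = c(0.7, 0.75))
  expect_true(all(high > low))
})

test_that("simulate_score_matrix honours its configuration contract", {
  cfg <- sim_config(n_clusters = 100L, seed = 123L)
  sim1 <- simulate_score_matrix(cfg)
  sim2 <- simulate_score_matrix(cfg)
  expect_identical(asm_scores(sim1$se), asm_scores(sim2$se))
  expect_identical(sim1$truth, sim2$truth)
  # exactly 20% of clusters carry an effect
  expect_equal(sum(sim1$truth$clusters$differential), 20L)
  # affected positions are consecutive and confined to their cluster
  tc <- sim1$truth$clusters[sim1$truth$clusters$differential, ]
  pos_tab <- sim1$truth$positions
  for (i in seq_len(nrow(tc))) {
    inside <- pos_tab$cluster == tc$cluster[i]
    aff <- which(pos_tab$affected & inside)
    expect_true(all(diff(aff) == 1L))
    expect_gte(pos_tab$pos[aff[1]], tc$start[i])
  }
  # scores stay in the unit interval, clusters respect maxgap layout
  expect_true(all(asm_scores(sim1$se) >= 0 & asm_scores(sim1$se) <= 1))
  key <- score_positions(sim1$se)
  recl <- make_clusters(key$chrom, key$pos, cfg$maxgap)
  expect_equal(length(unique(recl)), 100L)

  # no differential clusters when the proportion is zero
  sim0 <- simulate_score_matrix(sim_config(n_clusters = 50, seed = 5,
                                           prop_differential = 0))
  expect_false(any(sim0$truth$clusters$differential))
  expect_false(any(sim0$truth$positions$affected))
})

test_that("evaluate_detection computes TPR and FDR from overlaps", {
  truth <- list(
    clusters = data.frame(cluster = 1:20, chrom = "chr1",
                          start = (1:20) * 1000L, end = (1:20) * 1000L + 100L,
                          n_positions = 2L,
                          differential = rep(c(TRUE, FALSE), each = 10)),
    positions = data.frame(chrom = "chr1",
                           pos = c((1:20) * 1000L, (1:20) * 1000L + 50L),
                           cluster = rep(1:20, 2),
                           affected = rep(rep(c(TRUE, FALSE), each = 10), 2))
  )
  truth$clusters$differential[1:10] <- TRUE
  # 8 calls hitting affected clusters 1..8, 2 false calls in null clusters
  dames <- data.frame(chrom = "chr1",
                      start = c((1:8) * 1000L, 15000L, 16000L),
                      end = c((1:8) * 1000L + 60L, 15010L, 16010L),
                      adj_p = 0.01)
  ev <- evaluate_detection(dames, truth, adj_p_thresholds = 0.05)
  expect_equal(ev$TPR, 0.8)
  expect_equal(ev$FDR, 0.2)
  # no calls at a cutoff below every adj_p: both rates fall to 0
  ev0 <- evaluate_detection(dames, truth, adj_p_thresholds = 0.001)
  expect_equal(ev0$TPR, 0)
  expect_equal(ev0$FDR, 0)
  # a perfect caller
  perfect <- data.frame(chrom = "chr1", start = (1:10) * 1000L,
                        end = (1:10) * 1000L + 10L, adj_p = 0.001)
  evp <- evaluate_detection(perfect, truth, adj_p_thresholds = 0.05)
  expect_equal(evp$TPR, 1)
  expect_equal(evp$FDR, 0)
})

test_that("simulated reads carry the designed allele structure", {
  specs <- list(
    list(chrom = "chr1", cpg_pos = c(100L, 120L, 140L), snp_pos = 90L,
         coverage = 200L, probs = c(0.95, 0.05)),                 # imprinted-like with SNP
    list(chrom = "chr1", cpg_pos = c(1100L, 1120L, 1140L),
         coverage = 200L, probs = c(0.95, 0.95)),                 # null methylated
    list(chrom = "chr1", cpg_pos = c(2100L, 2120L, 2140L),
         coverage = 200L, probs = c(0.05, 0.05)),                 # null unmethylated
    list(chrom = "chr1", cpg_pos = c(3100L, 3120L, 3140L),
         coverage = 200L, probs = c(0.95, 0.05))                  # heterogeneous, no SNP
  )
  sim <- simulate_reads(specs, sample_ids = c("a", "b"), seed = 9)
  tp <- tuple_counts_from_reads(sim$reads$a)
  se <- score_tuples(list(a = tp))
  key <- score_positions(se)
  sc <- asm_scores(se)[, 1]
  imprint <- sc[key$pos1 >= 100 & key$pos2 <= 140]
  null_m <- sc[key$pos1 >= 1100 & key$pos2 <= 1140]
  null_u <- sc[key$pos1 >= 2100 & key$pos2 <= 2140]
  hetero <- sc[key$pos1 >= 3100 & key$pos2 <= 3140]
  expect_true(all(imprint > max(null_m)))
  expect_true(all(hetero > max(null_m)))
  expect_true(all(null_u < 0.05))
  # SNP score exists only where an allele-tagging SNP was simulated
  snp_se <- score_snp_sites(sim$reads["a"], sim$snps["a"])
  expect_true(all(score_positions(snp_se)$pos %in% c(100L, 120L, 140L)))
  expect_true(all(asm_scores(snp_se)[, 1] > 0.75))
})

test_that("tuple counting from reads matches hand-tallied pairs", {
  mk <- function(id, states) {
    list(read_id = id, chrom = "chr1", start = 1L, mapq = 60L,
         seq = "", qual = "", ref_pos = 1:50,
         calls = data.frame(pos = c(10L, 20L), state = states,
                            stringsAsFactors = FALSE))
  }
  reads <- list(mk("r1", c("methylated", "methylated")),
                mk("r2", c("methylated", "unmethylated")),
                mk("r3", c("unmethylated", "unmethylated")),
                mk("r3", c("unmethylated", "unmethylated")))  # mate: once
  tp <- tuple_counts_from_reads(reads)
  expect_equal(nrow(tp), 1L)
  expect_equal(tp$MM, 1L)
  expect_equal(tp$MU, 1L)
  expect_equal(tp$UM, 0L)
  expect_equal(tp$UU, 1L)
  # distant pairs are not tupled
  far <- list(mk("r4", c("methylated", "methylated")))
  far[[1]]$calls$pos <- c(10L, 500L)
  expect_equal(nrow(tuple_counts_from_reads(far)), 0L)
})

test_that("simulated reads and SNPs round-trip through SAM and VCF", {
  sim <- simulate_reads(
    list(list(chrom = "chr1", cpg_pos = c(100L, 130L), snp_pos = 90L,
              coverage = 20L, probs = c(1, 0))),
    sample_ids = "s1", seed = 33
  )
  sam <- tempfile(fileext = ".sam")
  write_sam(sim$reads$s1, sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  back <- extract_read_meth(bam)
  expect_equal(length(back), length(sim$reads$s1))
  orig <- sim$reads$s1[order(vapply(sim$reads$s1, `[[`, "", "read_id"))]
  back <- back[order(vapply(back, `[[`, "", "read_id"))]
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$calls, orig[[k]]$calls)
  }
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(sim$snps$s1, vcf)
  snps <- read_het_snps(vcf, "s1")
  expect_equal(snps$pos, unique(sim$snps$s1$pos))
  expect_equal(snps$ref, "A")
  expect_equal(snps$alt, "G")
})

test_that("detection power grows with the effect-size quantile range", {
  tpr_at <- function(u_range, seed) {
    sim <- simulate_score_matrix(sim_config(n_clusters = 100, seed = seed,
                                            effect_u_range = u_range))
    X <- cbind(1, rep(0:1, each = 3))
    st <- suppressWarnings(site_stats(filter_positions(sim$se), X, c(0, 1)))
    evaluate_detection(simes_pvalues(st), sim$truth,
                       adj_p_thresholds = 0.1)$TPR
  }
  seeds <- c(11, 12, 13)
  low <- vapply(seeds, function(s) tpr_at(c(0.35, 0.45), s), numeric(1))
  high <- vapply(seeds, function(s) tpr_at(c(0.65, 0.75), s), numeric(1))
  expect_gte(mean(high), mean(low))
  expect_gt(mean(high), 0)
})
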