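# damescan

Detection of **differential allele-specific methylation** from bisulfite
sequencing, for epigenomics researchers comparing two groups of samples
(tumour vs. normal, female vs. male, treated vs. untreated).

Allele-specific methylation (ASM) — one parental allele methylated, the
other not — underlies genomic imprinting, X-chromosome inactivation and
widespread sequence-dependent ASM at heterozygous SNPs. damescan scores
ASM per sample and per genomic position, then screens for regions where
allele specificity is consistently gained or lost between two conditions
(**DAMEs**: differentially allele-specifically methylated regions).

## The scores

With a VCF of heterozygous SNPs, reads are partitioned by their allele and
each CpG site *i* covered on both alleles gets

```
ASM_snp(i) = | X_ref_M / X_ref  -  X_alt_M / X_alt |          in [0, 1]
```

Without genotypes, ASM is inferred from the read-level co-methylation of
nearby CpG pairs ("tuples"): a balanced mixture of fully methylated (MM)
and fully unmethylated (UU) reads is the signature of two differentially
methylated alleles. From the pair's read counts,

```
ASM_tuple(i) = | log10( (X_MM + c)(X_UU + c) / ((X_MU + c)(X_UM + c)) ) * w |
w = P( 0.5 - eps < theta < 0.5 + eps ),   theta ~ Beta(gamma + X_MM, gamma + X_UU)
```

so fully methylated or fully unmethylated tuples — plain methylation, not
allele specificity — are attenuated toward zero. Defaults: `gamma = 0.5`,
`epsilon = 0.2`, pseudo-count `c = 1`, CpG pairs at most 150 bp apart.

## From scores to regions

Per position, scores across samples are filtered (more than 5 reads,
at least 80% of samples covered), transformed (square root for the tuple
score), and fit with a linear model; t-statistics are moderated by
empirical-Bayes variance shrinkage, coefficients are loess-smoothed
within 100 bp clusters, and regions receive FDR-controlled p-values either
by **permutation** of group labels (pooled null distribution of region
areas, Benjamini–Hochberg adjusted) or by the **Simes** combination of
position-level p-values per cluster.

## Worked example

Simulate reads for a cohort of 3 normals and 3 tumours in which an
imprinted region (allele methylation probabilities 0.95 / 0.05) loses its
imprint in the tumours (0.95 / 0.95), among 11 unchanged control regions;
score CpG tuples and call DAMEs:

```r
library(damescan)

samples <- c(paste0("normal_", 1:3), paste0("tumour_", 1:3))
imprint_probs <- c(lapply(1:3, function(i) c(0.95, 0.05)),   # normals keep ASM
                   lapply(1:3, function(i) c(0.95, 0.95)))   # tumours lose it
names(imprint_probs) <- samples
specs <- list(list(chrom = "chr11", cpg_pos = seq(1000L, 1100L, by = 20L),
                   coverage = 60L, probs = imprint_probs))
for (r in 1:11) {                                            # null regions
  base <- 1000L + r * 2000L
  pr <- if (r %% 2) c(0.95, 0.95) else c(0.05, 0.05)
  specs[[r + 1]] <- list(chrom = "chr11",
                         cpg_pos = seq(base, base + 100L, by = 20L),
                         coverage = 60L, probs = pr)
}
sim <- simulate_reads(specs, sample_ids = samples, seed = 42)

se <- score_tuples(lapply(sim$reads, tuple_counts_from_reads))
design <- cbind(intercept = 1, tumour = rep(0:1, each = 3))
dames <- find_dames(se, design, c(0, 1), method = "simes")
head(dames[, c("chrom", "start", "end", "n_positions",
               "mean_stat", "direction", "p", "adj_p")], 3)
```

```
  chrom start   end n_positions mean_stat direction        p    adj_p
1 chr11  1010  1090           5 -1.29e+00      loss 1.80e-10 2.16e-09
2 chr11 15010 15090           5 -9.01e-05      loss 4.30e-01 7.76e-01
3 chr11 11010 11090           5 -3.56e-05      loss 5.16e-01 7.76e-01
```

The planted region (tuple positions 1010–1090) is the only significant
DAME (adjusted p ≈ 2e-9): its smoothed group coefficient is strongly
negative on the square-root score scale, i.e. the tumours *lost* allele
specificity there; the control regions sit at adjusted p ≈ 0.8. The same
cohort can be analysed from files on disk via the command entry points
(`cmd_score_tuples`, `cmd_score_snps`, `cmd_dames`, `cmd_simulate`, or the
`inst/scripts/damescan` wrapper), which also write BED tracks and a run
manifest.

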