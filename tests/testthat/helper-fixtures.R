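# Shared fixtures, built in code at test time.

# tiny hand-specified genotype matrix (3 individuals x 4 SNPs)
toyGenotypes <- function() {
  d <- matrix(c(0, 1, 2, 2,
                1, 1, 0, 2,
                2, 0, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  snps <- data.frame(snp_id = paste0("s", 1:4), chrom = "1",
                     pos = c(100L, 200L, 300L, 400L),
                     effect_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  genotypeMatrix(d, snps)
}

# audiogram table with fully specified thresholds
toyAudiograms <- function(n = 10, seed = 1) {
  set.seed(seed)
  out <- data.frame(id = sprintf("i%02d", 1:n),
                    sex = rep_len(0:1, n),
                    age = seq(20, 70, length.out = n),
                    stringsAsFactors = FALSE)
  out[THRESHOLD_COLS] <- replicate(7, round(rnorm(n, 20, 8), 1))
  out
}

# AdjustedTrait wrapping given residuals (OLS intercept-only design)
plainAdjusted <- function(res, trait_name = "trait") {
  new("AdjustedTrait", ids = paste0("i", seq_along(res)),
      residuals = res - mean(res), traitName = trait_name, h2 = 0,
      fixedEffects = c(intercept = mean(res)), gamma = 1,
      X = matrix(1, length(res), 1, dimnames = list(NULL, "intercept")),
      sigma2 = c(genetic = 0, residual = var(res)), calib = list())
}

# 30-hit / 3-cluster GWAS fixture with an anchor SNP near three genes at
# ~39/92/100 kb, mirroring a multi-gene locus
clusterHits <- function(seed = 99) {
  set.seed(seed)
  centers <- data.frame(chrom = c("1", "1", "2"),
                        pos = c(1e6, 3e6, 5e5))
  rows <- lapply(1:3, function(k) {
    pos <- as.integer(centers$pos[k] +
                      c(0, seq(-90e3, 90e3, length.out = 9)))
    p <- 10^-runif(10, 5, 7)
    p[1] <- 10^-(7 + k)          # the cluster-centre SNP always wins
    data.frame(snp_id = sprintf("rs%d%02d", k, 1:10),
               chrom = centers$chrom[k], pos = pos, p_value = p,
               beta = rnorm(10, 0, 0.2), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

clusterGenes <- function() {
  # anchor = the strongest hit of cluster 1 lands at some position q;
  # genes placed at fixed gaps from position 1e6 (cluster centre)
  data.frame(gene_id = c("GENEA", "GENEB", "GENEC", "LOC99999", "DISG",
                         "FARGENE"),
             chrom = c("1", "1", "1", "1", "2", "2"),
             start = c(1e6 + 39e3, 1e6 + 92e3, 1e6 - 110e3, 1e6 + 5e3,
                       5e5 + 2e4, 5e5 + 4e5),
             end = c(1e6 + 60e3, 1e6 + 95e3, 1e6 - 100e3, 1e6 + 6e3,
                     5e5 + 3e4, 5e5 + 5e5),
             strand = "+", stringsAsFactors = FALSE)
}
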