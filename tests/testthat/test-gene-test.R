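test_that("intragenic selection uses inclusive 1-based bounds", {
  d <- matrix(rep(c(0, 1, 2), 4), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  snps <- data.frame(snp_id = paste0("s", 1:4), chrom = "1",
                     pos = c(99L, 100L, 200L, 201L),
                     effect_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  gm <- genotypeMatrix(d, snps)
  gene <- list(gene_id = "G1", chrom = "1", start = 100, end = 200)
  sub <- selectIntragenicSnps(gm, gene)
  expect_identical(snpInfo(sub)$snp_id, c("s2", "s3"))
  # wrong chromosome: empty selection
  gene2 <- list(gene_id = "G2", chrom = "2", start = 1, end = 1e6)
  expect_equal(nSnps(selectIntragenicSnps(gm, gene2)), 0)
})

test_that("a constructed 52-SNP gene selects exactly its SNPs", {
  cfg <- simConfig(n_individuals = 50, n_snps = 80, n_sib_pairs = 0,
                   seed = 41)
  gm <- simulateGenotypes(cfg)
  pos <- snpInfo(gm)$pos
  gene <- list(gene_id = "G52", chrom = "1", start = pos[10],
               end = pos[61])
  expect_equal(nSnps(selectIntragenicSnps(gm, gene)), 52)
})

test_that("genotype PCs match a brute-force covariance eigendecomposition", {
  cfg <- simConfig(n_individuals = 60, n_snps = 5, n_sib_pairs = 0,
                   ld_rho = 0.5, seed = 42)
  gm <- simulateGenotypes(cfg)
  pcs <- genotypePcs(gm)
  ev <- eigen(cov(hardCall(dosages(gm))), symmetric = TRUE)$values
  expect_equal(pcs$fractions, ev / sum(ev), tolerance = 1e-10)
  expect_equal(sum(pcs$fractions), 1, tolerance = 1e-12)
})

test_that("degenerate genotype PC cases behave as contracted", {
  # single SNP -> one component with all the variance
  cfg <- simConfig(n_individuals = 40, n_snps = 1, n_sib_pairs = 0,
                   seed = 43)
  gm <- simulateGenotypes(cfg)
  pcs <- genotypePcs(gm)
  expect_equal(pcs$fractions[1], 1, tolerance = 1e-10)
  # two perfectly correlated SNPs -> PC1 fraction 1
  d <- dosages(gm)
  d2 <- cbind(d, d)
  colnames(d2) <- c("sA", "sB")
  snps <- data.frame(snp_id = c("sA", "sB"), chrom = "1", pos = c(1L, 2L),
                     effect_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  pcs2 <- genotypePcs(genotypeMatrix(d2, snps))
  expect_equal(pcs2$fractions[1], 1, tolerance = 1e-10)
  # all-constant submatrix is an error
  dc <- matrix(1, 10, 2, dimnames = list(paste0("i", 1:10), NULL))
  snpc <- data.frame(snp_id = c("c1", "c2"), chrom = "1", pos = c(1L, 2L),
                     effect_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  expect_error(genotypePcs(genotypeMatrix(dc, snpc)), "constant")
})

test_that("the >1/N rule is strict, ordered, and falls back to PC1", {
  expect_identical(selectPcs(c(0.5, 0.3, 0.2), N = 5), 1:2)
  expect_warning(sel <- selectPcs(1.0, N = 1), "keeping PC1")
  expect_identical(sel, 1L)
  # 0.25 is not strictly greater than 1/4, so only PC1 qualifies
  expect_identical(selectPcs(c(0.6, 0.25, 0.15), N = 4), 1L)
})

test_that("single-PC gene test matches the squared-t identity", {
  set.seed(44)
  y <- rnorm(80)
  score <- rnorm(80)
  adj <- plainAdjusted(y)
  out <- geneBasedTest(adj, matrix(score, ncol = 1))
  tfit <- summary(lm(adj@residuals ~ score))$coefficients["score", ]
  expect_equal(out$p_value, unname(tfit["Pr(>|t|)"]), tolerance = 1e-10)
  expect_equal(out$f_stat, unname(tfit["t value"])^2, tolerance = 1e-10)
})

test_that("gene results are invariant to SNP and individual order", {
  cfg <- simConfig(n_individuals = 120, n_snps = 30, n_sib_pairs = 0,
                   ld_rho = 0.7, seed = 45)
  co <- simulateCohort(cfg)
  set.seed(46)
  adj <- adjustTrait(co$audiograms$thr_2000, co$audiograms$sex,
                     co$audiograms$age, ids = co$audiograms$id)
  genes <- data.frame(gene_id = "G1", chrom = "1", start = 1,
                      end = 1e9, strand = "+", stringsAsFactors = FALSE)
  base <- geneAssociation(adj, co$genotypes, genes)
  shuf_snp <- geneAssociation(adj, co$genotypes[, sample(30)], genes)
  expect_equal(base$p_value, shuf_snp$p_value, tolerance = 1e-8)
  expect_equal(base$n_selected_pcs, shuf_snp$n_selected_pcs)
  perm <- sample(120)
  shuf_ind <- geneAssociation(adj, co$genotypes[perm, ], genes)
  expect_equal(base$p_value, shuf_ind$p_value, tolerance = 1e-8)
  # variance-explained bookkeeping
  pcs <- genotypePcs(co$genotypes)
  sel <- selectPcs(pcs$fractions, 30)
  expect_equal(base$variance_explained_pct +
                 100 * sum(pcs$fractions[-sel]), 100, tolerance = 1e-8)
  expect_equal(base$total_n_snps, 30)
})

test_that("untestable gene cases are flagged, not errors", {
  cfg <- simConfig(n_individuals = 50, n_snps = 10, n_sib_pairs = 0,
                   seed = 47)
  co <- simulateCohort(cfg)
  set.seed(48)
  adj <- adjustTrait(rnorm(50), ids = sampleIds(co$genotypes))
  genes <- data.frame(gene_id = c("EMPTY", "G1"), chrom = c("9", "1"),
                      start = c(1, 1), end = c(100, 1e9), strand = "+",
                      stringsAsFactors = FALSE)
  out <- geneAssociation(adj, co$genotypes, genes)
  expect_equal(out$note, c("untestable", "ok"))
  expect_true(is.na(out$p_value[1]))
  expect_equal(out$total_n_snps, c(0L, 10L))
})

test_that("power does not decrease with effect size (paired seeds)", {
  runPower <- function(eff, seeds) {
    mean(sapply(seeds, function(r) {
      cfg <- simConfig(n_individuals = 250, n_snps = 20,
                       maf_range = c(0.3, 0.3001), ld_rho = 0.8,
                       n_sib_pairs = 0, h2 = 0,
                       shared_factor_loadings = rep(0, 7), noise_sd = 1,
                       snp_effects = list(list(snp = 10,
                                               model = "additive",
                                               effect = eff)),
                       seed = r)
      co <- simulateCohort(cfg)
      adj <- adjustTrait(co$audiograms$thr_1000, co$audiograms$sex,
                         co$audiograms$age, ids = co$audiograms$id)
      pcs <- genotypePcs(co$genotypes)
      sel <- selectPcs(pcs$fractions, 20)
      geneBasedTest(adj, pcs$scores[, sel, drop = FALSE])$p_value < 0.05
    }))
  }
  seeds <- 600:659
  p_small <- runPower(0.1, seeds)
  p_big <- runPower(0.6, seeds)
  expect_gte(p_big, p_small)
  expect_gt(p_big, 0.5)
})
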