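test_that("genetic-model codings follow their definitions", {
  cls <- c(0, 1, 2)
  expect_equal(encodeGeneticModel(cls, "additive"), c(0, 1, 2))
  expect_equal(encodeGeneticModel(cls, "dominant"), c(0, 1, 1))
  expect_equal(encodeGeneticModel(cls, "recessive"), c(0, 0, 1))
  expect_equal(encodeGeneticModel(cls, "overdominant"), c(0, 1, 0))
  # imputed dosages hard-called at 0.5 / 1.5 for the binary codings
  expect_equal(encodeGeneticModel(c(0.4, 0.5, 1.5, 1.6), "dominant"),
               c(0, 1, 1, 1))
  expect_equal(encodeGeneticModel(c(0.4, 0.5, 1.5, 1.6), "recessive"),
               c(0, 0, 0, 1))
  expect_error(encodeGeneticModel(c(0, 2.3), "additive"), "outside")
})

test_that("the four-point hand regression oracle is reproduced exactly", {
  adj <- plainAdjusted(c(-1, 0, 0, 1))
  g <- c(0, 0, 1, 1)
  res <- snpTest(adj, g, reference = "t")
  ols <- summary(lm(adj@residuals ~ g))$coefficients["g", ]
  expect_equal(res$beta, unname(ols["Estimate"]), tolerance = 1e-10)
  expect_equal(res$se, unname(ols["Std. Error"]), tolerance = 1e-10)
  expect_equal(res$p_value, unname(ols["Pr(>|t|)"]), tolerance = 1e-10)
  # hand arithmetic: slope 1, se sqrt(1/2), t = sqrt(2)
  expect_equal(res$beta, 1, tolerance = 1e-10)
  expect_equal(res$se, sqrt(1 / 2), tolerance = 1e-10)
})

test_that("a noise-free linear relation gives beta 1 and vanishing p", {
  set.seed(31)
  r <- rnorm(50)
  adj <- plainAdjusted(r)
  res <- snpTest(adj, adj@residuals)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$beta, 1, tolerance = 1e-6)
})

test_that("null p-values are uniform (Kolmogorov-Smirnov)", {
  cfg <- simConfig(n_individuals = 300, n_snps = 1000, n_sib_pairs = 0,
                   ld_rho = 0, maf_range = c(0.1, 0.5), seed = 32)
  gm <- simulateGenotypes(cfg)
  set.seed(33)
  y <- rnorm(300)
  adj <- adjustTrait(y, ids = sampleIds(gm), trait_name = "null")
  ps <- vapply(seq_len(1000), function(j)
    snpTest(adj, dosages(gm)[, j])$p_value, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1000))  # 1% critical value
})

test_that("allele flips negate the additive beta and swap dominant/recessive", {
  set.seed(34)
  g <- rbinom(120, 2, 0.4)
  r <- rnorm(120) + 0.3 * g
  adj <- plainAdjusted(r)
  a1 <- snpTest(adj, encodeGeneticModel(g, "additive"))
  a2 <- snpTest(adj, encodeGeneticModel(2 - g, "additive"))
  expect_equal(a2$beta, -a1$beta, tolerance = 1e-10)
  expect_equal(a2$p_value, a1$p_value, tolerance = 1e-10)
  expect_equal(encodeGeneticModel(2 - g, "dominant"),
               1 - encodeGeneticModel(g, "recessive"))
  expect_equal(encodeGeneticModel(2 - g, "overdominant"),
               encodeGeneticModel(g, "overdominant"))
})

test_that("monomorphic and low-count codings are flagged", {
  adj <- plainAdjusted(rnorm(40))
  res <- snpTest(adj, rep(1, 40))
  expect_equal(res$p_value, 1)
  expect_equal(res$beta, 0)
  expect_equal(res$note, "untestable")

  cfg <- simConfig(n_individuals = 200, n_snps = 5,
                   maf_range = c(0.12, 0.18), ld_rho = 0, n_sib_pairs = 0,
                   seed = 36)
  gm <- simulateGenotypes(cfg)
  set.seed(37)
  adj2 <- adjustTrait(rnorm(200), ids = sampleIds(gm))
  tab <- snpAssociation(adj2, gm, models = "recessive")
  rare <- vapply(seq_len(5), function(j)
    sum(hardCall(dosages(gm)[, j]) == 2), numeric(1))
  expect_true(all(tab$note[rare > 0 & rare < 10] == "low_confidence"))
})

test_that("replication requires nominal significance and matching direction", {
  # printed replication examples: ANK2-style and DCLK1-style records
  ank2 <- replicationCheck(
    list(beta = 0.25, effect_allele = "G"),
    list(snp_id = "rs17045059", beta = 0.08, p_value = 0.010,
         effect_allele = "G", other_allele = "A"))
  expect_true(ank2$replicated)
  dclk1 <- replicationCheck(
    list(beta = -0.17, effect_allele = "G"),
    list(snp_id = "rs9574464", beta = -0.06, p_value = 0.008,
         effect_allele = "G", other_allele = "A"))
  expect_true(dclk1$replicated)
  # opposite direction fails regardless of p
  flip <- replicationCheck(list(beta = 0.25),
                           list(beta = -0.08, p_value = 0.010))
  expect_false(flip$replicated)
  expect_false(flip$same_direction)
  # p at or above alpha fails (strict <)
  ns <- replicationCheck(list(beta = 0.25),
                         list(beta = 0.08, p_value = 0.06))
  expect_false(ns$replicated)
  at <- replicationCheck(list(beta = 0.25),
                         list(beta = 0.08, p_value = 0.05))
  expect_false(at$replicated)
})

test_that("effect-allele mismatches are flipped when resolvable, else error", {
  ok <- replicationCheck(
    list(beta = 0.25, effect_allele = "A"),
    list(beta = -0.08, p_value = 0.01, effect_allele = "G",
         other_allele = "A"))
  expect_true(ok$replicated)          # discovery flipped to -0.25
  expect_equal(ok$discovery_beta, -0.25)
  expect_error(replicationCheck(
    list(beta = 0.25, effect_allele = "T"),
    list(beta = 0.08, p_value = 0.01, effect_allele = "G",
         other_allele = "A")), "mismatch")
})

test_that("snpAssociation mirrors the SNP metadata into its rows", {
  cfg <- simConfig(n_individuals = 100, n_snps = 6, n_sib_pairs = 0,
                   seed = 38)
  gm <- simulateGenotypes(cfg)
  set.seed(39)
  adj <- adjustTrait(rnorm(100), ids = sampleIds(gm), trait_name = "pc1")
  tab <- snpAssociation(adj, gm)
  expect_equal(nrow(tab), 6 * 4)
  expect_setequal(unique(tab$model),
                  c("additive", "dominant", "recessive", "overdominant"))
  expect_true(all(tab$trait == "pc1"))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_true(all(tab$se[tab$note == "ok"] > 0))
})
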