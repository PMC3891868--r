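test_that("VCF GT fields map to effect-allele dosage counts", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
           "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  gm <- loadGenotypes(path, "vcf")
  expect_equal(unname(dosages(gm)[, 1]), c(0, 1, 2))
  expect_equal(snpInfo(gm)$effect_allele, "G")
  expect_equal(snpInfo(gm)$other_allele, "A")
  expect_equal(snpInfo(gm)$source, "genotyped")
})

test_that("dosage (DS) values pass through verbatim for imputed records", {
  vcf <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=TYP,Number=1,Type=String,Description=\"t\">",
           "##INFO=<ID=IQS,Number=1,Type=Float,Description=\"q\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"d\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
           "1\t100\trs1\tA\tG\t.\tPASS\tTYP=imp;IQS=0.93\tGT:DS\t0/0:0.13\t0/1:1.02\t1/1:1.87")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  gm <- loadGenotypes(path, "vcf")
  expect_equal(unname(dosages(gm)[, 1]), c(0.13, 1.02, 1.87))
  expect_equal(snpInfo(gm)$source, "imputed")
  expect_equal(snpInfo(gm)$info, 0.93)
})

test_that("missing genotypes and duplicate ids are handled", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
           "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t./.\t0/1")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  gm <- loadGenotypes(path, "vcf")
  expect_true(is.na(dosages(gm)[1, 1]))
  expect_equal(dosages(gm)[2, 1], 1)

  dup <- c(vcf, "1\t200\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/0")
  writeLines(dup, path)
  expect_error(loadGenotypes(path, "vcf"), "duplicate SNP id")
})

test_that("multi-allelic records keep the first ALT with a warning", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
           "1\t100\trs1\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t1/2")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_warning(gm <- loadGenotypes(path, "vcf"), "multi-allelic")
  expect_equal(dosages(gm)[1, 1], 1)
  expect_true(is.na(dosages(gm)[2, 1]))   # carries a dropped allele
})

test_that("dosage TSV round-trips to at least 6 significant digits", {
  cfg <- simConfig(n_individuals = 15, n_snps = 8, n_sib_pairs = 0,
                   seed = 33)
  gm <- simulateGenotypes(cfg)
  d <- dosages(gm)
  d[1, 1] <- 1.234567                      # imputed-style fractional dosage
  s <- snpInfo(gm)
  s$source[1] <- "imputed"; s$info[1] <- 0.876543
  gm <- genotypeMatrix(d, s)
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  writeDosageTsv(gm, p1, p2)
  gm2 <- loadGenotypes(p1, "dosage_tsv", meta_path = p2)
  expect_equal(dosages(gm2), dosages(gm), tolerance = 1e-6)
  expect_equal(snpInfo(gm2)$info[1], 0.876543, tolerance = 1e-6)
})

test_that("QC filter applies the strict MAF and Info thresholds", {
  d <- matrix(1, 4, 4, dimnames = list(paste0("i", 1:4), NULL))
  snps <- data.frame(snp_id = paste0("s", 1:4), chrom = "1",
                     pos = 1:4 * 100L, effect_allele = "A",
                     other_allele = "G", strand = "+",
                     source = c("genotyped", "imputed", "imputed",
                                "imputed"),
                     maf = c(0.005, 0.01, 0.3, 0.3),
                     info = c(NA, 0.40, 0.39, 0.95),
                     stringsAsFactors = FALSE)
  gm <- genotypeMatrix(d, snps)
  out <- suppressMessages(qcFilter(gm))
  # s1 removed (maf 0.005 < 0.01); s3 removed (imputed info 0.39 < 0.4);
  # s2 retained on both boundaries (strict <)
  expect_identical(snpInfo(out)$snp_id, c("s2", "s4"))
  # idempotent
  out2 <- suppressMessages(qcFilter(out))
  expect_identical(snpInfo(out2), snpInfo(out))
  expect_identical(dosages(out2), dosages(out))
})

test_that("BED intervals convert to 1-based inclusive coordinates in file order", {
  bed <- c("chr2\t499\t600\tG2\t0\t-",
           "chr1\t99\t200\tG1\t0\t+")
  path <- tempfile(fileext = ".bed")
  writeLines(bed, path)
  gi <- loadGeneIntervals(path)
  expect_identical(gi$gene_id, c("G2", "G1"))   # unsorted order preserved
  expect_equal(gi$start[2], 100)
  expect_equal(gi$end[2], 200)
  expect_identical(gi$strand, c("-", "+"))
})

test_that("genotype matrix validity catches malformed inputs", {
  d <- matrix(c(0, 1, 3), 3, 1, dimnames = list(letters[1:3], NULL))
  snps <- data.frame(snp_id = "s1", chrom = "1", pos = 1L,
                     effect_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  expect_error(genotypeMatrix(d, snps), "\\[0, 2\\]")
  d2 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), NULL))
  snps2 <- data.frame(snp_id = c("s1", "s1"), chrom = "1", pos = c(1L, 2L),
                      effect_allele = "A", other_allele = "G",
                      stringsAsFactors = FALSE)
  expect_error(genotypeMatrix(d2, snps2), "unique")
})

test_that("zero-length BED intervals are rejected", {
  path <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t100\tG0\t0\t+", path)
  expect_error(loadGeneIntervals(path), "zero-length")
})
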