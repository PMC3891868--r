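#' Audiometric frequencies used throughout the package (kHz)
#' @export
AUDIO_FREQS <- c(0.25, 0.5, 1, 2, 4, 6, 8)

#' Threshold column names for the 7 measured frequencies
#' @export
THRESHOLD_COLS <- paste0("thr_", c(250, 500, 1000, 2000, 4000, 6000, 8000))

#' Simulation configuration for a synthetic hearing cohort
#'
#' Defines the generative model used by [simulateGenotypes()] and
#' [simulateAudiograms()]: a Gaussian-copula AR(1) haplotype model for local
#' linkage disequilibrium, sibling-pair relatedness by haplotype sharing, and
#' an audiogram model
#' \deqn{y_{if} = b_f + age_i s_f + sex_i x_f + \sum_k c(g_{ik}) \beta_k +
#'   \lambda_f F_i + u_i + e_{if}}
#' with a per-individual common factor \eqn{F_i \sim N(0,1)} inducing
#' cross-frequency correlation, a polygenic effect \eqn{u_i} that is
#' multivariate normal with covariance \eqn{\sigma^2_g A} (A the expected
#' relationship matrix: twice the kinship coefficients, 1 on the diagonal
#' and 1/2 between siblings), and independent noise \eqn{e_{if}}.
#' The polygenic variance is scaled so
#' that \code{h2} is the heritability relative to the polygenic-plus-noise
#' variance: \eqn{\sigma^2_g = h2/(1-h2) \cdot noise\_sd^2}.
#'
#' Defaults emulate a rural replication cohort of around 500 adults: roughly
#' 500 individuals with a minority of sibling pairs, common variants with
#' local LD, a presbycusis-like age slope that steepens with frequency, worse
#' male high-frequency hearing, moderate heritability and a shared
#' susceptibility factor that correlates thresholds across frequencies.
#'
#' @param n_individuals cohort size.
#' @param n_snps number of SNPs on the simulated panel.
#' @param maf_range length-2 vector; per-SNP allele frequencies are drawn
#'   uniformly from this interval (must lie in (0, 0.5]).
#' @param ld_rho AR(1) correlation of the latent haplotype Gaussians in
#'   \eqn{[0, 1)}; controls local LD decay.
#' @param n_sib_pairs number of sibling pairs (each pair shares each parental
#'   haplotype with probability 1/2).
#' @param baseline_curve length-7 baseline thresholds (dB) at
#'   0.25/0.5/1/2/4/6/8 kHz.
#' @param age_slope_per_freq length-7 age slopes (dB per year).
#' @param sex_effect_per_freq length-7 additive male effect (dB; sex coded
#'   0 = female, 1 = male).
#' @param h2 polygenic heritability in \eqn{[0, 1)} (relative to
#'   polygenic + noise variance).
#' @param shared_factor_loadings length-7 loadings (dB) of the standard-normal
#'   per-individual common factor.
#' @param noise_sd per-frequency independent noise SD (dB).
#' @param snp_effects list of injected SNP effects, each a list with elements
#'   \code{snp} (column index), \code{model} (one of \code{"additive"},
#'   \code{"dominant"}, \code{"recessive"}, \code{"overdominant"}) and
#'   \code{effect} (dB per coded unit, applied at every frequency).
#' @param seed integer RNG seed; identical configs give byte-identical
#'   cohorts.
#' @return a validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(n_individuals = 493,
                      n_snps = 500,
                      maf_range = c(0.05, 0.5),
                      ld_rho = 0.6,
                      n_sib_pairs = 60,
                      baseline_curve = c(8, 6, 6, 8, 12, 16, 20),
                      age_slope_per_freq = c(0.15, 0.15, 0.2, 0.3, 0.55, 0.7, 0.85),
                      sex_effect_per_freq = c(0, 0, 0, 1, 3, 4, 5),
                      h2 = 0.3,
                      shared_factor_loadings = c(7, 7, 7, 8, 9, 9, 10),
                      noise_sd = 6,
                      snp_effects = list(),
                      seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_snps = as.integer(n_snps),
              maf_range = as.numeric(maf_range), ld_rho = as.numeric(ld_rho),
              n_sib_pairs = as.integer(n_sib_pairs),
              baseline_curve = as.numeric(baseline_curve),
              age_slope_per_freq = as.numeric(age_slope_per_freq),
              sex_effect_per_freq = as.numeric(sex_effect_per_freq),
              h2 = as.numeric(h2),
              shared_factor_loadings = as.numeric(shared_factor_loadings),
              noise_sd = as.numeric(noise_sd),
              snp_effects = snp_effects, seed = as.integer(seed))
  num <- unlist(cfg[setdiff(names(cfg), "snp_effects")])
  if (anyNA(num) || any(!is.finite(num)))
    stop("simConfig: non-finite or missing configuration value")
  if (cfg$n_individuals <= 0 || cfg$n_snps <= 0)
    stop("simConfig: counts must be positive")
  if (cfg$n_sib_pairs < 0 || 2 * cfg$n_sib_pairs > cfg$n_individuals)
    stop("simConfig: n_sib_pairs must fit inside the cohort")
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("simConfig: maf_range must be an increasing pair within (0, 0.5]")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1)
    stop("simConfig: ld_rho must lie in [0, 1)")
  if (cfg$h2 < 0 || cfg$h2 >= 1)
    stop("simConfig: h2 must lie in [0, 1)")
  if (cfg$noise_sd < 0)
    stop("simConfig: noise_sd must be >= 0")
  for (fld in c("baseline_curve", "age_slope_per_freq",
                "sex_effect_per_freq", "shared_factor_loadings"))
    if (length(cfg[[fld]]) != 7)
      stop("simConfig: ", fld, " must have 7 entries (one per frequency)")
  for (ef in cfg$snp_effects) {
    if (!all(c("snp", "model", "effect") %in% names(ef)))
      stop("simConfig: snp_effects entries need snp, model, effect")
    if (ef$snp < 1 || ef$snp > cfg$n_snps)
      stop("simConfig: snp_effects index out of range")
    if (!ef$model %in% c("additive", "dominant", "recessive", "overdominant"))
      stop("simConfig: unknown genetic model '", ef$model, "'")
  }
  structure(cfg, class = "simConfig")
}

## AR(1) latent Gaussian matrix, one row per haplotype
.ar1Latent <- function(n_hap, n_snps, rho) {
  z <- matrix(rnorm(n_hap * n_snps), n_hap, n_snps)
  if (rho > 0 && n_snps > 1) {
    w <- sqrt(1 - rho^2)
    for (j in 2:n_snps) z[, j] <- rho * z[, j - 1] + w * z[, j]
  }
  z
}

#' Simulate genotypes with local LD and sibling relatedness
#'
#' Two independent haplotypes per individual are drawn from a Gaussian-copula
#' AR(1) model: latent standard normals with lag-1 correlation
#' \code{ld_rho} are thresholded at the per-SNP allele-frequency quantile, so
#' adjacent SNPs are correlated and the correlation decays geometrically with
#' distance. Sibling pairs (the first \code{2 * n_sib_pairs} individuals,
#' taken consecutively) share each haplotype with probability 1/2, giving an
#' expected kinship coefficient of 1/4 (genomic-relationship entry 1/2).
#'
#' @param config a [simConfig()].
#' @return a [GenotypeMatrix-class]; per-SNP \code{maf} metadata is the
#'   folded sample frequency.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_snps
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  thr <- qnorm(p)
  z <- .ar1Latent(2L * n, m, config$ld_rho)
  h <- sweep(z, 2, thr, "<") * 1L   # 1 = effect allele carried
  if (config$n_sib_pairs > 0) {
    for (k in seq_len(config$n_sib_pairs)) {
      a <- 2L * k - 1L   # sib 1 of pair k
      b <- 2L * k        # sib 2 of pair k
      for (hp in 1:2)
        if (runif(1) < 0.5)
          h[2L * (b - 1L) + hp, ] <- h[2L * (a - 1L) + hp, ]
    }
  }
  odd <- seq(1L, 2L * n, by = 2L)
  dos <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  ids <- sprintf("ind%04d", seq_len(n))
  rownames(dos) <- ids
  alleles <- matrix(c("A", "G", "C", "T", "A", "C", "G", "A"), ncol = 2,
                    byrow = TRUE)
  pick <- sample.int(4L, m, replace = TRUE)
  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                     chrom = "1", pos = seq_len(m) * 1000L,
                     effect_allele = alleles[pick, 1],
                     other_allele = alleles[pick, 2],
                     strand = "+", source = "genotyped",
                     maf = sampleMaf(dos), info = NA_real_,
                     stringsAsFactors = FALSE)
  genotypeMatrix(dos, snps)
}

#' Sibling pedigree implied by a simulation config
#'
#' @param config a [simConfig()].
#' @return data.frame with columns \code{id1}, \code{id2}, one row per
#'   sibling pair (consecutive individuals at the head of the cohort).
#' @export
sibPedigree <- function(config) {
  k <- config$n_sib_pairs
  if (k == 0)
    return(data.frame(id1 = character(), id2 = character(),
                      stringsAsFactors = FALSE))
  data.frame(id1 = sprintf("ind%04d", 2L * seq_len(k) - 1L),
             id2 = sprintf("ind%04d", 2L * seq_len(k)),
             stringsAsFactors = FALSE)
}

## genetic-model coding used both in simulation and association
.codeDosage <- function(dosage, model) {
  if (model == "additive") return(dosage)
  cls <- hardCall(dosage)
  switch(model,
         dominant = (cls >= 1) * 1,
         recessive = (cls == 2) * 1,
         overdominant = (cls == 1) * 1,
         stop("unknown genetic model '", model, "'"))
}

#' Simulate audiograms for a genotyped cohort
#'
#' Builds the 7-frequency threshold table from the additive model described
#' in [simConfig()]: baseline + age and sex effects + injected SNP effects +
#' a per-individual common factor + a multivariate-normal polygenic effect
#' whose covariance is the h2-scaled expected relationship matrix (twice the
#' kinship coefficients implied by the sibling pedigree) + independent
#' noise. Ages are uniform on [18, 80] (adults only); sex is
#' Bernoulli(1/2), coded 0 = female / 1 = male.
#'
#' @param genotypes a [GenotypeMatrix-class] for the cohort.
#' @param pedigree sibling-pair data.frame (as from [sibPedigree()]); its ids
#'   must all be present in \code{genotypes}.
#' @param config the [simConfig()] used to generate \code{genotypes}.
#' @return an audiogram data.frame with columns \code{id}, \code{sex},
#'   \code{age} and \code{thr_250} ... \code{thr_8000}.
#' @export
simulateAudiograms <- function(genotypes, pedigree, config) {
  stopifnot(inherits(config, "simConfig"))
  ids <- sampleIds(genotypes)
  if (nrow(pedigree) &&
      !all(c(pedigree$id1, pedigree$id2) %in% ids))
    stop("simulateAudiograms: pedigree ids not present in genotypes")
  set.seed(config$seed + 1L)
  n <- length(ids)
  sex <- rbinom(n, 1, 0.5)
  age <- runif(n, 18, 80)
  y <- matrix(rep(config$baseline_curve, each = n), n, 7)
  y <- y + outer(age, config$age_slope_per_freq) +
           outer(sex, config$sex_effect_per_freq)
  for (ef in config$snp_effects) {
    coded <- .codeDosage(dosages(genotypes)[, ef$snp], ef$model)
    y <- y + matrix(coded * ef$effect, n, 7)
  }
  if (any(config$shared_factor_loadings != 0)) {
    f <- rnorm(n)
    y <- y + outer(f, config$shared_factor_loadings)
  }
  if (config$h2 > 0) {
    sigma_g <- config$noise_sd * sqrt(config$h2 / (1 - config$h2))
    u <- rnorm(n, 0, sigma_g)
    # siblings: correlation 1/2 (twice the kinship coefficient of 1/4)
    if (nrow(pedigree)) {
      a <- match(pedigree$id1, ids)
      b <- match(pedigree$id2, ids)
      u[b] <- 0.5 * u[a] + sqrt(0.75) * u[b]
    }
    y <- y + u
  }
  if (config$noise_sd > 0)
    y <- y + matrix(rnorm(n * 7, 0, config$noise_sd), n, 7)
  out <- data.frame(id = ids, sex = sex, age = age, stringsAsFactors = FALSE)
  out[THRESHOLD_COLS] <- as.data.frame(y)
  out
}

#' Simulate a complete synthetic cohort
#'
#' @param config a [simConfig()].
#' @return list with elements \code{genotypes} ([GenotypeMatrix-class]),
#'   \code{audiograms} (data.frame), \code{pedigree} (sibling pairs) and
#'   \code{true_params} (the config), sharing one ordered individual-id list.
#' @export
simulateCohort <- function(config) {
  gm <- simulateGenotypes(config)
  ped <- sibPedigree(config)
  audio <- simulateAudiograms(gm, ped, config)
  stopifnot(identical(audio$id, sampleIds(gm)))
  list(genotypes = gm, audiograms = audio, pedigree = ped,
       true_params = config)
}

#' Write a simulated cohort to disk
#'
#' Writes four plain-text files: \code{<prefix>.vcf} (GT + DS fields),
#' \code{<prefix>_pheno.tsv}, \code{<prefix>_pedigree.tsv} and
#' \code{<prefix>_params.json}.
#'
#' @param cohort output of [simulateCohort()].
#' @param prefix output path prefix.
#' @return invisibly, the vector of file paths written.
#' @export
writeCohort <- function(cohort, prefix) {
  paths <- c(vcf = paste0(prefix, ".vcf"),
             pheno = paste0(prefix, "_pheno.tsv"),
             ped = paste0(prefix, "_pedigree.tsv"),
             params = paste0(prefix, "_params.json"))
  writeGenotypesVcf(cohort$genotypes, paths["vcf"])
  write.table(cohort$audiograms, paths["pheno"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$pedigree, paths["ped"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cohort$true_params), paths["params"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
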