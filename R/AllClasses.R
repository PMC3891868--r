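#' @import methods
#' @importFrom stats coef complete.cases cor cov lm optimize pchisq pf pnorm
#'   pt qnorm quantile residuals rbinom rnorm runif sd setNames var
#' @importFrom utils read.table write.table head
NULL

#' GenotypeMatrix: individuals by SNPs dosage container
#'
#' Holds effect-allele dosages (hard calls 0/1/2 or imputed dosages in
#' \eqn{[0, 2]}) for a cohort, together with per-SNP metadata: identifier,
#' chromosome, 1-based position, effect/other allele, strand, whether the SNP
#' was genotyped or imputed, minor allele frequency and (for imputed SNPs) the
#' imputation quality score.
#'
#' Rows of \code{dosage} are individuals (rownames are individual ids),
#' columns are SNPs (colnames are SNP ids, matching \code{snps$snp_id}).
#'
#' @slot dosage numeric matrix, individuals x SNPs, values in \eqn{[0, 2]}
#'   or \code{NA} for missing genotypes.
#' @slot snps data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}, \code{strand},
#'   \code{source} (\code{"genotyped"} or \code{"imputed"}), \code{maf},
#'   \code{info} (\code{NA} for genotyped SNPs).
#'
#' @seealso [genotypeMatrix()], [dosages()], [snpInfo()], [sampleIds()]
#' @export
setClass("GenotypeMatrix",
  representation(dosage = "matrix", snps = "data.frame"))

.snp_meta_cols <- c("snp_id", "chrom", "pos", "effect_allele",
                    "other_allele", "strand", "source", "maf", "info")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosage
  s <- object@snps
  if (!all(.snp_meta_cols %in% names(s)))
    msg <- c(msg, paste("snps metadata must contain columns:",
                        paste(setdiff(.snp_meta_cols, names(s)), collapse = ", ")))
  else {
    if (ncol(d) != nrow(s))
      msg <- c(msg, "number of dosage columns must equal number of SNP metadata rows")
    if (anyDuplicated(s$snp_id))
      msg <- c(msg, "SNP ids must be unique")
    if (is.null(rownames(d)))
      msg <- c(msg, "dosage matrix must have individual ids as rownames")
    if (any(s$pos < 1, na.rm = TRUE))
      msg <- c(msg, "positions are 1-based and must be >= 1")
    if (any(s$maf > 0.5 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "maf must be folded to <= 0.5")
    bad_info <- (s$source == "imputed" & is.na(s$info)) |
                (s$source == "genotyped" & !is.na(s$info))
    if (any(bad_info, na.rm = TRUE))
      msg <- c(msg, "info score must be present iff source == 'imputed'")
    if (length(d) && !all(is.na(d))) {
      rng <- range(d, na.rm = TRUE)
      if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9)
        msg <- c(msg, "dosages must lie in [0, 2]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix (individuals x SNPs) with individual ids as
#'   rownames. Column names, if absent, are taken from \code{snps$snp_id}.
#' @param snps per-SNP metadata data.frame; missing optional columns
#'   (\code{strand}, \code{source}, \code{info}, \code{maf}) are filled with
#'   defaults (\code{"+"}, \code{"genotyped"}, \code{NA}, sample MAF).
#' @return a [GenotypeMatrix-class] object.
#' @export
genotypeMatrix <- function(dosage, snps) {
  dosage <- as.matrix(dosage)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!"strand" %in% names(snps)) snps$strand <- "+"
  if (!"source" %in% names(snps)) snps$source <- "genotyped"
  if (!"info" %in% names(snps))  snps$info   <- NA_real_
  snps$info[snps$source == "genotyped"] <- NA_real_
  if (!"maf" %in% names(snps) || anyNA(snps$maf))
    snps$maf <- sampleMaf(dosage)
  snps <- snps[, .snp_meta_cols]
  rownames(snps) <- NULL
  colnames(dosage) <- snps$snp_id
  new("GenotypeMatrix", dosage = dosage, snps = snps)
}

#' Compute folded minor allele frequency from dosages
#'
#' @param dosage dosage matrix (individuals x SNPs), effect-allele scale.
#' @return numeric vector of per-SNP MAF, folded to \eqn{\le 0.5}.
#' @export
sampleMaf <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' @describeIn GenotypeMatrix-class dosage matrix accessor
#' @param x,object a \code{GenotypeMatrix}
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosage)

#' @describeIn GenotypeMatrix-class per-SNP metadata accessor
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("snpInfo", "GenotypeMatrix", function(x) x@snps)

#' @describeIn GenotypeMatrix-class ordered individual ids
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosage))

#' @describeIn GenotypeMatrix-class number of SNPs
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSnps", "GenotypeMatrix", function(x) ncol(x@dosage))

#' @describeIn GenotypeMatrix-class number of individuals
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@dosage))

#' @rdname GenotypeMatrix-class
#' @param i,j individual / SNP indices (numeric, logical or character)
#' @param ...,drop ignored (subsetting always returns a GenotypeMatrix)
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_len(ncol(x@dosage))
  if (is.character(j)) j <- match(j, x@snps$snp_id)
  new("GenotypeMatrix",
      dosage = x@dosage[i, j, drop = FALSE],
      snps = x@snps[j, , drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosage), "individuals x",
      ncol(object@dosage), "SNPs\n")
  src <- table(object@snps$source)
  cat("  sources:", paste(names(src), src, sep = "=", collapse = ", "), "\n")
  cat("  chromosomes:", paste(unique(object@snps$chrom), collapse = ", "), "\n")
  if (anyNA(object@dosage))
    cat("  missing dosages:", sum(is.na(object@dosage)), "\n")
})

#' AdjustedTrait: covariate- and kinship-adjusted trait residuals
#'
#' The response used by every association test in the package: the trait
#' after removing sex, age and (optionally) the polygenic effect implied by
#' genomic kinship. Carries the design matrix of the fixed effects, the REML
#' heritability estimate, and the GRAMMAR-Gamma calibration factor used to
#' rescale naive residual-regression score statistics.
#'
#' @slot ids ordered individual ids.
#' @slot residuals adjusted trait values (one per individual).
#' @slot traitName name of the trait that was adjusted.
#' @slot h2 REML estimate of narrow-sense heritability (0 when no kinship
#'   adjustment was performed).
#' @slot fixedEffects named vector of fixed-effect estimates
#'   (intercept, sex, age).
#' @slot gamma calibration factor(s) for score tests (> 0; 1 for plain OLS
#'   adjustment). When genotypes were available at adjustment time this is a
#'   named vector with one factor per genetic-model coding.
#' @slot X fixed-effects design matrix used in the adjustment.
#' @slot sigma2 named vector \code{c(genetic =, residual =)} of variance
#'   component estimates.
#' @slot calib list of eigen-space mixed-model pieces
#'   (\code{U}, \code{lam}, \code{Xs}, \code{XtWX}, \code{sigma2_total},
#'   \code{sigma2_e}, \code{sigma2_r}) enabling the per-SNP exact
#'   score-variance calibration in [snpTest()]; empty for OLS adjustment.
#' @seealso [adjustTrait()], [snpTest()]
#' @export
setClass("AdjustedTrait",
  representation(ids = "character", residuals = "numeric",
                 traitName = "character", h2 = "numeric",
                 fixedEffects = "numeric", gamma = "numeric",
                 X = "matrix", sigma2 = "numeric", calib = "list"))

setValidity("AdjustedTrait", function(object) {
  msg <- character()
  if (length(object@ids) != length(object@residuals))
    msg <- c(msg, "ids and residuals must have equal length")
  if (nrow(object@X) != length(object@residuals))
    msg <- c(msg, "design matrix rows must match residual length")
  if (object@h2 < 0 || object@h2 > 1)
    msg <- c(msg, "h2 must lie in [0, 1]")
  if (any(object@gamma <= 0))
    msg <- c(msg, "gamma must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AdjustedTrait", function(object) {
  cat("AdjustedTrait:", object@traitName, "(n =", length(object@ids), ")\n")
  cat("  h2_hat =", signif(object@h2, 3),
      " gamma =", paste(signif(object@gamma, 4), collapse = "/"), "\n")
  fe <- signif(object@fixedEffects, 3)
  cat("  fixed effects:", paste(names(fe), fe, sep = "=", collapse = ", "), "\n")
})

#' @describeIn AdjustedTrait-class adjusted residual vector
#' @param x,object an \code{AdjustedTrait}
#' @export
setGeneric("adjustedValues", function(x) standardGeneric("adjustedValues"))

#' @rdname AdjustedTrait-class
#' @export
setMethod("adjustedValues", "AdjustedTrait",
          function(x) setNames(x@residuals, x@ids))

#' @describeIn AdjustedTrait-class REML heritability estimate
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname AdjustedTrait-class
#' @export
setMethod("heritability", "AdjustedTrait", function(x) x@h2)

#' @describeIn AdjustedTrait-class GRAMMAR-Gamma calibration factor
#' @export
setGeneric("gammaFactor", function(x) standardGeneric("gammaFactor"))

#' @rdname AdjustedTrait-class
#' @export
setMethod("gammaFactor", "AdjustedTrait", function(x) x@gamma)
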