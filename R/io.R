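#' Hard-call genotype classes from dosages
#'
#' Dosages below 0.5 become 0 copies, between 0.5 and 1.5 (inclusive) one
#' copy, above 1.5 two copies. Missing dosages stay missing.
#'
#' @param dosage numeric vector or matrix of effect-allele dosages in
#'   \eqn{[0, 2]}.
#' @return integer-valued object of the same shape with values 0/1/2.
#' @export
hardCall <- function(dosage) {
  out <- ifelse(dosage < 0.5, 0, ifelse(dosage <= 1.5, 1, 2))
  out
}

#' Write a GenotypeMatrix as VCF
#'
#' Emits a minimal VCFv4.2 file with one record per SNP: REF is the other
#' allele, ALT the effect allele (so dosages count ALT copies), GT holds the
#' hard call and DS the dosage. Source, imputation quality and MAF are
#' carried in the INFO keys \code{TYP}, \code{IQS} and \code{MAF}.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output file path (plain text).
#' @return invisibly, \code{path}.
#' @export
writeGenotypesVcf <- function(gm, path) {
  s <- snpInfo(gm)
  d <- dosages(gm)
  hdr <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=TYP,Number=1,Type=String,Description=\"genotyped or imputed\">",
    "##INFO=<ID=IQS,Number=1,Type=Float,Description=\"Imputation quality (Info) score\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Hard-call genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect-allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds(gm)), collapse = "\t"))
  gt_map <- c("0/0", "0/1", "1/1")
  info <- sprintf("TYP=%s%s;MAF=%.6g",
                  ifelse(s$source == "imputed", "imp", "gen"),
                  ifelse(is.na(s$info), "", sprintf(";IQS=%.6g", s$info)),
                  s$maf)
  recs <- vapply(seq_len(nSnps(gm)), function(j) {
    dj <- d[, j]
    cls <- hardCall(dj)
    field <- ifelse(is.na(dj), "./.:.",
                    paste0(gt_map[cls + 1], ":", sprintf("%.6g", dj)))
    paste(c(s$chrom[j], s$pos[j], s$snp_id[j], s$other_allele[j],
            s$effect_allele[j], ".", "PASS", info[j], "GT:DS", field),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

.gt_codes <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
               "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2,
               "0" = 0, "1" = 1)

#' Load genotypes from VCF or dosage TSV
#'
#' For VCF input, hard calls are read from GT (counting ALT = effect-allele
#' copies) and replaced by the DS dosage where present for imputed records;
#' missing genotypes are preserved as missing. Multi-allelic records keep the
#' first ALT allele (with a warning); genotypes carrying a dropped allele
#' become missing. For dosage TSV input, rows are individuals and columns
#' SNPs, with per-SNP metadata in a companion TSV.
#'
#' @param path genotype file.
#' @param format \code{"vcf"} or \code{"dosage_tsv"}.
#' @param meta_path for \code{dosage_tsv}: TSV of SNP metadata with columns
#'   \code{snp_id}, \code{chrom}, \code{pos}, \code{effect_allele},
#'   \code{other_allele} and optionally \code{strand}, \code{source},
#'   \code{maf}, \code{info}.
#' @return a [GenotypeMatrix-class].
#' @export
loadGenotypes <- function(path, format = c("vcf", "dosage_tsv"),
                          meta_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("loadGenotypes: file not found: ", path)
  if (format == "dosage_tsv") {
    if (is.null(meta_path))
      stop("loadGenotypes: dosage_tsv format needs meta_path")
    dos <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    meta <- read.table(meta_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    ids <- as.character(dos[[1]])
    m <- as.matrix(dos[, -1, drop = FALSE])
    rownames(m) <- ids
    if (!identical(colnames(m), as.character(meta$snp_id)))
      stop("loadGenotypes: dosage columns do not match metadata snp_id order")
    return(genotypeMatrix(m, meta))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  if (anyDuplicated(ids))
    stop("loadGenotypes: duplicate SNP id in VCF: ",
         ids[duplicated(ids)][1])
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning("loadGenotypes: ", sum(multi),
            " multi-allelic record(s); keeping first ALT allele only")
    alt[multi] <- sub(",.*", "", alt[multi])
  }
  gt <- vcfR::extract.gt(v)
  dos_gt <- matrix(.gt_codes[gt], nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  ds <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)),
    error = function(e) NULL)
  info_typ <- vcfR::extract.info(v, element = "TYP")
  info_iqs <- suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = "IQS")))
  src <- ifelse(!is.na(info_typ) & info_typ == "imp", "imputed", "genotyped")
  dos <- dos_gt
  if (!is.null(ds)) {
    use_ds <- which(src == "imputed")
    dos[use_ds, ] <- ds[use_ds, , drop = FALSE]
  }
  dos <- t(dos)   # individuals x SNPs
  storage.mode(dos) <- "double"
  snps <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     effect_allele = alt, other_allele = fix[, "REF"],
                     strand = "+", source = src,
                     maf = NA_real_,
                     info = ifelse(src == "imputed", info_iqs, NA_real_),
                     stringsAsFactors = FALSE)
  if (anyNA(snps$pos))
    stop("loadGenotypes: malformed POS field in VCF")
  info_maf <- suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = "MAF")))
  if (!all(is.na(info_maf))) snps$maf <- pmin(info_maf, 1 - info_maf)
  genotypeMatrix(dos, snps)
}

#' Write a GenotypeMatrix as dosage TSV plus metadata TSV
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output dosage TSV (rows individuals, columns SNPs).
#' @param meta_path output SNP metadata TSV.
#' @return invisibly, \code{c(path, meta_path)}.
#' @export
writeDosageTsv <- function(gm, path, meta_path) {
  d <- as.data.frame(dosages(gm))
  out <- cbind(id = sampleIds(gm), d)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(snpInfo(gm), meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Read a phenotype (audiogram) TSV
#'
#' @param path TSV with columns \code{id}, \code{sex}, \code{age} and the
#'   seven threshold columns \code{thr_250} ... \code{thr_8000}.
#' @return validated audiogram data.frame.
#' @export
readPhenotypes <- function(path) {
  ph <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "sex", "age", THRESHOLD_COLS)
  if (!all(need %in% names(ph)))
    stop("readPhenotypes: missing columns: ",
         paste(setdiff(need, names(ph)), collapse = ", "))
  ph$id <- as.character(ph$id)
  if (any(ph$age < 18, na.rm = TRUE))
    warning("readPhenotypes: ages below 18 present; the cohort model assumes adults")
  ph
}

#' Post-imputation quality-control filter
#'
#' Removes SNPs with minor allele frequency below \code{maf_min} and imputed
#' SNPs with imputation quality (Info) score below \code{info_min}. Both
#' comparisons are strict, so SNPs sitting exactly on a threshold are
#' retained. Surviving SNPs keep their original order.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param maf_min MAF exclusion threshold (default 0.01).
#' @param info_min Info-score exclusion threshold for imputed SNPs
#'   (default 0.4).
#' @param verbose log in/out counts (default TRUE).
#' @return the filtered [GenotypeMatrix-class].
#' @export
qcFilter <- function(gm, maf_min = 0.01, info_min = 0.4, verbose = TRUE) {
  s <- snpInfo(gm)
  maf <- s$maf
  if (anyNA(maf)) maf[is.na(maf)] <- sampleMaf(dosages(gm))[is.na(maf)]
  drop_maf <- maf < maf_min
  drop_info <- s$source == "imputed" & !is.na(s$info) & s$info < info_min
  keep <- !(drop_maf | drop_info)
  if (verbose)
    message(sprintf(
      "qcFilter: %d SNPs in, %d removed (MAF < %g: %d; Info < %g: %d), %d out",
      nSnps(gm), sum(!keep), maf_min, sum(drop_maf), info_min,
      sum(drop_info & !drop_maf), sum(keep)))
  if (!any(keep))
    warning("qcFilter: no SNPs survive quality control")
  gm[, which(keep)]
}

#' Load gene intervals from BED
#'
#' BED's half-open 0-based intervals are converted to the package's 1-based
#' inclusive convention (start + 1, end). File order is preserved.
#'
#' @param path BED file with at least 4 columns
#'   (chrom, start, end, name and optionally score, strand).
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}.
#' @export
loadGeneIntervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0)
    stop("loadGeneIntervals: no intervals in ", path)
  if (is.null(gr$name) || anyNA(gr$name))
    stop("loadGeneIntervals: BED needs a name (4th) column")
  df <- data.frame(gene_id = gr$name,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  if (any(df$start > df$end))
    stop("loadGeneIntervals: zero-length interval for ",
         df$gene_id[df$start > df$end][1])
  df
}
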