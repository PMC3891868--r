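#' Assemble a pipeline run configuration
#'
#' @param simulate a [simConfig()] to generate the cohort, or NULL to load
#'   files.
#' @param vcf,pheno input paths (used when \code{simulate} is NULL).
#' @param genes gene-interval data.frame or BED path (optional; enables the
#'   gene-based test).
#' @param discovery discovery-GWAS data.frame with \code{snp_id},
#'   \code{beta}, \code{p_value}, \code{effect_allele} (optional; enables
#'   replication decisions).
#' @param traits traits to analyze (subset of [TRAIT_NAMES]).
#' @param models genetic models to test.
#' @param alpha nominal replication significance level.
#' @param maf_min,info_min post-imputation QC thresholds.
#' @param profile_snps SNPs to profile (default: replicated SNPs).
#' @param out_dir output directory.
#' @param seed integer seed for the run.
#' @return list of class \code{"runConfig"}.
#' @export
runConfig <- function(simulate = NULL, vcf = NULL, pheno = NULL,
                      genes = NULL, discovery = NULL,
                      traits = c("pc1", "pta_high"),
                      models = GENETIC_MODELS, alpha = 0.05,
                      maf_min = 0.01, info_min = 0.4,
                      profile_snps = NULL, out_dir = tempfile("hearqtl_run"),
                      seed = 1L) {
  if (is.null(simulate) && (is.null(vcf) || is.null(pheno)))
    stop("runConfig: either a simulation config or vcf+pheno paths required")
  if (!is.null(vcf) && is.null(simulate) && !file.exists(vcf))
    stop("runConfig: vcf file not found: ", vcf)
  if (!is.null(pheno) && is.null(simulate) && !file.exists(pheno))
    stop("runConfig: phenotype file not found: ", pheno)
  stopifnot(alpha > 0, alpha < 1)
  bad <- setdiff(traits, TRAIT_NAMES)
  if (length(bad))
    stop("runConfig: unknown trait(s): ", paste(bad, collapse = ", "))
  structure(list(simulate = simulate, vcf = vcf, pheno = pheno,
                 genes = genes, discovery = discovery, traits = traits,
                 models = models, alpha = alpha, maf_min = maf_min,
                 info_min = info_min, profile_snps = profile_snps,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "runConfig")
}

.writeTsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full replication-analysis pipeline
#'
#' Stages, in order: cohort acquisition (simulation or file load),
#' post-imputation QC, trait derivation, genomic kinship, GRAMMAR trait
#' adjustment, per-SNP association under the configured genetic models,
#' gene-based PC association (when an annotation is given), replication
#' decisions against discovery results (when given), and genotype
#' profiles of the replicated SNPs. Every intermediate table is written to
#' \code{out_dir} as TSV, plus a JSON manifest with the seed, stage
#' timings and per-gene summary. Identical config + seed give identical
#' outputs.
#'
#' @param config a [runConfig()].
#' @return invisibly, the manifest list (with element \code{tables} naming
#'   the output files and \code{summary}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(seed = config$seed, started = format(Sys.time()),
                   stages = list(), tables = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  cohort <- stage("cohort", {
    if (!is.null(config$simulate)) simulateCohort(config$simulate)
    else list(genotypes = loadGenotypes(config$vcf, "vcf"),
              audiograms = readPhenotypes(config$pheno))
  })
  gm <- stage("qc", qcFilter(cohort$genotypes, config$maf_min,
                             config$info_min, verbose = FALSE))
  traits <- stage("derive_traits", deriveAllTraits(cohort$audiograms))
  manifest$tables$traits <- .writeTsv(traits, config$out_dir, "traits.tsv")
  K <- stage("kinship", suppressWarnings(genomicKinship(gm)))
  manifest$tables$kinship <- {
    writeKinshipTsv(K, file.path(config$out_dir, "kinship.tsv"))
    file.path(config$out_dir, "kinship.tsv")
  }
  ke <- kinshipEigen(K)

  assoc <- stage("assoc_snp", {
    do.call(rbind, lapply(config$traits, function(tr) {
      adj <- adjustTrait(traits[[tr]], traits$sex, traits$age, ke,
                         ids = traits$id, genotypes = gm, trait_name = tr)
      snpAssociation(adj, gm, config$models)
    }))
  })
  manifest$tables$assoc_snp <- .writeTsv(assoc, config$out_dir,
                                         "assoc_snp.tsv")

  gene_tab <- NULL
  if (!is.null(config$genes)) {
    genes <- if (is.character(config$genes)) loadGeneIntervals(config$genes)
             else config$genes
    gene_tab <- stage("assoc_gene", {
      do.call(rbind, lapply(config$traits, function(tr) {
        adj <- adjustTrait(traits[[tr]], traits$sex, traits$age, ke,
                           ids = traits$id, genotypes = gm, trait_name = tr)
        geneAssociation(adj, gm, genes)
      }))
    })
    manifest$tables$assoc_gene <- .writeTsv(gene_tab, config$out_dir,
                                            "assoc_gene.tsv")
  }

  repl <- NULL
  if (!is.null(config$discovery)) {
    repl <- stage("replication", {
      do.call(rbind, lapply(seq_len(nrow(config$discovery)), function(i) {
        disc <- config$discovery[i, ]
        cand <- assoc[assoc$snp_id == disc$snp_id & assoc$note != "untestable", ]
        if (nrow(cand) == 0) return(NULL)
        best <- cand[which.min(cand$p_value), ]
        dec <- replicationCheck(disc, best, config$alpha)
        dec$trait <- best$trait
        dec$model <- best$model
        dec
      }))
    })
    if (!is.null(repl))
      manifest$tables$replication <- .writeTsv(repl, config$out_dir,
                                               "replication.tsv")
  }

  prof_snps <- config$profile_snps
  if (is.null(prof_snps) && !is.null(repl))
    prof_snps <- repl$snp_id[repl$replicated]
  profiles <- NULL
  if (length(prof_snps)) {
    profiles <- stage("profiles", {
      do.call(rbind, lapply(prof_snps, function(sid) {
        pr <- genotypeProfile(cohort$audiograms, gm, sid)
        pr$curves$classification <- pr$classification
        pr$curves
      }))
    })
    manifest$tables$profiles <- .writeTsv(profiles, config$out_dir,
                                          "profiles.tsv")
  }

  summary_tab <- NULL
  if (!is.null(repl)) {
    summary_tab <- repl[, c("snp_id", "replicated", "trait", "model")]
    if (!is.null(profiles))
      summary_tab$profile_class <- vapply(summary_tab$snp_id, function(sid) {
        cl <- unique(profiles$classification[profiles$snp_id == sid])
        if (length(cl)) cl[1] else NA_character_
      }, character(1))
    manifest$tables$summary <- .writeTsv(summary_tab, config$out_dir,
                                         "summary.tsv")
  }
  manifest$summary <- summary_tab
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(
    list(seed = manifest$seed, stages = manifest$stages,
         tables = lapply(manifest$tables, basename)),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
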