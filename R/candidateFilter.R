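#' Greedy significance-first region pruning of GWAS hits
#'
#' Standard clumping semantics: repeatedly take the remaining hit with the
#' globally smallest p-value (ties broken by smaller position, then
#' chromosome, then SNP id, so the result is independent of input order) and
#' discard all remaining hits within \code{window} bp on the same
#' chromosome; repeat until no hits remain.
#'
#' @param hits data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{p_value} (and optionally \code{beta},
#'   \code{effect_allele}).
#' @param window half-width of the pruning region in bp (default 250 kb,
#'   i.e. 250 kb upstream and downstream).
#' @return the surviving hits, sorted by (chrom, pos).
#' @export
pruneRegions <- function(hits, window = 250000) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$p_value, hits$pos, hits$chrom, hits$snp_id)
  h <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(h))
  alive <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    hit_zone <- alive & h$chrom == h$chrom[i] &
      abs(h$pos - h$pos[i]) <= window
    alive[hit_zone] <- FALSE
  }
  out <- h[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## gap (bp) between a position and a gene interval; 0 if intragenic
.geneGap <- function(pos, start, end) {
  ifelse(pos < start, start - pos, ifelse(pos > end, pos - end, 0))
}

#' Annotate pruned hits with candidate genes and apply exclusion filters
#'
#' For each pruned hit: hits with no annotated gene within \code{window} bp
#' are dropped as gene deserts; otherwise the closest gene (gap to the
#' nearest interval edge, 0 if the SNP is intragenic) is assigned, plus --
#' when \code{multi_gene = TRUE} -- every further gene within the window.
#' Genes whose names match an exclusion pattern (unknown-function
#' designations such as LOC/FAM by default) or appear on the
#' disease-exclusion list are then removed.
#'
#' @param hits pruned hits (see [pruneRegions()]).
#' @param genes gene-interval data.frame (see [loadGeneIntervals()]).
#' @param window annotation window in bp (default 250 kb).
#' @param name_exclusions character vector of regular expressions for
#'   excluded gene names.
#' @param disease_exclusions character vector of gene ids known to act in
#'   diseases unrelated to the trait.
#' @param multi_gene assign all in-window genes rather than only the
#'   closest (default FALSE).
#' @param verbose log filter accounting (default TRUE).
#' @return data.frame with one row per (hit, gene): \code{snp_id},
#'   \code{chrom}, \code{pos}, \code{p_value}, \code{gene_id},
#'   \code{distance} (bp, 0 if intragenic), \code{intragenic}.
#' @export
annotateAndFilter <- function(hits, genes, window = 250000,
                              name_exclusions = c("^LOC", "^FAM"),
                              disease_exclusions = character(),
                              multi_gene = FALSE, verbose = TRUE) {
  if (nrow(genes) == 0)
    stop("annotateAndFilter: empty gene annotation")
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    hit <- hits[i, ]
    same <- genes[genes$chrom == hit$chrom, , drop = FALSE]
    if (nrow(same) == 0) return(NULL)
    gap <- .geneGap(hit$pos, same$start, same$end)
    inside <- gap <= window
    if (!any(inside)) return(NULL)              # gene desert
    pick <- if (multi_gene) which(inside) else which.min(gap)
    pick <- pick[order(gap[pick])]
    data.frame(snp_id = hit$snp_id, chrom = hit$chrom, pos = hit$pos,
               p_value = hit$p_value, gene_id = same$gene_id[pick],
               distance = gap[pick], intragenic = gap[pick] == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_desert <- nrow(hits) - length(unique(out$snp_id))
  if (is.null(out))
    out <- data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), p_value = numeric(),
                      gene_id = character(), distance = numeric(),
                      intragenic = logical(), stringsAsFactors = FALSE)
  excl_name <- Reduce(`|`, lapply(name_exclusions, grepl, x = out$gene_id),
                      accumulate = FALSE, right = FALSE,
                      init = rep(FALSE, nrow(out)))
  excl_dis <- out$gene_id %in% disease_exclusions
  if (verbose)
    message(sprintf(paste0(
      "annotateAndFilter: %d hits in, %d dropped as gene deserts; ",
      "%d gene rows, %d name-excluded, %d disease-excluded, %d out"),
      nrow(hits), n_desert, nrow(out), sum(excl_name),
      sum(excl_dis & !excl_name), sum(!(excl_name | excl_dis))))
  out <- out[!(excl_name | excl_dis), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prioritize candidate genes into a shortlist
#'
#' A gene is shortlisted when an antibody is available for expression
#' studies (the mandatory gate) and at least one further criterion holds:
#' a highly suggestive discovery p-value, similarity with hereditary
#' hearing-loss gene families, reported inner-ear expression, a pathway
#' link, or -- when \code{include_suggestive = TRUE}, the default -- a
#' suggestive discovery p-value. Criteria flags are supplied as inputs; no
#' external database is queried.
#'
#' @param candidates annotated candidates (see [annotateAndFilter()]).
#' @param criteria data.frame keyed by \code{gene_id} with logical columns
#'   \code{antibody_available}, \code{hhl_family_similarity},
#'   \code{suggestive_p}, \code{highly_suggestive_p},
#'   \code{ear_expression_db}, \code{pathway_link} (missing columns are
#'   treated as all-FALSE).
#' @param include_suggestive count a suggestive p-value as a qualifying
#'   criterion (default TRUE).
#' @return \code{candidates} with the criteria columns and a
#'   \code{shortlisted} flag appended.
#' @export
prioritizeCandidates <- function(candidates, criteria,
                                 include_suggestive = TRUE) {
  flags <- c("antibody_available", "hhl_family_similarity", "suggestive_p",
             "highly_suggestive_p", "ear_expression_db", "pathway_link")
  for (f in flags)
    if (!f %in% names(criteria)) criteria[[f]] <- FALSE
  idx <- match(candidates$gene_id, criteria$gene_id)
  out <- candidates
  for (f in flags) {
    v <- criteria[[f]][idx]
    v[is.na(v)] <- FALSE
    out[[f]] <- v
  }
  extra <- out$highly_suggestive_p | out$hhl_family_similarity |
    out$ear_expression_db | out$pathway_link
  if (include_suggestive) extra <- extra | out$suggestive_p
  out$shortlisted <- out$antibody_available & extra
  out
}

#' Full hit-to-candidate selection pipeline
#'
#' Chains [pruneRegions()], [annotateAndFilter()] and
#' [prioritizeCandidates()]; the composition is idempotent.
#'
#' @inheritParams pruneRegions
#' @inheritParams annotateAndFilter
#' @inheritParams prioritizeCandidates
#' @return the prioritized candidate table.
#' @export
selectCandidates <- function(hits, genes, criteria, window = 250000,
                             name_exclusions = c("^LOC", "^FAM"),
                             disease_exclusions = character(),
                             multi_gene = FALSE, include_suggestive = TRUE,
                             verbose = TRUE) {
  pruned <- pruneRegions(hits, window)
  if (verbose)
    message(sprintf("selectCandidates: %d hits pruned to %d region sentinels",
                    nrow(hits), nrow(pruned)))
  ann <- annotateAndFilter(pruned, genes, window, name_exclusions,
                           disease_exclusions, multi_gene, verbose)
  prioritizeCandidates(ann, criteria, include_suggestive)
}
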