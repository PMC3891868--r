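#' Select intragenic SNPs for a gene
#'
#' Keeps SNPs whose 1-based position satisfies
#' \code{start <= pos <= end} on the gene's chromosome (inclusive bounds, no
#' flanking margin), preserving SNP order.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param gene one-row data.frame (or list) with \code{gene_id},
#'   \code{chrom}, \code{start}, \code{end}.
#' @return the intragenic [GenotypeMatrix-class] (possibly with zero SNPs).
#' @export
selectIntragenicSnps <- function(gm, gene) {
  s <- snpInfo(gm)
  keep <- s$chrom == gene$chrom & s$pos >= gene$start & s$pos <= gene$end
  gm[, which(keep)]
}

#' Principal components of a gene's genotype matrix
#'
#' Dosages are hard-called to 0/1/2 (unless \code{hard_call = FALSE}, kept
#' as raw dosages for sensitivity analysis), columns are mean-centered, and
#' the covariance eigenstructure is extracted. Missing genotypes are
#' replaced by the SNP mean before centering.
#'
#' @param sub intragenic [GenotypeMatrix-class] (at least 1 SNP).
#' @param hard_call hard-call imputed dosages before the PCA (default TRUE).
#' @return list with \code{scores} (n x k), \code{fractions} (eigenvalue
#'   fractions, non-increasing, summing to 1).
#' @export
genotypePcs <- function(sub, hard_call = TRUE) {
  if (nSnps(sub) < 1)
    stop("genotypePcs: no SNPs in gene")
  g <- dosages(sub)
  if (hard_call) g <- hardCall(g)
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    nas <- which(is.na(g), arr.ind = TRUE)
    g[nas] <- mu[nas[, 2]]
  }
  g <- sweep(g, 2, colMeans(g))
  if (all(abs(g) < 1e-12))
    stop("genotypePcs: all SNPs constant in this gene")
  sv <- svd(g)
  ev <- sv$d^2 / (nrow(g) - 1)
  fractions <- ev / sum(ev)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores, fractions = fractions)
}

#' Select genotype PCs by the > 1/N variance rule
#'
#' With N the total number of intragenic SNPs, keeps the components whose
#' variance fraction strictly exceeds 1/N. If the strict rule selects
#' nothing (degenerate fraction patterns, e.g. a single SNP) PC1 is kept
#' with a warning so the gene is not silently dropped.
#'
#' @param fractions eigenvalue fractions from [genotypePcs()].
#' @param N total intragenic SNP count.
#' @return integer indices of the selected components (decreasing
#'   eigenvalue order).
#' @export
selectPcs <- function(fractions, N) {
  stopifnot(N >= 1)
  sel <- which(fractions > 1 / N)
  if (length(sel) == 0) {
    warning("selectPcs: strict >1/N rule selected no component; keeping PC1")
    sel <- 1L
  }
  sel
}

#' Gene-based association test on selected genotype PCs
#'
#' Joint multiple regression of the adjusted trait on the selected genotype
#' principal components; the p-value is the overall F test of the joint null
#' that all PC coefficients are zero.
#'
#' @param adj an [AdjustedTrait-class].
#' @param scores PC score matrix (individuals x selected PCs, aligned with
#'   \code{adj}).
#' @return list with \code{p_value}, \code{f_stat}, \code{df1}, \code{df2},
#'   \code{note}.
#' @export
geneBasedTest <- function(adj, scores) {
  scores <- as.matrix(scores)
  y <- adj@residuals
  n <- length(y)
  k <- ncol(scores)
  if (n != nrow(scores))
    stop("geneBasedTest: score rows do not match trait length")
  if (n <= k + 1)
    return(list(p_value = NA_real_, f_stat = NA_real_, df1 = k,
                df2 = n - k - 1, note = "untestable"))
  qx <- qr(cbind(1, scores))
  res <- qr.resid(qx, y)
  rss1 <- sum(res^2)
  rss0 <- sum((y - mean(y))^2)
  df1 <- qx$rank - 1
  df2 <- n - qx$rank
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(p_value = pf(f, df1, df2, lower.tail = FALSE), f_stat = f,
       df1 = df1, df2 = df2, note = "ok")
}

#' Gene-based association across a gene annotation
#'
#' For each gene: select intragenic SNPs, compute genotype PCs on the 0/1/2
#' coding, keep components explaining more than 1/N of the variance, and
#' jointly regress the adjusted trait on them. Mirrors the gene-level result
#' schema (total SNPs, selected PCs, variance explained, p-value, trait,
#' strand).
#'
#' @param adj an [AdjustedTrait-class].
#' @param gm a [GenotypeMatrix-class].
#' @param genes gene-interval data.frame (see [loadGeneIntervals()]).
#' @param hard_call passed to [genotypePcs()].
#' @return data.frame with columns \code{gene_id}, \code{total_n_snps},
#'   \code{n_selected_pcs}, \code{variance_explained_pct}, \code{p_value},
#'   \code{trait}, \code{strand}, \code{note}.
#' @export
geneAssociation <- function(adj, gm, genes, hard_call = TRUE) {
  idx <- match(adj@ids, sampleIds(gm))
  if (anyNA(idx))
    stop("geneAssociation: adjusted-trait ids missing from genotypes")
  gm <- gm[idx, ]
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gene <- genes[i, ]
    sub <- selectIntragenicSnps(gm, gene)
    base <- data.frame(gene_id = gene$gene_id, total_n_snps = nSnps(sub),
                       n_selected_pcs = 0L,
                       variance_explained_pct = NA_real_,
                       p_value = NA_real_, trait = adj@traitName,
                       strand = gene$strand, note = "untestable",
                       stringsAsFactors = FALSE)
    if (nSnps(sub) == 0) return(base)
    pcs <- tryCatch(genotypePcs(sub, hard_call), error = function(e) NULL)
    if (is.null(pcs)) return(base)
    sel <- selectPcs(pcs$fractions, nSnps(sub))
    fit <- geneBasedTest(adj, pcs$scores[, sel, drop = FALSE])
    base$n_selected_pcs <- length(sel)
    base$variance_explained_pct <- 100 * sum(pcs$fractions[sel])
    base$p_value <- fit$p_value
    base$note <- fit$note
    base
  })
  do.call(rbind, rows)
}
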