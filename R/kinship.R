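#' Genomic kinship (relationship) matrix
#'
#' Centered-and-scaled allele-sharing estimator:
#' \deqn{K_{ij} = \frac{1}{M}\sum_m \frac{(g_{im}-2p_m)(g_{jm}-2p_m)}
#'   {2p_m(1-p_m)}}
#' averaged over SNPs non-missing in both individuals. On this scale the
#' diagonal is near 1 and full siblings share about 0.5 (twice the kinship
#' coefficient of 1/4). Monomorphic SNPs are skipped with a warning. If the
#' estimate has negative eigenvalues they are clipped at zero (bending) with
#' a warning, so the result is positive semi-definite.
#'
#' @param gm a [GenotypeMatrix-class]; at least 50 SNPs are recommended
#'   (a warning is raised below that).
#' @return symmetric n x n matrix with individual ids as dimnames.
#' @export
genomicKinship <- function(gm) {
  d <- dosages(gm)
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1 & !is.na(p)
  if (any(!poly))
    warning("genomicKinship: skipping ", sum(!poly), " monomorphic SNP(s)")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  if (ncol(d) < 50)
    warning("genomicKinship: only ", ncol(d),
            " usable SNPs; estimates will be noisy")
  z <- sweep(sweep(d, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(z)
  z[!obs] <- 0
  counts <- tcrossprod(obs * 1)
  if (any(counts == 0))
    stop("genomicKinship: some individual pair shares no genotyped SNP")
  k <- tcrossprod(z) / counts
  k <- (k + t(k)) / 2
  eg <- eigen(k, symmetric = TRUE)
  if (any(eg$values < -1e-8)) {
    warning("genomicKinship: bending ", sum(eg$values < 0),
            " negative eigenvalue(s) to zero")
    vals <- pmax(eg$values, 0)
    k <- eg$vectors %*% (vals * t(eg$vectors))
    k <- (k + t(k)) / 2
  }
  dimnames(k) <- list(sampleIds(gm), sampleIds(gm))
  k
}

#' Precompute the eigendecomposition of a kinship matrix
#'
#' The REML fit and GRAMMAR adjustment both work in the eigenbasis of K;
#' when many traits are adjusted against the same kinship matrix the
#' decomposition can be shared by passing the result of this function
#' wherever a kinship matrix is accepted.
#'
#' @param K symmetric kinship matrix (ids as dimnames).
#' @return object of class \code{"kinshipEigen"} with elements \code{vectors},
#'   \code{values} (clipped at 0) and \code{ids}.
#' @export
kinshipEigen <- function(K) {
  if (inherits(K, "kinshipEigen")) return(K)
  if (max(abs(K - t(K))) > 1e-12)
    stop("kinshipEigen: matrix is not symmetric")
  eg <- eigen(K, symmetric = TRUE)
  structure(list(vectors = eg$vectors, values = pmax(eg$values, 0),
                 ids = rownames(K)),
            class = "kinshipEigen")
}

#' Write / read a kinship matrix as TSV
#'
#' Square matrix with an id header column, the on-disk interchange format of
#' the pipeline.
#'
#' @param K kinship matrix.
#' @param path TSV path.
#' @return invisibly \code{path} (write) / the matrix (read).
#' @export
writeKinshipTsv <- function(K, path) {
  out <- cbind(id = rownames(K), as.data.frame(K))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeKinshipTsv
#' @export
readKinshipTsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  k <- as.matrix(df[, -1, drop = FALSE])
  rownames(k) <- as.character(df[[1]])
  k
}

#' Expected relationship matrix from a sibling pedigree
#'
#' The pedigree-expected counterpart of [genomicKinship()]: twice the
#' kinship coefficients, i.e. 1 on the diagonal and 1/2 between full
#' siblings, 0 elsewhere. This is the exact covariance scale of the
#' polygenic term in the synthetic-cohort generator, and the natural
#' relationship matrix for variance-component recovery studies on
#' simulated data.
#'
#' @param ids ordered individual ids.
#' @param pedigree data.frame of sibling pairs (\code{id1}, \code{id2}).
#' @return symmetric matrix with \code{ids} as dimnames.
#' @export
pedigreeRelatedness <- function(ids, pedigree) {
  n <- length(ids)
  A <- diag(n)
  dimnames(A) <- list(ids, ids)
  if (nrow(pedigree)) {
    a <- match(pedigree$id1, ids)
    b <- match(pedigree$id2, ids)
    if (anyNA(a) || anyNA(b))
      stop("pedigreeRelatedness: pedigree ids not in id list")
    A[cbind(a, b)] <- 0.5
    A[cbind(b, a)] <- 0.5
  }
  A
}
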