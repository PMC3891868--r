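## Build the fixed-effects design matrix (intercept, sex, age).
.fixefDesign <- function(n, sex = NULL, age = NULL) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(sex)) X <- cbind(X, sex = sex)
  if (!is.null(age)) X <- cbind(X, age = age)
  X
}

#' REML fit of the polygenic model
#'
#' Fits \eqn{y = X\beta + g + e} with \eqn{Var(g) = \sigma^2_g K},
#' \eqn{Var(e) = \sigma^2_e I} by restricted maximum likelihood. The
#' covariance is reparameterized as \eqn{\sigma^2_P (h^2 K + (1-h^2) I)} and
#' the profiled REML criterion is minimized over \eqn{h^2 \in [0, 0.99]} by
#' golden-section/parabolic search (tolerance 1e-6) in the eigenbasis of K,
#' where every evaluation is O(np).
#'
#' When K carries no relatedness information (e.g. K = I) the profile is
#' flat in \eqn{h^2}; a non-identifiability warning is raised and the fixed
#' effects reduce to their OLS estimates.
#'
#' @param trait numeric response vector.
#' @param sex,age covariate vectors (either may be NULL).
#' @param kinship kinship matrix or a [kinshipEigen()] object.
#' @param h2 optional fixed heritability; skips the search when given.
#' @param tol search tolerance on h2.
#' @return list with \code{h2}, \code{fixed_effects} (named), \code{sigma2_g},
#'   \code{sigma2_e}, \code{sigma2_total}, \code{loglik} (restricted,
#'   up to a constant), plus the eigen-space pieces reused by
#'   [adjustTrait()].
#' @export
fitPolygenic <- function(trait, sex = NULL, age = NULL, kinship,
                         h2 = NULL, tol = 1e-6) {
  y <- as.numeric(trait)
  n <- length(y)
  if (n < 30)
    warning("fitPolygenic: n < 30; variance components will be unstable")
  if (var(y) == 0)
    stop("fitPolygenic: trait has zero variance")
  ke <- kinshipEigen(kinship)
  if (length(ke$values) != n)
    stop("fitPolygenic: kinship dimension does not match trait length")
  X <- .fixefDesign(n, sex, age)
  p <- ncol(X)
  U <- ke$vectors
  d <- ke$values
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  remlPieces <- function(h2v) {
    lam <- h2v * d + (1 - h2v)
    w <- 1 / lam
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    beta <- solve(XtWX, XtWy)
    resid <- ys - Xs %*% beta
    rss <- sum(w * resid^2)
    sigma2 <- rss / (n - p)
    nll <- 0.5 * (sum(log(lam)) + (n - p) * log(sigma2) +
                  determinant(XtWX, logarithm = TRUE)$modulus[1])
    list(nll = nll, beta = drop(beta), sigma2 = sigma2, lam = lam,
         resid = drop(resid), XtWX = XtWX)
  }

  flat <- FALSE
  if (is.null(h2)) {
    opt <- optimize(function(h) remlPieces(h)$nll, c(0, 0.99), tol = tol)
    h2_hat <- opt$minimum
    # the interior search can miss a boundary minimum at 0
    if (remlPieces(0)$nll <= opt$objective + 1e-10) {
      if (abs(remlPieces(0)$nll - opt$objective) < 1e-8 &&
          h2_hat > 0.01) {
        flat <- TRUE
        warning("fitPolygenic: REML criterion is flat in h2 (kinship carries ",
                "no information); h2 is not identifiable")
      } else {
        h2_hat <- 0
      }
    }
  } else {
    if (h2 < 0 || h2 > 0.99)
      stop("fitPolygenic: fixed h2 must lie in [0, 0.99]")
    h2_hat <- h2
  }
  fit <- remlPieces(h2_hat)
  beta <- setNames(fit$beta, colnames(X))
  list(h2 = h2_hat, fixed_effects = beta,
       sigma2_total = fit$sigma2,
       sigma2_g = h2_hat * fit$sigma2,
       sigma2_e = (1 - h2_hat) * fit$sigma2,
       loglik = -fit$nll, flat = flat,
       eigen = ke, X = X, Xs = Xs, ys = ys,
       lam = fit$lam, resid_s = fit$resid, XtWX = fit$XtWX)
}

#' Adjust a trait for sex, age and genomic kinship (GRAMMAR step)
#'
#' The first stage of the two-stage GRAMMAR association strategy: fit the
#' polygenic model by REML, subtract the fixed effects and the BLUP of the
#' polygenic effect, and compute the GRAMMAR-Gamma calibration factor so
#' that fast residual-regression score tests on the output are correctly
#' calibrated despite relatedness.
#'
#' The gamma factor is estimated as the average, over a random subset of
#' SNPs, of the ratio between the naive residual-regression score statistic
#' and the exact mixed-model score statistic for the same SNP. Because the
#' naive statistic uses the covariate-projected genotype, gamma tends to 1
#' as \eqn{\hat h^2 \to 0} and the per-SNP tests collapse to plain OLS.
#'
#' With \code{kinship = NULL} the adjustment is ordinary least squares on
#' (intercept, sex, age) with \code{gamma = 1} and \code{h2 = 0}.
#'
#' @param trait numeric trait vector.
#' @param sex,age covariates (either may be NULL).
#' @param kinship kinship matrix, [kinshipEigen()] object, or NULL.
#' @param ids individual ids (default \code{names(trait)} or ind1..indn).
#' @param genotypes optional [GenotypeMatrix-class] used to estimate gamma
#'   (at most \code{n_gamma_snps} random SNPs); without it gamma is 1.
#' @param trait_name label stored on the result.
#' @param h2 optional fixed heritability passed to [fitPolygenic()].
#' @param n_gamma_snps SNP subset size for the gamma estimate (default 1000).
#' @return an [AdjustedTrait-class].
#' @export
adjustTrait <- function(trait, sex = NULL, age = NULL, kinship = NULL,
                        ids = NULL, genotypes = NULL,
                        trait_name = "trait", h2 = NULL,
                        n_gamma_snps = 1000) {
  y <- as.numeric(trait)
  n <- length(y)
  if (is.null(ids)) ids <- names(trait)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (is.null(kinship)) {
    X <- .fixefDesign(n, sex, age)
    qx <- qr(X)
    beta <- qr.coef(qx, y)
    res <- qr.resid(qx, y)
    sigma2 <- sum(res^2) / (n - ncol(X))
    return(new("AdjustedTrait", ids = as.character(ids), residuals = res,
               traitName = trait_name, h2 = 0,
               fixedEffects = setNames(beta, colnames(X)), gamma = 1,
               X = X, sigma2 = c(genetic = 0, residual = sigma2),
               calib = list()))
  }
  fit <- fitPolygenic(y, sex, age, kinship, h2 = h2)
  U <- fit$eigen$vectors
  # environmental residual: y - X beta - BLUP(g) = sigma2_e V^{-1}(y - X beta)
  res_s <- (1 - fit$h2) / fit$lam * fit$resid_s
  res <- drop(U %*% res_s)
  gamma <- 1
  if (!is.null(genotypes)) {
    gamma <- .estimateGamma(fit, genotypes, n_gamma_snps)
  } else if (fit$h2 > 1e-6) {
    message("adjustTrait: no genotypes supplied; gamma left at 1 ",
            "(score tests may be conservative under relatedness)")
  }
  calib <- list(U = fit$eigen$vectors, lam = fit$lam, Xs = fit$Xs,
                XtWX = fit$XtWX, sigma2_total = fit$sigma2_total,
                sigma2_e = fit$sigma2_e,
                sigma2_r = sum(res_s^2) / (n - ncol(fit$X)))
  new("AdjustedTrait", ids = as.character(ids), residuals = res,
      traitName = trait_name, h2 = fit$h2,
      fixedEffects = fit$fixed_effects, gamma = gamma,
      X = fit$X, sigma2 = c(genetic = fit$sigma2_g,
                            residual = fit$sigma2_e),
      calib = calib)
}

## gamma = mean over SNPs of naive/exact score-statistic ratio; with the
## covariate-projected genotype both numerators coincide, so the ratio is
## sigma_e^4 c'P_V c / (c~'c~ * sigma_r^2) per coded SNP vector c. The ratio
## depends on the genetic-model coding, so one factor is estimated per model.
.estimateGamma <- function(fit, genotypes, n_gamma_snps,
                           models = GENETIC_MODELS) {
  G <- dosages(genotypes)
  n <- nrow(G)
  m <- ncol(G)
  take <- if (m > n_gamma_snps) sort(sample.int(m, n_gamma_snps)) else seq_len(m)
  G <- G[, take, drop = FALSE]
  G[is.na(G)] <- 0
  X <- fit$X
  p <- ncol(X)
  qx <- qr(X)
  U <- fit$eigen$vectors
  lam <- fit$lam
  res_s <- (1 - fit$h2) / lam * fit$resid_s
  sigma2_r <- sum(res_s^2) / (n - p)
  ratioFor <- function(C) {
    keep <- apply(C, 2, var) > 0
    C <- C[, keep, drop = FALSE]
    if (ncol(C) == 0) return(1)
    Ct <- qr.resid(qx, C)              # identity-metric projection
    ctc <- colSums(Ct^2)
    Cs <- crossprod(U, C)
    q1 <- colSums(Cs^2 / lam)
    B <- crossprod(fit$Xs, Cs / lam)   # p x m
    q2 <- colSums(B * solve(fit$XtWX, B))
    cPVc <- (q1 - q2) / fit$sigma2_total
    ratios <- fit$sigma2_e^2 * cPVc / (ctc * sigma2_r)
    ok <- is.finite(ratios) & ratios > 0
    if (!any(ok)) return(1)
    mean(ratios[ok])
  }
  vapply(setNames(models, models),
         function(mod) ratioFor(.codeDosage(G, mod)), numeric(1))
}
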