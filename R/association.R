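GENETIC_MODELS <- c("additive", "dominant", "recessive", "overdominant")

#' Code dosages under a genetic model
#'
#' The additive model uses the raw effect-allele dosage (0..2). The binary
#' models first hard-call the dosage (thresholds 0.5/1.5) and then code:
#' dominant = carrier of at least one effect allele, recessive = homozygous
#' for the effect allele, overdominant = heterozygous.
#'
#' @param dosage numeric vector of dosages in \eqn{[0, 2]} (NA allowed).
#' @param model one of \code{"additive"}, \code{"dominant"},
#'   \code{"recessive"}, \code{"overdominant"}.
#' @return numeric coded vector of the same length.
#' @export
encodeGeneticModel <- function(dosage,
                               model = c("additive", "dominant",
                                         "recessive", "overdominant")) {
  model <- match.arg(model)
  if (any(dosage < -1e-9 | dosage > 2 + 1e-9, na.rm = TRUE))
    stop("encodeGeneticModel: dosages outside [0, 2]")
  .codeDosage(dosage, model)
}

#' Score/regression test of an adjusted trait on a coded genotype
#'
#' Regresses the adjusted residuals on the covariate-projected coded
#' genotype and divides the resulting chi-square statistic by a gamma
#' calibration factor (the effect estimate by gamma, its standard error by
#' sqrt(gamma)). When the adjusted trait carries the mixed-model
#' eigen-space pieces the factor is computed exactly for the tested SNP
#' (the naive/exact score-variance ratio for that coded vector), which
#' keeps all four genetic-model codings calibrated even for sparse
#' homozygote cells; otherwise the trait's stored scalar (per-model) gamma
#' is used. With no kinship adjustment (gamma = 1, h2 = 0) the test is
#' numerically identical to ordinary least squares of the raw trait on
#' (covariates, genotype).
#'
#' Missing dosages are dropped pairwise for OLS-adjusted traits; for
#' kinship-adjusted traits (where the calibration works in the full-cohort
#' eigenbasis) they are imputed to the SNP mean.
#'
#' Two-sided p-values use the large-sample normal (chi-square 1 df)
#' reference by default; \code{reference = "t"} uses the exact t reference
#' with the OLS residual degrees of freedom.
#'
#' @param adj an [AdjustedTrait-class].
#' @param coded coded genotype vector aligned with \code{adj} (NAs are
#'   dropped pairwise).
#' @param reference \code{"normal"} or \code{"t"}.
#' @param model genetic-model name used to pick the matching calibration
#'   factor when \code{adj} carries per-model gammas (default
#'   \code{"additive"}).
#' @return list with \code{beta}, \code{se}, \code{p_value}, \code{n_used},
#'   \code{note} (\code{"ok"}, \code{"untestable"} or
#'   \code{"low_confidence"}).
#' @export
snpTest <- function(adj, coded, reference = c("normal", "t"),
                    model = "additive") {
  reference <- match.arg(reference)
  stopifnot(is(adj, "AdjustedTrait"))
  exact <- length(adj@calib) > 0
  n_used <- sum(!is.na(coded))
  if (exact && anyNA(coded))
    coded[is.na(coded)] <- mean(coded, na.rm = TRUE)
  ok <- !is.na(coded)
  r <- adj@residuals[ok]
  g <- coded[ok]
  X <- adj@X[ok, , drop = FALSE]
  n <- length(r)
  if (n < 3 || var(g) == 0)
    return(list(beta = 0, se = NA_real_, p_value = 1, n_used = n_used,
                note = "untestable"))
  gt <- qr.resid(qr(X), g)
  gtg <- sum(gt^2)
  if (gtg < 1e-12)
    return(list(beta = 0, se = NA_real_, p_value = 1, n_used = n_used,
                note = "untestable"))
  b <- sum(gt * r) / gtg
  rss <- sum(r^2) - b^2 * gtg
  df <- n - ncol(X) - 1
  se <- sqrt(rss / df / gtg)
  if (exact) {
    cb <- adj@calib
    cs <- crossprod(cb$U, g)
    q1 <- sum(cs^2 / cb$lam)
    bv <- crossprod(cb$Xs, cs / cb$lam)
    cPVc <- (q1 - crossprod(bv, solve(cb$XtWX, bv))[1]) / cb$sigma2_total
    gam <- cb$sigma2_e^2 * cPVc / (gtg * cb$sigma2_r)
    if (!is.finite(gam) || gam <= 0) gam <- 1
  } else {
    gam <- if (!is.null(names(adj@gamma)) && model %in% names(adj@gamma))
      adj@gamma[[model]] else adj@gamma[[1]]
  }
  beta_c <- b / gam
  se_c <- se / sqrt(gam)
  chi2 <- (beta_c / se_c)^2
  p <- if (reference == "normal") pchisq(chi2, 1, lower.tail = FALSE)
       else 2 * pt(-sqrt(chi2), df)
  list(beta = beta_c, se = se_c, p_value = p, n_used = n_used, note = "ok")
}

#' Per-SNP association of an adjusted trait under genetic models
#'
#' Runs [snpTest()] for every SNP and requested model. Non-additive codings
#' with a non-reference cell smaller than \code{min_cell} are flagged
#' \code{"low_confidence"}; monomorphic codings return p = 1 with an
#' \code{"untestable"} flag. No multiplicity correction is applied across
#' models.
#'
#' @param adj an [AdjustedTrait-class]; its ids must all be present in
#'   \code{gm}.
#' @param gm a [GenotypeMatrix-class].
#' @param models character subset of
#'   additive/dominant/recessive/overdominant.
#' @param reference p-value reference, see [snpTest()].
#' @param min_cell minimum non-reference cell count before a binary coding
#'   is flagged low-confidence (default 10).
#' @return data.frame with one row per SNP x model: \code{snp_id},
#'   \code{trait}, \code{model}, \code{maf}, \code{beta}, \code{se},
#'   \code{p_value}, \code{n_used}, \code{effect_allele}, \code{strand},
#'   \code{source}, \code{info}, \code{note}.
#' @export
snpAssociation <- function(adj, gm, models = GENETIC_MODELS,
                           reference = c("normal", "t"), min_cell = 10) {
  reference <- match.arg(reference)
  models <- match.arg(models, GENETIC_MODELS, several.ok = TRUE)
  idx <- match(adj@ids, sampleIds(gm))
  if (anyNA(idx))
    stop("snpAssociation: adjusted-trait ids missing from genotypes")
  d <- dosages(gm)[idx, , drop = FALSE]
  s <- snpInfo(gm)
  rows <- vector("list", nSnps(gm) * length(models))
  k <- 0
  for (j in seq_len(nSnps(gm))) {
    dj <- d[, j]
    for (mod in models) {
      coded <- encodeGeneticModel(dj, mod)
      res <- snpTest(adj, coded, reference, model = mod)
      if (mod != "additive" && res$note == "ok") {
        non_ref <- sum(coded > 0, na.rm = TRUE)
        if (min(non_ref, sum(coded == 0, na.rm = TRUE)) < min_cell)
          res$note <- "low_confidence"
      }
      k <- k + 1
      rows[[k]] <- data.frame(snp_id = s$snp_id[j], trait = adj@traitName,
                              model = mod, maf = s$maf[j], beta = res$beta,
                              se = res$se, p_value = res$p_value,
                              n_used = res$n_used,
                              effect_allele = s$effect_allele[j],
                              strand = s$strand[j], source = s$source[j],
                              info = s$info[j], note = res$note,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Replication decision at nominal significance
#'
#' A SNP replicates when the replication effect has the same direction as
#' the discovery effect and the replication p-value is below \code{alpha}
#' (default the nominal 5 percent). No correction is applied across the four
#' genetic models. If both sides carry effect alleles and they differ, the
#' discovery effect is flipped when its effect allele matches the
#' replication's other allele; an unresolvable mismatch is an error.
#'
#' @param discovery list or one-row data.frame with \code{beta} and
#'   optionally \code{effect_allele}.
#' @param replication list or one-row data.frame with \code{beta},
#'   \code{p_value} and optionally \code{effect_allele},
#'   \code{other_allele}, \code{snp_id}.
#' @param alpha significance level in (0, 1).
#' @return one-row data.frame: \code{snp_id}, \code{discovery_beta},
#'   \code{replication_beta}, \code{replication_p}, \code{same_direction},
#'   \code{replicated}, \code{alpha}.
#' @export
replicationCheck <- function(discovery, replication, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  db <- as.numeric(discovery$beta)
  rb <- as.numeric(replication$beta)
  rp <- as.numeric(replication$p_value)
  da <- discovery$effect_allele
  ra <- replication$effect_allele
  if (!is.null(da) && !is.null(ra) && !is.na(da) && !is.na(ra) &&
      da != ra) {
    oa <- replication$other_allele
    if (!is.null(oa) && !is.na(oa) && da == oa) {
      db <- -db
    } else {
      stop("replicationCheck: effect-allele mismatch not resolvable by flip (",
           da, " vs ", ra, ")")
    }
  }
  same <- sign(db) == sign(rb) && db != 0 && rb != 0
  data.frame(snp_id = if (!is.null(replication$snp_id))
               as.character(replication$snp_id) else NA_character_,
             discovery_beta = db, replication_beta = rb,
             replication_p = rp, same_direction = same,
             replicated = same && rp < alpha, alpha = alpha,
             stringsAsFactors = FALSE)
}
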