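#' The 13 hearing traits used in association analyses
#'
#' Seven single-frequency thresholds, three pure-tone averages and the first
#' three principal components of the 7 thresholds.
#' @export
TRAIT_NAMES <- c("f250", "f500", "f1000", "f2000", "f4000", "f6000", "f8000",
                 "pta_low", "pta_mid", "pta_high", "pc1", "pc2", "pc3")

.pta_bands <- list(low = c("thr_250", "thr_500", "thr_1000"),
                   mid = c("thr_500", "thr_1000", "thr_2000"),
                   high = c("thr_4000", "thr_8000"))

#' Pure-tone average over a frequency band
#'
#' Unweighted arithmetic mean of air-conduction thresholds over the band's
#' frequencies: low = 0.25/0.5/1 kHz, mid = 0.5/1/2 kHz, high = 4/8 kHz.
#' 6 kHz belongs to no band.
#'
#' @param thresholds named numeric vector (or single-row data.frame) with
#'   threshold columns \code{thr_250} ... \code{thr_8000}, or an audiogram
#'   data.frame (one PTA per row).
#' @param band \code{"low"}, \code{"mid"} or \code{"high"}.
#' @return numeric PTA in dB (vector if a table was given).
#' @export
computePta <- function(thresholds, band = c("low", "mid", "high")) {
  band <- match.arg(band)
  cols <- .pta_bands[[band]]
  if (is.data.frame(thresholds)) {
    if (!all(cols %in% names(thresholds)))
      stop("computePta: missing frequency column(s): ",
           paste(setdiff(cols, names(thresholds)), collapse = ", "))
    return(rowMeans(thresholds[cols]))
  }
  if (!all(cols %in% names(thresholds)))
    stop("computePta: missing frequency value(s): ",
         paste(setdiff(cols, names(thresholds)), collapse = ", "))
  mean(thresholds[cols])
}

#' Principal components of the 7-frequency audiogram
#'
#' Eigendecomposition of the 7 x 7 covariance matrix of raw thresholds
#' (unstandardized, preserving the dB scale), computed before any covariate
#' adjustment. Scores are centered projections on the top 3 eigenvectors;
#' each component's sign is fixed so its loading sum is non-negative, making
#' higher PC1 correspond to worse overall hearing in typical data.
#'
#' @param audiograms audiogram data.frame (\code{id} plus the seven
#'   \code{thr_*} columns; at least 8 complete rows).
#' @return list with \code{scores} (n x 3 matrix, columns pc1..pc3),
#'   \code{variance_fractions} (all 7 eigenvalue fractions, non-increasing,
#'   summing to 1) and \code{loadings} (7 x 3).
#' @export
computeTraitPcs <- function(audiograms) {
  y <- as.matrix(audiograms[, THRESHOLD_COLS])
  if (any(!complete.cases(y)))
    stop("computeTraitPcs: incomplete audiograms present")
  if (nrow(y) < 8)
    stop("computeTraitPcs: need at least 8 complete audiograms")
  cv <- cov(y)
  eg <- eigen(cv, symmetric = TRUE)
  n_pos <- sum(eg$values > max(eg$values) * 1e-12)
  if (n_pos == 0)
    stop("computeTraitPcs: thresholds have zero variance")
  if (n_pos < 3)
    warning("computeTraitPcs: covariance is rank-deficient (", n_pos,
            " positive eigenvalue(s)); trailing PC scores are degenerate")
  vals <- pmax(eg$values, 0)
  frac <- vals / sum(vals)
  vec <- eg$vectors[, 1:3, drop = FALSE]
  flip <- colSums(vec) < 0
  vec[, flip] <- -vec[, flip]
  centered <- sweep(y, 2, colMeans(y))
  scores <- centered %*% vec
  colnames(scores) <- c("pc1", "pc2", "pc3")
  rownames(vec) <- THRESHOLD_COLS
  list(scores = scores, variance_fractions = frac, loadings = vec)
}

#' Derive the 13 hearing traits from raw audiograms
#'
#' @param audiograms audiogram data.frame with \code{id}, \code{sex},
#'   \code{age} and the seven \code{thr_*} columns.
#' @return data.frame with \code{id}, \code{sex}, \code{age} and the 13
#'   trait columns named as in [TRAIT_NAMES]; the PC eigenvalue fractions are
#'   attached as attribute \code{"variance_fractions"}.
#' @export
deriveAllTraits <- function(audiograms) {
  pcs <- computeTraitPcs(audiograms)
  out <- data.frame(id = as.character(audiograms$id),
                    sex = audiograms$sex, age = audiograms$age,
                    stringsAsFactors = FALSE)
  out[TRAIT_NAMES[1:7]] <- audiograms[, THRESHOLD_COLS]
  out$pta_low <- computePta(audiograms, "low")
  out$pta_mid <- computePta(audiograms, "mid")
  out$pta_high <- computePta(audiograms, "high")
  out[c("pc1", "pc2", "pc3")] <- pcs$scores
  attr(out, "variance_fractions") <- pcs$variance_fractions
  out
}
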