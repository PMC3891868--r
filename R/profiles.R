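PROFILE_FREQS <- c(0.25, 0.5, 1, 2, 4, 8)   # 6 kHz excluded by default
PROFILE_COLS <- paste0("thr_", c(250, 500, 1000, 2000, 4000, 8000))

#' Age/sex-adjust audiogram thresholds for profiling
#'
#' Per-frequency ordinary least squares on (intercept, sex, age); the
#' residuals plus the grand mean are returned, keeping the dB scale. The
#' kinship BLUP is deliberately not removed: profile curves display
#' covariate-adjusted thresholds, not mixed-model residuals.
#'
#' @param audiograms audiogram data.frame.
#' @return the same data.frame with adjusted \code{thr_*} columns.
#' @export
adjustAudiograms <- function(audiograms) {
  X <- cbind(1, audiograms$sex, audiograms$age)
  qx <- qr(X)
  out <- audiograms
  for (cl in THRESHOLD_COLS)
    out[[cl]] <- qr.resid(qx, audiograms[[cl]]) + mean(audiograms[[cl]])
  out
}

#' Stratify adjusted audiograms by genotype at one SNP
#'
#' Dosages are hard-called (0.5/1.5 thresholds) and relabelled so that A is
#' the major allele in the sample: AA = homozygous major, AB heterozygous,
#' BB = homozygous minor. Groups smaller than \code{min_group_n} are flagged
#' underpowered.
#'
#' @param audiograms (adjusted) audiogram data.frame.
#' @param gm a [GenotypeMatrix-class] containing \code{snp_id}.
#' @param snp_id SNP to stratify on.
#' @param min_group_n underpowered-flag threshold (default 30).
#' @return list of three groups (\code{AA}, \code{AB}, \code{BB}), each a
#'   list with \code{data} (audiogram rows), \code{n} and
#'   \code{underpowered}; the SNP id is attached as an attribute.
#' @export
stratifyByGenotype <- function(audiograms, gm, snp_id, min_group_n = 30) {
  j <- match(snp_id, snpInfo(gm)$snp_id)
  if (is.na(j))
    stop("stratifyByGenotype: SNP not found: ", snp_id)
  idx <- match(audiograms$id, sampleIds(gm))
  if (anyNA(idx))
    stop("stratifyByGenotype: audiogram ids missing from genotypes")
  cls <- hardCall(dosages(gm)[idx, j])
  p_eff <- mean(cls, na.rm = TRUE) / 2
  if (p_eff <= 0 || p_eff >= 1 || var(cls, na.rm = TRUE) == 0)
    stop("stratifyByGenotype: SNP ", snp_id, " is monomorphic")
  minor_copies <- if (p_eff <= 0.5) cls else 2 - cls
  groups <- lapply(setNames(0:2, c("AA", "AB", "BB")), function(k) {
    rows <- which(!is.na(minor_copies) & minor_copies == k)
    list(data = audiograms[rows, , drop = FALSE], n = length(rows),
         underpowered = length(rows) < min_group_n)
  })
  attr(groups, "snp_id") <- snp_id
  groups
}

#' Per-genotype mean and standard-error audiogram curves
#'
#' Mean and SE (= sd / sqrt(n)) of the adjusted thresholds per frequency
#' and genotype group, over 0.25/0.5/1/2/4/8 kHz (6 kHz can be re-included
#' with \code{include_6khz = TRUE}).
#'
#' @param groups output of [stratifyByGenotype()].
#' @param include_6khz include the 6 kHz threshold (default FALSE).
#' @return long-format data.frame with columns \code{snp_id},
#'   \code{genotype}, \code{freq_khz}, \code{n}, \code{mean_db},
#'   \code{se_db}, \code{underpowered}. SE is missing for groups of size 1.
#' @export
profileCurves <- function(groups, include_6khz = FALSE) {
  cols <- if (include_6khz) THRESHOLD_COLS else PROFILE_COLS
  freqs <- if (include_6khz) AUDIO_FREQS else PROFILE_FREQS
  rows <- lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    if (g$n == 0)
      return(data.frame(snp_id = attr(groups, "snp_id"), genotype = gname,
                        freq_khz = freqs, n = 0L, mean_db = NA_real_,
                        se_db = NA_real_, underpowered = TRUE,
                        stringsAsFactors = FALSE))
    y <- as.matrix(g$data[, cols])
    data.frame(snp_id = attr(groups, "snp_id"), genotype = gname,
               freq_khz = freqs, n = g$n, mean_db = colMeans(y),
               se_db = if (g$n > 1) apply(y, 2, sd) / sqrt(g$n) else NA_real_,
               underpowered = g$underpowered, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a genotype-stratified audiogram profile
#'
#' A quantitative stand-in for visual inspection of the three curves. The
#' primary contrast is BB minus AA: the profile is called when the
#' difference has a consistent sign at \code{min_freqs} of the frequencies
#' and the across-frequency average difference exceeds
#' \code{z} times the pooled SE (the per-frequency SEs of the difference,
#' averaged -- a conservative choice whenever frequencies are positively
#' correlated). A positive significant contrast is attributed to whichever
#' homozygote deviates more from the heterozygote curve: BB deterioration
#' or AA improvement; a negative one is BB improvement.
#'
#' @param profile output of [profileCurves()].
#' @param z SE multiple for the average-difference gate (default 1.96).
#' @param min_freqs required number of same-sign frequencies (default 5
#'   of 6).
#' @return one of \code{"deterioration_BB"}, \code{"improvement_BB"},
#'   \code{"improvement_AA"}, \code{"none"}.
#' @export
classifyProfile <- function(profile, z = 1.96, min_freqs = 5) {
  if (any(profile$underpowered)) {
    warning("classifyProfile: underpowered genotype group; returning 'none'")
    return("none")
  }
  wide <- split(profile, profile$genotype)
  if (anyNA(c(wide$AA$mean_db, wide$AB$mean_db, wide$BB$mean_db)))
    return("none")
  d <- wide$BB$mean_db - wide$AA$mean_db
  se_d <- sqrt(wide$BB$se_db^2 + wide$AA$se_db^2)
  pooled <- mean(se_d)
  n_pos <- sum(d > 0)
  n_neg <- sum(d < 0)
  sig <- abs(mean(d)) > z * pooled
  consistent <- max(n_pos, n_neg) >= min_freqs
  if (!sig || !consistent) return("none")
  if (mean(d) < 0) return("improvement_BB")
  dev_bb <- mean(abs(wide$BB$mean_db - wide$AB$mean_db))
  dev_aa <- mean(abs(wide$AA$mean_db - wide$AB$mean_db))
  if (dev_bb >= dev_aa) "deterioration_BB" else "improvement_AA"
}

#' Genotype-phenotype profile for one SNP
#'
#' Convenience wrapper: age/sex-adjust the audiograms, stratify by
#' genotype, compute the mean/SE curves and classify the pattern.
#'
#' @inheritParams stratifyByGenotype
#' @inheritParams classifyProfile
#' @param adjust adjust thresholds for age and sex first (default TRUE).
#' @param include_6khz passed to [profileCurves()].
#' @return list with \code{curves} (long-format table) and
#'   \code{classification}.
#' @export
genotypeProfile <- function(audiograms, gm, snp_id, min_group_n = 30,
                            adjust = TRUE, include_6khz = FALSE,
                            z = 1.96, min_freqs = 5) {
  if (adjust) audiograms <- adjustAudiograms(audiograms)
  groups <- stratifyByGenotype(audiograms, gm, snp_id, min_group_n)
  curves <- profileCurves(groups, include_6khz)
  cls <- suppressWarnings(classifyProfile(curves, z, min_freqs))
  list(curves = curves, classification = cls)
}

#' Plot genotype-stratified audiogram curves
#'
#' Frequency (kHz, log-spaced x axis) against adjusted threshold (dB) with
#' one colored curve and error bars per genotype (AA black, AB red, BB
#' green) and group sizes in the legend.
#'
#' @param curves output of [profileCurves()].
#' @param title plot title (defaults to the SNP id).
#' @return a ggplot object.
#' @export
plotProfile <- function(curves, title = NULL) {
  lab <- vapply(split(curves, curves$genotype),
                function(d) sprintf("%s (n=%d)", d$genotype[1], d$n[1]),
                character(1))
  curves$genotype <- factor(curves$genotype, levels = c("AA", "AB", "BB"))
  if (is.null(title)) title <- curves$snp_id[1]
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = freq_khz, y = mean_db,
                               colour = genotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_db - se_db,
                                        ymax = mean_db + se_db),
                           width = 0.05) +
    ggplot2::scale_x_log10(breaks = unique(curves$freq_khz)) +
    ggplot2::scale_colour_manual(
      values = c(AA = "black", AB = "red", BB = "green3"),
      labels = lab[c("AA", "AB", "BB")]) +
    ggplot2::labs(x = "Frequency (kHz)",
                  y = "Adjusted threshold (dB)",
                  colour = "Genotype", title = title) +
    ggplot2::theme_classic()
}
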