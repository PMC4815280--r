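#' Detection configuration
#'
#' @param alpha family significance level for the confidence-interval
#'   detectors (default 0.05). Interval quantiles are Bonferroni-scaled by
#'   the per-chromosome marker count `M`.
#' @param genotype_specific for the copy-number detector: compare each
#'   marker's intensity against the reference statistics of the sample's own
#'   called genotype rather than the pooled statistics.
#' @param paired use a paired normal sample as the reference center instead
#'   of the panel mean (the panel still supplies the dispersion, since a
#'   single paired sample carries none).
#' @param mp_alpha significance threshold for the multipoint hypothesis-test
#'   procedure (`p < mp_alpha`, strict).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(alpha = 0.05, genotype_specific = FALSE,
                             paired = FALSE, mp_alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, genotype_specific = genotype_specific,
                 paired = paired, mp_alpha = mp_alpha),
            class = "detection_config")
}

# per-marker Bonferroni M: number of usable markers sharing the marker's
# chromosome and probe class (CN probes form their own track)
bonferroni_M <- function(ann, usable) {
  key <- paste(ann$chromosome, ann$probe_class)
  counts <- tapply(usable, key, sum)
  m <- as.numeric(counts[key])
  pmax(m, 1)
}

# ---- core flag computations (stats passed explicitly so the leave-one-out
# ---- reference construction can reuse them)

ai_flags_core <- function(fhat, f_mean, f_sd, ann, cfg) {
  usable <- ann$probe_class == "SNP" &
    rowSums(is.na(f_mean)) == 0 & rowSums(is.na(f_sd)) == 0 &
    apply(f_sd, 1, min) > 0
  M <- bonferroni_M(ann, usable)
  z_hom <- stats::qnorm(1 - cfg$alpha / (3 * M))
  z_het <- stats::qnorm(1 - cfg$alpha / (6 * M))
  in_AA <- fhat >= f_mean[, "AA"] - z_hom * f_sd[, "AA"] & fhat <= 1
  in_AB <- abs(fhat - f_mean[, "AB"]) <= z_het * f_sd[, "AB"]
  in_BB <- fhat >= 0 & fhat <= f_mean[, "BB"] + z_hom * f_sd[, "BB"]
  flag <- as.numeric(!(in_AA | in_AB | in_BB))
  flag[!usable | is.na(fhat)] <- NA_real_
  flag
}

loh_flags_core <- function(fhat, ab_mean, ab_sd, ann, cfg) {
  usable <- ann$probe_class == "SNP" & !is.na(ab_mean) & !is.na(ab_sd) & ab_sd > 0
  M <- bonferroni_M(ann, usable)
  z <- stats::qnorm(1 - cfg$alpha / (2 * M))
  flag <- as.numeric(abs(fhat - ab_mean) > z * ab_sd)
  flag[!usable | is.na(fhat)] <- NA_real_
  flag
}

cnv_flags_core <- function(t_track, mean, sd, ann, cfg) {
  usable <- !is.na(mean) & !is.na(sd) & sd > 0
  M <- bonferroni_M(ann, usable)
  z <- (t_track - mean) / sd
  thr <- stats::qnorm(1 - cfg$alpha / (2 * M))
  flag <- numeric(length(z))
  flag[!is.na(z) & z > thr] <- 1
  flag[!is.na(z) & z < -thr] <- -1
  p <- pmin(2 * (1 - stats::pnorm(abs(z))) * M, 1)
  bad <- !usable | is.na(t_track)
  flag[bad] <- NA_real_; z[bad] <- NA_real_; p[bad] <- NA_real_
  list(flags = flag, z = z, p = p)
}

#' Single-point allelic-imbalance detector
#'
#' Flags a SNP when its calibrated allele frequency falls outside the union
#' of three genotype confidence intervals built from the reference panel:
#' \deqn{CI(AA) = [\bar f(AA) - z_{1-\alpha/3M} S(AA),\, 1]}
#' \deqn{CI(AB) = \bar f(AB) \pm z_{1-\alpha/6M} S(AB)}
#' \deqn{CI(BB) = [0,\, \bar f(BB) + z_{1-\alpha/3M} S(BB)]}
#' with `M` the per-chromosome count of usable SNPs. In paired mode only the
#' interval of the paired-normal genotype is used, centered at the paired
#' sample's allele frequency, with quantiles \eqn{1-\alpha/M} (homozygous)
#' and \eqn{1-\alpha/2M} (heterozygous); the dispersion still comes from the
#' panel.
#'
#' @param f_track numeric vector of calibrated (CPA + LIM) allele
#'   frequencies, aligned to the panel annotation.
#' @param panel a [build_reference_panel()] object.
#' @param cfg a [detection_config()].
#' @param paired_af,paired_genotype paired-normal allele frequency and
#'   genotype tracks, required when `cfg$paired` is `TRUE`.
#' @return Numeric vector of flags in \{0, 1\}; `NA` where the marker is
#'   skipped (missing value, missing genotype statistics, or degenerate).
#' @export
detect_ai_single <- function(f_track, panel, cfg = detection_config(),
                             paired_af = NULL, paired_genotype = NULL) {
  ann <- panel$annotation
  stopifnot(length(f_track) == nrow(ann))
  if (!isTRUE(cfg$paired))
    return(ai_flags_core(f_track, panel$f_mean_g, panel$f_sd_g, ann, cfg))
  if (is.null(paired_af) || is.null(paired_genotype))
    stop("paired mode requires paired_af and paired_genotype")
  usable <- ann$probe_class == "SNP" & !is.na(paired_af) &
    paired_genotype %in% c("AA", "AB", "BB")
  sd_g <- panel$f_sd_g[cbind(seq_len(nrow(ann)),
                             match(paired_genotype, c("AA", "AB", "BB")))]
  usable <- usable & !is.na(sd_g) & sd_g > 0
  M <- bonferroni_M(ann, usable)
  z_hom <- stats::qnorm(1 - cfg$alpha / M)
  z_het <- stats::qnorm(1 - cfg$alpha / (2 * M))
  inside <- rep(NA, length(f_track))
  hom_a <- paired_genotype == "AA"
  hom_b <- paired_genotype == "BB"
  het <- paired_genotype == "AB"
  inside[hom_a] <- f_track[hom_a] >= (paired_af - z_hom * sd_g)[hom_a] &
    f_track[hom_a] <= 1
  inside[het] <- abs(f_track - paired_af)[het] <= (z_het * sd_g)[het]
  inside[hom_b] <- f_track[hom_b] >= 0 &
    f_track[hom_b] <= (paired_af + z_hom * sd_g)[hom_b]
  flag <- as.numeric(!inside)
  flag[!usable | is.na(f_track)] <- NA_real_
  flag
}

#' Single-point LOH/LCSH detector
#'
#' Flags a SNP when its calibrated allele frequency falls outside the
#' heterozygote reference interval
#' \eqn{\bar f(AB) \pm z_{1-\alpha/2M} S(AB)}. Runs of flagged SNPs are the
#' single-point signature of loss of heterozygosity or a long contiguous
#' stretch of homozygosity; homozygous SNPs flag by design and the
#' multipoint scan normalizes against reference behavior. Paired mode
#' substitutes the paired-normal allele frequency as the interval center
#' (center-only substitution; the panel keeps supplying `S(AB)`).
#'
#' @inheritParams detect_ai_single
#' @return Numeric vector of flags in \{0, 1\} with `NA` where skipped.
#' @export
detect_loh_single <- function(f_track, panel, cfg = detection_config(),
                              paired_af = NULL) {
  ann <- panel$annotation
  stopifnot(length(f_track) == nrow(ann))
  center <- if (isTRUE(cfg$paired)) {
    if (is.null(paired_af)) stop("paired mode requires paired_af")
    paired_af
  } else panel$f_mean_g[, "AB"]
  loh_flags_core(f_track, center, panel$f_sd_g[, "AB"], ann, cfg)
}

#' Single-point copy-number detector
#'
#' Tests each marker's final intensity `t` against the reference interval
#' \eqn{\bar t \pm z_{1-\alpha/2M} \hat\sigma}: flag `+1` (gain) above the
#' upper bound, `-1` (loss) below the lower bound (strict inequalities),
#' else `0`. The test statistic is \eqn{Z = (t - \bar t)/\hat\sigma} and the
#' Bonferroni-adjusted two-sided p-value
#' \eqn{p = \min\{2(1-\Phi(|Z|)) M,\, 1\}}. In genotype-specific mode the
#' reference mean and SD are those of the sample's called genotype (NoCall
#' markers fall back to the pooled statistics); in paired mode the paired
#' sample's `t` replaces the reference mean while the panel supplies the SD.
#'
#' @param t_track numeric vector of final intensities (see
#'   [remove_aberrant_probe_perturbation()]).
#' @param genotype_track the sample's genotype calls (used in
#'   genotype-specific mode).
#' @param panel a [build_reference_panel()] object.
#' @param cfg a [detection_config()].
#' @param paired_t paired-normal intensity track for paired mode.
#' @return A list with `flags` (-1/0/1), `z` and `p` vectors; `NA` where the
#'   marker is degenerate or missing.
#' @export
detect_cnv_single <- function(t_track, genotype_track = NULL, panel,
                              cfg = detection_config(), paired_t = NULL) {
  ann <- panel$annotation
  stopifnot(length(t_track) == nrow(ann))
  if (isTRUE(cfg$genotype_specific)) {
    if (is.null(genotype_track)) stop("genotype-specific mode needs genotypes")
    idx <- match(genotype_track, c("AA", "AB", "BB"))
    mean <- panel$t_mean_g[cbind(seq_len(nrow(ann)), idx)]
    sd <- panel$t_sd_g[cbind(seq_len(nrow(ann)), idx)]
    nocall <- is.na(idx) | is.na(mean) | is.na(sd)
    if (any(nocall)) {
      mean[nocall] <- panel$t_mean[nocall]
      sd[nocall] <- panel$t_sd[nocall]
    }
  } else {
    mean <- panel$t_mean
    sd <- panel$t_sd
  }
  if (isTRUE(cfg$paired)) {
    if (is.null(paired_t)) stop("paired mode requires paired_t")
    mean <- paired_t
  }
  sd[panel$degenerate] <- NA_real_
  cnv_flags_core(t_track, mean, sd, ann, cfg)
}
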