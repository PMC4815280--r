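#' Estimate the coefficient of preferential hybridization (CPA)
#'
#' At a marker, alleles A and B may hybridize with different efficiency, so
#' the raw relative intensity of heterozygotes drifts from 0.5. The CPA
#' \eqn{\kappa_m} is estimated from heterozygous normal reference samples as
#' the mean odds \eqn{\kappa_m = \mathrm{mean}_i\, h_{i,m}/(1-h_{i,m})}.
#' An optional leave-one-out correction mode adds the average of the
#' bracketed per-sample deviations from the mean odds, which is identically
#' zero, hence equivalent; it is exposed for transparency only.
#'
#' @param het_raw_afs raw allele frequencies of heterozygous reference
#'   samples at one marker, each strictly in (0, 1).
#' @param correction `"none"` (default) or `"loo"` (adds the zero-mean
#'   deviation term).
#' @return \eqn{\kappa_m > 0}. With fewer than 2 heterozygotes there is no
#'   information about preferential hybridization and `1` is returned with a
#'   warning.
#' @examples
#' estimate_cpa(c(0.5, 0.5))   # balanced: kappa = 1
#' estimate_cpa(c(0.6, 0.6))   # kappa = 1.5
#' @export
estimate_cpa <- function(het_raw_afs, correction = c("none", "loo")) {
  correction <- match.arg(correction)
  h <- het_raw_afs[!is.na(het_raw_afs)]
  if (length(h) < 2) {
    warning("fewer than 2 heterozygous reference samples; kappa set to 1")
    return(1)
  }
  if (any(h <= 0 | h >= 1))
    stop("heterozygote raw AFs must be strictly inside (0, 1)")
  ratios <- h / (1 - h)
  k <- mean(ratios)
  if (correction == "loo") {
    n <- length(ratios)
    k <- k + n / (n - 1) * mean(ratios - mean(ratios)) # identically zero
  }
  k
}

#' Adjust a raw allele frequency for preferential hybridization
#'
#' \deqn{\hat h = \frac{h}{h + \kappa (1 - h)}}
#' Strictly increasing in `h`, with fixed points at 0 and 1; the identity
#' when \eqn{\kappa = 1}.
#'
#' @param h raw allele frequency in \[0, 1\] (vectorized).
#' @param kappa positive CPA value(s), recycled against `h`.
#' @return Adjusted allele frequency \eqn{\hat h \in [0, 1]}.
#' @examples
#' cpa_adjust(0.5, 2) # 1/3
#' @export
cpa_adjust <- function(h, kappa) {
  if (any(kappa <= 0, na.rm = TRUE)) stop("kappa must be positive")
  if (any(h < 0 | h > 1, na.rm = TRUE)) stop("h must lie in [0, 1]")
  h / (h + kappa * (1 - h))
}

#' Genotype cluster means for allele-frequency calibration
#'
#' @param mean_AA,mean_AB,mean_BB per-marker reference averages of the
#'   CPA-adjusted allele frequency for each genotype (vectors or scalars).
#'   Calibration requires `mean_BB < mean_AB < mean_AA`; markers violating
#'   the ordering are uncalibratable.
#' @return A list of class `cluster_means`.
#' @export
cluster_means <- function(mean_AA, mean_AB, mean_BB) {
  n <- max(length(mean_AA), length(mean_AB), length(mean_BB))
  structure(list(mean_AA = rep_len(as.numeric(mean_AA), n),
                 mean_AB = rep_len(as.numeric(mean_AB), n),
                 mean_BB = rep_len(as.numeric(mean_BB), n)),
            class = "cluster_means")
}

#' Calibrate CPA-adjusted allele frequencies by linear interpolation
#'
#' Piecewise-linear map anchored at the genotype cluster means: the AA, AB
#' and BB cluster means are sent to 1, 1/2 and 0 exactly, values between
#' adjacent anchors are linearly interpolated, and values beyond the outer
#' anchors clamp to 1 or 0. Continuous and monotone in \eqn{\hat h}; a value
#' exactly equal to an anchor falls in the lower branch.
#'
#' @param h_hat CPA-adjusted allele frequency vector.
#' @param cluster a [cluster_means()] (scalar anchors recycle over `h_hat`).
#' @return Calibrated allele frequency \eqn{\hat f \in [0, 1]}; missing where
#'   an input is missing or the marker's anchors are unordered
#'   (uncalibratable).
#' @examples
#' lim_calibrate(2/3, cluster_means(1, 0.5, 0)) # 2/3
#' @export
lim_calibrate <- function(h_hat, cluster) {
  stopifnot(inherits(cluster, "cluster_means"))
  n <- length(h_hat)
  aa <- rep_len(cluster$mean_AA, n)
  ab <- rep_len(cluster$mean_AB, n)
  bb <- rep_len(cluster$mean_BB, n)
  ok <- !is.na(h_hat) & !is.na(aa) & !is.na(ab) & !is.na(bb) &
    (bb < ab) & (ab < aa)
  f <- rep(NA_real_, n)
  h <- h_hat
  up <- ok & h > aa
  hi <- ok & h > ab & h <= aa
  lo <- ok & h > bb & h <= ab
  dn <- ok & h <= bb
  f[up] <- 1
  f[hi] <- 0.5 + 0.5 * (h[hi] - ab[hi]) / (aa[hi] - ab[hi])
  f[lo] <- 0.5 * (h[lo] - bb[lo]) / (ab[lo] - bb[lo])
  f[dn] <- 0
  f
}

#' Individual-level allele frequency with CPA + LIM adjustment
#'
#' Convenience composition: adjusts a sample's raw allele-frequency track for
#' preferential hybridization with the panel's per-marker \eqn{\kappa} and
#' recalibrates against the panel's genotype cluster means.
#'
#' @param sample a [sample_data()].
#' @param panel a [build_reference_panel()] object supplying `kappa` and
#'   cluster means.
#' @return A data.frame with columns `marker_id`, `raw`, `cpa_adjusted`,
#'   `final`.
#' @export
estimate_af <- function(sample, panel) {
  stopifnot(inherits(sample, "sample_data"), inherits(panel, "snp_panel"))
  if (!identical(sample$annotation$marker_id, panel$annotation$marker_id))
    stop("sample and panel annotations differ")
  raw <- sample$raw_af
  adj <- cpa_adjust(raw, panel$kappa)
  fin <- lim_calibrate(adj, panel$cluster)
  data.frame(marker_id = sample$annotation$marker_id,
             raw = raw, cpa_adjusted = adj, final = fin,
             stringsAsFactors = FALSE)
}
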