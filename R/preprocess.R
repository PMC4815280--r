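#' Normalize per-marker total hybridization intensities
#'
#' Computes the per-marker total intensity (`h_A + h_B` for SNP probes) for a
#' set of samples and applies, in this fixed order, the optional steps
#' (1) log2 scale transformation, (2) chip-effect removal by subtracting the
#' per-sample mean or median and dividing by the per-sample standard
#' deviation, and (3) quantile normalization across samples. All eight
#' on/off combinations of the three steps are expressible, matching the
#' preprocessing grid used to build reference databases.
#'
#' @param samples a list of [sample_data()] sharing one annotation, or a
#'   numeric matrix (markers x samples) of total intensities.
#' @param log2_transform apply `log2` to total intensities (zeros become
#'   missing).
#' @param center `"mean"`, `"median"` or `"none"`: chip-effect removal.
#'   Either location estimate is followed by division by the chip standard
#'   deviation.
#' @param quantile_norm map each sample's sorted values onto the
#'   across-sample mean of sorted values; ties receive the mean of their
#'   target slots.
#' @param center_chromosomes chromosome labels entering the per-chip
#'   location/scale estimates (default: autosomes only; include `"X"` for
#'   female-configured samples).
#'
#' @return A numeric matrix `s` (markers x samples) with the annotation's
#'   marker ids as rownames.
#' @export
preprocess_intensities <- function(samples,
                                   log2_transform = TRUE,
                                   center = c("none", "mean", "median"),
                                   quantile_norm = FALSE,
                                   center_chromosomes = as.character(1:22)) {
  center <- match.arg(center)
  if (is.matrix(samples)) {
    s <- samples
    chrom <- NULL
  } else {
    mats <- samples_to_matrices(samples)
    s <- mats$h_A + mats$h_B
    if (!is.matrix(s)) s <- matrix(s, ncol = length(samples))
    rownames(s) <- mats$annotation$marker_id
    colnames(s) <- mats$sample_ids
    chrom <- mats$annotation$chromosome
  }
  if (log2_transform) {
    s[!is.na(s) & s <= 0] <- NA_real_
    s <- log2(s)
  }
  if (center != "none") {
    use <- if (is.null(chrom)) rep(TRUE, nrow(s)) else chrom %in% center_chromosomes
    for (j in seq_len(ncol(s))) {
      loc <- if (center == "mean") mean(s[use, j], na.rm = TRUE)
             else stats::median(s[use, j], na.rm = TRUE)
      sc <- stats::sd(s[use, j], na.rm = TRUE)
      if (!is.finite(sc) || sc == 0)
        stop("degenerate chip: zero intensity standard deviation in sample ",
             colnames(s)[j] %||% j)
      s[, j] <- (s[, j] - loc) / sc
    }
  }
  if (quantile_norm) s <- quantile_normalize(s)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantile-normalize a matrix of intensities
#'
#' Each column's sorted values are replaced by the across-column mean of
#' sorted values; tied values receive the mean of the target slots they
#' occupy. Missing cells are left missing and excluded from the target
#' distribution. Idempotent.
#'
#' @param x numeric matrix (markers x samples).
#' @return The normalized matrix, same dimensions and dimnames.
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2) return(x)
  cc <- stats::complete.cases(x)
  if (!any(cc)) return(x)
  ref <- rowMeans(apply(x[cc, , drop = FALSE], 2, sort))
  out <- x
  n <- length(ref)
  for (j in seq_len(ncol(x))) {
    v <- x[cc, j]
    # average rank -> linear interpolation into the target distribution,
    # so ties get the mean of their target slots
    r <- rank(v, ties.method = "average")
    out[cc, j] <- if (n == 1) ref else stats::approx(seq_len(n), ref, xout = r)$y
  }
  out
}

#' Remove aberrant-probe perturbation from an intensity track
#'
#' Produces the final copy-number intensity `t` by subtracting, from every
#' marker, the mean of `s` over allelically balanced autosomal SNPs:
#' \deqn{t_m = s_m - \frac{\sum_i s_i I[\Delta_i]}{\sum_i I[\Delta_i]}}
#' where \eqn{\Delta_i} flags balance (no allelic imbalance at SNP `i`).
#' After this step a value near zero is copy-neutral, positive suggests
#' gain, negative suggests loss. Markers in imbalanced regions are excluded
#' from the mean because their intensities are perturbed by the aberration
#' itself.
#'
#' @param s numeric vector of preprocessed total intensities for one sample.
#' @param balance_flags logical vector: `TRUE` where the SNP is allelically
#'   balanced (typically the negation of the single-point AI flag).
#' @param annotation optional [marker_annotation()]; when given, only
#'   autosomal SNP probes enter the mean.
#' @param fallback_all_snps if no balanced SNP is available, subtract the
#'   mean over all (autosomal SNP) markers instead of failing.
#' @return Numeric vector `t`, same length and missingness as `s`.
#' @export
remove_aberrant_probe_perturbation <- function(s, balance_flags,
                                               annotation = NULL,
                                               fallback_all_snps = FALSE) {
  stopifnot(length(s) == length(balance_flags))
  eligible <- !is.na(s)
  if (!is.null(annotation)) {
    stopifnot(nrow(annotation) == length(s))
    eligible <- eligible & annotation$probe_class == "SNP"
    # the reference mean uses autosomal SNPs; on a design without autosomes
    # (e.g. a single-X template) all SNP probes are used instead
    if (any(annotation$chromosome %in% as.character(1:22)))
      eligible <- eligible & annotation$chromosome %in% as.character(1:22)
  }
  use <- eligible & !is.na(balance_flags) & balance_flags
  if (!any(use)) {
    if (!fallback_all_snps)
      stop("no balanced autosomal SNPs available; set fallback_all_snps=TRUE ",
           "to subtract the all-SNP mean")
    use <- eligible
    if (!any(use)) stop("no autosomal SNPs with finite intensity")
  }
  s - mean(s[use])
}
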