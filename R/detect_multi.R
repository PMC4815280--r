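#' Sliding-window configuration
#'
#' @param v window half-width; the window anchored at marker `m` covers the
#'   `2v + 1` markers `m - v, ..., m + v` (truncated at chromosome ends).
#' @param n_c required number of consecutive significant markers for a
#'   marker to count as aberrant inside a window (`1` disables the run
#'   requirement).
#' @param Q_percent reference quantile level for the first significance
#'   procedure.
#' @param loess_span LOESS span, as a fraction of the chromosome's markers.
#' @param combine_mode `"quantile"` (reference-quantile exceedance),
#'   `"test"` (Bonferroni hypothesis test) or `"both"` (their product).
#' @return A list of class `window_config`.
#' @export
window_config <- function(v = 5, n_c = 2, Q_percent = 95, loess_span = 0.02,
                          combine_mode = c("both", "quantile", "test")) {
  combine_mode <- match.arg(combine_mode)
  stopifnot(v >= 0, n_c >= 1, n_c <= 2 * v + 1 || v == 0)
  structure(list(v = as.integer(v), n_c = as.integer(n_c),
                 Q_percent = Q_percent, loess_span = loess_span,
                 combine_mode = combine_mode),
            class = "window_config")
}

#' Consecutive-run indicator
#'
#' `J[x] = 1` iff marker `x` belongs to a run of at least `n_c` consecutive
#' significant markers, i.e. at least one placement of `n_c` consecutive
#' markers covering `x` is entirely significant. Only placements fully inside
#' the track are considered; a track shorter than `n_c` has no placements and
#' returns all zeros.
#'
#' @param flags numeric/logical vector of single-point indicators for one
#'   chromosome; for copy number, gains (+1) and losses (-1) must be
#'   binarized into separate tracks first, so a run is always
#'   direction-homogeneous. `NA` counts as not significant.
#' @param n_c run length required.
#' @param x positions to evaluate (default: all).
#' @return Numeric vector of 0/1 values, one per `x`.
#' @export
run_indicator <- function(flags, n_c, x = seq_along(flags)) {
  sig <- !is.na(flags) & flags != 0
  n <- length(sig)
  if (n < n_c) return(numeric(length(x)))
  r <- rle(sig)
  in_long_run <- inverse.rle(list(lengths = r$lengths,
                                  values = r$values & r$lengths >= n_c))
  as.numeric(in_long_run[x])
}

#' Window-based aberrant proportion (WAP)
#'
#' For each anchor marker, the proportion of markers in its window that
#' belong to a run of at least `n_c` consecutive significant markers (see
#' [run_indicator()]). Windows at chromosome ends are truncated to the
#' available markers, with the actual marker count as denominator, so every
#' marker receives a WAP.
#'
#' @param flags single-point indicator vector (binary; `NA` = not
#'   significant), across the whole annotation or one chromosome.
#' @param cfg a [window_config()].
#' @param chromosome optional chromosome label vector aligned to `flags`;
#'   windows and runs never span a chromosome boundary.
#' @return Numeric WAP vector in \[0, 1\].
#' @export
compute_wap <- function(flags, cfg, chromosome = NULL) {
  stopifnot(inherits(cfg, "window_config"))
  if (is.null(chromosome)) chromosome <- rep("0", length(flags))
  stopifnot(length(chromosome) == length(flags))
  out <- numeric(length(flags))
  for (chr in unique(chromosome)) {
    idx <- which(chromosome == chr)
    f <- flags[idx]
    n <- length(f)
    if (n < cfg$n_c) {
      warning("chromosome ", chr, " shorter than n_c = ", cfg$n_c,
              "; WAP track set to zero")
      out[idx] <- 0
      next
    }
    J <- run_indicator(f, cfg$n_c)
    cs <- c(0, cumsum(J))
    m <- seq_len(n)
    lo <- pmax(1L, m - cfg$v)
    hi <- pmin(n, m + cfg$v)
    out[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

#' LOESS-smooth a per-marker track
#'
#' Locally weighted linear regression of the track on the marker index,
#' chromosome by chromosome, with span expressed as a fraction of the
#' chromosome's markers; the result is clipped to \[0, 1\]. Constant and
#' linear tracks pass through unchanged. Chromosomes with fewer than 4
#' markers are returned as-is with a warning.
#'
#' @param track numeric vector (e.g. a WAP track).
#' @param span smoothing span in (0, 1\].
#' @param chromosome optional chromosome labels aligned to `track`.
#' @return The smoothed track.
#' @export
smooth_track <- function(track, span = 0.02, chromosome = NULL) {
  stopifnot(span > 0)
  if (is.null(chromosome)) chromosome <- rep("0", length(track))
  out <- track
  for (chr in unique(chromosome)) {
    idx <- which(chromosome == chr)
    n <- length(idx)
    if (n < 4) {
      warning("chromosome ", chr, " has fewer than 4 markers; not smoothed")
      next
    }
    # plain local linear fit (no robustness iterations): rare isolated
    # spikes must attenuate, not vanish
    sm <- stats::lowess(seq_len(n), track[idx], f = span, iter = 0)$y
    out[idx] <- pmin(1, pmax(0, sm))
  }
  out
}

#' Multipoint detection against a WAP reference
#'
#' Applies the two significance procedures to a test sample's WAP track:
#' (1) reference-quantile exceedance, `flag1 = I[smoothed WAP >
#' reference Q-quantile]` (strict), and (2) a one-sided hypothesis test with
#' continuity term,
#' \eqn{Z = (W - \hat\mu + 1/M) / S}, \eqn{p = \min\{(1-\Phi(Z)) M, 1\}},
#' `flag2 = I[p < 0.05]` (strict), where \eqn{\hat\mu} and `S` are the
#' reference WAP mean and SD and `M` is the per-chromosome marker count.
#' Anchors with `S = 0` carry no reference variability: `flag2` is missing
#' there and, in `"both"` mode, the combined call falls back to procedure 1
#' alone (the count of such anchors is reported as an attribute).
#'
#' @param wap,smoothed test-sample WAP track and its smoothed version.
#' @param panel a panel carrying the matching WAP reference (see
#'   [add_wap_reference()]).
#' @param cfg a [window_config()]; `(E, v, n_c, Q_percent)` select the
#'   reference track.
#' @param E aberration type of the track (`"AI"`, `"LOH"`, `"GAIN"`,
#'   `"LOSS"`).
#' @param mp_alpha threshold for procedure 2 (default 0.05).
#' @return A data.frame with columns `wap`, `smoothed`, `z`, `p`, `flag1`,
#'   `flag2`, `combined`.
#' @export
detect_multipoint <- function(wap, smoothed, panel, cfg, E,
                              mp_alpha = 0.05) {
  stopifnot(inherits(panel, "snp_panel"), inherits(cfg, "window_config"))
  key <- wap_key(E, cfg$v, cfg$n_c, cfg$Q_percent)
  ref <- panel$wap_refs[[key]]
  if (is.null(ref))
    stop("panel has no WAP reference for ", key,
         "; run add_wap_reference() first")
  ann <- panel$annotation
  stopifnot(length(wap) == nrow(ann), length(smoothed) == nrow(ann))
  M <- bonferroni_M(ann, !is.na(wap))
  z <- (wap - ref$mu + 1 / M) / ref$sd
  z[ref$sd == 0] <- NA_real_
  p <- pmin((1 - stats::pnorm(z)) * M, 1)
  flag1 <- as.numeric(smoothed > ref$quant)
  flag2 <- as.numeric(p < mp_alpha)
  degenerate_sd <- sum(ref$sd == 0, na.rm = TRUE)
  combined <- switch(cfg$combine_mode,
                     quantile = flag1,
                     test = flag2,
                     both = ifelse(is.na(flag2), flag1, flag1 * flag2))
  res <- data.frame(wap = wap, smoothed = smoothed, z = z, p = p,
                    flag1 = flag1, flag2 = flag2, combined = combined)
  attr(res, "degenerate_sd_anchors") <- degenerate_sd
  res
}

#' Join flagged markers into aberrant regions
#'
#' Single-point mode joins maximal runs of flagged markers; multipoint mode
#' takes, for every flagged anchor, its whole window `[m - v, m + v]`
#' (clipped to the chromosome) and merges overlapping windows. Gains and
#' losses must be joined in separate calls so regions are never mixed-type;
#' a single non-significant marker breaks a run (no gap bridging).
#'
#' @param flags binary flag vector over the annotation (`NA` = not flagged).
#' @param annotation the [marker_annotation()].
#' @param mode `"single"` or `"multi"`.
#' @param type region label (e.g. `"GAIN"`, `"LOSS"`, `"AI"`, `"LOH"`).
#' @param v window half-width (multipoint mode).
#' @param p optional per-marker p-value track (for `min_p`).
#' @param wap optional per-marker WAP track (for `mean_wap`).
#' @return A data.frame with columns `chromosome`, `start_idx`, `end_idx`
#'   (row indices into the annotation), `start_bp`, `end_bp` (1-based
#'   inclusive), `n_markers`, `type`, `min_p`, `mean_wap`, sorted by
#'   genome position.
#' @export
join_regions <- function(flags, annotation, mode = c("single", "multi"),
                         type = "ABERRATION", v = 0, p = NULL, wap = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(flags) == nrow(annotation))
  out <- list()
  for (chr in unique(annotation$chromosome)) {
    idx <- which(annotation$chromosome == chr)
    f <- !is.na(flags[idx]) & flags[idx] != 0
    if (!any(f)) next
    n <- length(idx)
    if (mode == "multi" && v > 0) {
      covered <- rep(FALSE, n)
      anchors <- which(f)
      for (a in anchors)
        covered[max(1, a - v):min(n, a + v)] <- TRUE
      f <- covered
    }
    r <- rle(f)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      gi <- idx[starts[k]:ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr,
        start_idx = gi[1], end_idx = gi[length(gi)],
        start_bp = annotation$position_bp[gi[1]],
        end_bp = annotation$position_bp[gi[length(gi)]],
        n_markers = length(gi), type = type,
        min_p = if (is.null(p)) NA_real_ else
          suppressWarnings(min(p[gi], na.rm = TRUE)),
        mean_wap = if (is.null(wap)) NA_real_ else mean(wap[gi], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), start_idx = integer(0),
                      end_idx = integer(0), start_bp = integer(0),
                      end_bp = integer(0), n_markers = integer(0),
                      type = character(0), min_p = numeric(0),
                      mean_wap = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$min_p[is.infinite(res$min_p)] <- NA_real_
  res <- res[order(chromosome_rank(res$chromosome), res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}
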