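#' Build a normal-reference panel
#'
#' Computes the per-marker statistics every detector compares against, from a
#' set of normal (copy-neutral) reference samples: genotype counts, the
#' preferential-hybridization coefficient \eqn{\kappa_m}, genotype cluster
#' means of the CPA-adjusted allele frequency, genotype-specific means and
#' standard deviations of the calibrated allele frequency, and pooled and
#' genotype-specific means and standard deviations of the preprocessed
#' copy-number intensity track `t` (and of the pre-perturbation track `s`,
#' used by the simulation donor filters). All standard deviations use the
#' unbiased (n-1) denominator; NoCall genotypes are excluded from all
#' per-genotype statistics; per-genotype statistics are reported only where
#' at least two samples carry the genotype.
#'
#' @param samples list of at least two [sample_data()] sharing an annotation.
#' @param preprocess list of preprocessing toggles passed to
#'   [preprocess_intensities()]: `log2`, `center`, `quantile`.
#' @param alpha significance level used for the allelic-imbalance flags that
#'   define the balanced-SNP set during perturbation removal.
#' @param fallback_all_snps passed to [remove_aberrant_probe_perturbation()].
#'
#' @return An object of class `snp_panel`. Markers whose pooled intensity
#'   standard deviation is zero or whose cluster means are unordered are
#'   flagged degenerate and excluded from detection.
#' @export
build_reference_panel <- function(samples,
                                  preprocess = list(log2 = TRUE,
                                                    center = "none",
                                                    quantile = FALSE),
                                  alpha = 0.05,
                                  fallback_all_snps = TRUE) {
  if (length(samples) < 2) stop("at least 2 normal reference samples required")
  mats <- samples_to_matrices(samples)
  ann <- mats$annotation
  M <- nrow(ann)
  n <- length(samples)
  G <- mats$genotype
  AF <- mats$raw_af

  # --- CPA kappa from heterozygotes with raw AF strictly inside (0,1)
  het <- (G == "AB") & !is.na(AF) & AF > 0 & AF < 1
  ratios <- AF / (1 - AF)
  ratios[!het] <- 0
  n_het <- rowSums(het)
  kappa <- ifelse(n_het >= 2, rowSums(ratios) / pmax(n_het, 1), 1)
  n_kappa_fallback <- sum(n_het < 2 & ann$probe_class == "SNP")
  if (n_kappa_fallback > 0)
    message(n_kappa_fallback,
            " SNP marker(s) with <2 heterozygotes: kappa set to 1")

  # --- CPA-adjusted AF and genotype cluster means
  HHAT <- AF / (AF + kappa * (1 - AF))
  cl <- lapply(c("AA", "AB", "BB"), function(g) {
    st <- genotype_stats(HHAT, G, g)
    ifelse(st$n >= 2, st$mean, NA_real_)
  })
  cluster <- cluster_means(cl[[1]], cl[[2]], cl[[3]])
  calibratable <- !is.na(cluster$mean_AA) & !is.na(cluster$mean_AB) &
    !is.na(cluster$mean_BB) & cluster$mean_BB < cluster$mean_AB &
    cluster$mean_AB < cluster$mean_AA

  # --- calibrated AF per sample, per-genotype AF stats
  FHAT <- matrix(lim_calibrate(as.vector(HHAT),
                               cluster_means(rep(cluster$mean_AA, n),
                                             rep(cluster$mean_AB, n),
                                             rep(cluster$mean_BB, n))),
                 nrow = M)
  dimnames(FHAT) <- dimnames(AF)
  f_stats <- lapply(c("AA", "AB", "BB"), function(g) genotype_stats(FHAT, G, g))
  names(f_stats) <- c("AA", "AB", "BB")
  geno_n <- vapply(c("AA", "AB", "BB"),
                   function(g) rowSums((G == g) & !is.na(AF)), numeric(M))

  panel <- structure(list(
    annotation = ann, n_samples = n, sample_ids = mats$sample_ids,
    preprocess = preprocess, alpha = alpha,
    kappa = kappa, cluster = cluster, calibratable = calibratable,
    n_g = geno_n,
    f_n_g = vapply(f_stats, `[[`, numeric(M), "n"),
    f_mean_g = vapply(f_stats, `[[`, numeric(M), "mean"),
    f_sd_g = vapply(f_stats, `[[`, numeric(M), "sd"),
    f_sum_g = vapply(f_stats, `[[`, numeric(M), "sum"),
    f_sumsq_g = vapply(f_stats, `[[`, numeric(M), "sumsq"),
    wap_refs = list()), class = "snp_panel")

  # --- intensity track: preprocess, then per-sample perturbation removal
  #     with balance flags from the single-point AI detector
  S <- preprocess_intensities(samples,
                              log2_transform = isTRUE(preprocess$log2),
                              center = preprocess$center %||% "none",
                              quantile_norm = isTRUE(preprocess$quantile))
  Tmat <- S
  cfg <- detection_config(alpha = alpha)
  for (j in seq_len(n)) {
    ai <- ai_flags_core(FHAT[, j], panel$f_mean_g, panel$f_sd_g, ann, cfg)
    balanced <- is.na(ai) | ai == 0
    Tmat[, j] <- remove_aberrant_probe_perturbation(
      S[, j], balanced, ann, fallback_all_snps = fallback_all_snps)
  }

  t_stats <- lapply(c("AA", "AB", "BB"), function(g) genotype_stats(Tmat, G, g))
  s_stats <- lapply(c("AA", "AB", "BB"), function(g) genotype_stats(S, G, g))
  pool_t <- pooled_stats(Tmat)
  pool_s <- pooled_stats(S)

  panel$t_mean_g <- vapply(t_stats, `[[`, numeric(M), "mean")
  panel$t_sd_g <- vapply(t_stats, `[[`, numeric(M), "sd")
  panel$t_sum_g <- vapply(t_stats, `[[`, numeric(M), "sum")
  panel$t_sumsq_g <- vapply(t_stats, `[[`, numeric(M), "sumsq")
  panel$t_n_g <- vapply(t_stats, `[[`, numeric(M), "n")
  panel$t_mean <- pool_t$mean; panel$t_sd <- pool_t$sd
  panel$t_sum <- pool_t$sum; panel$t_sumsq <- pool_t$sumsq
  panel$t_n <- pool_t$n
  panel$s_mean_g <- vapply(s_stats, `[[`, numeric(M), "mean")
  panel$s_sd_g <- vapply(s_stats, `[[`, numeric(M), "sd")
  panel$s_mean <- pool_s$mean; panel$s_sd <- pool_s$sd
  colnames(panel$t_mean_g) <- colnames(panel$t_sd_g) <-
    colnames(panel$s_mean_g) <- colnames(panel$s_sd_g) <-
    colnames(panel$n_g) <- colnames(panel$f_mean_g) <-
    colnames(panel$f_sd_g) <- c("AA", "AB", "BB")

  panel$degenerate <- (!is.na(panel$t_sd) & panel$t_sd == 0)
  n_deg <- sum(panel$degenerate)
  if (n_deg > 0)
    message(n_deg, " degenerate marker(s) (zero intensity variance) excluded ",
            "from detection")
  panel
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf(paste0("snp_panel: %d markers, %d normal samples; ",
                     "%d calibratable, %d degenerate; %d WAP reference track(s)\n"),
              nrow(x$annotation), x$n_samples, sum(x$calibratable),
              sum(x$degenerate), length(x$wap_refs)))
  invisible(x)
}

# sum-of-squares variances suffer catastrophic cancellation when a class is
# (near-)constant; variances this small are numerically zero at the scales
# handled here (log2 intensities, allele frequencies)
clamp_var <- function(v) {
  v[!is.na(v) & v < 1e-12] <- 0
  v
}

# per-genotype n/sum/sumsq/mean/sd over samples, one row per marker
genotype_stats <- function(X, G, g) {
  mask <- (G == g) & !is.na(X)
  X0 <- X; X0[!mask] <- 0
  n <- rowSums(mask)
  s <- rowSums(X0)
  ss <- rowSums(X0 * X0)
  mean <- ifelse(n >= 2, s / pmax(n, 1), NA_real_)
  v <- ifelse(n >= 2, pmax(ss - s^2 / pmax(n, 1), 0) / pmax(n - 1, 1), NA_real_)
  list(n = n, sum = s, sumsq = ss, mean = mean, sd = sqrt(clamp_var(v)))
}

pooled_stats <- function(X) {
  ok <- !is.na(X)
  X0 <- X; X0[!ok] <- 0
  n <- rowSums(ok)
  s <- rowSums(X0)
  ss <- rowSums(X0 * X0)
  mean <- ifelse(n >= 2, s / pmax(n, 1), NA_real_)
  v <- ifelse(n >= 2, pmax(ss - s^2 / pmax(n, 1), 0) / pmax(n - 1, 1), NA_real_)
  list(n = n, sum = s, sumsq = ss, mean = mean, sd = sqrt(clamp_var(v)))
}

# leave-one-out mean/sd from stored sums, removing value x from a class with
# n observations. Returns NA stats where the reduced class has < 2 members.
loo_mean_sd <- function(n, s, ss, x) {
  has <- !is.na(x)
  n1 <- n - has
  s1 <- s - ifelse(has, x, 0)
  ss1 <- ss - ifelse(has, x * x, 0)
  mean <- ifelse(n1 >= 2, s1 / pmax(n1, 1), NA_real_)
  v <- ifelse(n1 >= 2, pmax(ss1 - s1^2 / pmax(n1, 1), 0) / pmax(n1 - 1, 1),
              NA_real_)
  list(mean = mean, sd = sqrt(clamp_var(v)))
}

wap_key <- function(E, v, n_c, Q_percent) {
  sprintf("%s|v%d|nc%d|Q%g", E, as.integer(v), as.integer(n_c), Q_percent)
}

#' Build a window-based aberrant proportion (WAP) reference track
#'
#' For one aberration type and one window setting, computes each normal
#' reference sample's WAP track (single-point flags evaluated leave-one-out
#' against the panel, so a sample never contributes to its own reference
#' statistics), smooths each track by LOESS, and returns per-anchor summary
#' tracks: the mean and standard deviation of the raw WAPs and the empirical
#' `Q`-percent quantile (type-7, linear interpolation between order
#' statistics) of the smoothed WAPs.
#'
#' @param samples the normal reference samples the panel was built from.
#' @param panel a [build_reference_panel()] object.
#' @param E aberration type: `"AI"`, `"LOH"`, `"GAIN"` or `"LOSS"` (gains and
#'   losses are scanned as separate binary tracks).
#' @param v window half-width (window size `2v + 1`).
#' @param n_c required number of consecutive significant markers.
#' @param Q_percent reference quantile level (95, 97.5 or 99; default 95).
#' @param span LOESS span as a fraction of the chromosome's markers.
#' @return A list of class `wap_reference` with per-marker tracks `mu`, `sd`,
#'   `quant` and the settings used. If fewer samples than `100/(100-Q)` are
#'   available the quantile falls back to the per-anchor maximum, with a
#'   warning.
#' @export
build_wap_reference <- function(samples, panel, E = c("LOSS", "GAIN", "AI", "LOH"),
                                v = 5, n_c = 2, Q_percent = 95, span = 0.02) {
  E <- match.arg(E)
  stopifnot(inherits(panel, "snp_panel"))
  n <- length(samples)
  ann <- panel$annotation
  M <- nrow(ann)
  W <- matrix(NA_real_, M, n)
  Ws <- matrix(NA_real_, M, n)
  cfg <- detection_config(alpha = panel$alpha)
  S <- preprocess_intensities(samples,
                              log2_transform = isTRUE(panel$preprocess$log2),
                              center = panel$preprocess$center %||% "none",
                              quantile_norm = isTRUE(panel$preprocess$quantile))
  for (j in seq_len(n)) {
    smp <- samples[[j]]
    tr <- loo_sample_tracks(smp, S[, j], panel, cfg)
    flags <- switch(E,
                    AI = tr$ai,
                    LOH = tr$loh,
                    GAIN = as.numeric(tr$cnv == 1),
                    LOSS = as.numeric(tr$cnv == -1))
    flags[is.na(flags)] <- 0
    W[, j] <- compute_wap(flags, window_config(v = v, n_c = n_c),
                          chromosome = ann$chromosome)
    Ws[, j] <- smooth_track(W[, j], span = span, chromosome = ann$chromosome)
  }
  mu <- rowMeans(W)
  sd <- apply(W, 1, stats::sd)
  need <- ceiling(100 / (100 - Q_percent))
  if (n < need) {
    warning("only ", n, " reference samples for the ", Q_percent,
            "% quantile (need >= ", need, "); using the per-anchor maximum")
    quant <- apply(Ws, 1, max)
  } else {
    quant <- apply(Ws, 1, stats::quantile, probs = Q_percent / 100,
                   type = 7, names = FALSE)
  }
  structure(list(E = E, v = v, n_c = n_c, Q_percent = Q_percent, span = span,
                 mu = mu, sd = sd, quant = quant, n_samples = n),
            class = "wap_reference")
}

#' Attach a WAP reference track to a panel
#'
#' @inheritParams build_wap_reference
#' @return The panel with the new reference stored under a key derived from
#'   `(E, v, n_c, Q_percent)`.
#' @export
add_wap_reference <- function(panel, samples, E, v, n_c, Q_percent = 95,
                              span = 0.02) {
  ref <- build_wap_reference(samples, panel, E = E, v = v, n_c = n_c,
                             Q_percent = Q_percent, span = span)
  panel$wap_refs[[wap_key(E, v, n_c, Q_percent)]] <- ref
  panel
}

# Per-sample calibrated AF, intensity track and single-point flags, with the
# sample's own contribution removed from the panel comparison statistics
# (calibration constants kappa and cluster means stay panel-wide).
loo_sample_tracks <- function(smp, s_track, panel, cfg) {
  ann <- panel$annotation
  M <- nrow(ann)
  adj <- cpa_adjust(smp$raw_af, panel$kappa)
  fhat <- lim_calibrate(adj, panel$cluster)
  geno <- smp$genotype

  f_mean <- panel$f_mean_g
  f_sd <- panel$f_sd_g
  for (g in c("AA", "AB", "BB")) {
    x <- ifelse(geno == g, fhat, NA_real_)
    st <- loo_mean_sd(panel$f_n_g[, g], panel$f_sum_g[, g],
                      panel$f_sumsq_g[, g], x)
    f_mean[, g] <- st$mean
    f_sd[, g] <- st$sd
  }
  ai <- ai_flags_core(fhat, f_mean, f_sd, ann, cfg)
  loh <- loh_flags_core(fhat, f_mean[, "AB"], f_sd[, "AB"], ann, cfg)

  balanced <- is.na(ai) | ai == 0
  t_track <- remove_aberrant_probe_perturbation(s_track, balanced, ann,
                                                fallback_all_snps = TRUE)
  st <- loo_mean_sd(panel$t_n, panel$t_sum, panel$t_sumsq, t_track)
  cnv <- cnv_flags_core(t_track, st$mean, st$sd, ann, cfg)
  list(fhat = fhat, t = t_track, ai = ai, loh = loh, cnv = cnv$flags)
}

#' Save / load a reference panel as plain text
#'
#' The panel is persisted as a directory of TSV tables plus a JSON metadata
#' file, keyed per-(aberration, window, quantile) for the WAP tracks. Values
#' are written with 17 significant digits so the round trip is bit exact.
#'
#' @param panel a `snp_panel`.
#' @param dir directory to create/read.
#' @return `save_panel` returns `dir` invisibly; `load_panel` the panel.
#' @export
save_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) trimws(formatC(as.numeric(x), digits = 17, format = "g"))
  wtab <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wtab(as.data.frame(panel$annotation), "annotation.tsv")
  num_fields <- c("kappa", "calibratable", "degenerate", "t_mean", "t_sd",
                  "t_sum", "t_sumsq", "t_n", "s_mean", "s_sd")
  vec <- data.frame(lapply(panel[num_fields], fmt), stringsAsFactors = FALSE)
  names(vec) <- num_fields
  cluster_df <- data.frame(mean_AA = fmt(panel$cluster$mean_AA),
                           mean_AB = fmt(panel$cluster$mean_AB),
                           mean_BB = fmt(panel$cluster$mean_BB))
  wtab(cbind(vec, cluster_df), "marker_stats.tsv")
  mat_fields <- c("n_g", "f_n_g", "f_mean_g", "f_sd_g", "f_sum_g", "f_sumsq_g",
                  "t_mean_g", "t_sd_g", "t_sum_g", "t_sumsq_g", "t_n_g",
                  "s_mean_g", "s_sd_g")
  mats <- do.call(cbind, lapply(mat_fields, function(f) {
    m <- panel[[f]]
    colnames(m) <- paste(f, c("AA", "AB", "BB"), sep = ".")
    m
  }))
  wtab(as.data.frame(apply(mats, 2, fmt), stringsAsFactors = FALSE),
       "genotype_stats.tsv")
  for (k in names(panel$wap_refs)) {
    r <- panel$wap_refs[[k]]
    wtab(data.frame(mu = fmt(r$mu), sd = fmt(r$sd), quant = fmt(r$quant)),
         paste0("wap_", gsub("[|]", "_", k), ".tsv"))
  }
  meta <- list(n_samples = panel$n_samples, sample_ids = panel$sample_ids,
               preprocess = panel$preprocess, alpha = panel$alpha,
               wap_refs = lapply(panel$wap_refs, function(r)
                 r[c("E", "v", "n_c", "Q_percent", "span", "n_samples")]))
  writeLines(deparse_meta(meta), file.path(dir, "meta.txt"))
  invisible(dir)
}

deparse_meta <- function(x) deparse(x, control = c("all", "digits17"))

#' @rdname save_panel
#' @export
load_panel <- function(dir) {
  rtab <- function(f) utils::read.delim(file.path(dir, f),
                                        stringsAsFactors = FALSE,
                                        check.names = FALSE)
  meta <- eval(parse(text = paste(readLines(file.path(dir, "meta.txt")),
                                  collapse = "\n")))
  ann_df <- rtab("annotation.tsv")
  ann <- marker_annotation(ann_df$marker_id, ann_df$chromosome,
                           ann_df$position_bp, ann_df$probe_class,
                           ann_df$allele_A, ann_df$allele_B)
  ms <- rtab("marker_stats.tsv")
  gs <- rtab("genotype_stats.tsv")
  panel <- structure(list(annotation = ann, n_samples = meta$n_samples,
                          sample_ids = meta$sample_ids,
                          preprocess = meta$preprocess, alpha = meta$alpha,
                          kappa = as.numeric(ms$kappa),
                          cluster = cluster_means(as.numeric(ms$mean_AA),
                                                  as.numeric(ms$mean_AB),
                                                  as.numeric(ms$mean_BB)),
                          calibratable = as.logical(as.numeric(ms$calibratable)),
                          degenerate = as.logical(as.numeric(ms$degenerate)),
                          t_mean = as.numeric(ms$t_mean),
                          t_sd = as.numeric(ms$t_sd),
                          t_sum = as.numeric(ms$t_sum),
                          t_sumsq = as.numeric(ms$t_sumsq),
                          t_n = as.numeric(ms$t_n),
                          s_mean = as.numeric(ms$s_mean),
                          s_sd = as.numeric(ms$s_sd),
                          wap_refs = list()), class = "snp_panel")
  for (f in c("n_g", "f_n_g", "f_mean_g", "f_sd_g", "f_sum_g", "f_sumsq_g",
              "t_mean_g", "t_sd_g", "t_sum_g", "t_sumsq_g", "t_n_g",
              "s_mean_g", "s_sd_g")) {
    m <- as.matrix(gs[, paste(f, c("AA", "AB", "BB"), sep = ".")])
    m <- apply(m, 2, as.numeric)
    colnames(m) <- c("AA", "AB", "BB")
    panel[[f]] <- m
  }
  for (k in names(meta$wap_refs)) {
    info <- meta$wap_refs[[k]]
    tab <- rtab(paste0("wap_", gsub("[|]", "_", k), ".tsv"))
    panel$wap_refs[[k]] <- structure(
      c(info, list(mu = as.numeric(tab$mu), sd = as.numeric(tab$sd),
                   quant = as.numeric(tab$quant))),
      class = "wap_reference")
  }
  panel
}
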