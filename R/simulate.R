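#' Parameters of the synthetic array population
#'
#' Describes the generative model behind the synthetic reference panel and
#' test samples: per-marker allele frequencies drawn uniformly, genotypes
#' under Hardy-Weinberg equilibrium, raw allele-frequency clusters near
#' 0.95/0.50/0.05 with a configurable preferential-hybridization bias
#' \eqn{\kappa}, and per-marker log2 total intensity with a per-marker probe
#' baseline plus chip noise. Copy number acts on the log2 scale: each
#' halving/doubling shifts the mean by `copy_shift_log2`. With the default
#' chip noise of 0.25 this puts one-copy and two-copy states four chip-SDs
#' apart, the separation a physical halving of target DNA produces on a
#' well-behaved array.
#'
#' @param chromosomes named integer vector: markers per chromosome
#'   (default one 2001-SNP template chromosome labelled "2").
#' @param maf_range range of the uniform allele-frequency distribution.
#' @param cluster_af_mean,cluster_af_sd genotype-cluster means and SDs of the
#'   true allele fraction for AA, AB, BB.
#' @param kappa preferential-hybridization bias applied when converting the
#'   true allele fraction to observed relative intensity (1 = unbiased).
#' @param log2_mean grand mean of the log2 total intensity.
#' @param log2_sd chip noise SD of the log2 total intensity.
#' @param marker_effect_sd SD of fixed per-marker probe baselines.
#' @param copy_shift_log2 log2 intensity shift per copy-number halving or
#'   doubling (1.0 = intensity proportional to DNA amount).
#' @param gap_mean_bp mean inter-marker spacing in bp.
#' @return A list of class `population_params`.
#' @export
population_params <- function(chromosomes = c(`2` = 2001L),
                              maf_range = c(0.05, 0.95),
                              cluster_af_mean = c(AA = 0.95, AB = 0.50, BB = 0.05),
                              cluster_af_sd = c(AA = 0.02, AB = 0.03, BB = 0.02),
                              kappa = 1.2,
                              log2_mean = 11,
                              log2_sd = 0.25,
                              marker_effect_sd = 0.15,
                              copy_shift_log2 = 1.0,
                              gap_mean_bp = 1500) {
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] >= 1 ||
      maf_range[1] >= maf_range[2])
    stop("maf_range must be an increasing pair inside (0, 1)")
  stopifnot(kappa > 0, log2_sd > 0, all(chromosomes >= 1))
  structure(list(chromosomes = chromosomes, maf_range = maf_range,
                 cluster_af_mean = cluster_af_mean,
                 cluster_af_sd = cluster_af_sd, kappa = kappa,
                 log2_mean = log2_mean, log2_sd = log2_sd,
                 marker_effect_sd = marker_effect_sd,
                 copy_shift_log2 = copy_shift_log2,
                 gap_mean_bp = gap_mean_bp),
            class = "population_params")
}

#' Generate a synthetic normal reference population
#'
#' Draws the fixed marker map (positions, allele frequencies, probe
#' baselines) and `n_samples` copy-neutral samples from it. Samples are
#' two-copy everywhere except on chromosome X for male-configured samples
#' (one copy, hemizygous genotypes, intensity one `copy_shift_log2` lower).
#' Fully reproducible given `seed`.
#'
#' @param params a [population_params()].
#' @param n_samples number of normal samples.
#' @param seed RNG seed (the caller's RNG state is restored).
#' @param sex optional character vector ("F"/"M") per sample; default all
#'   female.
#' @return A list of class `synthetic_population` with `annotation`,
#'   `samples` (list of [sample_data()]), `maf`, `baseline`, `sex` and
#'   `params`.
#' @export
generate_reference_population <- function(params = population_params(),
                                          n_samples = 200, seed = 1,
                                          sex = NULL) {
  stopifnot(inherits(params, "population_params"))
  if (is.null(sex)) sex <- rep("F", n_samples)
  sex <- rep_len(sex, n_samples)
  with_seed(seed, {
    chroms <- rep(names(params$chromosomes), params$chromosomes)
    M <- length(chroms)
    pos <- unlist(lapply(params$chromosomes, function(k)
      cumsum(1L + stats::rgeom(k, 1 / params$gap_mean_bp))), use.names = FALSE)
    ann <- marker_annotation(sprintf("m%06d", seq_len(M)), chroms, pos,
                             probe_class = "SNP",
                             allele_A = "A", allele_B = "B")
    # marker_annotation re-sorts; regenerate aligned marker-level fields in
    # sorted order
    maf <- stats::runif(M, params$maf_range[1], params$maf_range[2])
    baseline <- stats::rnorm(M, params$log2_mean, params$marker_effect_sd)
    samples <- lapply(seq_len(n_samples), function(i) {
      copies <- ifelse(ann$chromosome == "X" & sex[i] == "M", 1L, 2L)
      d <- draw_marker_values(params, maf, baseline, copies)
      sample_data(sprintf("N%04d", i), d$h_A, d$h_B, d$genotype, ann)
    })
    structure(list(annotation = ann, samples = samples, maf = maf,
                   baseline = baseline, sex = sex, params = params),
              class = "synthetic_population")
  })
}

# One draw per marker: genotype under HWE given copy number, true allele
# fraction from the genotype cluster, kappa-biased observed fraction, and
# log2 total intensity shifted by the copy state. Vectorized over markers.
draw_marker_values <- function(params, maf, baseline, copies) {
  M <- length(maf)
  copies <- rep_len(copies, M)
  u <- stats::runif(M)
  # dose of allele A
  dose <- ifelse(copies == 2L,
                 ifelse(u < maf^2, 2L, ifelse(u < maf^2 + 2 * maf * (1 - maf), 1L, 0L)),
                 ifelse(u < maf, 1L, 0L))
  genotype <- ifelse(copies == 2L,
                     c("BB", "AB", "AA")[dose + 1L],
                     c("BB", "AA")[dose + 1L])
  gi <- match(genotype, c("AA", "AB", "BB"))
  f_true <- stats::rnorm(M, params$cluster_af_mean[gi], params$cluster_af_sd[gi])
  f_true <- pmin(1, pmax(0, f_true))
  h_frac <- params$kappa * f_true / (params$kappa * f_true + (1 - f_true))
  s <- stats::rnorm(M, baseline + params$copy_shift_log2 * log2(copies / 2),
                    params$log2_sd)
  tot <- 2^s
  list(genotype = genotype, s = s, h_frac = h_frac,
       h_A = tot * h_frac, h_B = tot * (1 - h_frac))
}

#' Draw a fresh normal sample from a synthetic population
#'
#' @param population a [generate_reference_population()] object.
#' @param sample_id identifier for the new sample.
#' @param sex "F" or "M"; defaults to the population's first sample's sex, so
#'   a one-copy (male-X) template population yields one-copy templates.
#' @return A [sample_data()].
#' @export
draw_normal_sample <- function(population, sample_id = "T0001",
                               sex = population$sex[1]) {
  ann <- population$annotation
  copies <- ifelse(ann$chromosome == "X" & sex == "M", 1L, 2L)
  d <- draw_marker_values(population$params, population$maf,
                          population$baseline, copies)
  sample_data(sample_id, d$h_A, d$h_B, d$genotype, ann)
}

#' Donor pool for aberration injection
#'
#' A parametric stand-in for drawing "donor" genotype/intensity values with a
#' given copy number at each marker of a synthetic population (one-copy
#' donors emulate hemizygous loss material, two-copy donors copy-neutral
#' material).
#'
#' @param population a [generate_reference_population()] object.
#' @param copies 1 or 2.
#' @return A list of class `donor_pool`.
#' @export
make_donor_pool <- function(population, copies) {
  stopifnot(copies %in% c(1L, 2L))
  structure(list(population = population, copies = as.integer(copies)),
            class = "donor_pool")
}

# n donor draws at one marker index m
draw_donors <- function(pool, m, n) {
  pop <- pool$population
  draw_marker_values(pop$params, rep(pop$maf[m], n),
                     rep(pop$baseline[m], n), pool$copies)
}

#' Simulation scenario configuration
#'
#' @param scenario `"loss"`, `"gain"` or `"neutral"`.
#' @param N_T number of target SNPs, centered in the template.
#' @param r effect size of the donor truncation filter, in reference-SD
#'   units (`0` for the neutral scenario).
#' @param q_percent percentage of target markers receiving an unconstrained
#'   noise draw (within 2 reference SDs) instead of the scenario draw.
#' @param seed optional seed for the injection.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(scenario = c("neutral", "loss", "gain"),
                              N_T = 51, r = 0, q_percent = 0, seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(N_T >= 1, r >= 0, q_percent >= 0, q_percent <= 100)
  if (scenario == "neutral" && r != 0)
    stop("the neutral scenario has effect size r = 0 by definition")
  structure(list(scenario = scenario, N_T = as.integer(N_T), r = r,
                 q_percent = q_percent, seed = seed),
            class = "simulation_config")
}

target_indices <- function(n_template, N_T) {
  if (N_T > n_template) stop("target larger than template")
  start <- floor((n_template - N_T) / 2) + 1L
  seq.int(start, start + N_T - 1L)
}

#' Inject a copy-number aberration into a template sample
#'
#' Replaces the genotypes and intensities of the central `N_T` markers of
#' the template with donor draws filtered against the reference panel's
#' per-genotype intensity statistics \eqn{(\hat\mu_g, \hat\sigma_g)} (log2
#' total-intensity scale): loss keeps one-copy draws with
#' \eqn{s \le \hat\mu - r\hat\sigma}, gain keeps extra-copy draws with
#' \eqn{s \ge \hat\mu + r\hat\sigma}, and the neutral scenario keeps
#' two-copy draws within \eqn{\hat\mu \pm 3\hat\sigma}. With probability
#' `q_percent`/100 a marker instead receives an unconstrained donor draw
#' within \eqn{\hat\mu \pm 2\hat\sigma}, emulating admixture/noise
#' interference. Draw rejection is capped at 1e5 attempts per marker.
#'
#' @param template_sample a [sample_data()] covering the template region.
#' @param donor_pool a [make_donor_pool()] with the scenario's copy number
#'   (ignored for `"neutral"`, which always uses two-copy draws).
#' @param panel the reference panel supplying the truncation statistics.
#' @param cfg a [simulation_config()].
#' @return The modified [sample_data()] with attribute `target_idx`.
#' @export
inject_aberration <- function(template_sample, donor_pool, panel, cfg) {
  stopifnot(inherits(template_sample, "sample_data"),
            inherits(cfg, "simulation_config"))
  ann <- template_sample$annotation
  idx <- target_indices(nrow(ann), cfg$N_T)
  smp <- template_sample
  with_seed(cfg$seed, {
    noise <- stats::runif(length(idx)) < cfg$q_percent / 100
    for (k in seq_along(idx)) {
      m <- idx[k]
      mu_g <- panel$s_mean_g[m, ]
      sd_g <- panel$s_sd_g[m, ]
      accept <- function(d) {
        mu <- mu_g[match(d$genotype, c("AA", "AB", "BB"))]
        sdv <- sd_g[match(d$genotype, c("AA", "AB", "BB"))]
        mu[is.na(mu)] <- panel$s_mean[m]
        sdv[is.na(sdv) | sdv == 0] <- panel$s_sd[m]
        if (noise[k]) return(abs(d$s - mu) <= 2 * sdv)
        switch(cfg$scenario,
               loss = d$s <= mu - cfg$r * sdv,
               gain = d$s >= mu + cfg$r * sdv,
               neutral = abs(d$s - mu) <= 3 * sdv)
      }
      pool <- donor_pool
      if (cfg$scenario == "neutral" || noise[k])
        pool <- make_donor_pool(donor_pool$population, 2L)
      got <- FALSE
      tries <- 0L
      while (!got && tries < 1e5) {
        batch <- min(if (tries == 0L) 16L else 1024L, 1e5 - tries)
        d <- draw_donors(pool, m, batch)
        tries <- tries + batch
        ok <- which(accept(d))
        if (length(ok)) {
          i <- ok[1]
          smp$h_A[m] <- d$h_A[i]
          smp$h_B[m] <- d$h_B[i]
          smp$genotype[m] <- d$genotype[i]
          got <- TRUE
        }
      }
      if (!got)
        stop(sprintf("truncation region empty after 1e5 draws at marker %s (r = %g)",
                     ann$marker_id[m], cfg$r))
    }
  })
  tot <- smp$h_A + smp$h_B
  smp$raw_af <- ifelse(is.na(tot) | tot == 0, NA_real_, smp$h_A / tot)
  attr(smp, "target_idx") <- idx
  smp
}

#' Run the copy-number detection pipeline on one sample
#'
#' Computes the calibrated allele-frequency track, single-point AI/LOH/CNV
#' flags, the balance-adjusted final intensity track, and (if WAP references
#' are present in the panel) the multipoint GAIN/LOSS tracks.
#'
#' @param sample a [sample_data()].
#' @param panel a [build_reference_panel()] panel (with WAP references for
#'   the requested window if multipoint output is wanted).
#' @param wcfg a [window_config()] or `NULL` for single-point only.
#' @param cfg a [detection_config()].
#' @return A list with `af`, `ai`, `loh`, `cnv` (list from
#'   [detect_cnv_single()]), `t`, and multipoint data.frames `mp_gain`,
#'   `mp_loss` when available.
#' @export
detect_sample <- function(sample, panel, wcfg = NULL,
                          cfg = detection_config()) {
  ann <- panel$annotation
  af <- estimate_af(sample, panel)
  ai <- detect_ai_single(af$final, panel, cfg)
  loh <- detect_loh_single(af$final, panel, cfg)
  s <- preprocess_intensities(list(sample),
                              log2_transform = isTRUE(panel$preprocess$log2),
                              center = panel$preprocess$center %||% "none",
                              quantile_norm = FALSE)[, 1]
  balanced <- is.na(ai) | ai == 0
  t_track <- remove_aberrant_probe_perturbation(s, balanced, ann,
                                                fallback_all_snps = TRUE)
  cnv <- detect_cnv_single(t_track, sample$genotype, panel, cfg)
  out <- list(af = af, ai = ai, loh = loh, cnv = cnv, t = t_track, s = s)
  if (!is.null(wcfg)) {
    for (E in c("GAIN", "LOSS", "AI", "LOH")) {
      key <- wap_key(E, wcfg$v, wcfg$n_c, wcfg$Q_percent)
      if (is.null(panel$wap_refs[[key]])) next
      flags <- switch(E,
                      GAIN = as.numeric(cnv$flags == 1),
                      LOSS = as.numeric(cnv$flags == -1),
                      AI = ai, LOH = loh)
      flags[is.na(flags)] <- 0
      wap <- compute_wap(flags, wcfg, chromosome = ann$chromosome)
      sm <- smooth_track(wap, span = wcfg$loess_span,
                         chromosome = ann$chromosome)
      out[[paste0("mp_", tolower(E))]] <-
        detect_multipoint(wap, sm, panel, wcfg, E, mp_alpha = cfg$mp_alpha)
    }
  }
  out
}

#' False/true positive rate simulation study
#'
#' For each grid row, repeatedly draws a fresh template sample from the
#' population, injects the scenario aberration into the centered target, runs
#' the single-point (and, when `wcfg` is given, multipoint) copy-number
#' detectors, and tallies SNP-level rates over replicates. Donor copy
#' numbers follow the scenario design: loss injects one-copy draws into a
#' two-copy template; gain injects two-copy draws and is meant to run
#' against a one-copy template population (an all-male X chromosome), the
#' mirrored contrast; neutral injects two-copy draws into a two-copy
#' template. The SNP-level
#' FPR is the proportion of (replicate x neutral-target-SNP) events flagged
#' in either direction; the SNP-level TPR counts only flags in the correct
#' direction. Region-level rates average the SNP-level rates over the target
#' region.
#'
#' @param population a [generate_reference_population()] object.
#' @param panel the reference panel built from the population's samples,
#'   with WAP references added when multipoint rates are wanted.
#' @param grid a data.frame with columns `scenario`, `N_T`, `r`, `q_percent`.
#' @param n_reps replicates per grid row (>= 10 recommended).
#' @param wcfg optional [window_config()] for the multipoint detector.
#' @param cfg a [detection_config()].
#' @param seed seed for the whole study.
#' @return The grid with appended columns `sp_snp_rate`, `sp_region_rate`,
#'   `sp_region_se`, and when multipoint ran, `mp_region_rate`,
#'   `mp_region_se`.
#' @export
run_simulation_study <- function(population, panel, grid, n_reps = 1000,
                                 wcfg = NULL, cfg = detection_config(),
                                 seed = 1) {
  if (n_reps < 10) warning("n_reps < 10 gives unstable rate estimates")
  grid$sp_snp_rate <- NA_real_
  grid$sp_region_rate <- NA_real_
  grid$sp_region_se <- NA_real_
  if (!is.null(wcfg)) {
    grid$mp_region_rate <- NA_real_
    grid$mp_region_se <- NA_real_
  }
  with_seed(seed, {
    for (g in seq_len(nrow(grid))) {
      scen <- as.character(grid$scenario[g])
      simc <- simulation_config(scenario = scen, N_T = grid$N_T[g],
                                r = grid$r[g], q_percent = grid$q_percent[g])
      pool <- make_donor_pool(population, if (scen == "loss") 1L else 2L)
      sp_rep <- numeric(n_reps)
      mp_rep <- numeric(n_reps)
      for (b in seq_len(n_reps)) {
        smp <- draw_normal_sample(population, sprintf("S%05d", b))
        smp <- inject_aberration(smp, pool, panel, simc)
        idx <- attr(smp, "target_idx")
        res <- detect_sample(smp, panel, wcfg = wcfg, cfg = cfg)
        fl <- res$cnv$flags[idx]
        hit <- switch(scen,
                      neutral = !is.na(fl) & fl != 0,
                      loss = !is.na(fl) & fl == -1,
                      gain = !is.na(fl) & fl == 1)
        sp_rep[b] <- mean(hit)
        if (!is.null(wcfg)) {
          mg <- res$mp_gain$combined[idx]
          ml <- res$mp_loss$combined[idx]
          mhit <- switch(scen,
                         neutral = (!is.na(mg) & mg == 1) | (!is.na(ml) & ml == 1),
                         loss = !is.na(ml) & ml == 1,
                         gain = !is.na(mg) & mg == 1)
          mp_rep[b] <- mean(mhit)
        }
      }
      grid$sp_snp_rate[g] <- mean(sp_rep)
      grid$sp_region_rate[g] <- mean(sp_rep)
      grid$sp_region_se[g] <- stats::sd(sp_rep) / sqrt(n_reps)
      if (!is.null(wcfg)) {
        grid$mp_region_rate[g] <- mean(mp_rep)
        grid$mp_region_se[g] <- stats::sd(mp_rep) / sqrt(n_reps)
      }
    }
  })
  grid
}

#' Overlap metrics between two region sets
#'
#' `S` ("successful detection rate") is the percentage of the benchmark
#' regions' total length that the test regions overlap. `C` ("consistency
#' rate") is the percentage of the test regions' total length contributed by
#' test regions whose own overlap ratio (overlapped length / region length)
#' with the benchmark is at least 50%.
#'
#' @param regions_test,regions_benchmark data.frames with `chromosome`,
#'   `start_bp`, `end_bp` (1-based inclusive).
#' @param mode `"S"` or `"C"`.
#' @return Percentage in \[0, 100\], or `NA` when the reference side of the
#'   metric is empty.
#' @export
overlap_metrics <- function(regions_test, regions_benchmark,
                            mode = c("S", "C")) {
  mode <- match.arg(mode)
  empty <- function(r) is.null(r) || nrow(r) == 0
  if (mode == "S" && empty(regions_benchmark)) return(NA_real_)
  if (mode == "C" && empty(regions_test)) return(NA_real_)
  if (empty(regions_test) && mode == "S") return(0)
  if (empty(regions_benchmark) && mode == "C") return(0)
  ov_len <- function(a_lo, a_hi, b) {
    if (nrow(b) == 0) return(0)
    sum(pmax(0, pmin(a_hi, b$end_bp) - pmax(a_lo, b$start_bp) + 1))
  }
  merge_regions <- function(r) {
    out <- list()
    for (chr in unique(r$chromosome)) {
      rc <- r[r$chromosome == chr, , drop = FALSE]
      rc <- rc[order(rc$start_bp), , drop = FALSE]
      lo <- rc$start_bp[1]; hi <- rc$end_bp[1]
      for (k in seq_len(nrow(rc))[-1]) {
        if (rc$start_bp[k] <= hi + 1) hi <- max(hi, rc$end_bp[k])
        else { out[[length(out) + 1]] <- data.frame(chromosome = chr,
                 start_bp = lo, end_bp = hi); lo <- rc$start_bp[k]; hi <- rc$end_bp[k] }
      }
      out[[length(out) + 1]] <- data.frame(chromosome = chr,
                                           start_bp = lo, end_bp = hi)
    }
    do.call(rbind, out)
  }
  if (mode == "S") {
    bench <- merge_regions(regions_benchmark)
    test <- merge_regions(regions_test)
    tot <- sum(bench$end_bp - bench$start_bp + 1)
    got <- sum(vapply(seq_len(nrow(bench)), function(k)
      ov_len(bench$start_bp[k], bench$end_bp[k],
             test[test$chromosome == bench$chromosome[k], , drop = FALSE]), 0))
    return(100 * got / tot)
  }
  bench <- merge_regions(regions_benchmark)
  lens <- regions_test$end_bp - regions_test$start_bp + 1
  ratio <- vapply(seq_len(nrow(regions_test)), function(k)
    ov_len(regions_test$start_bp[k], regions_test$end_bp[k],
           bench[bench$chromosome == regions_test$chromosome[k], , drop = FALSE]) /
      lens[k], 0)
  100 * sum(lens[ratio >= 0.5]) / sum(lens)
}

#' Relative copy number from qPCR cycle thresholds
#'
#' Delta-delta-Ct estimator: per replicate,
#' \eqn{2^{-[(T_{target} - T_{control}) - (R_{target} - R_{control})]}},
#' reported on the haploid scale (1 = same dose as the reference) with the
#' sample SD over replicates; a diploid-scale convenience value (x2) is also
#' returned.
#'
#' @param T_target,T_control Ct replicate vectors of the test sample at the
#'   target and internal-control loci.
#' @param R_target,R_control scalar mean Ct of the reference samples at the
#'   two loci.
#' @return A list with `ratios`, `mean`, `se` (`NA` with < 2 replicates) and
#'   `diploid_mean`.
#' @export
qpcr_copy_number <- function(T_target, T_control, R_target, R_control) {
  stopifnot(length(T_target) == length(T_control),
            all(is.finite(c(T_target, T_control, R_target, R_control))))
  ddct <- (T_target - T_control) - (R_target - R_control)
  ratios <- 2^(-ddct)
  list(ratios = ratios, mean = mean(ratios),
       se = if (length(ratios) >= 2) stats::sd(ratios) else NA_real_,
       diploid_mean = 2 * mean(ratios))
}

#' Mix an aberrant and a normal sample
#'
#' Emulates an admixture titration: allele intensities are mixed linearly,
#' `h_mix = (p/100) h_aberrant + (1 - p/100) h_normal`, so both the total
#' intensity and the allele-frequency signal dilute on the intensity scale.
#' The genotype calls of the majority component are retained.
#'
#' @param aberrant,normal two [sample_data()] on the same annotation.
#' @param p_percent admixture proportion of the aberrant sample (0-100).
#' @return A [sample_data()].
#' @export
mix_samples <- function(aberrant, normal, p_percent) {
  stopifnot(p_percent >= 0, p_percent <= 100)
  w <- p_percent / 100
  geno <- if (w >= 0.5) aberrant$genotype else normal$genotype
  sample_data(sprintf("%s_mix%g", aberrant$sample_id, p_percent),
              w * aberrant$h_A + (1 - w) * normal$h_A,
              w * aberrant$h_B + (1 - w) * normal$h_B,
              geno, aberrant$annotation)
}
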