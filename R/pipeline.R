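#' Run configuration for the whole-genome pipeline
#'
#' Validated bundle of paths and parameters for [run_pipeline()]. The
#' preprocessing toggles span the standard 8-combination grid (log2 x
#' mean/median/none centering x quantile normalization).
#'
#' @param calls_path,summary_path,annotation_path input tables (see
#'   [read_genotype_intensity_tables()]).
#' @param test_samples character vector of sample ids to analyse; the
#'   remaining columns form the normal reference panel. `NULL` analyses
#'   every sample against a panel of all the others is NOT done; instead all
#'   samples form the panel and each is analysed unpaired against it.
#' @param out_dir output directory.
#' @param preprocess list with `log2`, `center`, `quantile`.
#' @param alpha significance level.
#' @param v,n_c,Q_percent,loess_span,combine_mode multipoint settings.
#' @param genotype_specific,paired detector modes; paired mode requires
#'   `paired_sample`, the id of the matched normal.
#' @param paired_sample sample id of the matched normal (paired mode).
#' @param segmentation_method `"original"` or `"quick"`.
#' @param cbs a [cbs_params()].
#' @param seed RNG seed for the segmentation permutations.
#' @return A list of class `run_config`.
#' @export
run_config <- function(calls_path, summary_path, annotation_path,
                       test_samples = NULL, out_dir = "snpscan_out",
                       preprocess = list(log2 = TRUE, center = "none",
                                         quantile = FALSE),
                       alpha = 0.05, v = 5, n_c = 2, Q_percent = 95,
                       loess_span = 0.02, combine_mode = "both",
                       genotype_specific = FALSE, paired = FALSE,
                       paired_sample = NULL,
                       segmentation_method = c("original", "quick"),
                       cbs = cbs_params(), seed = 1) {
  segmentation_method <- match.arg(segmentation_method)
  if (paired && is.null(paired_sample))
    stop("paired mode requires paired_sample")
  for (p in c(calls_path, summary_path, annotation_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(list(calls_path = calls_path, summary_path = summary_path,
                 annotation_path = annotation_path,
                 test_samples = test_samples, out_dir = out_dir,
                 preprocess = preprocess, alpha = alpha,
                 v = as.integer(v), n_c = as.integer(n_c),
                 Q_percent = Q_percent, loess_span = loess_span,
                 combine_mode = combine_mode,
                 genotype_specific = genotype_specific, paired = paired,
                 paired_sample = paired_sample,
                 segmentation_method = segmentation_method,
                 cbs = cbs, seed = seed),
            class = "run_config")
}

#' Whole-genome integrated analysis pipeline
#'
#' Orchestrates panel construction, allele-frequency estimation,
#' single-point and multipoint detection of allelic imbalance, LOH/LCSH and
#' copy-number change, copy-number segmentation, and the six-panel numeric
#' output per test sample: calibrated AF; AI flags and WAP; LOH flags and
#' WAP; the final intensity `t` with its segmentation; the CNV WAP; and the
#' CNV p-value track. Regions of each aberration type are joined and written
#' as BED and TSV alongside a parameter log. Outputs are a pure function of
#' (inputs, config, seed).
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the panel and, per test sample, the tracks
#'   and regions; files are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  samples <- read_genotype_intensity_tables(config$calls_path,
                                            config$summary_path,
                                            config$annotation_path)
  ids <- vapply(samples, `[[`, "", "sample_id")
  test_ids <- config$test_samples %||% ids
  missing_ids <- setdiff(test_ids, ids)
  if (length(missing_ids))
    stop("pipeline stage 'input': unknown test sample(s): ",
         paste(missing_ids, collapse = ", "))
  normal_ids <- setdiff(ids, test_ids)
  if (length(normal_ids) < 2) normal_ids <- ids  # panel of everyone
  normals <- samples[ids %in% normal_ids]

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  panel <- stage("reference panel",
                 build_reference_panel(normals, preprocess = config$preprocess,
                                       alpha = config$alpha))
  wcfg <- window_config(v = config$v, n_c = config$n_c,
                        Q_percent = config$Q_percent,
                        loess_span = config$loess_span,
                        combine_mode = config$combine_mode)
  for (E in c("AI", "LOH", "GAIN", "LOSS"))
    panel <- stage(paste("WAP reference", E),
                   add_wap_reference(panel, normals, E, wcfg$v, wcfg$n_c,
                                     wcfg$Q_percent, wcfg$loess_span))
  cfg <- detection_config(alpha = config$alpha,
                          genotype_specific = config$genotype_specific,
                          paired = config$paired)
  paired_res <- NULL
  if (config$paired) {
    psmp <- samples[[match(config$paired_sample, ids)]]
    paired_res <- stage("paired normal", detect_sample(psmp, panel, NULL,
                                                       detection_config(config$alpha)))
  }
  ann <- panel$annotation
  results <- list()
  for (sid in test_ids) {
    smp <- samples[[match(sid, ids)]]
    res <- stage(paste("detection", sid), detect_sample(smp, panel, wcfg, cfg))
    regions <- rbind(
      join_regions(res$mp_ai$combined, ann, "multi", "AI", v = wcfg$v,
                   p = res$mp_ai$p, wap = res$mp_ai$wap),
      join_regions(res$mp_loh$combined, ann, "multi", "LOH", v = wcfg$v,
                   p = res$mp_loh$p, wap = res$mp_loh$wap),
      join_regions(res$mp_gain$combined, ann, "multi", "GAIN", v = wcfg$v,
                   p = res$mp_gain$p, wap = res$mp_gain$wap),
      join_regions(res$mp_loss$combined, ann, "multi", "LOSS", v = wcfg$v,
                   p = res$mp_loss$p, wap = res$mp_loss$wap))
    segs <- stage(paste("segmentation", sid), {
      if (config$segmentation_method == "quick") {
        d_ai <- res$mp_ai$wap -
          panel$wap_refs[[wap_key("AI", wcfg$v, wcfg$n_c, wcfg$Q_percent)]]$quant
        d_loh <- res$mp_loh$wap -
          panel$wap_refs[[wap_key("LOH", wcfg$v, wcfg$n_c, wcfg$Q_percent)]]$quant
        wts <- quick_cbs_weights(d_ai, d_loh)
        prm <- config$cbs; prm$rng_seed <- config$seed
        quick_cbs_segment(res$t, regions[regions$type == "AI", ],
                          regions[regions$type == "LOH", ],
                          weights = wts, params = prm, annotation = ann)
      } else {
        prm <- config$cbs; prm$rng_seed <- config$seed
        cbs_segment(res$t, params = prm, annotation = ann)
      }
    })
    tracks <- data.frame(
      marker_id = ann$marker_id, chromosome = ann$chromosome,
      position_bp = ann$position_bp,
      af = res$af$final,
      ai_flag = res$ai, ai_wap = res$mp_ai$wap,
      loh_flag = res$loh, loh_wap = res$mp_loh$wap,
      t = res$t,
      cnv_flag = res$cnv$flags,
      cnv_wap_gain = res$mp_gain$wap, cnv_wap_loss = res$mp_loss$wap,
      cnv_p = res$cnv$p, stringsAsFactors = FALSE)
    sdir <- file.path(config$out_dir, sid)
    export_results(tracks, regions, sdir,
                   params = list(alpha = config$alpha, w = 2 * config$v + 1,
                                 n_c = config$n_c, Q = config$Q_percent,
                                 span = config$loess_span,
                                 combine = config$combine_mode,
                                 segmentation = config$segmentation_method,
                                 seed = config$seed))
    utils::write.table(segs, file.path(sdir, "segments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results[[sid]] <- list(tracks = tracks, regions = regions,
                           segments = segs)
  }
  invisible(list(panel = panel, samples = results, out_dir = config$out_dir))
}
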