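#' Convert "Log Ratio"/"Strength" values to allele intensities
#'
#' Vendor per-sample exports provide, for each SNP, the arithmetic mean `S`
#' of the log2 allele intensities ("Strength") and the log2 ratio `L` of the
#' allele-A to allele-B intensity ("Log Ratio"). Solving the two equations
#' gives the linear-scale allele intensities
#' \deqn{h_A = 2^{S + L/2}, \qquad h_B = 2^{S - L/2}.}
#'
#' @param S,L numeric vectors of equal length, finite.
#' @return A list with components `h_A` and `h_B` (positive numerics). The
#'   transform round-trips: `mean(log2(h_A), log2(h_B)) == S` and
#'   `log2(h_A / h_B) == L`.
#' @examples
#' convert_log_ratio_strength(1, 0)   # h_A = h_B = 2
#' convert_log_ratio_strength(0.5, 1) # h_A = 2, h_B = 1
#' @export
convert_log_ratio_strength <- function(S, L) {
  S <- as.numeric(S); L <- as.numeric(L)
  if (length(S) != length(L)) stop("S and L must have equal length")
  if (any(!is.finite(S)) || any(!is.finite(L)))
    stop("S and L must be finite")
  list(h_A = 2^(S + 0.5 * L), h_B = 2^(S - 0.5 * L))
}

#' Read a marker annotation TSV
#'
#' Expects tab-delimited columns `marker_id`, `chromosome`, `position`
#' (or `position_bp`), `allele_A`, `allele_B`, `probe_class`; the last three
#' are optional (default SNP probes).
#'
#' @param path file path.
#' @return A [marker_annotation()].
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pos_col <- intersect(c("position_bp", "position"), names(tab))
  need <- c("marker_id", "chromosome")
  if (!all(need %in% names(tab)) || length(pos_col) == 0)
    stop("annotation must have columns marker_id, chromosome, position")
  marker_annotation(
    marker_id = tab$marker_id,
    chromosome = tab$chromosome,
    position_bp = tab[[pos_col[1]]],
    probe_class = if ("probe_class" %in% names(tab)) tab$probe_class else "SNP",
    allele_A = if ("allele_A" %in% names(tab)) tab$allele_A else NA_character_,
    allele_B = if ("allele_B" %in% names(tab)) tab$allele_B else NA_character_)
}

#' Read genotype-call and intensity-summary exports
#'
#' Parses the tab-delimited "calls" (markers x samples, integer genotype
#' codes) and "summary" (two rows per SNP marker, suffixed `-A` and `-B`,
#' x samples) tables exported by array genotyping pipelines, aligning both
#' to a marker annotation.
#'
#' @param calls_path path to the calls table; first column `probeset_id`
#'   (any name accepted), remaining columns one per sample.
#' @param summary_path path to the allele-summary table with rows
#'   `<marker>-A` / `<marker>-B`.
#' @param annotation_path path to the annotation TSV (see
#'   [read_annotation()]), or a ready [marker_annotation()].
#' @param code_map named integer-to-genotype map; vendor exports vary, the
#'   default is `0 -> AA, 1 -> AB, 2 -> BB, -1 -> NoCall`.
#'
#' @return A list of [sample_data()], one per sample column, markers ordered
#'   as in the annotation. Missing intensity cells become missing markers for
#'   that sample, never zeros.
#' @export
read_genotype_intensity_tables <- function(calls_path, summary_path,
                                           annotation_path,
                                           code_map = c(`0` = "AA", `1` = "AB",
                                                        `2` = "BB", `-1` = "NoCall")) {
  ann <- if (inherits(annotation_path, "marker_annotation")) annotation_path
         else read_annotation(annotation_path)
  calls <- utils::read.delim(calls_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  summ <- utils::read.delim(summary_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  call_ids <- as.character(calls[[1]])
  samp <- names(calls)[-1]
  samp_s <- names(summ)[-1]
  if (!identical(sort(samp), sort(samp_s)))
    stop("calls and summary tables have mismatched sample columns")
  summ <- summ[, c(1, match(samp, samp_s) + 1L), drop = FALSE]

  missing_ann <- setdiff(call_ids, ann$marker_id)
  if (length(missing_ann))
    stop("marker(s) in calls but absent from annotation: ",
         paste(utils::head(missing_ann, 5), collapse = ", "))

  sum_ids <- as.character(summ[[1]])
  rowA <- match(paste0(ann$marker_id, "-A"), sum_ids)
  rowB <- match(paste0(ann$marker_id, "-B"), sum_ids)
  is_snp <- ann$probe_class == "SNP"
  half_missing <- is_snp & (is.na(rowA) != is.na(rowB))
  if (any(half_missing))
    stop("summary table has only one allele row for marker(s): ",
         paste(utils::head(ann$marker_id[half_missing], 5), collapse = ", "))

  call_row <- match(ann$marker_id, call_ids)
  lapply(seq_along(samp), function(j) {
    codes <- calls[[j + 1L]][call_row]
    geno <- unname(code_map[as.character(codes)])
    geno[is.na(geno)] <- "NoCall"
    h_A <- as.numeric(summ[[j + 1L]][rowA])
    h_B <- as.numeric(summ[[j + 1L]][rowB])
    sample_data(samp[j], h_A, h_B, geno, ann)
  })
}

#' Read a per-sample "Log Ratio"/"Strength" export
#'
#' Two-column tab-delimited file per sample with columns containing
#' "Log Ratio" and "Strength" plus a marker-id column; converted to
#' allele intensities via [convert_log_ratio_strength()].
#'
#' @param path file path.
#' @param annotation a [marker_annotation()].
#' @param sample_id sample identifier (default: file base name).
#' @param genotype optional genotype call vector aligned to the annotation.
#' @return A [sample_data()].
#' @export
read_log_ratio_strength <- function(path, annotation,
                                    sample_id = sub("\\.[^.]*$", "", basename(path)),
                                    genotype = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lr_col <- grep("log.?ratio", names(tab), ignore.case = TRUE, value = TRUE)
  st_col <- grep("strength", names(tab), ignore.case = TRUE, value = TRUE)
  if (length(lr_col) != 1 || length(st_col) != 1)
    stop("export must contain one 'Log Ratio' and one 'Strength' column")
  idx <- match(annotation$marker_id, as.character(tab[[1]]))
  S <- as.numeric(tab[[st_col]][idx])
  L <- as.numeric(tab[[lr_col]][idx])
  h <- list(h_A = 2^(S + 0.5 * L), h_B = 2^(S - 0.5 * L))
  if (is.null(genotype)) genotype <- rep("NoCall", nrow(annotation))
  sample_data(sample_id, h$h_A, h$h_B, genotype, annotation)
}

#' Export detection tracks and aberrant regions
#'
#' Writes per-marker tracks as TSV, regions both as BED (0-based half-open,
#' name = aberration type, score = -log10 adjusted p capped at 1000) and as a
#' TSV with 1-based inclusive coordinates, plus a plain-text run-parameter
#' file.
#'
#' @param tracks a data.frame of per-marker values (first columns should
#'   identify the marker), or `NULL`.
#' @param regions a data.frame with columns `chromosome`, `start_bp`,
#'   `end_bp`, `type`, `n_markers`, `min_p` (see [join_regions()]), or `NULL`.
#' @param out_dir output directory (created if needed).
#' @param params optional named list of run parameters to log.
#' @return Invisibly, the paths written.
#' @export
export_results <- function(tracks, regions, out_dir, params = list()) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  if (!is.null(tracks)) {
    p <- file.path(out_dir, "tracks.tsv")
    utils::write.table(tracks, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  bed <- file.path(out_dir, "regions.bed")
  tsv <- file.path(out_dir, "regions.tsv")
  if (is.null(regions) || nrow(regions) == 0) {
    writeLines("# no aberrant regions detected", bed)
    utils::write.table(
      data.frame(chromosome = character(0), start_bp = integer(0),
                 end_bp = integer(0), type = character(0),
                 n_markers = integer(0), min_p = numeric(0)),
      tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    reg <- regions[order(chromosome_rank(regions$chromosome), regions$start_bp), ,
                   drop = FALSE]
    minp <- if ("min_p" %in% names(reg)) reg$min_p else rep(NA_real_, nrow(reg))
    score <- ifelse(is.na(minp), 0, pmin(1000, round(-log10(pmax(minp, 1e-300)), 3)))
    bed_lines <- sprintf("%s\t%d\t%d\t%s\t%s", reg$chromosome,
                         as.integer(reg$start_bp) - 1L, as.integer(reg$end_bp),
                         reg$type, format(score, trim = TRUE))
    writeLines(bed_lines, bed)
    utils::write.table(reg, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths <- c(paths, bed, tsv)
  parf <- file.path(out_dir, "run_parameters.txt")
  lines <- c(sprintf("snpscan %s", as.character(utils::packageVersion("snpscan"))),
             sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             vapply(names(params),
                    function(k) sprintf("%s = %s", k,
                                        paste(format(params[[k]]), collapse = ",")),
                    ""))
  writeLines(lines, parf)
  invisible(c(paths, parf))
}
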