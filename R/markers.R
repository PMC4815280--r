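#' Marker annotation table
#'
#' Constructs and validates the genomic coordinate system used by every
#' per-marker track in the package: an ordered table of array markers with
#' chromosome, 1-based physical position and probe class.
#'
#' @param marker_id character vector of unique marker identifiers.
#' @param chromosome character vector of chromosome labels (1-22, X). A
#'   leading `"chr"` prefix is stripped.
#' @param position_bp integer vector of 1-based physical positions.
#' @param probe_class `"SNP"` or `"CN"` per marker. CN probes carry no
#'   genotype and are analysed in their own track.
#' @param allele_A,allele_B optional nucleotide labels for SNP probes.
#'
#' @return A `data.frame` of class `marker_annotation`, strictly sorted by
#'   (chromosome, position_bp).
#' @export
marker_annotation <- function(marker_id, chromosome, position_bp,
                              probe_class = "SNP",
                              allele_A = NA_character_,
                              allele_B = NA_character_) {
  marker_id <- as.character(marker_id)
  chromosome <- normalize_chromosome(chromosome)
  position_bp <- as.integer(position_bp)
  n <- length(marker_id)
  probe_class <- rep_len(as.character(probe_class), n)
  allele_A <- rep_len(as.character(allele_A), n)
  allele_B <- rep_len(as.character(allele_B), n)
  if (length(chromosome) != n || length(position_bp) != n)
    stop("marker_id, chromosome and position_bp must have equal length")
  if (anyDuplicated(marker_id))
    stop("duplicate marker_id: ",
         paste(utils::head(marker_id[duplicated(marker_id)], 3), collapse = ", "))
  if (!all(probe_class %in% c("SNP", "CN")))
    stop("probe_class must be 'SNP' or 'CN'")
  if (any(!is.finite(position_bp)) || any(position_bp < 1L))
    stop("position_bp must be positive 1-based integers")
  ann <- data.frame(marker_id = marker_id, chromosome = chromosome,
                    position_bp = position_bp, probe_class = probe_class,
                    allele_A = allele_A, allele_B = allele_B,
                    stringsAsFactors = FALSE)
  ord <- order(chromosome_rank(ann$chromosome), ann$position_bp)
  ann <- ann[ord, , drop = FALSE]
  rownames(ann) <- NULL
  if (any(duplicated(ann[, c("chromosome", "position_bp")])))
    stop("markers must be strictly sorted: duplicated (chromosome, position)")
  class(ann) <- c("marker_annotation", "data.frame")
  ann
}

#' @export
print.marker_annotation <- function(x, ...) {
  cat(sprintf("marker_annotation: %d markers on %d chromosome(s) (%d SNP, %d CN)\n",
              nrow(x), length(unique(x$chromosome)),
              sum(x$probe_class == "SNP"), sum(x$probe_class == "CN")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

normalize_chromosome <- function(chr) {
  chr <- sub("^chr", "", as.character(chr))
  chr[chr == "23"] <- "X"
  chr
}

chromosome_rank <- function(chr) {
  r <- suppressWarnings(as.integer(chr))
  r[chr == "X"] <- 23L
  r[chr == "Y"] <- 24L
  if (anyNA(r)) stop("unrecognized chromosome label: ",
                     paste(unique(chr[is.na(r)]), collapse = ", "))
  r
}

GENOTYPE_LEVELS <- c("AA", "AB", "BB", "NoCall")

#' Per-sample intensity and genotype container
#'
#' Holds allele-specific hybridization intensities (linear scale) and
#' genotype calls for one sample, aligned to a [marker_annotation()].
#' The raw allele frequency `h_A / (h_A + h_B)` is computed on construction
#' and is missing where the total intensity is zero or an intensity is
#' missing.
#'
#' @param sample_id scalar sample identifier.
#' @param h_A,h_B numeric vectors of nonnegative allele intensities, one per
#'   annotation marker. `NA` marks a missing marker for this sample.
#' @param genotype character vector of calls in `AA`, `AB`, `BB`, `NoCall`;
#'   CN probes should be `NoCall`.
#' @param annotation the [marker_annotation()] the vectors align to.
#'
#' @return A list of class `sample_data` with elements `sample_id`, `h_A`,
#'   `h_B`, `genotype`, `raw_af` and `annotation`.
#' @export
sample_data <- function(sample_id, h_A, h_B, genotype, annotation) {
  stopifnot(inherits(annotation, "marker_annotation"))
  n <- nrow(annotation)
  if (length(h_A) != n || length(h_B) != n || length(genotype) != n)
    stop("sample vectors must match the annotation length (", n, ")")
  h_A <- as.numeric(h_A); h_B <- as.numeric(h_B)
  if (any(h_A < 0, na.rm = TRUE) || any(h_B < 0, na.rm = TRUE))
    stop("allele intensities must be nonnegative")
  genotype <- as.character(genotype)
  if (!all(genotype %in% GENOTYPE_LEVELS | is.na(genotype)))
    stop("genotype values must be one of ", paste(GENOTYPE_LEVELS, collapse = ", "))
  genotype[is.na(genotype)] <- "NoCall"
  tot <- h_A + h_B
  raw_af <- ifelse(is.na(tot) | tot == 0, NA_real_, h_A / tot)
  structure(list(sample_id = as.character(sample_id)[1],
                 h_A = h_A, h_B = h_B, genotype = genotype,
                 raw_af = raw_af, annotation = annotation),
            class = "sample_data")
}

#' @export
print.sample_data <- function(x, ...) {
  cat(sprintf("sample_data '%s': %d markers (%d called, %d missing intensity)\n",
              x$sample_id, length(x$h_A),
              sum(x$genotype != "NoCall"), sum(is.na(x$h_A) | is.na(x$h_B))))
  invisible(x)
}

# Assemble aligned matrices (markers x samples) from a list of sample_data.
# Internal workhorse used by the reference-panel and preprocessing code.
samples_to_matrices <- function(samples) {
  stopifnot(length(samples) >= 1, all(vapply(samples, inherits, TRUE, "sample_data")))
  ann <- samples[[1]]$annotation
  ids <- vapply(samples, `[[`, "", "sample_id")
  for (s in samples)
    if (!identical(s$annotation$marker_id, ann$marker_id))
      stop("all samples must share one annotation")
  list(annotation = ann,
       sample_ids = ids,
       h_A = vapply(samples, `[[`, numeric(nrow(ann)), "h_A"),
       h_B = vapply(samples, `[[`, numeric(nrow(ann)), "h_B"),
       genotype = vapply(samples, `[[`, character(nrow(ann)), "genotype"),
       raw_af = vapply(samples, `[[`, numeric(nrow(ann)), "raw_af"))
}

# Evaluate expr with a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
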