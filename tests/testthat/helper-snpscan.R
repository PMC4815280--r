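# shared fixtures, built once per test run
.snpscan_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .snpscan_cache))
    assign(name, force(expr), envir = .snpscan_cache)
  get(name, envir = .snpscan_cache)
}

# small template population/panel for mechanics tests (fast)
small_pop <- function() cached("small_pop", {
  generate_reference_population(
    population_params(chromosomes = c(`2` = 401L)), n_samples = 60, seed = 101)
})

small_panel <- function() cached("small_panel", {
  pop <- small_pop()
  p <- suppressMessages(build_reference_panel(pop$samples))
  for (E in c("AI", "LOH", "GAIN", "LOSS"))
    p <- add_wap_reference(p, pop$samples, E, v = 5, n_c = 2,
                           Q_percent = 95, span = 0.02)
  p
})

# full-scale template (2001 SNPs, 200 normals) used by the acceptance tests
full_pop <- function() cached("full_pop", {
  generate_reference_population(n_samples = 200, seed = 20240501)
})

full_panel <- function() cached("full_panel", {
  pop <- full_pop()
  p <- suppressMessages(build_reference_panel(pop$samples))
  for (E in c("GAIN", "LOSS"))
    p <- add_wap_reference(p, pop$samples, E, v = 5, n_c = 2,
                           Q_percent = 95, span = 0.02)
  p
})

# one-copy (male X) template population for the gain scenario
gain_pop <- function() cached("gain_pop", {
  generate_reference_population(
    population_params(chromosomes = c(X = 2001L)), n_samples = 200,
    seed = 20240502, sex = "M")
})

gain_panel <- function() cached("gain_panel", {
  pop <- gain_pop()
  p <- suppressMessages(build_reference_panel(pop$samples))
  for (E in c("GAIN", "LOSS"))
    p <- add_wap_reference(p, pop$samples, E, v = 5, n_c = 2,
                           Q_percent = 95, span = 0.02)
  p
})

tiny_annotation <- function(n, chr = "1", start = 1000L, step = 1000L) {
  marker_annotation(sprintf("m%03d", seq_len(n)), rep(chr, n),
                    seq(start, by = step, length.out = n))
}

# minimal hand-built panel for the single-point detector oracles: identical
# reference statistics at every one of M markers on a single chromosome
fake_panel <- function(M, f_mean = c(AA = 0.95, AB = 0.5, BB = 0.05),
                       f_sd = c(AA = 0.01, AB = 0.02, BB = 0.01),
                       t_mean = 0, t_sd = 1, alpha = 0.05) {
  ann <- tiny_annotation(M)
  mk <- function(v) {
    m <- matrix(rep(v, each = M), nrow = M)
    colnames(m) <- c("AA", "AB", "BB")
    m
  }
  structure(list(
    annotation = ann, n_samples = 100, alpha = alpha,
    preprocess = list(log2 = FALSE, center = "none", quantile = FALSE),
    kappa = rep(1, M),
    cluster = cluster_means(rep(f_mean["AA"], M), rep(f_mean["AB"], M),
                            rep(f_mean["BB"], M)),
    calibratable = rep(TRUE, M),
    n_g = mk(c(30, 40, 30)),
    f_mean_g = mk(f_mean), f_sd_g = mk(f_sd),
    t_mean_g = mk(rep(t_mean, 3)), t_sd_g = mk(rep(t_sd, 3)),
    t_mean = rep(t_mean, M), t_sd = rep(t_sd, M),
    degenerate = rep(FALSE, M),
    wap_refs = list()), class = "snp_panel")
}

# 3-marker / 2-sample calls + summary + annotation fixture on disk; the
# temporary directory lives until the calling test exits
write_fixture_tables <- function(dir = NULL, drop_summary_row = NULL) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  ann <- data.frame(marker_id = c("rs1", "rs2", "rs3"),
                    chromosome = c("1", "1", "2"),
                    position = c(100L, 200L, 150L),
                    allele_A = "A", allele_B = "B", probe_class = "SNP")
  calls <- data.frame(probeset_id = c("rs1", "rs2", "rs3"),
                      S1 = c(0L, 1L, 2L), S2 = c(-1L, 2L, 1L))
  summ <- data.frame(probeset_id = c("rs1-A", "rs1-B", "rs2-A", "rs2-B",
                                     "rs3-A", "rs3-B"),
                     S1 = c(1000, 50, 480, 520, 30, 900),
                     S2 = c(400, 410, 25, 800, 510, 490))
  if (!is.null(drop_summary_row))
    summ <- summ[summ$probeset_id != drop_summary_row, ]
  paths <- list(annotation = file.path(dir, "annotation.tsv"),
                calls = file.path(dir, "calls.tsv"),
                summary = file.path(dir, "summary.tsv"))
  utils::write.table(ann, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(calls, paths$calls, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summ, paths$summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

# brute-force oracle for the consecutive-run indicator: enumerate all
# placements of n_c consecutive markers covering x, fully in bounds
brute_J <- function(flags, n_c) {
  n <- length(flags)
  sig <- !is.na(flags) & flags != 0
  vapply(seq_len(n), function(x) {
    for (l in seq_len(n_c)) {
      z <- (x - n_c + l):(x + l - 1)
      if (z[1] >= 1 && z[length(z)] <= n && all(sig[z])) return(1)
    }
    0
  }, 0)
}

# brute-force WAP: window mean of brute_J with end truncation
brute_wap <- function(flags, v, n_c) {
  J <- brute_J(flags, n_c)
  n <- length(J)
  vapply(seq_len(n), function(m)
    mean(J[max(1, m - v):min(n, m + v)]), 0)
}
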