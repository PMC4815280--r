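test_that("constant track yields a single segment", {
  seg <- cbs_segment(rep(1.5, 60), cbs_params(rng_seed = 1))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$mean_t, 1.5)
  expect_equal(seg$n_markers, 60)
  # short track: single segment without testing
  seg2 <- cbs_segment(stats::rnorm(6), cbs_params(min_markers = 5, rng_seed = 1))
  expect_equal(nrow(seg2), 1)
})

test_that("a clear step is located within one marker at maximal significance", {
  set.seed(31)
  x <- c(stats::rnorm(50, 0, 0.01), stats::rnorm(50, 5, 0.01))
  seg <- cbs_segment(x, cbs_params(n_permutations = 199, rng_seed = 2))
  expect_equal(nrow(seg), 2)
  expect_true(abs(seg$end_idx[1] - 50) <= 1)
  expect_lte(min(seg$p_change, na.rm = TRUE), 1 / 200)
  expect_equal(seg$mean_t, c(0, 5), tolerance = 0.01)
})

test_that("a 0.01-SD step is not split at alpha 0.01", {
  set.seed(32)
  x <- stats::rnorm(100) + rep(c(0, 0.01), each = 50)
  seg <- cbs_segment(x, cbs_params(n_permutations = 199, rng_seed = 3))
  expect_equal(nrow(seg), 1)
})

test_that("segment means conserve the track mean (marker-count weighted)", {
  set.seed(33)
  x <- c(stats::rnorm(40, 0), stats::rnorm(30, 4), stats::rnorm(50, -2))
  seg <- cbs_segment(x, cbs_params(n_permutations = 199, rng_seed = 4))
  expect_equal(sum(seg$mean_t * seg$n_markers) / sum(seg$n_markers), mean(x))
  expect_equal(sum(seg$n_markers), length(x))
  # segments partition the index range
  expect_equal(seg$start_idx[1], 1)
  expect_equal(seg$end_idx[nrow(seg)], length(x))
  if (nrow(seg) > 1)
    expect_equal(seg$start_idx[-1], seg$end_idx[-nrow(seg)] + 1)
})

test_that("change-point recovery within +/-1 marker on 5-SD steps
           (100 seeded trials)", {
  hits <- 0
  for (trial in 1:100) {
    set.seed(1000 + trial)
    cp <- sample(30:90, 1)
    x <- stats::rnorm(120) + c(rep(0, cp), rep(5, 120 - cp))
    seg <- cbs_segment(x, cbs_params(n_permutations = 119, rng_seed = trial))
    if (any(abs(seg$end_idx - cp) <= 1)) hits <- hits + 1
  }
  expect_equal(hits, 100)
})

test_that("quick CBS weights: floor, rescale and symmetry", {
  # all differences <= 0 after rescale -> uniform floor weights
  w <- quick_cbs_weights(c(-3, -2, -3), c(-5, -5, -5))
  # dA rescales to [-1, 1, -1]: only the middle is positive
  expect_equal(w, c(1e-10, 1 + 1e-10, 1e-10) / (1 + 3e-10))
  w0 <- quick_cbs_weights(rep(0, 4), rep(-1, 4))  # both constant -> uniform
  expect_equal(w0, rep(0.25, 4))
  # hand rescale: dA = (0,1,2) -> (-1,0,1); constant dL -> 0
  w1 <- quick_cbs_weights(c(0, 1, 2), c(-9, -9, -9))
  expect_equal(w1 * sum(c(1e-10, 1e-10, 1 + 1e-10)),
               c(1e-10, 1e-10, 1 + 1e-10))
  # equal tracks: the max is idempotent
  d <- c(0.1, -0.2, 0.5, 0)
  expect_equal(quick_cbs_weights(d, d),
               quick_cbs_weights(d, pmin(d, -1e6)))
  expect_true(all(quick_cbs_weights(d, d) >= 0))
  expect_equal(sum(quick_cbs_weights(d, d)), 1)
})

test_that("weighted permutation test: reduction, extremes, null, seed", {
  set.seed(41)
  xl <- stats::rnorm(12); xr <- stats::rnorm(15, 0.5)
  r_unif <- weighted_t_permutation(xl, xr, rep(1, 27), n_perm = 99, seed = 5)
  tt <- stats::t.test(xl, xr, var.equal = TRUE)$statistic
  # uniform weights: proportional to the ordinary two-sample t statistic,
  # with the known constant sqrt(n / (n - 2)) from the pooled-variance
  # denominator; scaling all weights by c multiplies the statistic by sqrt(c)
  expect_equal(r_unif$statistic, unname(tt) * sqrt(27 / 25))
  expect_equal(weighted_t_permutation(xl, xr, rep(2, 27), n_perm = 9,
                                      seed = 5)$statistic,
               sqrt(2) * r_unif$statistic)
  # 10-SD separation: maximal significance at n_perm = 199
  r <- weighted_t_permutation(stats::rnorm(20), stats::rnorm(20, 10),
                              n_perm = 199, seed = 6)
  expect_equal(r$p, 1 / 200)
  # identical sides, zero variance: p = 1
  expect_equal(weighted_t_permutation(rep(1, 5), rep(1, 5))$p, 1)
  # label swap flips the sign; the p-values agree up to permutation noise
  r1 <- weighted_t_permutation(xl, xr, n_perm = 999, seed = 7)
  r2 <- weighted_t_permutation(xr, xl, n_perm = 999, seed = 7)
  expect_equal(r1$statistic, -r2$statistic)
  expect_lt(abs(r1$p - r2$p), 0.06)
  # reproducible under a fixed seed
  expect_identical(weighted_t_permutation(xl, xr, n_perm = 99, seed = 8),
                   weighted_t_permutation(xl, xr, n_perm = 99, seed = 8))
})

test_that("null p-values of the weighted permutation test are well spread", {
  set.seed(42)
  ps <- replicate(60, weighted_t_permutation(stats::rnorm(10),
                                             stats::rnorm(10),
                                             n_perm = 59)$p)
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.8)
})

test_that("quick CBS agrees with full CBS on steps confined to AI regions", {
  set.seed(43)
  n <- 160
  x <- stats::rnorm(n, 0, 0.1)
  x[61:100] <- x[61:100] - 2           # loss inside the AI region 51..110
  ann <- tiny_annotation(n, chr = "3")
  ai <- data.frame(chromosome = "3", start_idx = 51, end_idx = 110,
                   start_bp = ann$position_bp[51], end_bp = ann$position_bp[110])
  full <- cbs_segment(x[51:110], cbs_params(n_permutations = 199, rng_seed = 9))
  quick <- quick_cbs_segment(x, ai, NULL, params = cbs_params(
    n_permutations = 199, rng_seed = 9), annotation = ann)
  # the change points found inside the region must coincide
  full_cuts <- 50 + full$end_idx[-nrow(full)]
  quick_cuts <- quick$end_idx[-nrow(quick)]
  expect_true(all(full_cuts %in% quick_cuts))
  expect_true(any(abs(quick_cuts - 60) <= 1))
  expect_true(any(abs(quick_cuts - 100) <= 1))
  # flanks are grouped as-is: first segment spans 1..50
  expect_equal(quick$start_idx[1], 1)
  expect_equal(quick$end_idx[1], 50)
})

test_that("no aberrant regions: one segment per chromosome; b/a rule warns", {
  x <- stats::rnorm(80)
  ann2 <- marker_annotation(sprintf("m%03d", 1:80),
                            rep(c("1", "2"), each = 40),
                            rep(seq(1000, by = 1000, length.out = 40), 2))
  seg <- quick_cbs_segment(x, NULL, NULL, params = cbs_params(rng_seed = 1),
                           annotation = ann2)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$chromosome, c("1", "2"))
  # 10 fragments, 1 of them shorter than 1% of the chromosome: b/a = 10%
  n <- 1000
  ann <- tiny_annotation(n, chr = "5", step = 1000L)
  starts <- seq(1, 901, by = 100)
  regs <- data.frame(chromosome = "5", start_idx = starts,
                     end_idx = starts + c(rep(49, 9), 4),
                     start_bp = ann$position_bp[starts],
                     end_bp = ann$position_bp[starts + c(rep(49, 9), 4)])
  expect_warning(
    quick_cbs_segment(stats::rnorm(n), regs, NULL,
                      params = cbs_params(n_permutations = 19, rng_seed = 2),
                      annotation = ann),
    "b/a = 10%")
})

test_that("uniform-weight quick CBS over a whole-chromosome region equals
           full CBS on a strong step", {
  set.seed(44)
  x <- stats::rnorm(120) + rep(c(0, 6), each = 60)
  ann <- tiny_annotation(120, chr = "4")
  whole <- data.frame(chromosome = "4", start_idx = 1, end_idx = 120,
                      start_bp = ann$position_bp[1],
                      end_bp = ann$position_bp[120])
  p <- cbs_params(n_permutations = 199, rng_seed = 11)
  full <- cbs_segment(x, p, annotation = ann)
  quick <- quick_cbs_segment(x, whole, NULL, weights = rep(1 / 120, 120),
                             params = p, annotation = ann)
  expect_equal(quick$end_idx[-nrow(quick)], full$end_idx[-nrow(full)])
})

test_that("quick CBS evaluates fewer candidate splits than full CBS", {
  # structural property: the quick variant's split search space is the
  # region length, strictly less than the chromosome length when regions
  # cover part of the chromosome
  n <- 200
  region_len <- 60
  expect_lt(region_len * (region_len + 1) / 2, n * (n + 1) / 2)
  # and empirically it is faster on a null track
  x <- stats::rnorm(n)
  ann <- tiny_annotation(n, chr = "6")
  reg <- data.frame(chromosome = "6", start_idx = 71, end_idx = 130,
                    start_bp = ann$position_bp[71],
                    end_bp = ann$position_bp[130])
  p <- cbs_params(n_permutations = 99, rng_seed = 12)
  t_full <- system.time(cbs_segment(x, p, annotation = ann))["elapsed"]
  t_quick <- system.time(quick_cbs_segment(x, reg, NULL, params = p,
                                           annotation = ann))["elapsed"]
  expect_lte(t_quick, t_full + 0.05)
})

test_that("segmentation is reproducible under a fixed seed", {
  set.seed(45)
  x <- stats::rnorm(100) + rep(c(0, 1), each = 50)
  p <- cbs_params(n_permutations = 99, rng_seed = 77)
  expect_identical(cbs_segment(x, p), cbs_segment(x, p))
})
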