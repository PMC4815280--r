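test_that("population generation is deterministic and restores the RNG", {
  set.seed(99); before <- stats::runif(1)
  set.seed(99)
  p1 <- generate_reference_population(
    population_params(chromosomes = c(`1` = 50L)), n_samples = 5, seed = 3)
  after <- stats::runif(1)
  expect_equal(after, before)  # caller RNG state untouched
  p2 <- generate_reference_population(
    population_params(chromosomes = c(`1` = 50L)), n_samples = 5, seed = 3)
  expect_identical(p1$maf, p2$maf)
  expect_identical(p1$samples[[3]]$h_A, p2$samples[[3]]$h_A)
  expect_identical(p1$samples[[5]]$genotype, p2$samples[[5]]$genotype)
})

test_that("genotypes follow Hardy-Weinberg at the drawn allele frequencies", {
  pop <- generate_reference_population(
    population_params(chromosomes = c(`1` = 10000L)), n_samples = 500,
    seed = 17)
  G <- vapply(pop$samples, `[[`, character(10000), "genotype")
  het <- rowMeans(G == "AB")
  expected <- 2 * pop$maf * (1 - pop$maf)
  se <- sqrt(expected * (1 - expected) / 500)
  frac_outside <- mean(abs(het - expected) > 3 * se)
  expect_lt(frac_outside, 0.01)  # ~0.3% expected outside 3 SDs
})

test_that("male X sits one copy-shift below female X by construction", {
  pp <- population_params(chromosomes = c(`1` = 200L, X = 200L))
  pop <- generate_reference_population(pp, n_samples = 60, seed = 23,
                                       sex = rep(c("F", "M"), 30))
  s <- log2(vapply(pop$samples, function(z) z$h_A + z$h_B, numeric(400)))
  on_x <- pop$annotation$chromosome == "X"
  male <- pop$sex == "M"
  gap <- mean(s[on_x, !male]) - mean(s[on_x, male])
  expect_equal(gap, pp$copy_shift_log2, tolerance = 0.05)
  # autosomes unaffected
  expect_lt(abs(mean(s[!on_x, !male]) - mean(s[!on_x, male])), 0.05)
  # hemizygous markers carry no heterozygote calls
  Gm <- vapply(pop$samples[male], `[[`, character(400), "genotype")
  expect_false(any(Gm[on_x, ] == "AB"))
})

test_that("raw AF clusters reflect the kappa bias and CPA recovers it", {
  pop <- small_pop()
  panel <- small_panel()
  expect_equal(median(panel$kappa), pop$params$kappa, tolerance = 0.05)
})

test_that("loss injection respects the truncation filter exactly", {
  pop <- small_pop()
  panel <- small_panel()
  pool <- make_donor_pool(pop, 1L)
  cfg <- simulation_config("loss", N_T = 51, r = 4, q_percent = 0, seed = 31)
  smp <- draw_normal_sample(pop)
  inj <- inject_aberration(smp, pool, panel, cfg)
  idx <- attr(inj, "target_idx")
  s <- log2(inj$h_A + inj$h_B)
  gi <- match(inj$genotype[idx], c("AA", "AB", "BB"))
  mu <- panel$s_mean_g[cbind(idx, gi)]
  sd <- panel$s_sd_g[cbind(idx, gi)]
  mu[is.na(mu)] <- panel$s_mean[idx][is.na(mu)]
  sd[is.na(sd) | sd == 0] <- panel$s_sd[idx][is.na(sd) | sd == 0]
  expect_true(all(s[idx] <= mu - 4 * sd))
  # markers outside the target untouched
  expect_identical(inj$h_A[-idx], smp$h_A[-idx])
  expect_identical(inj$genotype[-idx], smp$genotype[-idx])
})

test_that("target centering convention: N_T = 501 in 2001 occupies 751-1251", {
  ann <- tiny_annotation(2001)
  smp <- sample_data("t", rep(100, 2001), rep(100, 2001),
                     rep("AB", 2001), ann)
  pop <- small_pop()  # only used for the pool; injection fails later anyway
  cfg <- simulation_config("neutral", N_T = 501, seed = 1)
  idx <- snpscan:::target_indices(2001, 501)
  expect_equal(range(idx), c(751, 1251))
  expect_equal(snpscan:::target_indices(7, 3), 3:5)
  expect_error(snpscan:::target_indices(5, 7), "larger than")
})

test_that("noise draws occur at the configured binomial rate", {
  pop <- small_pop()
  panel <- small_panel()
  pool <- make_donor_pool(pop, 1L)
  counts <- vapply(1:12, function(sd) {
    cfg <- simulation_config("loss", N_T = 200, r = 4, q_percent = 25,
                             seed = 300 + sd)
    inj <- inject_aberration(draw_normal_sample(pop), pool, panel, cfg)
    idx <- attr(inj, "target_idx")
    s <- log2(inj$h_A + inj$h_B)
    gi <- match(inj$genotype[idx], c("AA", "AB", "BB"))
    mu <- panel$s_mean_g[cbind(idx, gi)]
    sdv <- panel$s_sd_g[cbind(idx, gi)]
    mu[is.na(mu)] <- panel$s_mean[idx][is.na(mu)]
    sdv[is.na(sdv) | sdv == 0] <- panel$s_sd[idx][is.na(sdv) | sdv == 0]
    # noise draws are two-copy values within +/-2 SD, far above the r = 4
    # loss bound: count them as violations of the loss truncation
    sum(s[idx] > mu - 4 * sdv)
  }, 0)
  # Binomial(200, 0.25) per replicate: mean 50, SE of the mean over 12
  # replicates ~ 1.7; allow 3 SDs plus rounding slack
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(200 * 0.25 * 0.75 / 12) + 1)
})

test_that("infeasible truncation reports the marker and effect size", {
  pop <- small_pop()
  panel <- small_panel()
  pool <- make_donor_pool(pop, 2L)  # two-copy donors cannot sit 8 SDs low
  cfg <- simulation_config("loss", N_T = 3, r = 8, seed = 5)
  expect_error(inject_aberration(draw_normal_sample(pop), pool, panel, cfg),
               "truncation region empty")
})

test_that("overlap metrics S and C follow the interval arithmetic", {
  a <- data.frame(chromosome = "1", start_bp = 1, end_bp = 100)
  b <- data.frame(chromosome = "1", start_bp = 51, end_bp = 150)
  expect_equal(overlap_metrics(a, a, "S"), 100)
  expect_equal(overlap_metrics(a, a, "C"), 100)
  expect_equal(overlap_metrics(b, a, "S"), 50)   # covers 50 of 100 bench bp
  # test region overlapping 49% of its own length: excluded from C
  t49 <- data.frame(chromosome = "1", start_bp = 52, end_bp = 151)  # 100 bp
  bench <- data.frame(chromosome = "1", start_bp = 1, end_bp = 100)
  expect_equal(overlap_metrics(t49, bench, "C"), 0)     # 49/100 < 0.5
  t50 <- data.frame(chromosome = "1", start_bp = 51, end_bp = 150)
  expect_equal(overlap_metrics(t50, bench, "C"), 100)   # 50/100 >= 0.5
  # empty benchmark: undefined, not zero
  expect_true(is.na(overlap_metrics(a, a[0, ], "S")))
  expect_true(is.na(overlap_metrics(a[0, ], a, "C")))
  # chromosome mismatch contributes nothing
  c2 <- data.frame(chromosome = "2", start_bp = 1, end_bp = 100)
  expect_equal(overlap_metrics(c2, a, "S"), 0)
})

test_that("qPCR delta-delta-Ct estimator", {
  r <- qpcr_copy_number(c(20, 20, 20), c(20, 20, 20), 20, 20)
  expect_equal(r$mean, 1); expect_equal(r$se, 0); expect_equal(r$diploid_mean, 2)
  r2 <- qpcr_copy_number(19, 20, 20, 20)  # ddCt = -1 -> ratio 2
  expect_equal(r2$ratios, 2)
  expect_true(is.na(r2$se))
  # replicate ratios {1.0, 1.2, 0.8}: mean 1.0, se 0.2
  ct <- 20 - log2(c(1.0, 1.2, 0.8))
  r3 <- qpcr_copy_number(ct, c(20, 20, 20), 20, 20)
  expect_equal(r3$mean, 1)
  expect_equal(r3$se, 0.2)
})

test_that("admixture mixing dilutes the copy-number signal linearly", {
  pop <- small_pop()
  panel <- small_panel()
  pool <- make_donor_pool(pop, 1L)
  tumor <- inject_aberration(draw_normal_sample(pop, "tum"), pool, panel,
                             simulation_config("loss", N_T = 101, r = 2,
                                               seed = 8))
  normal <- draw_normal_sample(pop, "nrm")
  idx <- attr(tumor, "target_idx")
  mix <- mix_samples(tumor, normal, 50)
  tot_m <- mix$h_A + mix$h_B
  expect_equal(tot_m, 0.5 * (tumor$h_A + tumor$h_B) +
                 0.5 * (normal$h_A + normal$h_B))
  # mean target intensity: tumor < 50% mix < normal
  s_t <- mean(log2(tumor$h_A + tumor$h_B)[idx])
  s_m <- mean(log2(tot_m)[idx])
  s_n <- mean(log2(normal$h_A + normal$h_B)[idx])
  expect_true(s_t < s_m && s_m < s_n)
})

test_that("simulation study output is reproducible bit-for-bit under a seed", {
  pop <- small_pop()
  panel <- small_panel()
  wcfg <- window_config(v = 5, n_c = 2)
  grid <- data.frame(scenario = "loss", N_T = 31, r = 2, q_percent = 0)
  r1 <- run_simulation_study(pop, panel, grid, n_reps = 10, wcfg = wcfg,
                             seed = 55)
  r2 <- run_simulation_study(pop, panel, grid, n_reps = 10, wcfg = wcfg,
                             seed = 55)
  expect_identical(r1, r2)
  expect_warning(run_simulation_study(pop, panel, grid, n_reps = 5,
                                      wcfg = NULL, seed = 1),
                 "unstable")
})
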