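# Generator contracts: determinism, parameter validation, and the stated
# statistical structure of each synthetic world.

test_that("all generators are byte-identical under a fixed seed", {
  cs <- c(chrX = 5e6, chr1 = 5e6)
  pairs <- list(
    list(gen_ms_scores(30, 5, n_unique = 2, seed = 7),
         gen_ms_scores(30, 5, n_unique = 2, seed = 7)),
    list(gen_padlock_counts(10, seed = 7), gen_padlock_counts(10, seed = 7)),
    list(gen_atac_sites(cs, seed = 7), gen_atac_sites(cs, seed = 7)),
    list(gen_shape_profiles(100, depth = 1000, seed = 7),
         gen_shape_profiles(100, depth = 1000, seed = 7)),
    list(gen_decay_series(seed = 7), gen_decay_series(seed = 7)))
  for (p in pairs) expect_identical(p[[1]], p[[2]])
  # different seeds change the draw
  expect_false(identical(gen_decay_series(seed = 1)$series,
                         gen_decay_series(seed = 2)$series))
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- runif(5)
  set.seed(123); invisible(gen_ms_scores(10, 2, seed = 3)); after <- runif(5)
  expect_identical(before, after)
})

test_that("gen_ms_scores builds the stated tables and rejects bad input", {
  g <- gen_ms_scores(20, 3, n_unique = 5, seed = 1)
  expect_setequal(setdiff(g$flag$protein_id, g$empty$protein_id),
                  g$truth$truth$unique_to_flag)
  expect_length(g$truth$truth$unique_to_flag, 5)
  expect_length(g$truth$truth$binders, 8)
  expect_error(gen_ms_scores(-1, 5), "non-negative")
  expect_error(gen_ms_scores(10, 5, enrichment_factor = 0.5), ">= 1")
  # enrichment 1, no uniques: the two tables are exchangeable, so the
  # expected gain of every protein is 0 (and gains sum to 0 exactly per
  # seed, since both rank sets are permutations of 1..N)
  binder_gains <- vapply(1:40, function(s) {
    g0 <- gen_ms_scores(15, 5, enrichment_factor = 1, seed = s)
    gg <- ranking_gains(g0$flag, g0$empty)
    expect_identical(sum(gg$gain), 0L)
    mean(gg$gain[startsWith(gg$protein_id, "XB")])
  }, 0)
  # binder mean gain: se ~ sd_gain / sqrt(40 * 5) ~ 0.6, use 3 sigma
  expect_lt(abs(mean(binder_gains)), 2)
})

test_that("gen_padlock_counts emits class-structured beta-binomial counts", {
  expect_error(gen_padlock_counts(10, class_fractions = c(1, 1, 1)),
               "simplex")
  # overdispersion 0, biallelic class, high depth: allele fraction near 1/2
  g <- gen_padlock_counts(1, snps_per_gene = 100,
                          class_fractions = c(0, 0, 1),
                          depth_mean = 1000, overdispersion = 0,
                          n_samples = 1, seed = 5)
  frac <- g$counts$count_129 / (g$counts$count_129 + g$counts$count_cast)
  expect_lt(abs(mean(frac) - 0.5), 0.05)
  # class apportionment is deterministic (largest remainder)
  g2 <- gen_padlock_counts(10, class_fractions = c(.7, .15, .15), seed = 1)
  expect_identical(as.vector(table(g2$truth$truth$class)[
    c("silenced", "escapee", "biallelic")]), c(7L, 2L, 1L))
  # silenced truth fractions live in [0.95, 1]
  sil <- g2$truth$truth$p129[g2$truth$truth$class == "silenced"]
  expect_true(all(sil >= 0.95 & sil <= 1))
  # depth 1: nearly everything is zeroed by the detection filter
  g3 <- gen_padlock_counts(5, depth_mean = 1, n_samples = 2, seed = 2)
  f <- filter_undetected(g3$counts)
  expect_gt(mean(f$count_129 + f$count_cast == 0), 0.9)
})

test_that("silenced genes score high on aggregated counts across seeds", {
  hits <- vapply(1:100, function(s) {
    g <- gen_padlock_counts(1, snps_per_gene = 1,
                            class_fractions = c(1, 0, 0),
                            depth_mean = 500, n_samples = 1, seed = s)
    allelotype_score(sum(g$counts$count_129), sum(g$counts$count_cast)) > 0.8
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("gen_atac_sites realises per-bin Poisson compaction structure", {
  expect_error(gen_atac_sites(c(chrX = 0)), "zero-length")
  cs <- c(chrX = 1e7, chr1 = 1e7)
  g <- gen_atac_sites(cs, base_intensity = 2000, seed = 3)
  expect_s3_class(g$sites, "insertion_sites")
  expect_true(all(g$sites$sites$pos >= 0))
  expect_identical(g$truth$truth$total_autosomal_reads,
                   sum(g$sites$sites$chrom != "chrX"))
  # null factors: per-bin counts within 1 +/- 3 CV of the Poisson mean
  b <- bin_cut_counts(g$sites, cs, distinct = FALSE)
  lam <- 2000
  expect_true(all(abs(b$cut_count / lam - 1) <= 3 / sqrt(lam)))
  # doubling library_scale doubles intensity but normalisation cancels it
  g2 <- gen_atac_sites(cs, base_intensity = 2000, library_scale = 2,
                       seed = 3)
  b1 <- bin_cut_counts(g$sites, cs, reference_total =
                         g$sites$total_autosomal_reads, distinct = FALSE)
  b2 <- bin_cut_counts(g2$sites, cs, reference_total =
                         g$sites$total_autosomal_reads, distinct = FALSE)
  sc <- compaction_score(b1, b2)$compaction_score
  expect_true(all(abs(sc - 1) < 3 * sqrt(2 / lam) + 0.02))
})

test_that("gen_shape_profiles draws binomial events over the truth profile", {
  expect_error(gen_shape_profiles(100, true_reactivity = 0.9,
                                  background_rate = 0.2), "rates")
  # null reactivity: mean treated rate within 3 sigma of the background
  g <- gen_shape_profiles(2000, true_reactivity = 0, background_rate = 2e-4,
                          depth = 10000, samples = c(t = "treated"),
                          seed = 11)
  rate <- mean(g$profiles$t$events) / 10000
  se <- sqrt(2e-4 / (10000 * 2000))
  expect_lt(abs(rate - 2e-4), 3 * se)
  # low-depth positions are excluded from the profiled set
  gd <- gen_shape_profiles(100, depth = rep(c(5000, 20000), 50),
                           samples = c(t = "treated"), seed = 2)
  prof <- profiled_positions(gd$profiles, min_reads = 10000)
  expect_setequal(prof, seq(2, 100, by = 2))
})

test_that("gen_decay_series encodes the stated decay truth", {
  expect_error(gen_decay_series(k = -1), ">= 0")
  g <- gen_decay_series(k = log(2), noise_cv = 0, lag_hours = 0,
                        timepoints = 0:4, seed = 1)
  expect_equal(fit_decay(g$series)$half_life, 1, tolerance = 1e-12)
  expect_equal(g$truth$truth$half_life, 1)
  # lognormal noise has mean one: large-sample mean near the clean level
  g2 <- gen_decay_series(k = 0, noise_cv = 0.2,
                         timepoints = seq(0, 99), seed = 9)
  expect_lt(abs(mean(g2$series$level) - 1), 3 * 0.2 / sqrt(100))
})
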