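# Mutation counting, one-control reactivity, depth filters, PCA.

test_that("count_mutations counts depth and events with primer trimming", {
  # one clean 100M read on a 200-nt transcript: depth 1 on the untrimmed
  # interior, zero events
  r <- data.frame(pos = 1L, cigar = "100M", md = "100")
  p <- count_mutations(r, 200, min_depth = 1)
  expect_identical(p$depth[31:70], rep(1L, 40))
  expect_identical(p$depth[c(1:30, 71:200)], rep(0L, 160))
  expect_identical(sum(p$events), 0L)
  # a mismatch inside the trimmed 30-nt end is not counted
  r2 <- data.frame(pos = 1L, cigar = "100M", md = "9A90")   # mismatch @10
  expect_identical(sum(count_mutations(r2, 200, min_depth = 1)$events), 0L)
  r3 <- data.frame(pos = 1L, cigar = "100M", md = "49A50")  # mismatch @50
  p3 <- count_mutations(r3, 200, min_depth = 1)
  expect_identical(p3$events[50], 1L)
  # 5'-only trimming keeps the 3' end
  p4 <- count_mutations(data.frame(pos = 1L, cigar = "100M", md = "99A0"),
                        200, trim_both_ends = FALSE, min_depth = 1)
  expect_identical(p4$events[100], 1L)
  expect_identical(p4$depth[100], 1L)
})

test_that("indels count as single events at reference positions", {
  # deletion of 2 ref bases at 51-52, insertion after position 60
  r <- data.frame(pos = 1L, cigar = c("50M2D50M", "60M3I40M"),
                  md = c("50^AA50", "100"))
  p <- count_mutations(r, 200, min_depth = 1)
  expect_identical(p$events[51], 1L)
  expect_identical(p$events[52], 1L)
  expect_identical(p$events[60], 1L)
  # deletion spans contribute to depth (footprint); both reads cover 51
  expect_identical(p$depth[51], 2L)
  # one event per position per read even when mismatch+indel coincide
  r2 <- data.frame(pos = 1L, cigar = "50M1D50M", md = "49A0^A50")
  p2 <- count_mutations(r2, 200, min_depth = 1)
  expect_identical(max(p2$events), 1L)
})

test_that("malformed records are skipped with a warning", {
  r <- data.frame(pos = c(1L, 1L), cigar = c("100M", "BADCIGAR"),
                  md = c("100", NA))
  expect_warning(p <- count_mutations(r, 200, min_depth = 1), "malformed")
  expect_identical(max(p$depth), 1L)
})

test_that("the counting path reproduces generator-drawn binomial counts", {
  g <- gen_shape_profiles(seq_length = 150, true_reactivity = 0.03,
                          background_rate = 0.002, depth = 400,
                          samples = c(tr = "treated", ct = "control"),
                          as_reads = TRUE, seed = 21)
  for (nm in names(g$profiles)) {
    p <- count_mutations(g$reads[[nm]], 150, min_depth = 1)
    expect_identical(p$events, g$profiles[[nm]]$events)
    expect_identical(p$depth, g$profiles[[nm]]$depth)
  }
  # and identically via a round-trip through a SAM file on disk
  sam <- tempfile(fileext = ".sam")
  write_sam(g$reads$tr, sam, ref_length = 150)
  p <- count_mutations(sam, 150, min_depth = 1)
  expect_identical(p$events, g$profiles$tr$events)
})

test_that("reactivity is the positionwise rate difference", {
  tr <- shape_profile(depth = rep(20000, 5), events = c(40, 10, 0, 44, 20),
                      min_depth = 1)
  ct <- shape_profile(depth = rep(20000, 5), events = c(10, 10, 0, 4, 20),
                      min_depth = 1)
  r <- reactivity(tr, ct)
  expect_equal(r$reactivity, c(30, 0, 0, 40, 0) / 20000)
  expect_true(all(r$defined))
  expect_equal(reactivity(tr, tr)$reactivity, rep(0, 5))
  expect_error(reactivity(tr, shape_profile(1, 0, min_depth = 1)),
               "coordinate frame")
  # low-depth rates propagate as NA
  low <- shape_profile(depth = c(rep(20000, 4), 10), events = rep(0, 5))
  expect_true(is.na(reactivity(tr, low)$reactivity[5]))
})

test_that("profiled_positions applies a strict cross-sample depth filter", {
  a <- shape_profile(depth = c(10000, 10001, 20000), events = c(0, 0, 0),
                     min_depth = 1)
  b <- shape_profile(depth = c(20000, 10001, 9000), events = c(0, 0, 0),
                     min_depth = 1)
  expect_identical(profiled_positions(list(a, b)), 2L)   # strict >
  expect_identical(profiled_positions(list(a)), 2:3)
  # adding a sample never grows the set
  expect_true(all(profiled_positions(list(a, b)) %in%
                    profiled_positions(list(a))))
  # monotone in min_reads
  expect_length(profiled_positions(list(a), min_reads = 500), 3)
})

test_that("positive_calls uses a strict rate threshold", {
  p <- shape_profile(depth = rep(100000, 4),
                     events = c(100, 200, 0, 99), min_depth = 1)
  expect_identical(positive_calls(p, 0.001), 2L)  # rate exactly 0.001 is out
  expect_identical(positive_calls(shape_profile(rep(1000, 3), rep(0, 3),
                                                min_depth = 1)),
                   integer(0))
})

test_that("pca_profiles matches an eigen-decomposition oracle", {
  set.seed(31)
  x <- matrix(rnorm(6 * 40), 6, 40,
              dimnames = list(paste0("s", 1:6), 1:40))
  got <- pca_profiles(x)
  want <- oracle_pca_scores(x)
  for (k in 1:5) {
    expect_equal(abs(got$scores[, k]), abs(want$scores[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_equal(got$explained_variance,
               want$values[1:6] / sum(want$values[1:6]), tolerance = 1e-8)
  expect_true(all(diff(got$explained_variance) <= 1e-12))
  # deterministic sign convention: largest-magnitude loading positive
  for (k in 1:5) {
    expect_gte(got$loadings[which.max(abs(got$loadings[, k])), k], 0)
  }
})

test_that("identical profiles give zero variance and equal scores", {
  r <- data.frame(position = 1:10, reactivity = rep(0.001, 10),
                  defined = TRUE)
  p <- pca_profiles(list(a = r, b = r))
  expect_equal(unname(p$scores[1, ]), unname(p$scores[2, ]))
  expect_equal(p$explained_variance[1], 0)
  expect_error(pca_profiles(list(a = r)), "2 samples")
})

test_that("PC1 separates wild-type from perturbed replicate pairs", {
  set.seed(17)
  hits <- 0L
  for (s in 1:25) {
    wt <- gen_shape_profiles(400, true_reactivity = rep(c(0.004, 0), 200),
                             depth = 30000, samples = c(w1 = "treated",
                                                        w2 = "treated",
                                                        ct = "control"),
                             seed = s)
    mu <- gen_shape_profiles(400, true_reactivity = rep(c(0, 0.004), 200),
                             depth = 30000, samples = c(m1 = "treated",
                                                        m2 = "treated",
                                                        ct = "control"),
                             seed = s + 1000)
    reac <- c(
      lapply(wt$profiles[c("w1", "w2")], reactivity,
             control = wt$profiles$ct),
      lapply(mu$profiles[c("m1", "m2")], reactivity,
             control = mu$profiles$ct))
    p <- pca_profiles(reac, restrict_to = 1:400)
    pc1 <- p$scores[, 1]
    if (max(pc1[1:2]) < min(pc1[3:4]) || min(pc1[1:2]) > max(pc1[3:4])) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 25, 0.95)
})
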