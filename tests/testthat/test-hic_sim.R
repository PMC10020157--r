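# The generative contact model and the fragment-level sampler.

test_that("expected matrix is a pure power law without TAD or loop structure", {
  loc <- small_locus()
  params <- contact_params(alpha = 1.2, tad_boost = 1, leakiness = 1,
                           loop_strength = 0, n_pairs = 1e4)
  E <- expected_matrix(loc, params, bin_size = 10000)
  # ratios follow (distance + 1)^-alpha in base pairs
  d <- function(i, j) abs(i - j) * 10000
  expect_equal(E[1, 5] / E[3, 11],
               ((d(3, 11) + 1) / (d(1, 5) + 1))^1.2, tolerance = 1e-12)
  expect_equal(E[2, 2] / E[2, 10],
               (d(2, 10) + 1)^1.2, tolerance = 1e-12)
  expect_equal(sum(E), 1e4)
})

test_that("expected matrix is exactly symmetric for arbitrary parameters", {
  loc <- small_locus()
  params <- contact_params(alpha = 0.8, tad_boost = 4, leakiness = 0.2,
                           loop_strength = 2, loop_width = 5000,
                           n_pairs = 5e4)
  E <- expected_matrix(loc, params, bin_size = 5000)
  expect_identical(E, t(E))
})

test_that("boundary crossing attenuates contacts by the leakiness factor", {
  loc <- small_locus()
  params <- contact_params(alpha = 1, tad_boost = 3, leakiness = 0.5,
                           loop_strength = 0, n_pairs = 1e4)
  bs <- 5000
  E <- expected_matrix(loc, params, bin_size = bs)
  # classify bins by TAD membership independently of the implementation
  mids <- 0 + (seq_len(nrow(E)) - 1) * bs + bs / 2
  tad <- findInterval(mids, c(60000, 140000))
  n <- nrow(E)
  for (dd in c(4, 10, 16)) {
    i <- seq_len(n - dd)
    j <- i + dd
    same <- tad[i] == tad[j]
    cross1 <- abs(tad[i] - tad[j]) == 1
    if (any(same) && any(cross1)) {
      ratio <- mean(E[cbind(i[same], j[same])]) /
        mean(E[cbind(i[cross1], j[cross1])])
      expect_equal(ratio, 2, tolerance = 1e-12)   # 1 / leakiness
    }
  }
})

test_that("a degenerate weight matrix yields only that fragment pair", {
  rm <- make_rm(c(250, 500, 750), 0, 1000)
  W <- matrix(0, 4, 4)
  W[2, 4] <- 1
  params <- contact_params(n_pairs = 500, p_highq = 1)
  cp <- sample_pairs(W, rm, params, seed = 7)
  expect_true(all(cp$pairs$frag1 == 2 & cp$pairs$frag2 == 4))
  expect_true(all(cp$pairs$end1_pos >= 250 & cp$pairs$end1_pos < 500))
  expect_true(all(cp$pairs$end2_pos >= 750 & cp$pairs$end2_pos < 1000))
  # p_highq = 1: the MAPQ filter removes nothing
  expect_true(all(pmin(cp$pairs$mapq1, cp$pairs$mapq2) >= 30))
  expect_error(sample_pairs(matrix(0, 4, 4), rm, params, seed = 1),
               "zero total weight")
})

test_that("sampled pair frequencies match the multinomial expectation", {
  rm <- make_rm(c(250, 500, 750), 0, 1000)
  W <- matrix(1, 4, 4)                  # uniform over 10 unordered pairs
  n <- 40000
  cp <- sample_pairs(W, rm, contact_params(n_pairs = n), seed = 11)
  key <- paste(cp$pairs$frag1, cp$pairs$frag2)
  obs <- table(factor(key, levels = c("1 1", "1 2", "1 3", "1 4", "2 2",
                                      "2 3", "2 4", "3 3", "3 4", "4 4")))
  p <- 1 / 10
  sigma <- sqrt(n * p * (1 - p))
  expect_true(all(abs(as.numeric(obs) - n * p) < 5 * sigma))
})

test_that("identical parameters and seed reproduce the pair set exactly", {
  loc <- small_locus()
  params <- contact_params(n_pairs = 5000, seed = 3L)
  a <- simulate_contacts(loc, "dup", params, seed = 3L)
  b <- simulate_contacts(loc, "dup", params, seed = 3L)
  expect_identical(a$pairs$pairs, b$pairs$pairs)
  c <- simulate_contacts(loc, "dup", params, seed = 4L)
  expect_false(identical(a$pairs$pairs, c$pairs$pairs))
})

test_that("projection through the identity map is the identity", {
  loc <- small_locus()
  sim <- simulate_contacts(loc, "wildtype", contact_params(n_pairs = 2000),
                           seed = 5L, keep_rearranged = TRUE)
  raw <- sim$rearranged$pairs
  proj <- project_pairs(sim$segment_map, raw, loc$rm, loc$region)
  expect_equal(proj$pairs$end1_pos, raw$pairs$end1_pos)
  expect_equal(proj$pairs$end2_pos, raw$pairs$end2_pos)
  expect_equal(sim$n_dropped, 0)
})

test_that("duplication projection doubles relative end coverage in the span", {
  loc <- small_locus()
  n <- 1e5
  wt <- simulate_contacts(loc, "wildtype", contact_params(n_pairs = n),
                          seed = 21L)
  du <- simulate_contacts(loc, "dup", contact_params(n_pairs = n),
                          seed = 22L)
  span <- gi("chrS", 50000, 120000)
  frac <- function(sim) {
    pos <- c(sim$pairs$pairs$end1_pos, sim$pairs$pairs$end2_pos)
    mean(pos >= span$start & pos < span$end)
  }
  fw <- frac(wt); fd <- frac(du)
  # odds double because every base in the span is present in two copies
  ratio <- (fd / (1 - fd)) / (fw / (1 - fw))
  cn <- copy_number(du$segment_map)
  expected <- mean(cn[(span$start + 1):span$end]) /
    mean(cn[-((span$start + 1):span$end)])
  expect_equal(expected, 2)
  expect_lt(abs(ratio - expected), 0.2)
})

test_that("knock-in payload drops match the expected contact mass", {
  loc <- small_locus()
  n <- 1e5
  params <- contact_params(n_pairs = n, loop_strength = 0)
  sim <- simulate_contacts(loc, "ki", params, seed = 31L,
                           keep_rearranged = TRUE)
  rm_re <- sim$rearranged$rm
  fr <- rm_re$fragments
  mids <- (fr$start + fr$end) / 2
  # independent dense weight matrix from the documented model formula
  bnd_re <- chicsv:::map_from_reference_points(
    sim$segment_map, loc$boundaries - loc$region$start)$re
  D <- abs(outer(mids, mids, "-"))
  k <- abs(outer(findInterval(mids, sort(bnd_re)),
                 findInterval(mids, sort(bnd_re)), "-"))
  W <- (D + 1)^(-1) * 3 * 0.3^k
  W[lower.tri(W, diag = TRUE)] <- 0
  # payload occupies [40000, 43000) on the rearranged genome
  pay_frac <- chicsv:::overlap_len(fr$start, fr$end, 40000, 43000) /
    (fr$end - fr$start)
  Wn <- W / sum(W)
  # P(at least one end in payload); ends are uniform within fragments
  keep_prob <- sum(Wn * outer(1 - pay_frac, 1 - pay_frac))
  exp_drop <- 1 - keep_prob
  obs_drop <- sim$n_dropped / n
  expect_lt(abs(obs_drop - exp_drop),
            5 * sqrt(exp_drop * (1 - exp_drop) / n))
})

test_that("pairs round-trip through the tab-separated text format", {
  loc <- small_locus()
  sim <- simulate_contacts(loc, "wildtype", contact_params(n_pairs = 1000),
                           seed = 9L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(sim$pairs, path)
  back <- read_pairs(path)
  expect_equal(back$pairs, sim$pairs$pairs)
  expect_equal(back$genome, "reference")
  expect_equal(back$seed, 9L)
})
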