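# Virtual 4C: count -> bin -> smooth -> scale -> integrate.

v4c_rm <- function() make_rm(c(500, 2000, 3000, 4500, 6000, 8000), 0, 10000)

test_that("only pairs with exactly one end in the viewpoint are counted", {
  rm <- v4c_rm()
  vp <- gi("chrT", 2000, 3000)          # exactly fragment 3
  df <- data.frame(
    end1_pos = c(2500, 2100, 2200, 100, 2300, 2400),
    end2_pos = c(2600,  700, 5000, 700, 9000, 5200),
    mapq1 =    c( 60L,  60L,  60L, 60L,  29L,  60L),
    mapq2 =    c( 60L,  60L,  60L, 60L,  60L,  60L))
  fc <- count_by_fragment(make_pairs(df, rm), vp, rm)
  # pair 1: both ends in vp -> excluded; pair 4: neither end -> excluded;
  # pair 5: low MAPQ -> excluded
  expect_equal(fc$total_qualifying, 3)
  expect_equal(fc$counts, c(0, 1, 0, 0, 2, 0, 0))
  # fragments overlapping the viewpoint carry no counts
  expect_equal(fc$counts[3], 0)
  expect_error(count_by_fragment(make_pairs(df, rm),
                                 gi("chrT", 9000, 11000), rm), "outside")
})

test_that("qualifying totals match an independent per-pair predicate loop", {
  set.seed(23)
  rm <- v4c_rm()
  vp <- gi("chrT", 4500, 6000)
  n <- 1e4
  df <- data.frame(end1_pos = sample(0:9999, n, TRUE),
                   end2_pos = sample(0:9999, n, TRUE),
                   mapq1 = sample(c(10L, 60L), n, TRUE),
                   mapq2 = sample(c(10L, 60L), n, TRUE))
  fc <- count_by_fragment(make_pairs(df, rm), vp, rm)
  oracle <- 0L
  fr <- rm$fragments
  for (r in seq_len(n)) {
    if (min(df$mapq1[r], df$mapq2[r]) < 30) next
    i1 <- df$end1_pos[r] >= 4500 && df$end1_pos[r] < 6000
    i2 <- df$end2_pos[r] >= 4500 && df$end2_pos[r] < 6000
    if (i1 == i2) next
    distal <- if (i1) df$end2_pos[r] else df$end1_pos[r]
    f <- findInterval(distal, fr$start)
    # distal fragment must not overlap the viewpoint
    if (fr$end[f] > 4500 && fr$start[f] < 6000) next
    oracle <- oracle + 1L
  }
  expect_equal(fc$total_qualifying, oracle)
  expect_equal(sum(fc$counts), oracle)
})

test_that("fragment counts spread proportionally onto the grid", {
  rm <- make_rm(c(500, 2000), 0, 3000)
  fc <- structure(list(counts = c(0, 3, 0), viewpoint = gi("chrT", 0, 100),
                       rm = rm, total_qualifying = 3, mapq_min = 30),
                  class = "fragment_profile")
  bp <- bin_profile(fc, grid_size = 1000)
  # fragment [500, 2000), count 3: overlaps 500/1500 and 1000/1500
  expect_equal(bp$values, c(1, 2, 0))

  # single-bin fragment keeps its full count
  fc$counts <- c(5, 0, 0)
  expect_equal(bin_profile(fc, 1000)$values[1], 5)
})

test_that("grid binning matches a per-base spreading oracle and conserves mass", {
  set.seed(24)
  rm <- v4c_rm()
  counts <- sample(0:20, nrow(rm$fragments), TRUE)
  fc <- structure(list(counts = counts, viewpoint = gi("chrT", 0, 10),
                       rm = rm, total_qualifying = sum(counts),
                       mapq_min = 30),
                  class = "fragment_profile")
  bp <- bin_profile(fc, grid_size = 1000)
  expect_equal(sum(bp$values), sum(counts), tolerance = 1e-12)
  # per-base oracle: spread count/len over each base, then bin
  per_base <- numeric(10000)
  fr <- rm$fragments
  for (i in seq_len(nrow(fr))) {
    idx <- (fr$start[i] + 1):fr$end[i]
    per_base[idx] <- counts[i] / (fr$end[i] - fr$start[i])
  }
  oracle <- vapply(seq_len(10), function(k)
    sum(per_base[((k - 1) * 1000 + 1):(k * 1000)]), 0)
  expect_equal(bp$values, oracle, tolerance = 1e-9)
})

test_that("sliding-window smoothing averages with shrinking edges", {
  rm <- v4c_rm()
  mk <- function(values) structure(
    list(region = rm$region, grid_size = 1000, values = values,
         stage = "binned", viewpoint = gi("chrT", 0, 10),
         total_qualifying = sum(values)),
    class = "binned_profile")
  const <- smooth_profile(mk(rep(3, 10)), 5000)
  expect_equal(const$values, rep(3, 10))

  imp <- smooth_profile(mk(c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0)), 5000)
  expect_equal(imp$values, c(0, 0, 0.2, 0.2, 0.2, 0.2, 0.2, 0, 0, 0))

  set.seed(25)
  v <- stats::runif(10)
  sm <- smooth_profile(mk(v), 5000)
  expect_equal(sm$values[5], mean(v[3:7]))
  expect_equal(sm$values[1], mean(v[1:3]))   # shrunk edge window
  expect_equal(sm$values[10], mean(v[8:10]))
  expect_error(smooth_profile(mk(v), 4000), "odd multiple")
  expect_error(smooth_profile(mk(v), 500), "smaller than grid")
})

test_that("scaling fixes the eligible-region sum at the scale total", {
  rm <- make_rm(seq(500, 99500, by = 500), 0, 100000)
  vp <- gi("chrT", 0, 2000)
  set.seed(26)
  bp <- structure(list(region = rm$region, grid_size = 1000,
                       values = stats::runif(100), stage = "smoothed",
                       viewpoint = vp, total_qualifying = 0),
                  class = "binned_profile")
  p <- scale_profile(bp, vp = vp, margin = 5000)
  expect_equal(sum(p$values[p$eligible]), 1000, tolerance = 1e-9)
  # viewpoint bins are scaled, not zeroed
  expect_true(all(p$values[!p$eligible] > 0))

  # already at the target: factor 1
  at <- bp; at$values <- bp$values * (1000 / sum(bp$values[p$eligible]))
  expect_equal(scale_profile(at, vp = vp, margin = 5000)$scale_factor, 1,
               tolerance = 1e-12)

  # uniform closed form: value u over m eligible bins -> factor 1000/(m u)
  uv <- bp; uv$values <- rep(0.5, 100)
  pu <- scale_profile(uv, vp = vp, margin = 5000)
  m_elig <- sum(pu$eligible)
  expect_equal(pu$scale_factor, 1000 / (m_elig * 0.5), tolerance = 1e-12)

  z <- bp; z$values <- rep(0, 100)
  expect_error(scale_profile(z, vp = vp), "no signal")
})

test_that("integrated signal matches a per-base accumulation oracle", {
  rm <- make_rm(seq(500, 9500, by = 500), 0, 10000)
  vp <- gi("chrT", 0, 1000)
  set.seed(27)
  bp <- structure(list(region = rm$region, grid_size = 1000,
                       values = stats::runif(10), stage = "smoothed",
                       viewpoint = vp, total_qualifying = 0),
                  class = "binned_profile")
  p <- scale_profile(bp, vp = vp, margin = 1000)
  # eligible set is [2000, 10000); integrating it returns the full total
  expect_equal(integrate_signal(p, gi("chrT", 2000, 10000)), 1000,
               tolerance = 1e-9)
  expect_equal(integrate_signal(p, gi("chrT", 2000, 2001)) > 0, TRUE)
  # no-signal window
  pz <- p; pz$values[8:10] <- 0
  expect_equal(integrate_signal(pz, gi("chrT", 7000, 10000)), 0)
  # arbitrary window vs base-by-base accumulation
  win <- gi("chrT", 3350, 7725)
  per_base <- rep(p$values / 1000, each = 1000)
  expect_equal(integrate_signal(p, win),
               sum(per_base[(win$start + 1):win$end]), tolerance = 1e-9)
  expect_error(integrate_signal(p, gi("chrT", 5, 4)), "start < end")
})

test_that("replicate merging is the entrywise mean and keeps the invariant", {
  loc <- small_locus()
  vp <- gi("chrS", 30000, 32000)
  profs <- lapply(1:3, function(s) {
    sim <- simulate_contacts(loc, "wildtype",
                             contact_params(n_pairs = 3e4), seed = s)
    virtual4c(sim$pairs, vp, loc$rm)
  })
  same <- merge_replicates(list(profs[[1]], profs[[1]]))
  expect_equal(same$values, profs[[1]]$values)
  two <- merge_replicates(profs[1:2])
  expect_equal(two$values, (profs[[1]]$values + profs[[2]]$values) / 2)
  expect_equal(sum(two$values[two$eligible]), 1000, tolerance = 1e-9)
  other <- profs[[3]]
  other$viewpoint <- gi("chrS", 40000, 42000)
  expect_error(merge_replicates(list(profs[[1]], other)), "mismatch")
})

test_that("adding qualifying pairs never decreases the pre-scaled profile", {
  rm <- v4c_rm()
  vp <- gi("chrT", 2000, 3000)
  set.seed(28)
  n <- 500
  df <- data.frame(end1_pos = sample(2000:2999, n, TRUE),
                   end2_pos = sample(c(0:1999, 3000:9999), n, TRUE))
  base <- smooth_profile(bin_profile(
    count_by_fragment(make_pairs(df, rm), vp, rm), 1000), 5000)
  extra <- rbind(df, data.frame(end1_pos = rep(2500, 50),
                                end2_pos = rep(7000, 50)))
  more <- smooth_profile(bin_profile(
    count_by_fragment(make_pairs(extra, rm), vp, rm), 1000), 5000)
  expect_true(all(more$values >= base$values - 1e-12))
  expect_gt(more$values[8], base$values[8])
})
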