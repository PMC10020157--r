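# Binning, balancing and contact-map I/O.

test_that("bin_pairs counts symmetric qualifying pairs", {
  region <- gi("chrT", 0, 50000)
  one <- make_pairs(data.frame(end1_pos = 16000, end2_pos = 17000,
                               mapq1 = 60L, mapq2 = 60L))
  m <- bin_pairs(one, region, bin_size = 5000, mapq_min = 30)
  expect_equal(m$matrix[4, 4], 1)      # both ends in bin 3 (0-based)
  expect_equal(sum(m$matrix), 1)

  low <- make_pairs(data.frame(end1_pos = 16000, end2_pos = 17000,
                               mapq1 = 29L, mapq2 = 60L))
  expect_equal(sum(bin_pairs(low, region, 5000, 30)$matrix), 0)

  off <- make_pairs(data.frame(end1_pos = 1000, end2_pos = 26000))
  mo <- bin_pairs(off, region, 5000, 30)
  expect_equal(mo$matrix[1, 6], 1)
  expect_equal(mo$matrix[6, 1], 1)
  expect_equal(sum(mo$matrix), 2)
})

test_that("binning a random pair set matches a per-pair counting oracle", {
  set.seed(77)
  region <- gi("chrT", 0, 100000)
  n <- 1e4
  df <- data.frame(end1_pos = sample(0:99999, n, TRUE),
                   end2_pos = sample(0:99999, n, TRUE),
                   mapq1 = sample(c(10L, 60L), n, TRUE, prob = c(0.2, 0.8)),
                   mapq2 = sample(c(10L, 60L), n, TRUE, prob = c(0.2, 0.8)))
  m <- bin_pairs(make_pairs(df), region, bin_size = 10000, mapq_min = 30)
  # naive per-pair loop
  O <- matrix(0, 10, 10)
  for (r in seq_len(n)) {
    if (min(df$mapq1[r], df$mapq2[r]) < 30) next
    i <- df$end1_pos[r] %/% 10000 + 1
    j <- df$end2_pos[r] %/% 10000 + 1
    O[i, j] <- O[i, j] + 1
    if (i != j) O[j, i] <- O[j, i] + 1
  }
  expect_equal(m$matrix, O)
  expect_equal(sum(m$matrix),
               2 * sum(O[upper.tri(O)]) + sum(diag(O)))
})

test_that("balancing equalizes row sums and returns proportional biases", {
  m2 <- make_map(matrix(c(0, 2, 2, 0), 2, 2))
  out <- kr_balance(m2)
  rs <- rowSums(out$map$matrix)
  expect_equal(rs[1], rs[2], tolerance = 1e-9)
  expect_equal(out$bias$bias[1], out$bias$bias[2], tolerance = 1e-9)

  M <- rand_sym(50, seed = 5)
  out2 <- kr_balance(make_map(M), tol = 1e-8)
  v <- out2$map$valid
  rs2 <- rowSums(out2$map$matrix[v, v])
  expect_lt(stats::sd(rs2) / mean(rs2), 1e-8)
  # symmetry preserved
  expect_lt(max(abs(out2$map$matrix - t(out2$map$matrix)), na.rm = TRUE),
            1e-12)
})

test_that("balancing is idempotent up to scale", {
  M <- rand_sym(40, seed = 6)
  once <- kr_balance(make_map(M), tol = 1e-10)
  m1 <- once$map
  m1$norm_state <- "raw"               # re-enter the balancing path
  twice <- kr_balance(m1, tol = 1e-10)
  b <- twice$bias$bias
  expect_lt(stats::sd(b) / mean(b), 1e-8)
})

test_that("LOIC with constant copy number reduces to uniform correction", {
  M <- rand_sym(30, seed = 7)
  kr <- kr_balance(make_map(M), tol = 1e-10)
  lo <- loic_normalize(make_map(M), rep(2, 30), tol = 1e-10)
  v <- lo$map$valid
  rs <- rowSums(lo$map$matrix[v, v])
  expect_lt(stats::sd(rs) / mean(rs), 1e-8)
  # same normalized map up to a global scale
  ratio <- lo$map$matrix[v, v] / kr$map$matrix[v, v]
  expect_lt(diff(range(ratio)), 1e-6 * mean(ratio))
})

test_that("LOIC retains the configured marginal ratio", {
  M <- rand_sym(40, seed = 8)
  cn <- ifelse(seq_len(40) %in% 11:20, 4, 2)
  out <- loic_normalize(make_map(M), cn, tol = 1e-10)
  v <- out$map$valid
  rs <- rowSums(out$map$matrix[v, v])
  ratio <- mean(rs[cn[v] == 4]) / mean(rs[cn[v] == 2])
  expect_equal(ratio, 2, tolerance = 1e-8)
  expect_error(loic_normalize(make_map(M), rep(0, 40)), "positive")
})

test_that("low-coverage masking is monotone in the threshold", {
  set.seed(9)
  M <- rand_sym(30, seed = 9)
  M[3, ] <- M[, 3] <- stats::runif(30, 0, 0.05)
  M[17, ] <- M[, 17] <- stats::runif(30, 0, 0.4)
  M <- (M + t(M)) / 2
  v_small <- kr_balance(make_map(M), min_frac = 0.05)$map$valid
  v_large <- kr_balance(make_map(M), min_frac = 0.3)$map$valid
  # enlarging the mask never unmasks a bin
  expect_true(all(v_large <= v_small))
  expect_gt(sum(v_small) , sum(v_large))
})

test_that("contact maps round-trip through COO and dense TSV", {
  # empty map: header-only file
  m0 <- make_map(matrix(0, 3, 3))
  p0 <- withr::local_tempfile(fileext = ".coo")
  write_contact_map(m0, p0, "coo")
  expect_equal(read_contact_map(p0)$matrix, m0$matrix)

  # single entry -> single triplet line
  M1 <- matrix(0, 3, 3); M1[1, 3] <- M1[3, 1] <- 2
  p1 <- withr::local_tempfile(fileext = ".coo")
  write_contact_map(make_map(M1), p1, "coo")
  body <- grep("^#", readLines(p1), value = TRUE, invert = TRUE)
  expect_length(body, 1)
  expect_equal(read_contact_map(p1)$matrix, M1)

  # random symmetric maps, both formats, raw and normalized
  M <- rand_sym(25, seed = 10)
  m <- make_map(M)
  for (fmt in c("coo", "tsv")) {
    p <- withr::local_tempfile()
    write_contact_map(m, p, fmt)
    expect_lt(max(abs(read_contact_map(p)$matrix - M)), 1e-12)
  }
  norm <- kr_balance(m)$map
  pn <- withr::local_tempfile()
  write_contact_map(norm, pn, "coo")
  back <- read_contact_map(pn)
  expect_equal(back$norm_state, "KR")
  expect_equal(back$valid, norm$valid)
  expect_lt(max(abs(back$matrix - norm$matrix), na.rm = TRUE), 1e-12)

  # malformed line reported with its number
  bad <- withr::local_tempfile()
  writeLines(c(chicsv:::map_header(m0), "# format=coo", "0\t1"), bad)
  expect_error(read_contact_map(bad), "line 9")
})

test_that("decay_exponent recovers the exponent of an exact power law", {
  n <- 100; bs <- 5000
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  M <- (pmax(d, 1) * bs)^(-1.3)
  m <- make_map(M, bin_size = bs)
  expect_equal(decay_exponent(m, min_d = 2, max_d = 50), 1.3,
               tolerance = 1e-9)
})

test_that("marginals and bedGraph export agree with the matrix", {
  M <- rand_sym(10, seed = 11)
  m <- make_map(M, bin_size = 1000)
  expect_equal(contact_marginals(m), rowSums(M))
  p <- withr::local_tempfile(fileext = ".bedgraph")
  export_bedgraph(contact_marginals(m), m$region, m$bin_size, p)
  gr <- rtracklayer::import(p, format = "bedGraph")
  expect_equal(length(gr), 10)
  expect_equal(gr$score, rowSums(M), tolerance = 1e-6)
})
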