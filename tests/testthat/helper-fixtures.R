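# Shared fixtures: a scaled-down locus for fast unit tests, hand-built
# restriction maps, and small random matrices.  Everything is generated
# in code under fixed seeds.

small_locus <- function(seed = 42L) {
  model_locus(
    region = gi("chrS", 0, 200000),
    seed = seed,
    boundaries = c(60000, 140000),
    ctcf = data.frame(pos = c(58000, 62000, 138000, 142000),
                      strand = c("-", "+", "-", "+")),
    genes = data.frame(start = c(30000, 170000), end = c(32000, 172000),
                       name = c("geneA", "geneB")),
    enhancers = data.frame(start = 90000, end = 92000, name = "enhE"),
    viewpoints = list(geneA = c(30000, 32000)),
    windows = list(enh = c(85000, 95000)),
    svs = list(dup = rearrangement("tandem_duplication", c(50000, 120000)),
               inv = rearrangement("inversion", c(70000, 160000)),
               ki = rearrangement("insertion", 40000, payload_length = 3000)))
}

small_config <- function(n_pairs = 2e4) {
  cfg <- default_run_config()
  cfg$region <- "chrS:1-200,000"
  cfg$locus_seed <- 42
  cfg$model$n_pairs <- n_pairs
  cfg$boundaries <- c(60000, 140000)
  cfg$ctcf <- list(pos = c(58000, 62000, 138000, 142000),
                   strand = c("-", "+", "-", "+"))
  cfg$genes <- list(start = c(30000, 170000), end = c(32000, 172000),
                    name = c("geneA", "geneB"))
  cfg$enhancers <- list(start = 90000, end = 92000, name = "enhE")
  cfg$svs <- list(dup = list(kind = "tandem_duplication",
                             breakpoints = c(50000, 120000)),
                  inv = list(kind = "inversion",
                             breakpoints = c(70000, 160000)))
  cfg$viewpoints <- list(geneA = c(30000, 32000))
  cfg$windows <- list(enh = c(85000, 95000))
  cfg
}

# restriction map with explicit cut positions over [start, end)
make_rm <- function(cuts, start = 0, end = 1000, chrom = "chrT") {
  digest(as.numeric(cuts), "GATC", gi(chrom, start, end))
}

# contact_pairs from a plain data frame of columns end1_pos, end2_pos,
# mapq1, mapq2 (fragment indices filled from rm when given)
make_pairs <- function(df, rm = NULL, genome_length = 1e6) {
  if (is.null(df$mapq1)) df$mapq1 <- 60L
  if (is.null(df$mapq2)) df$mapq2 <- 60L
  if (!is.null(rm)) {
    df$frag1 <- frag_index(rm, df$end1_pos)
    df$frag2 <- frag_index(rm, df$end2_pos)
    genome_length <- gi_width(rm$region)
  } else {
    if (is.null(df$frag1)) df$frag1 <- 1L
    if (is.null(df$frag2)) df$frag2 <- 1L
  }
  structure(list(pairs = df[, c("end1_pos", "end2_pos", "frag1", "frag2",
                                "mapq1", "mapq2")],
                 genome = "reference", genome_length = genome_length,
                 seed = NA),
            class = "contact_pairs")
}

# random symmetric positive matrix
rand_sym <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n, 0.5, 2), n, n)
  (A + t(A)) / 2
}

# wrap a matrix as a raw contact map on a unit-offset grid
make_map <- function(M, bin_size = 1000, chrom = "chrT", start = 0) {
  n <- nrow(M)
  chicsv:::new_contact_map(gi(chrom, start, start + n * bin_size),
                           bin_size, M)
}

# per-base reference copy number by brute-force enumeration of every
# rearranged base (the independent oracle for segment-map algebra)
enumerate_copy_number <- function(sm) {
  hit <- map_to_reference(sm, seq_len(sm$rearranged_length) - 1)
  cn <- numeric(sm$ref_length)
  tab <- table(hit$ref[!hit$payload])
  cn[as.numeric(names(tab)) + 1] <- as.numeric(tab)
  cn
}
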