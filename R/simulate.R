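# Fragment-resolution contact sampling and reference projection.

new_contact_pairs <- function(df, genome, genome_length, seed = NA) {
  structure(list(pairs = df, genome = genome,
                 genome_length = as.numeric(genome_length),
                 seed = seed),
            class = "contact_pairs")
}

#' @export
print.contact_pairs <- function(x, ...) {
  cat("<contact pairs> ", nrow(x$pairs), " pairs on genome '", x$genome,
      "' (", format(x$genome_length, big.mark = ","), " bp)\n", sep = "")
  invisible(x)
}

# draw end positions and MAPQ values for sampled fragment index pairs
finish_pairs <- function(f1, f2, rm, params) {
  fr <- rm$fragments
  len1 <- fr$end[f1] - fr$start[f1]
  len2 <- fr$end[f2] - fr$start[f2]
  n <- length(f1)
  p1 <- fr$start[f1] + floor(stats::runif(n) * len1)
  p2 <- fr$start[f2] + floor(stats::runif(n) * len2)
  m1 <- ifelse(stats::runif(n) < params$p_highq, params$mapq_high, params$mapq_low)
  m2 <- ifelse(stats::runif(n) < params$p_highq, params$mapq_high, params$mapq_low)
  data.frame(end1_pos = p1, end2_pos = p2, frag1 = f1, frag2 = f2,
             mapq1 = as.integer(m1), mapq2 = as.integer(m2))
}

#' Sample contact pairs from fragment-level weights
#'
#' Draws `params$n_pairs` fragment pairs with probability proportional to
#' the given weights (upper triangle including the diagonal), then places
#' each end uniformly within its fragment and assigns mapping qualities
#' from the two-point distribution in `params`.  Fully reproducible given
#' the seed.
#'
#' @param weights Dense symmetric (or upper-triangular) nonnegative
#'   matrix of fragment-pair weights, `n_frag x n_frag`.
#' @param rm Restriction map whose fragments index the weights.
#' @param params [contact_params()].
#' @param seed RNG seed (defaults to `params$seed`).
#' @return A `"contact_pairs"` object with columns `end1_pos`,
#'   `end2_pos`, `frag1`, `frag2`, `mapq1`, `mapq2` (positions in the
#'   coordinates of `rm`).
#' @export
sample_pairs <- function(weights, rm, params, seed = params$seed) {
  n <- nrow(rm$fragments)
  stopifnot(is.matrix(weights), nrow(weights) == n, ncol(weights) == n)
  if (any(weights < 0)) stop("weights must be nonnegative")
  ut <- upper.tri(weights, diag = TRUE)
  w <- weights[ut]
  if (sum(w) <= 0) stop("zero total weight")
  idx_map <- which(ut)
  if (is.null(seed)) stop("seed must be set for sampling")
  with_seed(seed, {
    draw <- sample.int(length(w), params$n_pairs, replace = TRUE, prob = w)
    ij <- arrayInd(idx_map[draw], c(n, n))
    new_contact_pairs(finish_pairs(ij[, 1], ij[, 2], rm, params),
                      genome = "reference", genome_length = gi_width(rm$region),
                      seed = seed)
  })
}

# Block-wise sampler over strictly upper-triangular fragment weights
# (self-fragment pairs excluded) defined by midpoints + model parameters.
# Avoids materializing the full n_frag^2 weight matrix: the exact
# multinomial over all fragment pairs is decomposed into a chain of
# binomials across row blocks.  RNG state must be set by the caller.
sample_pairs_blocked <- function(rm, boundaries, loops, params,
                                 block = 512L) {
  fr <- rm$fragments
  mids <- (fr$start + fr$end) / 2
  n <- length(mids)
  i0s <- seq(1L, n, by = block)
  block_w <- function(i0) {
    i1 <- min(i0 + block - 1L, n)
    rows <- i0:i1
    w <- pair_weights(mids[rows], mids[i0:n], boundaries, loops,
                      params$alpha, params$tad_boost, params$leakiness)
    # keep strictly upper triangle: within the block, absolute column
    # index i0 + c - 1 must exceed absolute row index i0 + r - 1
    for (r in seq_along(rows)) w[r, seq_len(r)] <- 0
    list(w = w, rows = rows, cols = i0:n)
  }
  blocks <- lapply(i0s, block_w)
  totals <- vapply(blocks, function(b) sum(b$w), 0)
  if (sum(totals) <= 0) stop("zero total weight")
  n_rem <- params$n_pairs
  w_rem <- sum(totals)
  f1 <- f2 <- vector("list", length(i0s))
  for (b in seq_along(i0s)) {
    nb <- if (b == length(i0s)) n_rem
          else stats::rbinom(1L, n_rem, min(1, totals[b] / w_rem))
    n_rem <- n_rem - nb
    w_rem <- w_rem - totals[b]
    if (nb > 0) {
      bw <- blocks[[b]]
      draw <- sample.int(length(bw$w), nb, replace = TRUE, prob = as.vector(bw$w))
      ij <- arrayInd(draw, dim(bw$w))
      f1[[b]] <- bw$rows[ij[, 1]]
      f2[[b]] <- bw$cols[ij[, 2]]
    }
    blocks[b] <- list(NULL)
  }
  finish_pairs(unlist(f1), unlist(f2), rm, params)
}

#' Simulate a capture Hi-C contact-pair set for a locus genotype
#'
#' Builds the rearranged genome for the named structural variant
#' (`"wildtype"` for the identity map), digests its sequence, carries the
#' annotation (boundary positions, CTCF sites with orientation) through
#' the segment map so that TAD membership and loop convergence are
#' recomputed on the rearranged allele, samples fragment pairs from the
#' contact model, and projects them back to reference coordinates
#' (dropping pairs with an end in non-reference payload sequence).
#'
#' @param locus A [model_locus()].
#' @param sv SV name in `locus$svs`, or `"wildtype"`.
#' @param params [contact_params()].
#' @param seed RNG seed for sampling.
#' @param keep_rearranged Also return the unprojected rearranged-genome
#'   pairs.
#' @return List with `pairs` (reference-projected `contact_pairs`,
#'   absolute coordinates), `segment_map`, `n_dropped` (payload-end
#'   pairs removed at projection), `sv`, `params`, `seed`, and optionally
#'   `rearranged` (local-coordinate pairs + restriction map).
#' @export
simulate_contacts <- function(locus, sv = "wildtype", params = contact_params(),
                              seed = params$seed, keep_rearranged = FALSE) {
  if (is.null(seed)) stop("seed must be set")
  region <- locus$region
  L <- gi_width(region)
  sm <- locus_segment_map(locus, sv)
  identity <- identical(sv, "wildtype")
  if (identity) {
    rm_re <- digest(locus$rm$cut_positions - region$start, locus$motif,
                    gi(region$chrom, 0, L))
  } else {
    seq_re <- rearranged_sequence(locus$seq, sm,
                                  payload_seed = locus$seed + 7919L)
    rm_re <- digest(seq_re, locus$motif,
                    gi(region$chrom, 0, sm$rearranged_length))
  }
  # annotation on the rearranged genome (local coordinates)
  bnd <- map_from_reference_points(sm, locus$boundaries - region$start)
  ctcf_re <- map_from_reference_points(sm, locus$ctcf$pos - region$start,
                                       locus$ctcf$strand)
  loops <- locus_loops(data.frame(pos = ctcf_re$re, strand = ctcf_re$strand),
                       params)
  raw <- with_seed(seed,
    sample_pairs_blocked(rm_re, sort(bnd$re), loops, params))
  re_pairs <- new_contact_pairs(raw, genome = if (identity) "reference"
                                else paste0("rearranged:", sv),
                                genome_length = sm$rearranged_length,
                                seed = seed)
  proj <- project_pairs(sm, re_pairs, locus$rm, region)
  out <- list(pairs = proj, segment_map = sm,
              n_dropped = nrow(re_pairs$pairs) - nrow(proj$pairs),
              sv = sv, params = params, seed = seed)
  if (keep_rearranged) out$rearranged <- list(pairs = re_pairs, rm = rm_re)
  out
}

#' Project rearranged-genome pairs onto the reference
#'
#' Maps both ends of every pair through [map_to_reference()], drops pairs
#' with an end in payload (non-reference) sequence, converts to absolute
#' reference coordinates and re-assigns restriction-fragment indices
#' under the reference restriction map.  Both copies of a duplicated
#' segment project to the same reference interval (reference-only
#' mapping, no allele tagging).
#'
#' @param sm Segment map (local coordinates over the region width).
#' @param pairs `contact_pairs` on the rearranged genome of `sm` (local
#'   coordinates).
#' @param rm Reference restriction map (absolute coordinates).
#' @param region Reference capture region.
#' @return Reference `contact_pairs` with absolute coordinates.
#' @export
project_pairs <- function(sm, pairs, rm, region) {
  if (pairs$genome_length != sm$rearranged_length)
    stop("genome mismatch: pairs were not generated on this segment map")
  p <- pairs$pairs
  m1 <- map_to_reference(sm, p$end1_pos)
  m2 <- map_to_reference(sm, p$end2_pos)
  keep <- !m1$payload & !m2$payload
  r1 <- m1$ref[keep] + region$start
  r2 <- m2$ref[keep] + region$start
  df <- data.frame(end1_pos = r1, end2_pos = r2,
                   frag1 = frag_index(rm, r1), frag2 = frag_index(rm, r2),
                   mapq1 = p$mapq1[keep], mapq2 = p$mapq2[keep])
  new_contact_pairs(df, genome = "reference",
                    genome_length = gi_width(region), seed = pairs$seed)
}

#' Write / read contact pairs as tab-separated text
#'
#' One pair per line (`end1_pos`, `end2_pos`, `frag1`, `frag2`, `mapq1`,
#' `mapq2`) preceded by `#` header lines recording the genome tag, genome
#' length and seed.
#'
#' @param pairs A `contact_pairs` object.
#' @param path Output file.
#' @return `write_pairs` returns `path` invisibly; `read_pairs` returns a
#'   `contact_pairs` object.
#' @export
write_pairs <- function(pairs, path) {
  hdr <- c("# chicsv contact pairs",
           paste0("# genome=", pairs$genome),
           sprintf("# genome_length=%.0f", pairs$genome_length),
           paste0("# seed=", pairs$seed))
  writeLines(hdr, path)
  data.table::fwrite(pairs$pairs, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    m <- sub(paste0("^# ?", key, "="), "", hdr[grepl(paste0("^# ?", key, "="), hdr)])
    if (length(m)) m[1] else NA
  }
  df <- as.data.frame(data.table::fread(path, skip = length(hdr), sep = "\t",
                                        header = TRUE))
  need <- c("end1_pos", "end2_pos", "frag1", "frag2", "mapq1", "mapq2")
  if (!all(need %in% names(df)))
    stop("malformed pairs file (missing columns): ", path)
  new_contact_pairs(df[, need],
                    genome = get("genome"),
                    genome_length = as.numeric(get("genome_length")),
                    seed = suppressWarnings(as.integer(get("seed"))))
}
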