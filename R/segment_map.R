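# Segment maps: the coordinate algebra behind structural-variant
# simulation.  A rearranged genome is an ordered list of oriented
# reference segments (plus optional non-reference "payload" segments for
# knock-ins); every rearranged base maps back to at most one reference
# base, which is exactly what a reference-only read mapper sees.

#' Describe a structural rearrangement
#'
#' @param kind One of `"tandem_duplication"`, `"inversion"`, `"deletion"`,
#'   `"insertion"`.
#' @param breakpoints Sorted 0-based positions: two for duplication /
#'   inversion / deletion, one for insertion.
#' @param payload_length Length of inserted non-reference sequence
#'   (insertions only, > 0).
#' @return A `"rearrangement"` spec used by [build_segment_map()].
#' @export
rearrangement <- function(kind = c("tandem_duplication", "inversion",
                                   "deletion", "insertion"),
                          breakpoints, payload_length = NULL) {
  kind <- match.arg(kind)
  breakpoints <- as.numeric(breakpoints)
  if (any(is.na(breakpoints)) || any(breakpoints < 0))
    stop("breakpoints must be nonnegative numbers")
  if (kind == "insertion") {
    if (length(breakpoints) != 1L) stop("insertion takes one breakpoint")
    if (is.null(payload_length) || payload_length <= 0)
      stop("insertion requires payload_length > 0")
  } else {
    if (length(breakpoints) != 2L) stop(kind, " takes two breakpoints")
    if (breakpoints[1] >= breakpoints[2])
      stop("zero-length rearrangement: breakpoints must satisfy b1 < b2")
    if (!is.null(payload_length)) stop("payload_length only valid for insertions")
  }
  structure(list(kind = kind, breakpoints = breakpoints,
                 payload_length = if (is.null(payload_length)) 0 else as.numeric(payload_length)),
            class = "rearrangement")
}

new_segment_map <- function(segments, ref_length) {
  segments$length <- ifelse(segments$payload, segments$length,
                            segments$ref_end - segments$ref_start)
  segments <- segments[segments$length > 0, , drop = FALSE]
  if (nrow(segments) == 0L) stop("segment map would be empty")
  rownames(segments) <- NULL
  structure(list(segments = segments,
                 rearranged_length = sum(segments$length),
                 ref_length = as.numeric(ref_length)),
            class = "segment_map")
}

seg_row <- function(s, e, strand = "+") {
  data.frame(ref_start = s, ref_end = e, strand = strand,
              payload = FALSE, length = e - s)
}

payload_row <- function(len) {
  data.frame(ref_start = NA_real_, ref_end = NA_real_, strand = "+",
              payload = TRUE, length = len)
}

#' Build a segment map for a rearranged genome
#'
#' Encodes the linear architecture of the rearranged allele as ordered,
#' oriented reference segments: a direct (head-to-tail) tandem
#' duplication of `[b1,b2)` is `[0,b2)+` followed by `[b1,L)+`; an
#' inversion is `[0,b1)+`, `[b1,b2)-`, `[b2,L)+`; an insertion places a
#' non-reference payload segment at the breakpoint.
#'
#' @param reference_length Length of the reference genome (bases).
#' @param spec A [rearrangement()].
#' @return A `"segment_map"`: `segments` data.frame (`ref_start`,
#'   `ref_end`, `strand`, `payload`, `length`) plus `rearranged_length`
#'   and `ref_length`.
#' @export
build_segment_map <- function(reference_length, spec) {
  L <- as.numeric(reference_length)
  stopifnot(inherits(spec, "rearrangement"), L > 0)
  b <- spec$breakpoints
  if (any(b > L)) stop("breakpoint outside [0, reference_length]")
  segs <- switch(spec$kind,
    tandem_duplication = rbind(seg_row(0, b[2]), seg_row(b[1], L)),
    inversion = rbind(seg_row(0, b[1]), seg_row(b[1], b[2], "-"), seg_row(b[2], L)),
    deletion = rbind(seg_row(0, b[1]), seg_row(b[2], L)),
    insertion = rbind(seg_row(0, b[1]), payload_row(spec$payload_length),
                      seg_row(b[1], L)))
  sm <- new_segment_map(segs, L)
  if (spec$kind == "deletion" && all(sm$segments$payload))
    stop("deletion removes the entire reference")
  sm
}

#' @rdname build_segment_map
#' @export
identity_segment_map <- function(reference_length) {
  new_segment_map(seg_row(0, reference_length), reference_length)
}

#' @export
print.segment_map <- function(x, ...) {
  cat("<segment map> ", nrow(x$segments), " segments, reference ",
      format(x$ref_length, big.mark = ","), " bp -> rearranged ",
      format(x$rearranged_length, big.mark = ","), " bp\n", sep = "")
  print(x$segments)
  invisible(x)
}

seg_cumstarts <- function(sm) cumsum(c(0, sm$segments$length))

#' Map rearranged-genome positions back to the reference
#'
#' Forward segments map by offset; reverse segments mirror
#' (`ref_end - 1 - offset`); positions falling in payload (non-reference)
#' segments are flagged unmappable, mirroring what a reference-only
#' mapper does with novel sequence.
#'
#' @param sm A [build_segment_map()] segment map.
#' @param pos Rearranged-genome positions, `0 <= pos < rearranged_length`.
#' @return data.frame with `pos`, `ref` (reference position, `NA` for
#'   payload), `strand` (`"+"` forward, `"-"` through a reversed
#'   segment) and logical `payload`.
#' @export
map_to_reference <- function(sm, pos) {
  pos <- as.numeric(pos)
  if (any(pos < 0 | pos >= sm$rearranged_length))
    stop("position outside rearranged genome")
  cs <- seg_cumstarts(sm)
  k <- findInterval(pos, cs, rightmost.closed = FALSE)
  offs <- pos - cs[k]
  seg <- sm$segments
  fwd <- seg$strand[k] == "+"
  ref <- ifelse(seg$payload[k], NA_real_,
                ifelse(fwd, seg$ref_start[k] + offs, seg$ref_end[k] - 1 - offs))
  data.frame(pos = pos, ref = ref,
             strand = ifelse(fwd, "+", "-"),
             payload = seg$payload[k])
}

#' Per-base reference copy number of a segment map
#'
#' @param sm Segment map.
#' @return Numeric vector of length `ref_length`: how many rearranged
#'   bases map to each reference base.
#' @export
copy_number <- function(sm) {
  L <- sm$ref_length
  d <- numeric(L + 1)
  seg <- sm$segments[!sm$segments$payload, , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    d[seg$ref_start[i] + 1] <- d[seg$ref_start[i] + 1] + 1
    d[seg$ref_end[i] + 1] <- d[seg$ref_end[i] + 1] - 1
  }
  cumsum(d)[seq_len(L)]
}

#' Per-bin copy-number track
#'
#' Converts segment-map copy number into the per-bin track used by LOIC
#' normalization: a bin overlapping any region of elevated (or reduced)
#' copy takes the maximum per-base copy number it touches, scaled by the
#' diploid baseline, reproducing the "4 for bins overlapping the
#' duplication, 2 otherwise" assignment for a heterozygous-free diploid
#' duplication.
#'
#' @param sm Segment map (coordinates local to the region).
#' @param n_bins Number of bins.
#' @param bin_size Bin width in bases.
#' @param base_cn Baseline copies per reference base (default diploid, 2).
#' @return Numeric vector of per-bin copy numbers.
#' @export
copy_number_bins <- function(sm, n_bins, bin_size, base_cn = 2) {
  cn <- copy_number(sm)
  L <- sm$ref_length
  vapply(seq_len(n_bins), function(i) {
    lo <- (i - 1) * bin_size + 1
    hi <- min(i * bin_size, L)
    if (lo > hi) return(base_cn)
    base_cn * max(cn[lo:hi])
  }, 0)
}

# Map reference point positions into the rearranged genome.  Points inside
# duplicated spans yield one hit per copy; strands flip through reversed
# segments.  Returns data.frame(ref, re, strand).
map_from_reference_points <- function(sm, pos, strand = NULL) {
  if (is.null(strand)) strand <- rep("*", length(pos))
  cs <- seg_cumstarts(sm)
  out <- vector("list", nrow(sm$segments))
  for (i in seq_len(nrow(sm$segments))) {
    seg <- sm$segments[i, ]
    if (seg$payload) next
    hit <- pos >= seg$ref_start & pos < seg$ref_end
    if (!any(hit)) next
    p <- pos[hit]
    s <- strand[hit]
    if (seg$strand == "+") {
      re <- cs[i] + (p - seg$ref_start)
      s_out <- s
    } else {
      re <- cs[i] + (seg$ref_end - 1 - p)
      s_out <- ifelse(s == "+", "-", ifelse(s == "-", "+", "*"))
    }
    out[[i]] <- data.frame(ref = p, re = re, strand = s_out)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(ref = numeric(0), re = numeric(0),
                               strand = character(0))
  else res[order(res$re), , drop = FALSE]
}

# Map reference intervals into the rearranged genome (one row per
# overlapping segment copy).  Returns data.frame(ref_start, ref_end,
# re_start, re_end, flipped).
map_from_reference_intervals <- function(sm, start, end) {
  cs <- seg_cumstarts(sm)
  out <- list()
  for (i in seq_len(nrow(sm$segments))) {
    seg <- sm$segments[i, ]
    if (seg$payload) next
    for (j in seq_along(start)) {
      s2 <- max(start[j], seg$ref_start)
      e2 <- min(end[j], seg$ref_end)
      if (s2 >= e2) next
      if (seg$strand == "+") {
        re_s <- cs[i] + (s2 - seg$ref_start)
        re_e <- cs[i] + (e2 - seg$ref_start)
      } else {
        re_s <- cs[i] + (seg$ref_end - e2)
        re_e <- cs[i] + (seg$ref_end - s2)
      }
      out[[length(out) + 1L]] <- data.frame(
        ref_start = start[j], ref_end = end[j],
        re_start = re_s, re_end = re_e, flipped = seg$strand == "-")
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(ref_start = numeric(0), ref_end = numeric(0),
                               re_start = numeric(0), re_end = numeric(0),
                               flipped = logical(0))
  else res[order(res$re_start), , drop = FALSE]
}

#' Rearranged genome sequence
#'
#' Concatenates the reference sequence of each segment in order, reverse
#' complementing reversed segments (GATC is palindromic, so DpnII sites
#' are preserved through inversions).  Payload segments receive a random
#' sequence generated from `payload_seed`, so a given locus model always
#' produces the same knock-in sequence.
#'
#' @param ref_seq Reference sequence (character), local coordinates.
#' @param sm Segment map over `nchar(ref_seq)`.
#' @param payload_seed Seed for payload sequence generation.
#' @return Character sequence of length `sm$rearranged_length`.
#' @export
rearranged_sequence <- function(ref_seq, sm, payload_seed = 1L) {
  stopifnot(nchar(ref_seq) == sm$ref_length)
  parts <- character(nrow(sm$segments))
  for (i in seq_len(nrow(sm$segments))) {
    seg <- sm$segments[i, ]
    if (seg$payload) {
      parts[i] <- with_seed(payload_seed, paste(
        sample(c("A", "C", "G", "T"), seg$length, replace = TRUE),
        collapse = ""))
    } else {
      s <- substr(ref_seq, seg$ref_start + 1, seg$ref_end)
      if (seg$strand == "-")
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      parts[i] <- s
    }
  }
  paste(parts, collapse = "")
}
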