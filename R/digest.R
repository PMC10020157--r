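#' In-silico restriction digestion
#'
#' Scans a sequence for a restriction motif (DpnII's GATC by default
#' throughout the package) and tiles the region into restriction
#' fragments.  The cut is placed at the motif start, the convention used
#' consistently by all downstream fragment arithmetic; overlapping motif
#' occurrences are resolved by a non-overlapping left-to-right scan.
#'
#' @param x Either a DNA sequence (character or
#'   [Biostrings::DNAString]) whose length equals `gi_width(region)`, or a
#'   numeric vector of precomputed 0-based motif start positions in
#'   absolute (region) coordinates.
#' @param motif Recognition motif, ACGT letters only.
#' @param region [gi()] interval the sequence spans.
#' @return An object of class `"restriction_map"`: list with `region`,
#'   `cut_positions` (sorted, strictly interior to the region) and
#'   `fragments` (data.frame `start`/`end` tiling the region exactly).
#' @examples
#' digest("AAGATCTT", "GATC", gi("chrT", 0, 8))
#' @export
digest <- function(x, motif = "GATC", region) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 1L)
    stop("empty motif")
  if (grepl("[^ACGT]", motif)) stop("motif contains non-ACGT characters")
  stopifnot(is_gi(region))
  if (is.numeric(x)) {
    starts <- sort(unique(as.numeric(x)))
  } else {
    seq <- if (methods::is(x, "DNAString")) x else {
      if (!is.character(x) || length(x) != 1L) stop("x must be a single sequence")
      Biostrings::DNAString(x)
    }
    if (length(seq) != gi_width(region))
      stop("sequence length does not match region width")
    hits <- Biostrings::matchPattern(motif, seq)
    starts0 <- BiocGenerics::start(hits) - 1  # 0-based offsets
    keep <- nonoverlapping_left_to_right(starts0, nchar(motif))
    starts <- region$start + starts0[keep]
  }
  cuts <- starts[starts > region$start & starts < region$end]
  bounds <- c(region$start, cuts, region$end)
  rm <- list(region = region,
             cut_positions = cuts,
             fragments = data.frame(start = bounds[-length(bounds)],
                                    end = bounds[-1]))
  class(rm) <- "restriction_map"
  rm
}

# greedy left-to-right selection of non-overlapping motif occurrences
nonoverlapping_left_to_right <- function(starts, width) {
  keep <- logical(length(starts))
  last_end <- -Inf
  for (i in seq_along(starts)) {
    if (starts[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- starts[i] + width
    }
  }
  keep
}

#' @export
print.restriction_map <- function(x, ...) {
  cat("<restriction map> ", format(x$region), ": ",
      nrow(x$fragments), " fragments (mean ",
      round(mean(x$fragments$end - x$fragments$start)), " bp)\n", sep = "")
  invisible(x)
}

#' Fragment index of base positions
#'
#' @param rm A [digest()] restriction map.
#' @param pos Base positions inside `rm$region` (absolute coordinates).
#' @return 1-based fragment indices.
#' @export
frag_index <- function(rm, pos) {
  if (any(pos < rm$region$start | pos >= rm$region$end))
    stop("position outside restriction map region")
  findInterval(pos, rm$fragments$start)
}
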