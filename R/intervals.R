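# Coordinate conventions: every interval in this package is 0-based,
# half-open [start, end), the BED/bedGraph dialect.  Coordinates are
# converted to 1-based inclusive only when parsing or printing the
# "chrN:start-end" notation used in genome browsers.

#' Create a genomic interval
#'
#' The basic coordinate container of chicsv: a single interval on one
#' chromosome, stored 0-based half-open.
#'
#' @param chrom Chromosome label (non-empty string).
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"*"`.
#' @return An object of class `"gi"` with fields `chrom`, `start`, `end`,
#'   `strand`.
#' @examples
#' gi("chr19", 44440000, 46400000)
#' @export
gi <- function(chrom, start, end, strand = "*") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("chrom must be a non-empty string")
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop("need 0 <= start < end")
  if (!strand %in% c("+", "-", "*")) stop("strand must be +, - or *")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "gi")
}

#' @export
is_gi <- function(x) inherits(x, "gi")

#' Width of a genomic interval in bases
#' @param x A `gi` object.
#' @export
gi_width <- function(x) x$end - x$start

#' @export
format.gi <- function(x, ...) {
  sprintf("%s:%s-%s%s", x$chrom,
          format(x$start + 1, big.mark = ",", scientific = FALSE),
          format(x$end, big.mark = ",", scientific = FALSE),
          if (x$strand == "*") "" else paste0(" (", x$strand, ")"))
}

#' @export
print.gi <- function(x, ...) {
  cat("<genomic interval> ", format(x), "  [", gi_width(x), " bp]\n", sep = "")
  invisible(x)
}

#' Parse browser-style region notation
#'
#' Converts 1-based inclusive `"chr:start-end"` text (commas allowed) to the
#' internal 0-based half-open representation.
#'
#' @param text Region string, e.g. `"chr19:44,440,001-46,400,000"`.
#' @return A [gi()] interval.
#' @export
parse_region <- function(text) {
  text <- gsub(",", "", text)
  m <- regmatches(text, regexec("^([^:]+):([0-9]+)-([0-9]+)$", text))[[1]]
  if (length(m) != 4L) stop("cannot parse region: ", text)
  gi(m[2], as.numeric(m[3]) - 1, as.numeric(m[4]))
}

#' @rdname parse_region
#' @param x A `gi` interval to format as 1-based inclusive text.
#' @export
format_region <- function(x) {
  sprintf("%s:%.0f-%.0f", x$chrom, x$start + 1, x$end)
}

# vectorized overlap length of [s1,e1) with [s2,e2)
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# does interval [s,e) overlap gi x by >= 1 bp
overlaps_gi <- function(s, e, x) overlap_len(s, e, x$start, x$end) > 0

# is a base position inside gi x
point_in <- function(pos, x) pos >= x$start & pos < x$end

# validate a feature table (chrom/start/end [+ name, strand]); returns it
# with canonical column order
as_features <- function(df, within = NULL) {
  stopifnot(is.data.frame(df), all(c("start", "end") %in% names(df)))
  if (is.null(df$chrom)) df$chrom <- if (is.null(within)) "." else within$chrom
  if (is.null(df$name)) df$name <- sprintf("feature_%d", seq_len(nrow(df)))
  if (is.null(df$strand)) df$strand <- "*"
  if (any(df$start >= df$end)) stop("feature with start >= end")
  if (!is.null(within) &&
      any(df$start < within$start | df$end > within$end))
    stop("feature outside ", format(within))
  df[, c("chrom", "start", "end", "name", "strand")]
}

#' Read / write BED files
#'
#' Thin wrappers around [rtracklayer::import()]/[rtracklayer::export()] that
#' return and accept plain 0-based half-open data frames with columns
#' `chrom`, `start`, `end`, `name`, `score`, `strand`.
#'
#' @param path File path.
#' @return `read_bed` returns a data.frame; `write_bed` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  md <- as.data.frame(S4Vectors::mcols(gr))
  df$name <- if (!is.null(md$name)) md$name else sprintf("feature_%d", seq_len(nrow(df)))
  df$score <- if (!is.null(md$score)) md$score else 0
  df$strand <- as.character(GenomicRanges::strand(gr))
  df
}

#' @rdname read_bed
#' @param df Data frame with at least `chrom`, `start`, `end` (0-based
#'   half-open); optional `name`, `score`, `strand`.
#' @export
write_bed <- function(df, path) {
  df <- as_features(df)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"),
    name = df$name)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# evaluate code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
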