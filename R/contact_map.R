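# Binned contact maps and their normalizations.

new_contact_map <- function(region, bin_size, matrix, valid = NULL,
                            norm_state = "raw", metadata = list()) {
  n <- ceiling(gi_width(region) / bin_size)
  stopifnot(nrow(matrix) == n, ncol(matrix) == n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  structure(list(region = region, bin_size = bin_size, matrix = matrix,
                 valid = valid, norm_state = norm_state,
                 metadata = metadata),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact map> ", format(x$region), " @ ", x$bin_size, " bp (",
      nrow(x$matrix), " bins, ", sum(x$valid), " valid), norm=",
      x$norm_state, "\n", sep = "")
  invisible(x)
}

n_bins <- function(m) nrow(m$matrix)

bin_starts <- function(m) {
  m$region$start + (seq_len(n_bins(m)) - 1) * m$bin_size
}

bin_ends <- function(m) pmin(bin_starts(m) + m$bin_size, m$region$end)

same_grid <- function(a, b) {
  a$region$chrom == b$region$chrom && a$region$start == b$region$start &&
    a$region$end == b$region$end && a$bin_size == b$bin_size
}

# logical vector: does each bin overlap any of the exclusion intervals
# (list of gi or data.frame chrom/start/end) by >= 1 bp
bins_in_intervals <- function(m, intervals) {
  hit <- rep(FALSE, n_bins(m))
  if (is.null(intervals)) return(hit)
  if (is_gi(intervals)) intervals <- list(intervals)
  if (is.data.frame(intervals))
    intervals <- lapply(seq_len(nrow(intervals)), function(i)
      gi(intervals$chrom[i], intervals$start[i], intervals$end[i]))
  s <- bin_starts(m); e <- bin_ends(m)
  for (iv in intervals) hit <- hit | overlaps_gi(s, e, iv)
  hit
}

#' Bin contact pairs into a symmetric matrix
#'
#' A pair contributes iff both ends fall within the region and
#' `min(mapq1, mapq2) >= mapq_min`.  Counts are stored symmetrically:
#' +1 to `(i, j)` and, when `i != j`, +1 to `(j, i)`, so the matrix
#' total equals twice the off-diagonal qualifying pairs plus the
#' diagonal ones.
#'
#' @param pairs A `contact_pairs` object (reference coordinates).
#' @param region Capture region to bin over.
#' @param bin_size Bin width in bases (default 5 kb).
#' @param mapq_min Minimum mapping quality for both ends (default 30).
#' @return A raw `"contact_map"`.
#' @export
bin_pairs <- function(pairs, region, bin_size = 5000, mapq_min = 30) {
  stopifnot(bin_size > 0)
  p <- pairs$pairs
  keep <- pmin(p$mapq1, p$mapq2) >= mapq_min &
    point_in(p$end1_pos, region) & point_in(p$end2_pos, region)
  n <- ceiling(gi_width(region) / bin_size)
  i <- (p$end1_pos[keep] - region$start) %/% bin_size
  j <- (p$end2_pos[keep] - region$start) %/% bin_size
  off <- i != j
  idx <- c(i * n + j, (j[off] * n + i[off])) + 1
  M <- matrix(tabulate(idx, nbins = n * n), n, n, byrow = TRUE)
  new_contact_map(region, bin_size, M,
                  metadata = list(mapq_min = mapq_min,
                                  pairs_used = sum(keep)))
}

#' Raw marginals (row sums) of a contact map
#' @param m A `contact_map`.
#' @return Numeric vector of per-bin row sums (NA treated as 0).
#' @export
contact_marginals <- function(m) {
  M <- m$matrix
  M[is.na(M)] <- 0
  rowSums(M)
}

# shared balancing core: find positive b so that the row sums of
# diag(b) A diag(b) are proportional to `target`, by symmetric iterative
# proportional fitting.  A is the valid-only submatrix.
balance_core <- function(A, target, tol, max_iter) {
  b <- rep(1, nrow(A))
  err <- Inf
  iter <- 0L
  repeat {
    s <- as.vector(A %*% b) * b
    sc <- sum(s) / sum(target)
    r <- s / (target * sc)
    err <- max(abs(r - 1))
    if (err < tol || iter >= max_iter) break
    b <- b / sqrt(r)
    iter <- iter + 1L
  }
  list(bias = b, convergence_error = err, iterations = iter,
       converged = err < tol)
}

# mask low-coverage bins: raw marginal below `min_frac` of the median
# positive marginal (generalizes the ad hoc removal of a handful of
# low-coverage rows/columns before normalization)
low_coverage_mask <- function(m, min_frac) {
  marg <- contact_marginals(m)
  med <- stats::median(marg[marg > 0])
  if (!length(med) || is.na(med)) rep(FALSE, n_bins(m))
  else marg < min_frac * med
}

apply_balance <- function(m, target_full, tol, max_iter, min_frac,
                          norm_state) {
  if (m$norm_state != "raw")
    warning("balancing a map with norm_state '", m$norm_state, "'")
  valid <- m$valid & !low_coverage_mask(m, min_frac)
  if (!any(valid)) stop("no valid bins to balance")
  if (any(target_full[valid] <= 0))
    stop("target marginal (copy number) must be positive on valid bins")
  M0 <- m$matrix
  M0[is.na(M0)] <- 0
  A <- M0[valid, valid, drop = FALSE]
  res <- balance_core(A, target_full[valid], tol, max_iter)
  if (!res$converged)
    warning(sprintf("balancing did not converge in %d iterations (residual %.3g); returning best iterate",
                    max_iter, res$convergence_error))
  B <- A * outer(res$bias, res$bias)
  # keep the overall scale of the input: preserve the valid-entry total
  sc <- sum(A) / sum(B)
  B <- B * sc
  n <- n_bins(m)
  out <- matrix(NA_real_, n, n)
  out[valid, valid] <- B
  bias_full <- rep(NA_real_, n)
  bias_full[valid] <- res$bias * sqrt(sc)
  bias <- structure(list(bias = bias_full,
                         convergence_error = res$convergence_error,
                         iterations = res$iterations,
                         converged = res$converged),
                    class = "bias_vector")
  map <- new_contact_map(m$region, m$bin_size, out, valid = valid,
                         norm_state = norm_state,
                         metadata = c(m$metadata,
                                      list(balance_tol = tol,
                                           balance_iterations = res$iterations,
                                           balance_residual = res$convergence_error)))
  list(map = map, bias = bias)
}

#' Balance a contact map to equal row sums
#'
#' Finds a positive diagonal rescaling `diag(b) M diag(b)` whose
#' valid-row sums agree to within `tol` (relative), the matrix-balancing
#' contract of KR-normalized Hi-C maps, implemented as symmetric
#' iterative proportional fitting.  Low-coverage bins (raw marginal
#' below `min_frac` of the median positive marginal) are masked before
#' balancing and carry `NA` in the output.
#'
#' @param m Raw `contact_map`.
#' @param tol Relative tolerance on row-sum equality.
#' @param max_iter Iteration cap; non-convergence warns and returns the
#'   best iterate, flagged in the bias vector.
#' @param min_frac Low-coverage masking threshold.
#' @return List with `map` (norm_state `"KR"`) and `bias` (a
#'   `"bias_vector"`: per-bin multipliers, convergence residual).
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 1000L, min_frac = 0.1) {
  apply_balance(m, rep(1, n_bins(m)), tol, max_iter, min_frac, "KR")
}

#' Copy-number-aware (LOIC) normalization
#'
#' Iterative correction in which the target marginal of bin `i` is
#' proportional to its copy number `cn_i` instead of uniform, so that a
#' duplication's doubled coverage is retained rather than balanced away:
#' on convergence the valid-row sums satisfy
#' `rowsum_i / cn_i = const` within `tol`.  With constant `cn` this
#' reduces exactly to uniform iterative correction.
#'
#' @param m Raw `contact_map`.
#' @param cn Per-bin copy numbers (positive on valid bins), e.g. from
#'   [copy_number_bins()]: 4 for bins overlapping a duplication, 2
#'   elsewhere.
#' @inheritParams kr_balance
#' @return List with `map` (norm_state `"LOIC"`) and `bias`.
#' @export
loic_normalize <- function(m, cn, tol = 1e-6, max_iter = 1000L,
                           min_frac = 0.1) {
  stopifnot(length(cn) == n_bins(m))
  apply_balance(m, as.numeric(cn), tol, max_iter, min_frac, "LOIC")
}

#' Distance-decay exponent of a binned map
#'
#' Log-log regression of the mean per-entry contact count against
#' genomic distance over a range of sub-diagonals; returns the negative
#' slope (the power-law exponent `alpha`).
#'
#' @param m `contact_map`.
#' @param min_d,max_d Sub-diagonal range (in bins) used for the fit.
#' @return Fitted exponent (positive for decaying signal).
#' @export
decay_exponent <- function(m, min_d = 2L, max_d = floor(n_bins(m) / 2)) {
  M <- m$matrix
  M[is.na(M)] <- 0
  v <- m$valid
  ds <- min_d:max_d
  meanc <- vapply(ds, function(d) {
    i <- seq_len(n_bins(m) - d)
    ok <- v[i] & v[i + d]
    mean(M[cbind(i[ok], i[ok] + d)])
  }, 0)
  ok <- meanc > 0
  fit <- stats::lm(log(meanc[ok]) ~ log(ds[ok] * m$bin_size))
  -unname(stats::coef(fit)[2])
}

map_header <- function(m) {
  c("# chicsv contact map",
    sprintf("# chrom=%s", m$region$chrom),
    sprintf("# start=%.0f", m$region$start),
    sprintf("# end=%.0f", m$region$end),
    sprintf("# bin_size=%.0f", m$bin_size),
    sprintf("# norm=%s", m$norm_state),
    sprintf("# valid=%s", paste(as.integer(m$valid), collapse = "")))
}

parse_map_header <- function(lines) {
  get <- function(key) {
    hit <- grepl(sprintf("^# ?%s=", key), lines)
    if (!any(hit)) stop("missing header field: ", key)
    sub(sprintf("^# ?%s=", key), "", lines[hit][1])
  }
  list(chrom = get("chrom"), start = as.numeric(get("start")),
       end = as.numeric(get("end")), bin_size = as.numeric(get("bin_size")),
       norm = get("norm"),
       valid = as.integer(strsplit(get("valid"), "")[[1]]) == 1L)
}

#' Write / read binned contact maps
#'
#' Two text dialects: `"coo"` stores the upper triangle (`i <= j`) as
#' `bin_i<TAB>bin_j<TAB>value` triplets (0-based bin indices, zero and
#' `NA` entries omitted), `"tsv"` stores the dense matrix with a header
#' row of bin start coordinates.  Both carry a `#` header block with the
#' region, bin size, normalization state and valid-bin mask, and
#' round-trip raw counts exactly (normalized values to better than
#' 1e-12).
#'
#' @param m `contact_map` to write.
#' @param path File path.
#' @param format `"coo"` or `"tsv"` (for reading, `"auto"` sniffs the
#'   file).
#' @return `write_contact_map` returns `path` invisibly;
#'   `read_contact_map` a `contact_map`.
#' @export
write_contact_map <- function(m, path, format = c("coo", "tsv")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(map_header(m), sprintf("# format=%s", format)), con)
  if (format == "coo") {
    M <- m$matrix
    keep <- which(upper.tri(M, diag = TRUE) & !is.na(M) & M != 0,
                  arr.ind = TRUE)
    if (nrow(keep)) {
      o <- order(keep[, 1], keep[, 2])
      keep <- keep[o, , drop = FALSE]
      writeLines(sprintf("%d\t%d\t%.17g", keep[, 1] - 1L, keep[, 2] - 1L,
                         M[keep]), con)
    }
  } else {
    writeLines(paste(sprintf("%.0f", bin_starts(m)), collapse = "\t"), con)
    apply(m$matrix, 1, function(row)
      writeLines(paste(sprintf("%.17g", row), collapse = "\t"), con))
  }
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path, format = c("auto", "coo", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  hdr_n <- sum(startsWith(lines, "#"))
  hdr <- lines[seq_len(hdr_n)]
  info <- parse_map_header(hdr)
  fmt_line <- grepl("^# ?format=", hdr)
  if (format == "auto") {
    format <- if (any(fmt_line)) sub("^# ?format=", "", hdr[fmt_line][1]) else "coo"
  }
  region <- gi(info$chrom, info$start, info$end)
  n <- ceiling((info$end - info$start) / info$bin_size)
  body <- lines[-seq_len(hdr_n)]
  M <- matrix(0, n, n)
  if (format == "coo") {
    M[!info$valid, ] <- NA_real_
    M[, !info$valid] <- NA_real_
    for (k in seq_along(body)) {
      f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
      if (length(f) != 3L)
        stop("malformed COO line ", k + hdr_n, " in ", path)
      i <- as.integer(f[1]) + 1L
      j <- as.integer(f[2]) + 1L
      v <- as.numeric(f[3])
      if (is.na(i) || is.na(j) || i < 1 || j < i || j > n)
        stop("malformed COO line ", k + hdr_n, " in ", path)
      M[i, j] <- v
      M[j, i] <- v
    }
  } else {
    if (length(body) != n + 1L)
      stop("malformed dense TSV body in ", path)
    for (k in seq_len(n)) {
      row <- as.numeric(strsplit(body[k + 1L], "\t", fixed = TRUE)[[1]])
      if (length(row) != n)
        stop("malformed dense TSV line ", k + 1L + hdr_n, " in ", path)
      M[k, ] <- row
    }
  }
  new_contact_map(region, info$bin_size, M, valid = info$valid,
                  norm_state = info$norm)
}

#' Export a per-bin track as bedGraph
#'
#' Writes one line per bin (0-based half-open), used for contact-map
#' marginals, bias vectors and virtual-4C profiles.
#'
#' @param values Per-bin numeric values (NA bins are skipped).
#' @param region Region the bins tile.
#' @param bin_size Bin width.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(values, region, bin_size, path) {
  n <- ceiling(gi_width(region) / bin_size)
  stopifnot(length(values) == n)
  starts <- region$start + (seq_len(n) - 1) * bin_size
  ends <- pmin(starts + bin_size, region$end)
  ok <- !is.na(values)
  gr <- GenomicRanges::GRanges(
    seqnames = region$chrom,
    ranges = IRanges::IRanges(start = starts[ok] + 1, end = ends[ok]),
    score = values[ok])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
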