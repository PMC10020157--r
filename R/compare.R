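# Pairwise subtraction maps.  Two normalized maps are made comparable by
# matching their distance-dependent signal decay: the entries of each
# sub-diagonal of one map are divided by the sum of that sub-diagonal
# and multiplied by the average of these sums from both maps, after
# which each map is scaled by 1e6 / its total.  Rearranged regions
# (duplication, inversion) are excluded from the computation of all
# scaling factors -- but the factors are still applied to every entry,
# so excluded regions remain visible in the subtraction map.

#' Per-sub-diagonal sums of a contact map
#'
#' Sums the entries at each bin distance `d = |i - j|` over the full
#' symmetric matrix (both triangles; off-diagonal distances therefore
#' count each unordered pair twice -- the convention cancels in the
#' joint scaling because both maps use it).  An entry contributes only
#' if both of its bins are valid and neither overlaps an excluded
#' interval by >= 1 bp.
#'
#' @param m `contact_map`.
#' @param exclude Excluded intervals: `NULL`, a [gi()], a list of them,
#'   or a BED-like data.frame.
#' @return Numeric vector of length `n_bins` (distances 0 .. n-1).
#' @export
diagonal_sums <- function(m, exclude = NULL) {
  n <- n_bins(m)
  elig <- m$valid & !bins_in_intervals(m, exclude)
  M <- m$matrix
  M[is.na(M)] <- 0
  M[!elig, ] <- 0
  M[, !elig] <- 0
  vapply(0:(n - 1), function(d) {
    if (d == 0) return(sum(diag(M)))
    i <- seq_len(n - d)
    sum(M[cbind(i, i + d)]) + sum(M[cbind(i + d, i)])
  }, 0)
}

#' Jointly scale two maps across their sub-diagonals
#'
#' @param a,b Normalized `contact_map`s on the same grid.
#' @param exclude Intervals excluded from scaling-factor computation (in
#'   both maps); entries there are still scaled and kept.
#' @param total Final fixed total per map over non-excluded valid
#'   entries (default 1e6).
#' @return List with maps `a` and `b` (norm_state `"scaled"`): each has
#'   non-excluded total exactly `total`, and their per-diagonal
#'   non-excluded sums are equal to each other.  Masked bins are set to
#'   0 so outputs contain no non-finite values.
#' @export
joint_distance_scale <- function(a, b, exclude = NULL, total = 1e6) {
  if (!same_grid(a, b)) stop("grid mismatch")
  n <- n_bins(a)
  sA <- diagonal_sums(a, exclude)
  sB <- diagonal_sums(b, exclude)
  if (sum(sA) == 0 && sum(sB) == 0) stop("both maps empty")
  m_d <- (sA + sB) / 2
  dist_mat <- abs(row(a$matrix) - col(a$matrix))
  scale_one <- function(m, s_d) {
    f_d <- ifelse(s_d > 0, m_d / s_d, 0)
    M <- m$matrix
    M[is.na(M)] <- 0
    M <- M * matrix(f_d[dist_mat + 1], n, n)
    # fixed-total scaling over non-excluded valid entries
    elig <- m$valid & !bins_in_intervals(m, exclude)
    tot <- sum(M[elig, elig])
    if (tot <= 0) stop("map has no signal in non-excluded region")
    M <- M * (total / tot)
    new_contact_map(m$region, m$bin_size, M, valid = m$valid,
                    norm_state = "scaled",
                    metadata = c(m$metadata,
                                 list(joint_scale_total = total,
                                      global_factor = total / tot)))
  }
  list(a = scale_one(a, sA), b = scale_one(b, sB))
}

#' Subtraction map between two jointly scaled maps
#'
#' Computed as `minuend - subtrahend`; the package convention at the
#' pipeline level is mutant minus wild-type, so gained contacts are
#' positive.  Swapping the arguments negates every entry exactly.
#'
#' @param minuend,subtrahend `contact_map`s from
#'   [joint_distance_scale()], same grid.
#' @param excluded Intervals that were excluded from scaling (stored for
#'   provenance).
#' @return A `"subtraction_map"`: signed matrix plus orientation
#'   metadata.
#' @export
subtract_maps <- function(minuend, subtrahend, excluded = NULL) {
  if (!same_grid(minuend, subtrahend)) stop("grid mismatch")
  M <- minuend$matrix - subtrahend$matrix
  M[is.na(M)] <- 0
  structure(list(region = minuend$region, bin_size = minuend$bin_size,
                 matrix = M,
                 valid = minuend$valid & subtrahend$valid,
                 orientation = "minuend - subtrahend",
                 excluded = excluded,
                 norm_state = "subtraction"),
            class = c("subtraction_map", "contact_map"))
}

#' Mean of a subtraction map over a rectangular block
#'
#' Averages the signed entries pairing bins overlapping `window1` with
#' bins overlapping `window2` (both orderings), the quantity used for
#' sign tests on gained/lost contact blocks.
#'
#' @param sub A `subtraction_map` (or any `contact_map`).
#' @param window1,window2 [gi()] intervals.
#' @return Mean signed value over the block.
#' @export
block_mean <- function(sub, window1, window2) {
  r1 <- bins_in_intervals(sub, window1)
  r2 <- bins_in_intervals(sub, window2)
  if (!any(r1) || !any(r2)) stop("window covers no bins")
  vals <- c(sub$matrix[r1, r2], sub$matrix[r2, r1])
  mean(vals, na.rm = TRUE)
}

# percentile by linear interpolation of order statistics (quantile type 7)
clip_threshold <- function(x, p) {
  stats::quantile(x, p / 100, names = FALSE, type = 7, na.rm = TRUE)
}

#' Render a contact or subtraction map as a heatmap
#'
#' Linear color scale with values above the clip percentile truncated;
#' subtraction maps use a signed diverging scale symmetric about 0
#' (clipping at the percentile of absolute values).  Output is
#' deterministic for fixed input.
#'
#' @param m `contact_map` or `subtraction_map`.
#' @param clip_percentile Percentile in (50, 100] above which values are
#'   truncated (default 99).
#' @param path Optional PNG output path; when `NULL`, no file is
#'   written.
#' @return The clipped matrix, invisibly.
#' @export
render_heatmap <- function(m, clip_percentile = 99, path = NULL) {
  if (clip_percentile <= 50 || clip_percentile > 100)
    stop("clip_percentile must be in (50, 100]")
  M <- m$matrix
  if (all(is.na(M))) stop("empty map")
  signed <- inherits(m, "subtraction_map")
  if (signed) {
    q <- clip_threshold(abs(M), clip_percentile)
    clipped <- pmax(pmin(M, q), -q)
    cols <- grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(101)
    zlim <- c(-q, q)
  } else {
    q <- clip_threshold(M, clip_percentile)
    clipped <- pmin(M, q)
    cols <- grDevices::colorRampPalette(c("#FFFFFF", "#FDD49E", "#D7301F",
                                          "#7F0000"))(101)
    zlim <- c(min(clipped, na.rm = TRUE), q)
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 800)
    on.exit(grDevices::dev.off())
    plot_m <- clipped
    plot_m[is.na(plot_m)] <- if (signed) 0 else zlim[1]
    if (zlim[1] == zlim[2]) zlim <- zlim + c(-0.5, 0.5)
    graphics::image(x = seq_len(nrow(M)), y = seq_len(ncol(M)),
                    z = plot_m[, rev(seq_len(ncol(M))), drop = FALSE],
                    zlim = zlim, col = cols, useRaster = TRUE,
                    xlab = "bin", ylab = "bin", main = format(m$region))
  }
  invisible(clipped)
}
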