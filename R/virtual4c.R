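# Virtual 4C: a one-dimensional viewpoint interaction profile extracted
# from fragment-resolved contact pairs.  The pipeline order is fixed as
# count (per restriction fragment) -> bin (1 kb grid, proportional
# spreading) -> smooth (5 kb centered sliding mean) -> scale (1e3 over
# the enriched region, viewpoint +- margin excluded from the factor).

#' Count viewpoint contacts per restriction fragment
#'
#' A read pair qualifies iff both ends have `mapq >= mapq_min`, exactly
#' one end position lies within the viewpoint interval, and the distal
#' end falls in a fragment not overlapping the viewpoint (fragments
#' overlapping the viewpoint carry no counts, so the profile never
#' reports the viewpoint's self-signal).  The distal end's fragment is
#' incremented by one per qualifying pair.
#'
#' @param pairs `contact_pairs` on reference coordinates.
#' @param vp Viewpoint interval ([gi()]), inside the restriction map
#'   region.
#' @param rm Reference restriction map.
#' @param mapq_min Minimum mapping quality (default 30).
#' @return A `"fragment_profile"`: per-fragment `counts`,
#'   `total_qualifying`, the viewpoint and restriction map.
#' @export
count_by_fragment <- function(pairs, vp, rm, mapq_min = 30) {
  stopifnot(is_gi(vp))
  if (vp$start < rm$region$start || vp$end > rm$region$end)
    stop("viewpoint outside region")
  p <- pairs$pairs
  in1 <- point_in(p$end1_pos, vp)
  in2 <- point_in(p$end2_pos, vp)
  qual <- xor(in1, in2) & pmin(p$mapq1, p$mapq2) >= mapq_min &
    point_in(p$end1_pos, rm$region) & point_in(p$end2_pos, rm$region)
  distal <- ifelse(in1[qual], p$end2_pos[qual], p$end1_pos[qual])
  fr <- rm$fragments
  vp_frag <- overlap_len(fr$start, fr$end, vp$start, vp$end) > 0
  f <- frag_index(rm, distal)
  keep <- !vp_frag[f]
  counts <- tabulate(f[keep], nbins = nrow(fr))
  structure(list(counts = counts, viewpoint = vp, rm = rm,
                 total_qualifying = sum(keep),
                 mapq_min = mapq_min),
            class = "fragment_profile")
}

#' Bin a fragment count profile to a regular grid
#'
#' Fragment counts are distributed over the grid proportionally to
#' overlap: a fragment of length `len` with count `c` contributes
#' `c * overlap_k / len` to each bin `k` it overlaps, so the binned
#' values conserve the fragment totals exactly.
#'
#' @param fc A [count_by_fragment()] profile.
#' @param grid_size Grid bin width in bases (default 1 kb).
#' @return A `"binned_profile"` at stage `"binned"`.
#' @export
bin_profile <- function(fc, grid_size = 1000) {
  stopifnot(grid_size > 0)
  region <- fc$rm$region
  n <- ceiling(gi_width(region) / grid_size)
  values <- numeric(n)
  fr <- fc$rm$fragments
  nz <- which(fc$counts > 0)
  for (i in nz) {
    s <- fr$start[i]; e <- fr$end[i]
    len <- e - s
    k0 <- (s - region$start) %/% grid_size
    k1 <- (e - 1 - region$start) %/% grid_size
    ks <- k0:k1
    bs <- region$start + ks * grid_size
    be <- pmin(bs + grid_size, region$end)
    ov <- overlap_len(s, e, bs, be)
    values[ks + 1] <- values[ks + 1] + fc$counts[i] * ov / len
  }
  structure(list(region = region, grid_size = grid_size, values = values,
                 stage = "binned", viewpoint = fc$viewpoint,
                 total_qualifying = fc$total_qualifying),
            class = "binned_profile")
}

#' Smooth a binned profile with a centered sliding window
#'
#' Each bin is replaced by the mean of the bins within a centered window
#' of `window` bases (an odd multiple of the grid size, default 5 kb =
#' 5 bins); windows shrink at the profile edges.
#'
#' @param bp A `binned_profile`.
#' @param window Window size in bases.
#' @return The profile at stage `"smoothed"`.
#' @export
smooth_profile <- function(bp, window = 5000) {
  g <- bp$grid_size
  if (window < g) stop("window smaller than grid size")
  wb <- window / g
  if (wb != round(wb) || wb %% 2 != 1)
    stop("window must be an odd multiple of the grid size")
  h <- (wb - 1) / 2
  n <- length(bp$values)
  cs <- cumsum(c(0, bp$values))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  bp$values <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  bp$stage <- "smoothed"
  bp
}

#' Scale a smoothed profile to a fixed enriched-region total
#'
#' Multiplies every bin by `scale_total / S`, where `S` is the sum of
#' smoothed values over bins overlapping the enriched region, excluding
#' bins overlapping the viewpoint expanded by `margin` on each side.
#' Bins partially overlapping the enriched region contribute their full
#' value to `S` (set `prorate = TRUE` for bp-prorated contributions).
#' Viewpoint bins are scaled like all others, not zeroed.
#'
#' @param bp Smoothed `binned_profile`.
#' @param enriched Enriched (capture) region; defaults to the profile
#'   region.
#' @param vp Viewpoint interval; defaults to the profile's.
#' @param margin Exclusion margin around the viewpoint (default 5 kb).
#' @param scale_total Fixed post-scaling total (default 1e3).
#' @param prorate Weight partial enriched-region overlaps by fraction.
#' @return A `"v4c_profile"` (stage `"scaled"`) with the scale factor
#'   and eligible-bin mask recorded.
#' @export
scale_profile <- function(bp, enriched = NULL, vp = bp$viewpoint,
                          margin = 5000, scale_total = 1e3,
                          prorate = FALSE) {
  if (bp$stage != "smoothed")
    warning("scaling a profile at stage '", bp$stage, "'")
  if (is.null(enriched)) enriched <- bp$region
  stopifnot(margin >= 0)
  n <- length(bp$values)
  bs <- bp$region$start + (seq_len(n) - 1) * bp$grid_size
  be <- pmin(bs + bp$grid_size, bp$region$end)
  in_enr <- overlap_len(bs, be, enriched$start, enriched$end)
  vp_lo <- max(vp$start - margin, bp$region$start)
  vp_hi <- min(vp$end + margin, bp$region$end)
  near_vp <- overlap_len(bs, be, vp_lo, vp_hi) > 0
  eligible <- in_enr > 0 & !near_vp
  wts <- if (prorate) in_enr / (be - bs) else as.numeric(in_enr > 0)
  S <- sum(bp$values[eligible] * wts[eligible])
  if (S <= 0) stop("no signal in enriched region")
  factor <- scale_total / S
  structure(list(region = bp$region, grid_size = bp$grid_size,
                 values = bp$values * factor, stage = "scaled",
                 viewpoint = vp, enriched = enriched, margin = margin,
                 scale_factor = factor, eligible = eligible,
                 total_qualifying = bp$total_qualifying),
            class = c("v4c_profile", "binned_profile"))
}

#' Integrated signal over a window
#'
#' Sums the scaled profile over the bins overlapping `window`, weighting
#' partial bins by their overlap fraction.
#'
#' @param p A `v4c_profile` (any `binned_profile` works).
#' @param window [gi()] window inside the profile region.
#' @return The integrated signal (a single number).
#' @export
integrate_signal <- function(p, window) {
  stopifnot(is_gi(window))
  if (window$start >= window$end) stop("empty window")
  n <- length(p$values)
  bs <- p$region$start + (seq_len(n) - 1) * p$grid_size
  be <- pmin(bs + p$grid_size, p$region$end)
  ov <- overlap_len(bs, be, window$start, window$end)
  sum(p$values * ov / (be - bs))
}

#' Merge replicate profiles
#'
#' Per-bin arithmetic mean of scaled replicate profiles on identical
#' grids with identical viewpoint and enriched region.  Because each
#' replicate sums to the fixed scale total over the eligible bins, so
#' does the merged profile.
#'
#' @param profiles List of `v4c_profile`s.
#' @return The merged `v4c_profile`.
#' @export
merge_replicates <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  p0 <- profiles[[1]]
  for (p in profiles[-1]) {
    if (p$grid_size != p0$grid_size ||
        p$region$start != p0$region$start || p$region$end != p0$region$end ||
        p$viewpoint$start != p0$viewpoint$start ||
        p$viewpoint$end != p0$viewpoint$end ||
        p$enriched$start != p0$enriched$start ||
        p$enriched$end != p0$enriched$end)
      stop("grid/viewpoint/enriched-region mismatch between replicates")
  }
  vals <- rowMeans(vapply(profiles, function(p) p$values,
                          numeric(length(p0$values))))
  p0$values <- vals
  p0$scale_factor <- mean(vapply(profiles, function(p) p$scale_factor, 0))
  p0$n_replicates <- length(profiles)
  p0
}

#' Run the full virtual-4C pipeline for one viewpoint
#'
#' Convenience wrapper: count per fragment, bin, smooth, scale.
#'
#' @inheritParams count_by_fragment
#' @inheritParams scale_profile
#' @param grid_size Grid width (default 1 kb).
#' @param window Smoothing window (default 5 kb).
#' @return A `v4c_profile`.
#' @export
virtual4c <- function(pairs, vp, rm, mapq_min = 30, grid_size = 1000,
                      window = 5000, enriched = NULL, margin = 5000,
                      scale_total = 1e3) {
  fc <- count_by_fragment(pairs, vp, rm, mapq_min)
  bp <- smooth_profile(bin_profile(fc, grid_size), window)
  scale_profile(bp, enriched = enriched, vp = vp, margin = margin,
                scale_total = scale_total)
}

#' Write a profile as bedGraph
#'
#' @param p A `binned_profile` or `v4c_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_bedgraph <- function(p, path) {
  export_bedgraph(p$values, p$region, p$grid_size, path)
}
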