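# The generative contact model: power-law distance decay modulated by
# TAD membership (boundary crossings attenuate a within-TAD boost) and
# by radially decaying loop "bumps" anchored at convergent CTCF pairs.
# This is the standard minimal model of locus-scale Hi-C signal; it
# exists so every downstream operation (balancing, subtraction maps,
# virtual 4C) has realistic, structured input with known truth.

#' Contact-model parameters
#'
#' @param alpha Distance-decay exponent (> 0); contact weight falls off
#'   as `(distance + 1)^-alpha`.
#' @param tad_boost Within-TAD enrichment factor (>= 1).
#' @param leakiness Per-boundary attenuation in (0, 1]: crossing `k`
#'   boundaries multiplies the TAD factor by `leakiness^k`.  1 = fully
#'   permeable boundaries, small values = strong insulation.
#' @param n_pairs Number of contact pairs to sample.
#' @param loops Optional data.frame of explicit loops (`a1`, `a2`,
#'   `strength`, `width` in bases).  When `NULL` (default), loops are
#'   derived from convergent CTCF pairs of the annotation via
#'   [convergent_loops()].
#' @param loop_strength,loop_width Strength (relative enrichment at the
#'   loop center) and Gaussian width (bases) for CTCF-derived loops.
#' @param p_highq Probability that a read end receives the high mapping
#'   quality `mapq_high` (>= 30); otherwise `mapq_low` (< 30), so that
#'   MAPQ filters are exercised.
#' @param mapq_high,mapq_low The two MAPQ values.
#' @param seed Default RNG seed for sampling operations.
#' @return A `"contact_params"` list.
#' @export
contact_params <- function(alpha = 1.0, tad_boost = 3.0, leakiness = 0.3,
                           n_pairs = 5e5, loops = NULL,
                           loop_strength = 1.0, loop_width = 10000,
                           p_highq = 0.9, mapq_high = 60L, mapq_low = 10L,
                           seed = NULL) {
  stopifnot(alpha > 0, tad_boost >= 1, leakiness > 0, leakiness <= 1,
            n_pairs >= 1, p_highq >= 0, p_highq <= 1,
            mapq_high >= 30, mapq_low < 30)
  structure(list(alpha = alpha, tad_boost = tad_boost, leakiness = leakiness,
                 n_pairs = as.numeric(n_pairs), loops = loops,
                 loop_strength = loop_strength, loop_width = loop_width,
                 p_highq = p_highq, mapq_high = as.integer(mapq_high),
                 mapq_low = as.integer(mapq_low), seed = seed),
            class = "contact_params")
}

#' Loops from convergent CTCF pairs
#'
#' Enumerates all pairs of CTCF sites in convergent (head-to-head)
#' orientation -- a `+` site upstream of a `-` site -- the preferred
#' configuration of loop anchors.  Orientation is honored through
#' inversions: a flipped site changes which pairs converge.
#'
#' @param ctcf data.frame with `pos` and `strand`.
#' @param strength,width Loop bump parameters (see [contact_params()]).
#' @return data.frame `a1`, `a2`, `strength`, `width` (one row per loop).
#' @export
convergent_loops <- function(ctcf, strength = 1.0, width = 10000) {
  ctcf <- ctcf[order(ctcf$pos), ]
  plus <- ctcf$pos[ctcf$strand == "+"]
  minus <- ctcf$pos[ctcf$strand == "-"]
  out <- expand.grid(a1 = plus, a2 = minus)
  out <- out[out$a1 < out$a2, , drop = FALSE]
  if (nrow(out) == 0L)
    return(data.frame(a1 = numeric(0), a2 = numeric(0),
                      strength = numeric(0), width = numeric(0)))
  out$strength <- strength
  out$width <- width
  rownames(out) <- NULL
  out[order(out$a1, out$a2), ]
}

# Expected contact weight for midpoints mi (rows) x mj (cols):
#   w = (|mi - mj| + 1)^-alpha * tad_boost * leakiness^k * (1 + sum bumps)
# where k is the number of TAD boundaries crossed and each loop
# contributes a Gaussian bump of the given strength and width (sd, bp)
# centered on its anchor pair (symmetrized over anchor order).
pair_weights <- function(mi, mj, boundaries, loops, alpha, tad_boost,
                         leakiness) {
  D <- abs(outer(mi, mj, "-"))
  w <- if (alpha == 1) 1 / (D + 1) else (D + 1)^(-alpha)
  fi <- findInterval(mi, boundaries)
  fj <- findInterval(mj, boundaries)
  k <- abs(outer(fi, fj, "-"))
  lp <- tad_boost * leakiness^(0:max(k))   # lookup: k takes few small values
  w <- w * lp[k + 1]
  if (!is.null(loops) && nrow(loops) > 0) {
    B <- matrix(0, nrow(w), ncol(w))
    add_bump <- function(a1, a2, strength, width) {
      # Gaussian bump support truncated at 6 sd (contribution < 1e-15)
      r <- 6 * width
      ri <- which(abs(mi - a1) < r)
      ci <- which(abs(mj - a2) < r)
      if (length(ri) && length(ci)) {
        s2 <- 2 * width^2
        B[ri, ci] <<- B[ri, ci] + strength *
          exp(-outer((mi[ri] - a1)^2, (mj[ci] - a2)^2, "+") / s2)
      }
    }
    for (l in seq_len(nrow(loops))) {
      add_bump(loops$a1[l], loops$a2[l], loops$strength[l], loops$width[l])
      add_bump(loops$a2[l], loops$a1[l], loops$strength[l], loops$width[l])
    }
    w <- w * (1 + B)
  }
  w
}

# loops for a locus under given params (explicit loops win)
locus_loops <- function(ctcf, params) {
  if (!is.null(params$loops)) params$loops
  else convergent_loops(ctcf, params$loop_strength, params$loop_width)
}

#' Expected binned contact matrix
#'
#' Evaluates the contact model on a bin grid over the locus region and
#' scales the matrix so its total equals `params$n_pairs`.  The result is
#' exactly symmetric.
#'
#' @param locus A [model_locus()].
#' @param params [contact_params()].
#' @param bin_size Bin width in bases (last bin may be truncated).
#' @return Dense symmetric matrix with attributes `region` and
#'   `bin_size`.
#' @export
expected_matrix <- function(locus, params, bin_size = 5000) {
  region <- locus$region
  L <- gi_width(region)
  if (L <= 0) stop("empty region")
  n <- ceiling(L / bin_size)
  starts <- region$start + (seq_len(n) - 1) * bin_size
  ends <- pmin(starts + bin_size, region$end)
  mids <- (starts + ends) / 2
  loops <- locus_loops(locus$ctcf, params)
  E <- pair_weights(mids, mids, locus$boundaries, loops,
                    params$alpha, params$tad_boost, params$leakiness)
  E <- (E + t(E)) / 2
  E <- E * (params$n_pairs / sum(E))
  attr(E, "region") <- region
  attr(E, "bin_size") <- bin_size
  E
}
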