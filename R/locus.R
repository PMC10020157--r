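#' Build the model locus
#'
#' Constructs the synthetic two-TAD regulatory locus used by the contact
#' simulator: a ~2 Mb capture region containing a centromeric TAD with a
#' muscle developmental gene (`Lbx1`) and a telomeric TAD with a
#' signalling gene (`Fgf8`), separated by a divergent-CTCF boundary that
#' is partially leaky, with a cluster of AER enhancers located in the
#' telomeric TAD close to that boundary.  Loop anchors are the convergent
#' CTCF pairs of the annotation.  The reference DNA sequence is drawn
#' uniformly at random from a fixed seed, giving DpnII (GATC) fragments
#' of ~256 bp on average, and is digested in silico to fragment
#' resolution.
#'
#' Named structural variants mirror the alleles studied at such loci: a
#' direct tandem duplication spanning `Lbx1`, the boundary and the
#' enhancer cluster while excluding `Fgf8` (`"dup"`), two inversions
#' repositioning boundary and enhancers (`"inv1"`, `"inv2"`), and an
#' enhancer knock-in insertion (`"ki"`).  Breakpoints are configurable;
#' the defaults reproduce the qualitative geometry (e.g. the
#' enhancer-to-`Lbx1` separation shrinks from ~380 kb in the reference to
#' ~140 kb in the duplication's neo-TAD).
#'
#' @param region Capture region ([gi()]); default
#'   `chr19:44,440,001-46,400,000` in browser notation.
#' @param seed Seed for the reference sequence (fixed property of the
#'   locus, independent of contact-sampling seeds).
#' @param motif Restriction motif.
#' @param boundaries Absolute positions of TAD boundary midpoints.
#' @param ctcf data.frame of CTCF sites: `pos` (absolute), `strand`.
#' @param genes,enhancers Feature data.frames (`start`, `end`, `name`).
#' @param viewpoints Named list of two-element numeric vectors
#'   `c(start, end)` (absolute, 0-based half-open).
#' @param windows Named list of integration windows, same encoding.
#' @param svs Named list of [rearrangement()] specs (absolute breakpoints).
#' @return A `"locus_model"` list: annotation tables, reference sequence
#'   (`seq`, local to the region) and its restriction map (`rm`, absolute
#'   coordinates).
#' @export
model_locus <- function(region = gi("chr19", 44440000, 46400000),
                        seed = 1903L,
                        motif = "GATC",
                        boundaries = c(44700000, 45400000, 46100000),
                        ctcf = data.frame(
                          pos = c(44698000, 44702000, 45396000,
                                  45404000, 46098000, 46102000),
                          strand = c("-", "+", "-", "+", "-", "+")),
                        genes = data.frame(
                          start = c(45100000, 45200000, 45380000,
                                    45406000, 45460000, 46000000),
                          end = c(45105000, 45260000, 45392000,
                                  45418000, 45545000, 46006000),
                          name = c("Lbx1", "Btrc", "Poll",
                                   "Dpcd", "Fbxw4", "Fgf8")),
                        enhancers = data.frame(
                          start = c(45480000, 45492000, 45504000,
                                    45516000, 45990000),
                          end = c(45482000, 45494000, 45506000,
                                  45518000, 45992000),
                          name = c("CE58", "CE59", "CE61", "CE66", "CE80")),
                        viewpoints = list(
                          Lbx1 = c(45100000, 45105000),
                          Fgf8 = c(46000000, 46006000),
                          Btrc = c(45200000, 45205000)),
                        windows = list(
                          enhancer_region = c(45455000, 45580000)),
                        svs = list(
                          dup = rearrangement("tandem_duplication",
                                              c(45020000, 45560000)),
                          inv1 = rearrangement("inversion",
                                               c(45300000, 45900000)),
                          inv2 = rearrangement("inversion",
                                               c(45150000, 45900000)),
                          ki = rearrangement("insertion", 45110000,
                                             payload_length = 6993))) {
  stopifnot(is_gi(region))
  if (any(boundaries <= region$start | boundaries >= region$end))
    stop("boundary outside region")
  if (any(ctcf$pos < region$start | ctcf$pos >= region$end))
    stop("CTCF site outside region")
  if (!all(ctcf$strand %in% c("+", "-")))
    stop("CTCF orientations must be + or -")
  genes <- as_features(genes, within = region)
  enhancers <- as_features(enhancers, within = region)
  L <- gi_width(region)
  seq <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                               collapse = ""))
  locus <- list(region = region, seed = as.integer(seed), motif = motif,
                seq = seq,
                rm = digest(seq, motif, region),
                boundaries = sort(boundaries),
                ctcf = ctcf[order(ctcf$pos), ],
                genes = genes, enhancers = enhancers,
                viewpoints = viewpoints, windows = windows,
                svs = svs)
  class(locus) <- "locus_model"
  locus
}

#' @export
print.locus_model <- function(x, ...) {
  cat("<locus model> ", format(x$region), "\n",
      "  ", nrow(x$rm$fragments), " ", x$motif, " fragments; ",
      length(x$boundaries), " TAD boundaries; ",
      nrow(x$ctcf), " CTCF sites; SVs: ",
      paste(names(x$svs), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# segment map for a named SV of the locus, breakpoints converted to
# coordinates local to the region
locus_segment_map <- function(locus, sv = "wildtype") {
  L <- gi_width(locus$region)
  if (identical(sv, "wildtype")) return(identity_segment_map(L))
  spec <- locus$svs[[sv]]
  if (is.null(spec)) stop("unknown SV name: ", sv)
  local <- rearrangement(spec$kind, spec$breakpoints - locus$region$start,
                         payload_length = if (spec$kind == "insertion")
                           spec$payload_length else NULL)
  build_segment_map(L, local)
}

# viewpoint or window entry -> gi in absolute coordinates
locus_interval <- function(locus, x) {
  if (is_gi(x)) return(x)
  gi(locus$region$chrom, x[1], x[2])
}
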