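---
title: "chicsv: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chicsv: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`chicsv` implements the locus-scale computations needed to interpret
capture Hi-C (cHi-C) maps of structural-variant (SV) alleles:

1. **Contact-map construction and normalization** — binning of
   fragment-resolved read pairs into a symmetric matrix over the capture
   region, matrix balancing to equal row sums (the KR contract), and
   copy-number-aware iterative correction (LOIC) that deliberately
   *retains* the coverage footprint of a duplication.
2. **Subtraction maps** — pairwise comparison of two normalized maps
   after matching their distance-dependent signal decay sub-diagonal by
   sub-diagonal, with rearranged regions excluded from scaling-factor
   computation.
3. **Virtual 4C** — one-dimensional viewpoint interaction profiles
   derived from the same pairs: per-fragment counting, 1 kb binning
   with proportional spreading, 5 kb sliding-window smoothing, and
   scaling to a fixed enriched-region total, plus windowed
   integrated-signal quantification and replicate merging.
4. **A synthetic contact-data engine** — a generative model of a two-TAD
   regulatory locus at restriction-fragment granularity, an explicit
   segment-map algebra for tandem duplications, inversions, deletions
   and knock-in insertions, and projection of rearranged-genome contacts
   back to reference coordinates, emulating what a reference-only read
   mapper produces.

The synthetic engine is first-class, tested code: it supplies every
downstream operation with realistic input whose ground truth is known,
so the analysis contracts can be verified quantitatively.

## The model locus

The default locus mirrors a well-studied limb-malformation region: a
~2 Mb capture interval (printed as `chr19:44,440,001-46,400,000`)
containing two TADs of 700 kb each.  The centromeric TAD holds the
muscle gene *Lbx1* and *Btrc*; the telomeric TAD holds *Fgf8*, with a
40 kb cluster of AER (apical ectodermal ridge) enhancers located in the
introns of *Fbxw4*, close to the TAD boundary.  The two TADs are
separated by a divergent-CTCF boundary that is partially permeable
("leaky"), and additionally connected by a larger loop between the
outer convergent CTCF pair.

The named SV alleles reproduce the geometry described for this class of
locus:

* `dup` — a 540 kb direct tandem duplication spanning *Lbx1*, *Btrc*,
  the boundary and the enhancer cluster while excluding *Fgf8*.  In the
  rearranged allele a **neo-TAD** forms between the two boundary
  copies; the enhancer cluster of the first copy sits ~140 kb from the
  *Lbx1* copy that follows it (versus ~380 kb in the reference), the
  configuration that drives ectopic enhancer–promoter contact.
* `inv1` — a 600 kb inversion whose centromeric breakpoint lies close
  to the boundary; the inversion carries boundary and enhancers to the
  other side, enlarging the *Lbx1* TAD, shrinking the *Fgf8* TAD and
  isolating *Fgf8* from its AER enhancers.
* `inv2` — a larger inversion additionally containing *Btrc*.
* `ki` — a 6,993 bp enhancer-cassette insertion in the *Lbx1* TAD,
  modeled as non-reference payload sequence.

Published work on such loci gives figure-level schematics but not exact
animal-model breakpoint coordinates, so breakpoints here are free
configuration values; the defaults were chosen once to reproduce the
qualitative geometry above and are not tuned afterwards.

The reference sequence is uniform random DNA from a fixed seed
(`locus_seed`, default 1903).  Uniform random sequence contains the
DpnII motif GATC every 256 bp on average, giving ~7,700 restriction
fragments over the capture interval — the right granularity for
fragment-level simulation without planting cut sites by hand.  GATC is
palindromic, so in-silico digestion is consistent through inversions.

## The generative contact model

The expected contact weight between two loci with midpoints $m_i, m_j$
is

$$ w_{ij} \;=\; (|m_i - m_j| + 1)^{-\alpha}\; \cdot\;
   \tau\,\lambda^{\,k(i,j)}\; \cdot\; \Bigl(1 + \sum_{\ell}
   s_\ell\, e^{-\bigl((m_i-a_\ell)^2 + (m_j-b_\ell)^2\bigr)/2\sigma_\ell^2}\Bigr) $$

with distance-decay exponent $\alpha$, within-TAD boost $\tau$,
boundary leakiness $\lambda$, $k(i,j)$ the number of TAD boundaries
between the two loci, and Gaussian loop bumps of strength $s_\ell$ and
width $\sigma_\ell$ anchored at convergent CTCF pairs $(a_\ell,
b_\ell)$ (symmetrized over anchor order; support truncated at
$6\sigma$, where the bump is below $10^{-15}$).

Parameter defaults, with units:

| parameter | default | unit | rationale |
|---|---|---|---|
| `alpha` | 1.0 | – | canonical contact-decay exponent at the sub-megabase scale |
| `tad_boost` | 3.0 | fold | within-TAD enrichment typical of strong domains |
| `leakiness` | 0.3 | fold/boundary | partial boundary permeability; crossing *k* boundaries multiplies the TAD factor by `leakiness^k` |
| `loop_strength` | 1.0 | fold at center | doubles contact at the loop anchor pair |
| `loop_width` | 10,000 | bp (Gaussian sd) | anchor peak size at fragment resolution |
| `n_pairs` | 5×10⁵ | pairs | locus-scale depth that keeps simulations desk-fast while giving stable 5 kb maps |
| `p_highq` / `mapq_high` / `mapq_low` | 0.9 / 60 / 10 | – | two-point MAPQ distribution so the MAPQ ≥ 30 filter is exercised |

Three conventions are worth stating explicitly:

* **Distance is measured in base pairs**, also in the bin-level
  expected matrix, so fragment-level and bin-level evaluations of the
  model agree; at bin distances ≥ 1 the binned decay is
  indistinguishable from a bin-index power law.
* With `tad_boost = 1` *and* `leakiness = 1` the model is a pure power
  law; the leakiness factor applies per boundary crossing regardless of
  the boost, following the model formula literally.
* **Same-fragment pairs are excluded** from sampling (weight 0 on the
  diagonal), mirroring the removal of self-ligation artefacts by Hi-C
  pair filters.  The bin-level expected matrix keeps its diagonal.

Loops attach only to convergent (`+` upstream of `-`) CTCF pairs taken
from the annotation.  On a rearranged genome the annotation — boundary
positions and CTCF sites with orientation — is carried through the
segment map first; TAD membership and convergence are then *recomputed*
on the rearranged allele.  This is what makes the neo-TAD stripe, the
inversion bow-tie and enhancer repositioning emerge from the geometry
instead of being painted onto the expected matrix.  The relative
strength of the large inter-TAD loop is not separately configured: it
arises from the convergent outer CTCF pair and is attenuated by the
boundary-crossing factor like any other cross-boundary contact.

### Sampling and projection

Fragment pairs are drawn from an exact multinomial over all
upper-triangular fragment pairs, decomposed into a chain of binomials
across row blocks so the full weight matrix is never materialized.
Each end is then placed uniformly within its fragment and assigned a
MAPQ value.  Everything is reproducible from a single integer seed.

Projection maps every end through the segment map: forward segments map
by offset, reversed segments mirror, and ends in knock-in payload are
dropped — the behavior of a reference-only mapper confronted with novel
sequence.  Both copies of a duplicated segment project onto the same
reference interval (no allele tagging), which is precisely why a
duplication shows doubled coverage and a neo-TAD stripe in reference
coordinates.

## Normalization

`kr_balance()` and `loic_normalize()` share one core: symmetric
iterative proportional fitting towards a target marginal, updating
$b_i \leftarrow b_i / \sqrt{r_i}$ with $r_i$ the ratio of the current
row sum to its target.  The balanced-map contract is the postcondition
— valid-row sums equal (KR) or proportional to the per-bin copy number
(LOIC) within `tol` — not a particular inner iteration; a Newton-based
KR solver would satisfy the same contract.  Defaults: `tol = 1e-6`,
`max_iter = 1000`.  On non-convergence the best iterate is returned
with a warning and the residual recorded.  Output keeps the total
count scale of the input, a choice that makes raw and balanced maps
directly comparable; all downstream scaling is explicit.

Low-coverage bins are masked before balancing when their raw marginal
falls below 10% of the median positive marginal (`min_frac = 0.1`).  A
relative rule generalizes the ad hoc removal of a handful of
low-coverage rows that locus-specific analyses typically apply; it is
monotone in the threshold, so tightening it never unmasks a bin.  The
last bin of the grid may be truncated by the region edge; marginals are
not length-corrected, matching standard practice.

The copy-number track for LOIC assigns `base_cn × max(per-base copy)`
to each bin — 4 for every bin overlapping the duplication by at least
1 bp and 2 elsewhere in the diploid default, the assignment used for
duplication alleles in practice.

## Subtraction maps

Sub-diagonal sums are computed over the **full symmetric matrix** (both
triangles; off-diagonal distances count each unordered pair twice).
Any consistent convention cancels in the joint factors $m(d)/s_X(d)$;
this one is declared and pinned by enumeration tests.  Entries on
diagonals empty in a map are set to zero rather than propagating
division by zero, and masked bins enter the scaled output as zeros, so
subtraction maps never contain non-finite values.

Exclusion semantics follow the stated procedure exactly: intervals
covering the rearrangement are excluded from the computation of both
the per-diagonal and the global `1e6/total` factors (a bin is excluded
if it overlaps an excluded interval by ≥ 1 bp), but the factors are
applied to *every* entry, so the excluded neighborhood remains visible
in the subtraction map.  Consequently the non-excluded total of each
scaled map is exactly 10⁶ and their non-excluded per-diagonal sums
match.

Orientation is mutant − wild-type, so gained contacts are positive;
the orientation is recorded in the object.  Heatmap rendering clips at
the 99th percentile by default (signed maps clip symmetrically on
absolute values) — a display choice that never feeds back into any
computation.

## Virtual 4C

The stage order is fixed: count → bin → smooth → scale, and the scaling
denominator is computed on the *smoothed* values.  Decisions on points
the procedure leaves open:

* A pair qualifies when exactly one **end position** lies in the
  viewpoint interval (the test uses the position, not its fragment);
  the distal end is assigned to its containing fragment.  Fragments
  overlapping the viewpoint carry no counts — a pair whose distal end
  falls in such a fragment is not counted as qualifying, which keeps
  the conservation identity (binned sum = qualifying pairs) exact.
* The smoothing window is **centered**, an odd multiple of the grid
  (default 5 bins = 5 kb), with shrinking windows at the edges.
* The **enriched region defaults to the capture region** and is
  exposed as a parameter; bins partially overlapping it contribute
  their full value to the scaling sum (bp-prorated contribution is
  available behind `prorate = TRUE`).
* Viewpoint bins are scaled like all others, never zeroed; suppressing
  the viewpoint is a rendering concern.
* Default viewpoints are gene-body intervals (5–6 kb), wide enough to
  collect a stable number of qualifying pairs at desk-scale depth.

Integrated signal sums the scaled profile over a window (125 kb over
the enhancer cluster in the default configuration), weighting partial
bins by overlap fraction.  Replicate merging is the per-bin arithmetic
mean; because each replicate sums to 10³ over the eligible bins, so
does the merge.

## What the simulation does and does not establish

The generator emulates: power-law decay, TAD structure with leaky
boundaries, CTCF-anchored loops, restriction-fragment granularity,
MAPQ filtering, copy-number effects of duplications, bow-tie geometry
of inversions, payload loss of knock-ins, and reference-projection
ambiguity of duplicated sequence.  It deliberately omits:
sequence-level read simulation, duplicate reads, trans contacts,
capture-efficiency and GC bias fields, genotype mixtures
(heterozygosity), and cell-population heterogeneity.  Passing tests
therefore demonstrate that the *computations* implement their contracts
and that SV signatures of the modeled kind are recovered end to end;
they do not calibrate biological effect sizes, which in real data
depend on the omitted factors.

## Problem sizes and numerical checks

The shipped checks run at sizes chosen to exercise the full-size locus
while staying desk-fast: unit tests use a 200 kb miniature of the
locus; the end-to-end checks use the full ~2 Mb locus at 5×10⁵ pairs
per genotype, five seeds per sign test (5/5 successes correspond to a
one-sided sign-test p = 2⁻⁵ < 0.05), and 10⁶ pairs for decay-exponent
recovery (recovered within ±0.1 of the generating α).  Scaling
constants (10³ profile total, 10⁶ map total) are verified to 10⁻⁹
relative; balancing contracts to coefficients of variation below 10⁻⁶;
text round trips to 10⁻¹² or exactly.

## Known limitations

* The balancing core is plain iterative proportional fitting; for
  matrices with pathological sparsity patterns a Newton-based solver
  would converge faster (the iteration cap and residual reporting
  guard against silent failure).
* Segment maps compose single rearrangements; compound alleles (e.g.
  an inversion carrying an internal deletion) can be expressed by
  constructing the segment table directly but have no named
  constructor.
* The simulated genome is a single chromosome: no trans contacts, no
  genome-wide background.
* Virtual-4C profiles are computed from contact pairs only; real
  4C-seq read processing (primer trimming, self-ligation artefacts) is
  out of scope.
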