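# chicsv

Locus-scale capture Hi-C (cHi-C) analysis around structural variants
(SVs), for researchers studying how duplications, inversions and
insertions rewire chromatin contacts and enhancer–promoter
communication at disease loci.

Rearranged alleles confound the two standard questions asked of a cHi-C
map — *where did contacts change?* and *is coverage consistent with
copy number?* — because matrix balancing erases copy-number footprints
and because two maps cannot be subtracted until their
distance-dependent decay is matched. `chicsv` implements the analysis
toolkit for this setting:

* **Contact maps** — binning of fragment-resolved pairs (MAPQ ≥ 30 on
  both ends) into symmetric 5 kb matrices; balancing to equal row sums
  (`kr_balance()`, the Knight–Ruiz contract: find positive `b` with
  `diag(b)·M·diag(b)` having constant row sums); copy-number-aware
  iterative correction (`loic_normalize()`) whose target marginals are
  proportional to a per-bin copy-number track (4 over a duplication,
  2 elsewhere), so the duplication's doubled signal is retained rather
  than balanced away.
* **Subtraction maps** — the entries of each sub-diagonal `d = |i−j|`
  of a map are divided by that sub-diagonal's sum and multiplied by the
  average of the two maps' sums, then each map is scaled by
  `10⁶ / total`; rearranged regions are excluded from all factor
  computations but remain present in the output. Subtraction is mutant
  − wild-type, so gains are positive.
* **Virtual 4C** — viewpoint profiles built per restriction fragment,
  binned to a 1 kb grid with proportional spreading, smoothed in a 5 kb
  sliding window, scaled by `10³ / sum` over the enriched region
  (viewpoint ± 5 kb excluded from the factor), with windowed integrated
  signal and replicate merging.
* **Synthetic contact engine** — a generative model
  `w ∝ (d+1)^−α · τ·λ^k · (1 + loop bumps)` of a two-TAD locus with
  CTCF-anchored loops at restriction-fragment (DpnII/GATC) granularity;
  SVs are expressed as segment maps (ordered, oriented reference
  segments), simulated on the rearranged genome and projected back to
  reference coordinates the way a reference-only mapper would, with
  knock-in payload contacts dropped as unmappable.

## Worked example

Simulate a wild-type and a tandem-duplication allele of the model locus
at matched depth, compare their balanced maps, and quantify enhancer
contact gain from the *Lbx1* viewpoint:

```r
library(chicsv)
locus <- model_locus()
locus
#> <locus model> chr19:44,440,001-46,400,000
#>   7692 GATC fragments; 3 TAD boundaries; 6 CTCF sites; SVs: dup, inv1, inv2, ki

params <- contact_params(n_pairs = 5e5)
wt  <- simulate_contacts(locus, "wildtype", params, seed = 1)
dup <- simulate_contacts(locus, "dup",      params, seed = 2)

m_wt  <- kr_balance(bin_pairs(wt$pairs,  locus$region))$map
m_dup <- kr_balance(bin_pairs(dup$pairs, locus$region))$map

dup_region <- gi("chr19", 45020000, 45560000)
scaled <- joint_distance_scale(m_dup, m_wt, exclude = dup_region)
sub <- subtract_maps(scaled$a, scaled$b, excluded = dup_region)

enhancers <- gi("chr19", 45455000, 45580000)   # 125 kb enhancer window
lbx1_tad  <- gi("chr19", 44700000, 45400000)
round(block_mean(sub, enhancers, lbx1_tad), 3)
#> [1] 1.721

vp <- gi("chr19", 45100000, 45105000)          # Lbx1 viewpoint
prof_wt  <- virtual4c(wt$pairs,  vp, locus$rm)
prof_dup <- virtual4c(dup$pairs, vp, locus$rm)
round(c(wildtype = integrate_signal(prof_wt,  enhancers),
        dup      = integrate_signal(prof_dup, enhancers)), 2)
#> wildtype      dup
#>     8.89    66.06
```

The positive block mean (`1.721`, on the jointly scaled 10⁶-total
scale) says the duplication *gains* contacts between the enhancer
window and the *Lbx1* TAD even after KR balancing has removed the raw
copy-number effect — the neo-TAD signature. The integrated virtual-4C
signal (profile units: each profile sums to 10³ over the enriched
region) rises from 8.9 to 66.1, a direct readout of enhancer
repositioning toward *Lbx1*.

The copy-number footprint itself is preserved by LOIC:

```r
cn <- copy_number_bins(dup$segment_map, 392, 5000)  # 4 over the dup, 2 elsewhere
loic <- loic_normalize(bin_pairs(dup$pairs, locus$region), cn)$map
v <- loic$valid
marg <- rowSums(loic$matrix[v, v])
round(mean(marg[cn[v] == 4]) / mean(marg[cn[v] == 2]), 4)
#> [1] 2
```

`simulate_dataset()` and `run_pipeline()` wrap this workflow with
text-file outputs (pairs TSV, COO/dense matrices, bedGraph tracks,
integrated-signal TSV, JSON truth sidecars), configured by a YAML file
(`default_run_config()`); a thin command-line wrapper lives at
`inst/cli/chicsv.R`. The methods vignette
(`vignettes/chicsv-methods.Rmd`) documents the model, parameters and
design decisions.

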