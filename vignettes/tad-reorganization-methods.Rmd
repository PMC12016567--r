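---
title: "Methods: detecting TAD reorganization and CTCF-mediated enhancer-gene rewiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting TAD reorganization and CTCF-mediated enhancer-gene rewiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadreorg)
```

# The problem

Topologically associating domains (TADs) partition mammalian chromosomes
into self-interacting blocks, typically 200 kb to 1 Mb, whose boundaries
are enriched for CTCF. When a boundary appears, disappears or moves
between two cellular states, enhancers and promoters can change TAD
co-membership, and with it their ability to form regulatory loops. This
package identifies genes whose expression change between two conditions
co-occurs with such a CTCF-supported boundary alteration, and classifies
each candidate enhancer-gene pair as *intra-TAD* (mechanism 1: a proximal
loop is cut or restored by a boundary between enhancer and promoter) or
*inter-TAD* (mechanism 2: fusion or separation moves the enhancer into or
out of the promoter's TAD).

All coordinates are 0-based half-open (BED convention); GTF input is
shifted on read. Chromosome names are taken verbatim, with an optional
`chr`-prefix harmonization flag, because public peak sets mix conventions.

# Directionality index and TAD calling

For each 40-kb bin the upstream flank sum $A$ (bins $[i-w, i)$),
downstream sum $B$ (bins $(i, i+w]$, $w$ = 2 Mb / bin width) and
$E = (A+B)/2$ give

$$\mathrm{DI}_i = \mathrm{sign}(B-A)\left[\frac{(A-E)^2}{E} +
\frac{(B-E)^2}{E}\right],$$

a signed chi-square-like contrast that is strongly positive at TAD starts
and strongly negative at TAD ends. Flanks are truncated at chromosome
edges; $\mathrm{DI}=0$ when $A+B=0$. DI scales linearly under count
scaling, so TAD calls are invariant to sequencing depth rescaling.

Segmentation uses a deterministic run automaton rather than an HMM: bins
are labeled downstream-biased ($\mathrm{DI} \ge t$), upstream-biased
($\mathrm{DI} \le -t$) or neutral with $t = t_{sd}\cdot
\mathrm{SD}(\mathrm{DI} \ne 0)$ per chromosome ($t_{sd} = 0.5$); a TAD
runs from the first bin of a downstream-biased run to the last bin of the
next upstream-biased run; TADs under `min_size_bins` (3 bins = 120 kb;
a 5-bin option matches the conventional 200-kb lower bound for TADs) are
dropped. We chose the automaton because it is reproducible,
parameter-light, and directly checkable against planted truth; its
per-chromosome SD threshold is the one scale-free choice that keeps calls
invariant under depth scaling. Boundaries are bins: each TAD contributes
its start bin and last inside bin, and adjacent TADs share the junction
boundary.

Within ~2 Mb of chromosome ends the truncated flank biases DI (the first
TAD start is still found, but sub-scale boundaries there are unreliable);
the simulator therefore keeps planted events away from edges.

# Cross-condition comparison

Boundary sets are matched greedily, closest pairs first, within
`tol_bins` (default 1 bin = 40 kb; the matching tolerance is not stated in
the source descriptions of boundary sharing, so it is config-exposed).
Unmatched boundaries are gained/lost. Reorganization typing:

- **separation** — a condition-1 TAD reciprocally overlapping (>= 0.8)
  the union span of >= 2 condition-2 TADs, with a gained boundary strictly
  inside;
- **fusion** — the mirror case;
- **shift** — boundaries matched at distance in (`tol_bins`, `shift_max`]
  (default 5 bins) whose flanking TADs keep their outer edges, matched
  within the same `shift_max` radius — the outer edges are themselves
  boundary calls carrying calling noise, so holding them to the 1-bin
  tolerance would veto genuine shifts. Beyond `shift_max` a moved boundary
  is treated as an independent gain plus loss.

Swapping the two conditions maps fusion to separation and preserves
shifts; this duality is tested.

# A/B compartments

At 100 kb, each chromosome's matrix is smoothed with a truncated
box mean (half-span $h = 1$; the window mean divides by the number of
*available* cells so constant matrices are fixed points), transformed to
observed/expected by diagonal means, restricted to bins with nonzero raw
coverage, and converted to a Pearson correlation matrix with the main
diagonal excluded (the self-correlation diagonal otherwise dominates).
The eigenvector of the largest-magnitude eigenvalue scores bins; because
an eigenvector is defined only up to sign, the sign is fixed by requiring
the positive class to have the higher mean gene density (GC content is the
alternative basis). A-labels are positive scores, B negative; bins without
coverage are NA and break compartment segments. TAD-level labels take the
overlap-weighted mean score over 100-kb bins, with an exact zero mean
giving NA.

# Significant interactions

At 10-kb resolution, cis bin pairs at distance >= 2 bins (adjacent bins
are dominated by self-ligation artifacts) are partitioned into up to 100
equal-occupancy distance strata — contiguous distance ranges carrying
approximately equal total counts, so every stratum's expectation is
estimated from comparable evidence. A stratum's expected contact
probability is its count sum over (possible pairs x total cis reads); each
tested pair (count >= 1) gets an upper-tail binomial p-value and
Benjamini-Hochberg q-value over all tested pairs (zero-count pairs enter
the stratum pair totals but not the BH family — this choice changes the BH
denominator and is therefore documented). Retention requires read count
> 2 and, jointly, p <= 0.01 and q <= 0.01. Trans pairs use a single
uniform expectation of one over the number of possible inter-chromosomal
bin pairs. The binomial model with equal-occupancy strata is the standard
simplification of spline-refined distance models; calibration under the
stratum-uniform null is part of the test suite.

# Expression

TMM normalization and the negative-binomial exact test are delegated to
edgeR (`calcNormFactors`, `exactTest`); the unit tests check the TMM
factors against an independently hand-coded implementation of the
double-trimmed weighted-mean rule. Because the design has one library per
condition there is no replicate structure to estimate dispersions from, so
the exact test runs at a fixed dispersion (default 0.1, config-exposed;
pre-computed DE tables can be supplied instead). RPKM uses
$10^9 \cdot \mathrm{count} / (\mathrm{effective\ library} \cdot
\mathrm{exonic\ length})$ with TMM-scaled effective libraries and
union-exon lengths. The low-abundance rule is literal — RPKM < 1 in *at
least one* sample flags the gene — with an `all_samples` alternative
because the literal rule removes genuinely on/off genes. Differential
flags require FDR < 0.05 and linear fold change >= 2 in either direction.

# Pair classification

Step 1 retains boundary alterations co-occurring with condition-specific
CTCF: a gained boundary needs a condition-2 CTCF peak with no condition-1
peak within `tol_bp` (default one 40-kb bin) overlapping the boundary
within the same tolerance; lost boundaries mirror this. Presence/absence
overlap is used rather than differential binding because the two CTCF sets
typically come from different sources and are not quantitatively
comparable.

Step 2 keeps genes that are differential, whose promoter (TSS ± 2 kb, a
standard default) lies within 1 Mb of an event (the search radius is not
stated in the source description of "located around" and is
config-exposed), and whose promoter overlaps an ATAC peak in *both*
conditions. The consistent-accessibility wording is ambiguous between
"filtered out" and "retained"; we retain, matching the pair criteria's
requirement that sites be accessible in both cases. "Top" differential
genes are all genes passing the stated thresholds, since no ranking or N
is defined.

Step 3 emits pairs for both-condition-accessible, promoter-distal ATAC
peaks (distance measured TSS to peak midpoint; absolute distance by
default, since the validated example enhancers sit downstream of their
promoters despite "upstream" wording — a strict strand-aware switch
exists):

- **mechanism 1** (distance < 20 kb): an event boundary must lie between
  peak and TSS. Boundaries are bins, so betweenness is assessed on bin
  indices with the same ±1-bin slack used for boundary matching.
  Direction: boundary gained ∧ gene down → deactivation; lost ∧ up →
  activation.
- **mechanism 2** (distance < 100 kb): peak and TSS must share a TAD in
  exactly one condition, with an associated event boundary in the peak-TSS
  window. The printed direction rule (gained → activation, lost →
  deactivation; preset `novel_boundary_activates`) conflicts with the
  fusion-driven activation case study, where a *lost* boundary activates
  the gene; both presets ship
  (`novel_boundary_insulates` swaps the directions) and the printed rule
  is the default rather than guessing intent.

Roles are labels, not biological assertions: up-regulated in condition 2 →
oncogene candidate, down-regulated → suppressor candidate. Output order is
deterministic (gene, mechanism, distance), and the suite verifies equality
with an independent brute-force filter over the full gene × peak × event
cross product, plus the condition-swap duality (roles, directions and
event changes all invert).

# The synthetic-data generator

The generator emulates the data regime the pipeline targets: per
chromosome, expected counts decay as $(d+1)^{-\alpha}$ ($\alpha = 1$)
times a within-TAD enrichment (3), scaled to 1e5 cis pairs per 20-Mb
chromosome, with independent Poisson draws; RNA counts are negative
binomial (dispersion 0.1) with planted fold changes; CTCF peaks sit at
every boundary of each condition's layout; ATAC promoter peaks exist in
both conditions and enhancer peaks follow each planted pair's geometry.
Decoys violate exactly one criterion each (distance, accessibility,
differential status, direction) so a classifier failure localizes the
broken rule. Everything is a deterministic function of the scenario and
seed, and written files are byte-stable.

Design choices worth stating:

- The condition-1 layout cycles TAD sizes 10, 17, 8, 18, 11, 9, 17, 12
  bins (400-720 kb, mean ~510 kb, inside the conventional 200 kb - 1 Mb
  range). Planted separations split the 17-18-bin TADs at their midpoints
  and fusions merge ~20-bin TAD pairs, so each altered boundary flanks
  domains large enough for the DI automaton to resolve at the default
  depth; events sit at least 6 bins apart (12 in the auto-assigned event
  scenarios) and away from chromosome edges.
- Planted fold change defaults to 8. With one library per condition the
  log fold-change standard deviation at dispersion 0.1 is ~0.65, so
  4-fold changes are detected unreliably while 8-fold changes are
  recovered with high sensitivity — the same magnitude the expression
  test bench uses.
- Null-gene promoters stay >= 250 kb from event anchors: planted TSSs sit
  up to 70 kb from their anchor and mechanism 2 scans 100 kb, so closer
  background promoters could masquerade as enhancer peaks.

What the simulator does *not* emulate: ICE-style balancing artifacts,
fragment-level biases, replicate structure, peak-width and signal
heterogeneity, compartment-level plaid structure overlaid on TADs, or
sequence context (the FASTA helper used in GC tests is synthetic). Passing
tests therefore demonstrate correctness of the algorithms under the stated
generative model, not performance on real tumor genomes, where unstated
parameters of the original analyses (HMM segmentation settings, matching
tolerances, dispersion estimates) additionally prevent exact reproduction
of published counts.

At the default depth the DI automaton recovers ~95-99% of planted
boundaries within ±1 bin, but single events can still be missed through
calling noise (a spurious boundary inside a fused domain, a weak run at a
new boundary). Event *typing* among recovered events is essentially
perfect; event *detection* recall is the binding constraint, which is why
the acceptance checks separate the two.

# Numerical choices and degenerate inputs

- Smoothing windows truncate at matrix edges and divide by available
  cells; constant matrices are exact fixed points.
- Observed/expected returns 0 on zero-mean diagonals; empty matrices pass
  through silently.
- Correlation matrices use pairwise-complete observations with the
  diagonal removed; residual NAs (zero-variance columns) become 0 before
  the symmetric eigendecomposition.
- Eigenvalue selection is by largest magnitude; ties resolve to the first
  index, which the sign orientation then fixes.
- A TAD compartment mean of exactly 0, an all-zero DI chromosome, a
  chromosome with < 3 covered bins, and an all-N interval all yield NA (or
  an empty result) with a warning rather than an error.
- TMM factors are rescaled to geometric mean exactly 1; a zero library is
  an error.
- `read count > 2` is implemented as `>= 3`, strictly per the printed
  inequality.

# Problem sizes

The test-bench and acceptance computations use two 20-Mb chromosomes at
40-kb bins (500 bins each) for TAD work, 180 bins at 100 kb for
compartments, a 150-bin chromosome at 10 kb (~11,000 tested pairs, ~220
expected reads per pair) for interaction calibration, and 1,050 genes for
the expression bench — sizes chosen so every property is measured on a
few thousand informative units while the full suite stays fast on a
single core.

# Limitations

- The run-based TAD automaton is a deliberate simplification of HMM
  segmentation; hierarchical (subTAD/metaTAD) structure is out of scope.
- Interaction calling uses the binomial equal-occupancy model, not
  spline-refined variants; loop calling is out of scope.
- Fixed-dispersion exact tests cannot model replicate variability; with
  replicates available, an external DE table is the better input.
- The mechanism-2 direction presets encode a genuine ambiguity in the
  source pipeline description; conclusions about activation vs.
  deactivation under mechanism 2 depend on the chosen preset.
- `.cool` input is not supported (no HDF5 reader dependency); HiC-Pro
  triplet + bins BED is the supported matrix format.
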