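---
title: "Reconstructing core regulatory networks from multi-omics evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing core regulatory networks from multi-omics evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coregrn)
```

## The model

A cellular phenotype is assumed to be maintained by a small core of
transcription factors: *identity TFs*, whose expression is highly specific
to the phenotype, plus *co-factors*, which are more broadly expressed but
still significantly more specific to the phenotype than expected.
`coregrn` reconstructs the directed regulatory network among these TFs by
requiring every edge to be grounded in physical evidence: a ChIP-seq
binding event of the source TF inside an accessible, epigenetically active
regulatory region of the target TF.

The pipeline's four stages and the reasoning behind them:

1. **Background atlas.** Specificity is only meaningful against a broad,
   non-redundant background. Libraries below 15,000 total counts are
   removed (too shallow for a stable expression profile), single-cell
   experiments are removed (sparsity would distort the per-gene
   distributions), and polyA and total RNA libraries are kept separate
   because their gene coverage differs systematically. Redundancy is
   removed greedily: a seeded random order is fixed, the first sample is
   kept, and each following sample is kept only if its Pearson correlation
   with *every* kept sample is below `r_max = 0.7`. Correlation is
   computed on the raw count scale, since selection precedes the TPM
   transform in the stage order; the greedy pass runs before
   normalisation so that redundant resequencing of the same material is
   removed on the scale on which it is most visible.

2. **Specificity.** For each TF we compare two distributions over the
   `N + 1` sample positions: the idealised profile `P` (all mass on the
   query) and the observed profile `Q` (TPM values scaled to sum to one).
   Their Jensen–Shannon divergence with base-2 logarithms is bounded in
   [0, 1] bits, is 0 iff the TF is expressed only in the query, and 1 for
   a TF not expressed in the query at all. The 10 lowest-JSD TFs are the
   identity TFs (`n_top = 10`). Co-factor detection asks a different
   question — is this TF *more* specific than a typical background sample
   would be? — answered by ranking the query's JSD within the
   leave-one-out pseudo-query JSDs of the background and z-scoring the
   rank against the uniform-rank moments, mean `(N+1)/2` and SD
   `sqrt((N^2-1)/12)`. TFs with `z < -1.5` (strict) are co-factors;
   identity and co-factor are disjoint roles by construction.

3. **Regulatory regions.** Promoter windows are `up = 1500` bp upstream
   to `down = 500` bp downstream of the TSS, strand-aware, with the TSS
   base counted as the first downstream base; windows are clipped at the
   chromosome start. Activity calls use plain ≥ 1 bp overlap: H3K4me3 for
   promoters, H3K27ac for enhancers. Enhancers are evaluated only for TFs
   that already have an active promoter, and active enhancers are
   truncated to their intersections with the overlapping H3K27ac peaks —
   intersections rather than raw peak coordinates, so truncated intervals
   can never extend beyond the annotated enhancer. DNase peaks intersected
   with active region intervals yield the accessible sites; a region
   without accessible sites is kept but can support no edges.

4. **Network.** Edges require a source ChIP-seq peak overlapping an
   accessible site of the target by at least one base. Containment of the
   peak in the site is deliberately *not* required: peaks routinely
   straddle site borders, and demanding containment would discard exactly
   the strong, wide binding events. Self-edges (autoregulation) are
   permitted. The co-factor connectivity rule — each co-factor must
   regulate and be regulated by at least one identity TF — is iterated to
   a fixpoint, because removing one co-factor can strip another of its
   only qualifying partner; a single pass would leave the stated invariant
   violated. The fixpoint is unique (removal conditions are monotone), so
   the result is independent of input order.

## Cooperative vs competitive binding

Within one regulatory region, two bound TFs are *cooperative* when (i)
their supporting peaks reciprocally overlap by at least `ro_min = 0.62`
— `min(shared/width_a, shared/width_b)`, a symmetric stringency that a
small peak inside a broad domain cannot satisfy — and (ii) a
protein–protein interaction with confidence strictly above
`ppi_min = 800` (on the STRING 0–1000 scale) links them. Connected
components of the resulting per-region graph with ≥ 2 members are the
cooperative complexes, so cooperativity is transitive through shared
partners within a region. TFs whose peaks overlap another TF's peaks but
who join no component are *competitive* (contending for the same site);
PPI evidence is not required for the competitive call. A pair may be
cooperative in one region and competitive in another; the classification
is strictly per region.

`calibrate_overlap_threshold()` re-derives the overlap cutoff from
labelled interacting / non-interacting TF pairs. Among several defensible
estimators for "the overlap above which a pair is more likely to interact
than not", we use a density comparison: the threshold is the smallest
observed overlap value from which, at every observed value upward, the
class-normalised frequency of positives strictly exceeds that of
negatives. A cumulative-tail comparison was considered and rejected: with
well-separated classes it can return a value deep inside the negative
support (any point above which the positive tail fraction merely stays
ahead), while the density reading returns the lowest overlap actually
characteristic of interacting pairs and errors out when the two samples
are not separable.

## Numerical choices and degenerate inputs

* All coordinates are handled internally as `GRanges`; every
  BED-convention input (0-based half-open) is converted on read and back
  on write, so a single convention holds across all seven input formats.
  Chromosome names are matched as exact strings — no `chr1`/`1` aliasing —
  with a preflight warning when two sets share no names.
* `0 * log2(0) := 0` in all entropies; computed JSD is clamped to [0, 1]
  against floating-point drift. A TF with zero expression in query and
  background returns JSD 1 (maximally non-specific) rather than NaN.
* Pearson correlation with a zero-variance sample is defined as 0, so a
  constant column can never block the greedy decorrelation pass.
* The query's rank is `1 +` (background JSDs strictly below), clamped to
  `[1, N]` so the z-score stays on the background rank scale even when
  the query exceeds every pseudo-query.
* Identity-TF selection breaks JSD ties lexicographically by TF symbol,
  making the call deterministic.
* TPM of an all-zero library is all-zero (the per-million invariant has
  this one documented exception) instead of dividing by zero.
* All output tables are sorted (nodes by role then symbol; edges by
  source, target, region, peak) so that identical runs are byte-identical.

## The synthetic data generator

`generate_bundle()` writes every input the pipeline consumes around a
planted truth, with defaults of 200 TFs, 50 background samples, 10
identity TFs and 5 co-factors, and all noise rates 0 — so the default
bundle is exactly recoverable and the deterministic checks are separated
from the stochastic ones.

What it emulates: identity TFs expressed only in the query (high query
counts, zero background); co-factors expressed in the query and a ~10%
minority of background samples, a regime that places their query JSD at
rank 1 and hence their rank z below −1.5 at the default background size;
broadly expressed non-core TFs with log-normal counts (log-normal mean
scaled so every library clears the 15,000-count filter); gene loci spaced
100 kb apart on two chromosomes; H3K4me3 over each candidate promoter;
one or two enhancers per candidate TF with H3K27ac over their core (so
most TFs carry one or two enhancers, as in real reconstructions);
DNase sites inside each active region; ChIP-seq peaks placed in disjoint
200-bp slots inside those sites for exactly the planted edges; identical
member peaks plus PPI 900 for planted complexes; an identical-peak pair
with PPI 300 as a planted competitive case; and Hi-C interactions linking
each enhancer to its owner's promoter. Noise knobs independently drop
H3K27ac peaks, add decoy ChIP peaks, perturb counts multiplicatively, and
drop Hi-C interactions.

What it does **not** emulate — and therefore what passing tests do *not*
establish about real data: read-level noise and mapping artefacts; peak
callers' irregular peak shapes and signal-dependent widths; correlated
background structure (tissue families, batch effects) that makes real
decorrelation much more aggressive; enhancers shared between genes;
chromatin contacts beyond direct enhancer–promoter pairs; and genuine
biological ambiguity in TF role assignment. The fixture shows the
algorithm implements its stated rules exactly; accuracy on real atlases
depends on the quality of those inputs.

A deliberate side effect of drawing non-core query expression from the
background distribution: a handful of broadly expressed TFs pass the
z-test by chance (≈ 6% per TF at N = 50). They are planted with no
epigenetic or binding evidence, so the connectivity filter removes them —
which exercises, on every run, exactly the pruning behaviour the filter
exists for.

## Parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `min_counts` | 15000 | counts | library-size floor for background samples |
| `r_max` | 0.7 | Pearson r | decorrelation ceiling (exclusive) |
| `n_top` | 10 | TFs | identity TFs taken from the bottom of the JSD ranking |
| `z_cut` | −1.5 | SD | co-factor rank z threshold (strict) |
| `up`, `down` | 1500, 500 | bp | promoter window around the TSS |
| `ppi_min` | 800 | STRING score | PPI confidence floor (strict) for cooperativity |
| `ro_min` | 0.62 | fraction | reciprocal-overlap floor (inclusive) for cooperativity |
| `seed` | 1 | — | drives the decorrelation visit order |

The defaults are the method's published operating point; `ro_min` accepts
a re-calibrated value (e.g. from `calibrate_overlap_threshold()` on
labelled PPI data) where such data exist. `dnase_required = TRUE` makes
accessibility gating mandatory; `--no-dnase` / `dnase_required = FALSE`
relaxes it for datasets without accessibility tracks, loudly, by treating
every active region interval as accessible.

## Problem sizes used in the test suite

Module tests run on hand-built fixtures and bundles of 40–60 TFs with
20–25 background samples; the end-to-end recovery and stochastic
degradation checks use the full default scale (200 TFs, 50 background
samples) with fixed seeds. At these sizes the complete suite and the
acceptance script each run in well under a minute on a single CPU.

## Known limitations

* Edges are unsigned: activation is not distinguished from repression.
* Binding evidence must come from the supplied ChIP atlas; TFs without
  atlas entries can receive but not emit edges (a warning names them).
* The enhancer–gene assignment is taken from the association table as
  given; chromatin-conformation data are used only for validation, not
  assignment.
* All inputs must share one genome build; no liftover is attempted.
* With small backgrounds (N ≲ 20) the discrete rank z-score is
  conservative: only rank 1 can clear −1.5, so borderline co-factors are
  missed. This is a property of the rank statistic, not of the
  implementation.
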