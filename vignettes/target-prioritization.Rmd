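---
title: "Integrative prioritization of retinoid-responsive transcription factor targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative prioritization of retinoid-responsive transcription factor targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinotarget)
```

## The analysis problem

Tumor-repopulating cells (TRCs) are cancer stem-like cells selected by
growth in soft 3D fibrin gels; in hepatocellular carcinoma they are the
population that drives recurrence and drug resistance. A synthetic retinoid
acting through the retinoic-acid receptor alpha (RAR&alpha;) can
selectively kill TRCs, and the mechanistic question is which RAR&alpha;
target gene mediates that selectivity. The evidence available is
multi-omic: dose-escalation RNA expression in three cell contexts (TRCs,
the parental cancer line, and a normal liver analog), RAR&alpha; ChIP-Seq
binding peaks, an H3K27ac enhancer landscape, a pathway catalog, and
viability plates.

`retinotarget` implements the integration as a reusable, fully testable
pipeline. A candidate driver gene must clear four evidence filters and is
then ranked by four prioritized criteria:

1. **Network degree** - number of co-expression neighbors at
   |Pearson r| > 0.9 and P < 0.05 (degree filter >= 18);
2. **Pathway burden** - number of catalog pathways containing the gene,
   with tumorigenesis-associated pathways (RAS signaling, cell cycle,
   stemness/pluripotency, ubiquitin-mediated proteolysis) counted first;
3. **Binding evidence** - the best promoter peak M-value (filter
   M >= 0.5, P < 0.05);
4. **Dose-response membership** - fuzzy-cluster membership (>= 0.2) in a
   cluster whose centroid decreases with dose in the TRC context.

Because the raw data behind the motivating study are not published at desk
scale, the package ships a synthetic-data generator that emulates every
input with planted ground truth, so each stage - and the full pipeline -
is validated against known answers.

## The synthetic study design

`simulationConfig()` defaults encode the study conditions used by every
benchmark in this package: 200 genes, contexts TRC / parental / normal,
doses 0 / 1 / 5 uM, 3 replicates, 8 planted dose-response patterns, and
additive Gaussian noise with sd 0.05 on the log2 scale (a tight technical
noise level typical of averaged RNA-Seq log-expression in cell lines).

**Pattern templates.** The 8 planted patterns are built from orthonormal
dose contrasts (linear, quadratic, constant) crossed with orthonormal
context contrasts, scaled to a 3-log2-unit amplitude. Orthogonality is a
deliberate design choice: between-pattern expression correlations stay far
below the 0.9 edge threshold, so the planted co-expression cliques are
unambiguous and degree counts are stable. The first three templates are
strictly decreasing with dose in the TRC block (the analogue of the
"down-regulated oncogene" patterns); all remaining templates carry a small
positive dose tilt (0.15 of the linear contrast) in the TRC block so that
no cluster's trend call is ever a coin flip at the planted noise level.

**The planted driver.** One gene follows a decreasing pattern and receives,
by construction, evidence above every default threshold: 25 companion
genes generated as noisy affine copies of its profile (a planted
co-expression clique, so its degree comfortably exceeds 18), membership in
6 pathways of which 4 are oncogenic, and a promoter peak at M = 1.2.
Companions never receive passing promoter peaks; background genes may, at
lower M, which creates realistic competition in the ranking without
ambiguity about the intended winner.

**What the generator does not emulate.** Real read-level noise,
normalization artifacts, batch effects, correlated (rather than
independent) residuals, genome-scale gene counts, multi-chromosome
structure, and the unspecified differential-expression step that produced
the original union gene set. Passing the planted-recovery benchmarks
demonstrates the pipeline's correctness and its behavior under controlled
noise - not performance on genome-scale data.

## Fuzzy c-means choices

Profiles are condition means standardized per gene; standardization uses
the sample (n-1) standard deviation, matching the convention of the Mfuzz
tool family (a population-sd option is provided). Zero-variance genes
cannot be standardized and are excluded into a skip list.

The cluster count defaults to c = 8, mirroring the 8 dose-response
patterns the analysis scheme works with. The fuzzifier defaults to
m = 1.25, a common choice for standardized expression profiles; the
recovery benchmarks are insensitive to m across roughly 1.15-1.5.
Initialization is deterministic farthest-point seeding from the RNG seed
(first centroid a seeded random profile, each next the profile farthest
from those chosen, ties to the lowest row index), so a seed fully
determines the result. Iteration stops when the largest centroid
coordinate shift falls below 1e-6 (default) or after 200 iterations.
Membership rows sum to 1 after every iteration; exact centroid hits get
hard memberships; membership powers are computed on distances divided by
the row minimum to stay in floating-point range at small m.

A cluster is "down-regulated" when its centroid at the highest dose is
below its centroid at dose zero within the TRC context block - the
oncogene rationale concerns the TRC response - with an option to average
the trend over all contexts. Genes are assigned to their argmax-membership
cluster, and the membership filter (>= 0.2, boundary inclusive) applies to
that maximum; a gene is selected when its assigned cluster is
down-regulated.

## Peaks, networks, ranking

Peak filtering uses M >= 0.5 (inclusive) and P < 0.05 (strict); where the
source material is ambiguous between ">= 0.5" and "> 0.5" the inclusive
reading of the stated methods is used. Promoter windows default to 2000 bp
upstream / 500 bp downstream of the TSS, strand-oriented (the
`GenomicRanges::promoters()` construction); a peak overlapping several
windows is assigned to the nearest TSS, with exact ties broken toward the
lexicographically smaller gene id. Candidate genes must carry a
promoter-class peak by default (`anyLocation = TRUE` relaxes this).

The co-expression network is built on log2 expression across *all*
samples (contexts x doses x replicates), which maximizes n for the edge
P-value (t transform on n - 2 df, no multiple-testing correction, matching
the raw-threshold construction). Correlating condition means instead is
available as an option. The four criteria combine as
filters-then-lexicographic-sort in their stated priority order, with
oncogenic pathway count ranking above raw pathway count inside criterion
2, and residual ties broken by gene id so the ranking is a deterministic
total order. The ego network of a gene reuses the main network (induced
subgraph on the gene and its direct neighbors).

## Super-enhancer calling

Regions are optionally stitched (gaps strictly below 12.5 kb merged,
signal summed), ranked by ascending H3K27ac signal, and both axes scaled
to [0, 1]. The cutoff is the point on the scaled curve farthest below the
diagonal - equivalently the slope-1 tangent of the classic rank-ordering
construction - taking the last such point on ties; regions with signal
strictly above the cutoff signal are super-enhancers. Consequences worth
knowing: every super-enhancer's signal strictly exceeds every typical
enhancer's; the call set is invariant under positive rescaling of the
signal; a constant or exactly linear curve yields zero super-enhancers;
and on a background-only landscape with no planted tail the construction
still marks a thin (< 10%) upper fringe of the background, which is the
expected behavior of the tangent construction on a smooth unimodal signal
distribution.

The synthetic landscape draws background signal from a truncated normal
(mean 1, sd 0.3) and the planted tail from 15 + Exponential(mean 10), a
clean hockey stick on which the caller recovers essentially all planted
super-enhancers with at most a handful of false calls.

## Pharmacology

The inhibition rate is the plate formula
(OD~control~ - OD~treated~) / (OD~control~ - OD~blank~) x 100, unclipped
by default. Concentration-response curves are fitted with a symmetric
four-parameter logistic (variable slope), the field-standard model whose
midpoint is the IC50, by Levenberg-Marquardt least squares from a fixed
multi-start grid (hill in {0.5, 1, 1.5, 2.5, 4} x IC50 at the dose
quantiles), keeping the best-SSE fit - deterministic given the data.
Replicates are averaged per dose before fitting, matching plate practice.
Degenerate tables (all responses equal) return a non-converged flag
rather than an error.

Drug interaction uses the Chou-Talalay combination index with the
two-term (mutually nonexclusive-free) formula: median-effect fits
log(fa/(1-fa)) = h(log D - log Dm) for each single agent and for the
fixed-ratio combination treated as a virtual drug on its total dose; CI =
d~A~/Dx~A~ + d~B~/Dx~B~ at the requested effect level (default fa = 0.5,
exposed as a parameter since the appropriate level is assay-dependent).
Self-combination yields CI = 1 exactly, and simulated Loewe-additive
mixtures yield CI = 1 within fitting tolerance, which the test suite
verifies.

The generator's default viability curve (IC50 2.83 uM, hill 1.5) sits in
the potency range reported for TRC-selective retinoids; it calibrates
realistic simulation scales only and is not a reproduction target.

## Numerical and reproducibility notes

* All generators and both clustering and fitting are deterministic given
  their seed; the CLI stages write plain-text outputs with 10 significant
  digits, so identical seeds give byte-identical files.
* Benchmark problem sizes used throughout the package: 200-gene studies
  (100 seeds for recovery rates), 1000-region enhancer landscapes with 50
  planted super-enhancers, and 50 simulated viability curves - all sized
  to run in seconds to a few minutes on a single CPU while keeping the
  planted-recovery statistics stable.
* Known limitations: degree ties inside planted cliques are expected and
  resolved by the pathway criterion; the fuzzifier and cluster count are
  not auto-selected (the analysis scheme fixes c = 8); no multiple-testing
  correction is applied to network edges by design; the combination index
  assumes the median-effect model holds over the observed effect range.
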