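---
title: "Methods: genomic-context discovery of CutF-like copper chaperones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic-context discovery of CutF-like copper chaperones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coppermine)
```

## The discovery model

Small secreted copper chaperones of the CutF type resist enumeration by
pairwise sequence search: at ~118 residues with low conservation, their
BLAST signal drowns quickly. What they do conserve is *context* (a seat in
the gene neighborhood of multicopper-oxidase genes) and *architecture* (a
Sec signal peptide, a central CXXXC-type cysteine pair that can ligate
Cu(1+), and a proline-rich C-terminal tail ending in a PP motif).
`coppermine` operationalizes this as a two-phase procedure:

1. a **high-precision rule filter** over the gene windows of MCO anchors
   produces a seed set;
2. a **high-recall iterative profile-HMM search** over the whole proteome
   set generalizes from the seeds, then prunes anything carrying a known
   Pfam domain, since the family of interest is by construction
   domain-less.

The assumptions are explicit: anchors are identifiable from domain content
alone (PF00394/PF07731); family architecture is invariant enough for the
rule filter to find at least two seeds; and family membership is
recognizable by a profile HMM at an E-value threshold against a
Gumbel-calibrated null. The phases are independently testable, and the
synthetic generator (below) provides the ground truth to test them.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window_radius` | 10 | genes/side | gene-neighborhood convention of genomic-context tools; windows never cross contigs |
| `max_len` | 170 | residues | strict upper bound for "small" candidates (170 itself fails) |
| `motif_patterns` | CXXXC, CXXC | — | the chaperone motif and its one-residue-shorter variation |
| `motif_region` | 0.20–0.80 | fraction of length | the motif is central in known members; terminal cysteine pairs are usually disulfide or metal-site artifacts |
| `domain_evalue_max` | 1e−5 | E-value | ceiling for "matches a known Pfam domain"; applied identically in the filter and the removal rule |
| `evalue_include` | 0.01 | E-value | per-iteration inclusion threshold of the HMM search |
| `max_iter` | 11 | iterations | upper bound on search rounds; convergence is declared when an iteration adds nothing |
| `ssn_score_min` | 100 | raw SW score | edge threshold of the similarity network |
| `collapse_identity` | 90 | % identity | representative collapsing before network construction |
| `bootstrap_reps` | 100 | replicates | desk-scale default; 1,000 available |
| `support_min` | 0.5 | fraction | strict: supports below 0.5 collapse, exactly 0.5 survives |
| `operon_max_gap_bp` / `operon_same_strand` | 150 / TRUE | bp / — | standard prokaryotic operon heuristic; labels the "neighborhood" subset only, never the discovery filter |

## Design choices where the design was open

**Window semantics.** "10-gene window" is read as ten genes on *each*
side of the anchor (the convention of the genomic-context tools this
mirrors), positional by rank and strand-agnostic; strand matters only for
the operon labeling.

**Signal peptides.** Rather than bundling a neural predictor, the package
implements the classical tripartite heuristic: ≥1 K/R among residues 2–5
(n-region), an 8-residue window with mean Kyte–Doolittle hydropathy ≥ 1.6
inside residues 6..c−4 (h-region), and an A-X-A-type site (residues c−2
and c in {A,G,S,T}) for some cleavage position c in 15–40. It is
deterministic and documented; externally computed calls can be supplied
per gene and take precedence. Proteins under 25 residues are never called.
The precursor is used as given; start codons are not reannotated.

**Motif-alignment curation.** The manual step of discarding sequences that
fall out of the cysteine-motif alignment is automated: the two alignment
columns with the highest Cys frequency are located and rows lacking Cys in
either are dropped (`curate_by_motif_columns()`).

**Profile HMM construction.** Match columns are those with < 50% gaps;
Laplace pseudocounts (1.0) are applied to all emission and transition
counts; the transition set is {M→M, M→I, M→D, I→M, I→I, D→M, D→D}; I↔D
transitions observed in an alignment are not counted. The background is
uniform 1/20 by default, removing any data dependency (database residue
frequencies can be substituted). Scores are log-odds bits; `X` residues
emit at background odds from every state.

**E-value calibration.** Viterbi scores of `n_random` background-sampled
sequences are fitted with a maximum-likelihood Gumbel (location μ, rate
λ); E = N·(1 − exp(−exp(−λ(s−μ)))). The glocal-style score is strongly
length-dependent (every inserted residue pays a transition cost), so the
default null lengths are drawn within 20% of the model length: this keeps
λ sharp where true members live, while longer targets score
conservatively low. Calibration refuses n < 100 (unstable fit); 1,000 is
the default. Calibration uses Viterbi (not forward) scores for speed;
both scoring engines are exposed and oracle-tested.

**Iteration accounting.** Seeds are members from the start, so a run on a
database containing only the seeds converges in one iteration (the first
search adds nothing). Convergence means the final iteration added no
member; membership is monotone non-decreasing until the terminal
Pfam-removal step.

**SSN scores.** The web tools' "alignment score ~100" threshold is a
−log₁₀-E-like quantity; here raw Smith–Waterman BLOSUM62 scores (affine
11/1, the BLASTp defaults) are used with a configurable threshold. The two
are monotone-equivalent rankings but not numerically identical, which is
why the threshold is a first-class parameter. Collapsing at 90% identity
uses global percent identity with gaps in the denominator (the
conservative reading) and single linkage (the most permissive grouping);
representatives are the longest members, ties broken lexicographically.

**Phylogeny.** Approximate-ML tree inference is deliberately replaced by
neighbor joining on Poisson-corrected p-distances with column-resampling
bootstrap — deterministic, exactly testable against additive-matrix
oracles, and adequate for cluster-level structure. Negative NJ branches
are clamped to zero with the deficit moved to the sister branch of the
same join, preserving leaf-to-leaf path lengths. When a low-support edge
is collapsed its length is added to the parent edge (dropped in the
root-adjacent case). The support threshold is strict (<0.5 collapses).

**Welch test.** The Satterthwaite-corrected statistic is implemented in
closed form (the conventions — two-sided, p = 1 for zero variance with
equal means — are part of the contract); `stats::t.test(var.equal =
FALSE)` serves as the independent oracle in the tests, not as the
implementation.

## The synthetic benchmark

`synth_config()` describes the study conditions: 30 single-contig genomes
of 300 genes (taxonomy classes α14/β5/γ9/δ2), one CutO-like MCO anchor
per genome (PF00394+PF07731+PF07732), a 40-member CutF-like family
derived from one 118-residue seed protein at 30% per-site divergence
(signal-peptide core, motif cysteines and PP tail protected), a CutG-like
partner family, CueO-like (12) and FtsP-like (10) out-cluster MCOs, 100
decoys each of four classes (small motif-less; motif-bearing with a Pfam
hit; architecture-complete but outside every window; architecture-complete
but >170 aa), and planted rates neighbor 0.40, genome 0.70, both-families
0.55, annotated neighborhoods 0.88. Rates are realized as *exact counts*
(nearest integer, halves up), not Bernoulli draws, so co-occurrence
acceptance is sharp: the module's output must equal the recorded count
ratio identically. Family members are placed ≥ 2·radius+2 ranks apart and
isolated plants stay > radius from every MCO, so window counting is
unambiguous.

Two scale artifacts are worth naming. First, the family-side association
rate is emergent rather than planted: with one anchor per genome, every
planted neighbor pair contributes to both directions, so the family→MCO
fraction is `p_neighbor · n_genomes / family_size` (0.30 at the defaults)
and cannot be dialed independently of the anchor-side 0.40 at this size.
Second, the class composition (α 23 / β 8 / γ 8 / δ 1) was chosen so the
α share is 57.5% while per-proteome rates are near-equal for α and β,
about half for γ and a quarter-to-half for δ — the qualitative pattern the
per-class normalization is meant to reveal.

What the generator does *not* emulate: indel evolution (members are
fixed-length, so seed alignments are gapless and the HMM's delete states
are exercised only by the property tests), rate heterogeneity or
substitution matrices (substitutions are uniform over the 19
alternatives), paralogs, misannotated starts, and contig fragmentation.
Passing the planted-truth benchmark therefore demonstrates that the
machinery is correct and internally consistent, not that the rule
thresholds are optimal for any particular real proteome release.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally; every file dialect is
  1-based inclusive and converted at the boundary.
* DP tracebacks break ties diagonal > up > left; guide trees come from
  UPGMA (`hclust` average linkage) on k-mer distances (k = 3, smaller-set
  denominator); all outputs are deterministic given inputs and seed.
* Affine gaps cost `open + k·ext` for length k (11/1), matching the
  BLASTp convention; the pairwise engines are cross-checked against
  Biostrings and an exhaustive path-enumeration oracle.
* Percent identity counts gap columns in the denominator; a zero-length
  alignment has no identity and errors.
* Distance matrices error on pairs with no shared non-gap columns and on
  saturated pairs (p = 1) under the Poisson correction; bootstrap
  replicates that hit such pairs are dropped with a warning.
* Emission/transition groups must sum to 1 within 1e−9 (tested);
  unreachable state rows at pseudocount 0 stay zero.
* All-gap alignment columns carry 0 bits of information; logos use no
  pseudocounts.
* The empty local alignment (score 0) is legal; `X` never matches a
  literal motif residue but a pattern wildcard matches anything.
* Problem sizes used by the shipped tests and the acceptance script — a
  30×300-gene benchmark, 100-replicate bootstraps on ~50 leaves, 1,000
  null samples per calibration — were chosen as the package's desk-scale
  defaults; all are configurable upward (e.g. 1,000 bootstrap replicates).

## Limitations

The signal-peptide heuristic is a coarse stand-in for modern predictors
(no lipoprotein or Tat discrimination). The HMM is glocal (whole-model)
rather than local, so partial-domain matches score poorly; this is
conservative for a family defined by full-length architecture. E-values
rest on a single fitted Gumbel per model, not per-target-length
corrections. The SSN score scale is not numerically interchangeable with
web-tool "alignment scores". NJ+bootstrap is a topology-level stand-in
for likelihood methods. On real data, domain annotations are consumed,
never computed — the quality of the Pfam scan used upstream bounds both
the anchor set and the removal rule.
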