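---
title: "Predicting odorant-receptor gene enhancers from sequence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting odorant-receptor gene enhancers from sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orenhance)
library(Biostrings)
```

## The problem

Mammalian odorant-receptor (OR) genes — together with the related TAAR,
vomeronasal (V1R/V2R) and FPR chemoreceptor families — sit in genomic
clusters, and each olfactory sensory neuron expresses a single OR allele
(the one-neuron one-receptor rule). The choice is regulated in cis by
nearby enhancers called *elements* (H, P, J, Lipsi, Sfaktiria, ...):
AT-rich, evolutionarily conserved stretches carrying homeodomain (HD) and
olfactory/early-B (O/E) transcription-factor binding sites. Finding new
elements in vivo is slow and expensive; `orenhance` implements a purely
sequence-based screen that nominates candidates from public annotation,
conservation tracks and a set of position-specific weight matrices
(PSWMs) summarizing known element signatures.

The pipeline has four stages, each usable on its own:

1. **Gene lists.** BioMart-style exports are parsed, family-classified by
   symbol pattern, pruned of alternative-scaffold entries, and grouped
   into MOE (OR + TAAR), VNO (V1R + V2R + FPR), olfactome (their union)
   and TCR lists, with and without pseudogene-flagged entries.
2. **Locus architecture.** Each list is partitioned into clusters
   (≥ 3 genes), *miniclusters* (exactly 2) and solitary genes at an
   intergenic cutoff distance *t*, swept from 0.1 Mb to the widest
   chromosome in 0.1 Mb steps. An optimal univariate k-means architecture
   selected by BIC serves as the comparison clustering.
3. **Conserved segments.** Locus spans are expanded ±1 Mb, intersected
   with conservation tracks (GERP constrained elements, EPO mammal
   alignments), broadened ±150 bp, and extracted as FASTA.
4. **Candidate selection.** Segments are scanned with the PSWMs on both
   strands; window p-values come from an exact dynamic program under a
   zero-order background and are converted to Benjamini–Hochberg
   q-values (α = 0.05 for both). Segments with a significant hit are
   retained and re-scanned (round 2); those whose *round-1* significant
   hits include a core matrix (the HD/element signatures, ids 1–8) are
   accepted as candidate elements. A variant restricts the screen to the
   100 segments best matching the 13-bp core motif shared by H, P and
   the *Olfr713* promoter (`TCATTAAAAAGTT`), using only matrices free of
   post-2014 element information — a deliberate guard against circular
   rediscovery.

## Conventions and tunables

All internal coordinates are 0-based half-open; BioMart input is read as
1-based inclusive and report strings are rendered 1-based inclusive
(`chrN:start-end`), so printed coordinates are directly comparable with
the literature. BED output is 0-based, via `rtracklayer`.

Parameters that matter, with defaults and units:

| parameter | default | meaning |
|---|---|---|
| `t` (threshold) | 1 Mb | intergenic cutoff; a gap of exactly `t` joins, `t` + 1 bp splits |
| intergenic distance | edge-to-edge | inner gap between gene bodies, clamped at 0 for overlaps |
| `flank` | 1 Mb | locus expansion before conservation intersect |
| `pad` | 150 bp | broadening of each intersected range |
| `alpha` | 0.05 | significance level for p- and q-values |
| `bins` | 1000 | score-grid resolution of the p-value dynamic program |
| background | from segments | zero-order A/C/G/T frequencies; "uniform" or explicit vector available |
| `pseudocount` | 0.1 | background-distributed prior when building PSWMs |
| retention QC | 80 % identity over 50 % coverage | local-alignment thresholds for known-element retention |
| variant `top_n` | 100 | 13-mer best-matching subjects kept per database |

Whether the original distance measurements were gene-edge-to-gene-edge
or start-to-start is not stated in the sources this design follows;
edge-to-edge is used because it matches the plain meaning of
"intergenic". The "significant" filter applies both p ≤ α and q ≤ α by
default, with single-filter switches (`scan_config(filter =)`) since
the two-threshold reading is the stricter of the plausible
interpretations.

## The p-value dynamic program

For a PSWM of width *w* the scanner scores every window as the sum of
per-column log-odds `log2(p/bg)` in bits. Per-column scores are shifted
to a common integer grid of about `bins` steps spanning the attainable
range; the exact distribution of the integer window score under the
zero-order background is the convolution of the *w* column
distributions, and `p(s) = P(S ≥ s)`. The scanner scores windows on the
same integer grid, so the lookup is exact for the discretized matrix;
discretization can move a p-value only across roughly one grid step per
column, which the test suite bounds against exhaustive `4^w`
enumeration. p is non-increasing in the score and equals 1 at the
minimum attainable score. Windows containing ambiguous bases are not
scored; segments that are more than half N are skipped with a message.

## Multiple testing: how q-values are pooled

Hits are emitted at p ≤ α (a pre-filter, as scanner conventions have
it), but the Benjamini–Hochberg pool is the *full number of scanned
windows of the run* — all matrices, segments and strands — carried on
the hit table as the `n_tests` attribute. Pooling over emitted hits
only would understate the number of tests by a factor of about 1/α and
make the q-values anti-conservative. Because round 2 re-scans only the
retained segments, its pool is smaller and its q-values legitimately
differ — this is what makes the two-round design meaningful rather than
idempotent. `bh_qvalues()` on a bare p-value table (no attribute) uses
the table size, which is the textbook step-up.

A statistical consequence worth understanding: with a skewed background
the window-score distribution is effectively continuous, so background
windows reach the step-up boundary at the nominal false-discovery rate
— about α per true discovery. No correct FDR procedure at α = 0.05 can
promise literally zero background survivors in that regime. When
scoring columns are equally sharp and the background is uniform, the
attainable p-values instead jump by mismatch class, and for sharp
matrices of width ≈ 18 every background class sits an order of
magnitude below the boundary; the planted-recovery tests use that
regime, which is also why they demonstrate clean separation rather than
a lucky draw. Screens of real AT-rich elements should expect — and the
two-round core-matrix rule is designed to absorb — a small number of
boundary-level background hits.

## The 1-D k-means comparison

`optimal_partition()` is an exact dynamic program over sorted gene
midpoints (in one dimension the optimal clusters are contiguous, so the
global WCSS minimum is reachable without Lloyd-type restarts). Model
selection fits, for each k, a Gaussian mixture on the optimal partition
with cluster-specific means and variances and weights `n_c/n`, scoring
`BIC = 2·loglik − (3k − 1)·ln(n)`; variances are floored at 10⁻⁶ of the
squared data range so singleton clusters stay finite, and ties go to
the smallest k. The per-chromosome `BIC/n` curves are exported. The cap
`k_max = min(n, 50)` bounds the search; it is a tractability choice,
not a statistical one. On gene data the method tends to oversplit dense
regions and fuse sparse ones — which is precisely why the
threshold-based architecture is the primary definition and k-means the
comparison.

## What the synthetic fixtures emulate — and what they do not

`fixture_config()` defaults describe the study conditions at desk
scale: 3 chromosomes × 3.5 Mb (≈ 10 Mb total), 2 loci per chromosome
with 1–5 genes each, within-locus gaps drawn from 4–175 Kb (the
observed range of mean within-cluster distances), a minimum
between-locus gap of 1.2 Mb so the 1 Mb working threshold sits strictly
inside the recoverable band, background A+T = 0.6 (elements and OR
promoters are AT-rich), 15 % pseudogenes, two conserved features per
locus plus decoys placed > 1.05 Mb from every locus that the harvest
must ignore. Every generator takes a mandatory seed and uses one
isolated RNG stream, so fixtures are bit-reproducible.

The fixtures deliberately do *not* emulate: phylogenetic conservation
(features are placed, not evolved), indels and segmental duplications,
assembly gaps, GC isochores, or realistic motif degeneracy. Passing
tests therefore demonstrate the correctness of the machinery —
coordinate arithmetic, the partition/threshold semantics, the p-value
mathematics, the two-round logic — not the biological yield on real
genomes, which depends on annotation quality and track choice.

## Numerical choices and degenerate inputs

* Probability columns are renormalized when read from printed-precision
  MEME files; zero probabilities (possible only with a zero
  pseudocount) are floored at 10⁻⁴ with a warning before log-odds.
* Hit ordering and all tie-breaks are deterministic: (segment, start,
  matrix, strand) for hits, chromosomal order for candidate numbering,
  score then coordinate for the 13-mer ranking, smallest k for BIC ties.
* Overlapping conserved segments are kept separate (only exact
  duplicates are removed): independently conserved overlapping
  stretches are distinct observations, and merging them would silently
  change candidate coordinates.
* Empty inputs degrade to empty outputs (empty gene list → empty
  architecture; no retained segments → empty round 2), never to errors,
  except where a configuration is genuinely unusable (unknown
  chromosome, empty matrix set, k > n).
* The 13-mer variant's "BLAST" stage is an exhaustive ungapped local
  alignment (match +1, mismatch −3, gaps prohibited): for a 13 bp query
  heuristic seeding buys nothing, and exhaustive scoring makes the
  "100 best subjects" selection deterministic.

## Problem sizes

The default test suite and the acceptance script run entirely on
generated data: ≈ 10 Mb fixture genomes, segments of a few hundred bp,
matrices of width 12–18, twenty seeded replicates for the recovery
properties, and exhaustive oracles at n ≤ 12 (k-means), 4^w with w ≤ 6
(p-values) and n ≤ 50 (clustering). These sizes were chosen so that
every oracle remains exactly enumerable while each property is still
exercised far from trivial edge cases. Real-genome runs scale linearly
in sequence length; scanning is the dominant cost.

## Known limitations

* Family assignment is symbol-pattern based and shipped as editable
  rules; annotation databases occasionally rename families, so the
  rules should be reviewed per release.
* The scanner supports zero-order backgrounds only — no Markov
  backgrounds, position-specific priors or gapped motifs.
* Known-element retention uses local alignment identity/coverage
  thresholds (80 %/50 %) that are explicit but arbitrary; they are
  parameters, not facts.
* Provenance-aware rediscovery flagging is only as good as the supplied
  matrix-provenance map; a candidate hit only by matrices built from
  the element it overlaps is flagged, not removed.
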