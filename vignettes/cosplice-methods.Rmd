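---
title: "Methods: co-splicing network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-splicing network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery behind `cosplicenet()`,
the choices that were genuinely open when the package was designed, and
what the synthetic test world does and does not establish about behavior
on real data.

## The inference problem

A splicing factor (SF) acts on a pre-mRNA through short RNA elements near
its splice junctions. Neither signal alone identifies targets: temporal
co-expression of an SF and a transcript is consistent with shared
transcriptional regulation, and short motifs recur by chance. The package
therefore intersects the two: an SF→transcript link requires (i) tight
rank correlation of their expression over the time course and (ii) a
shared, statistically enriched motif in a defined splice-junction window
of the SF's co-expressed transcripts, with a significant per-transcript
hit. Both halves are deliberately conservative; the product is a
hypothesis network, not a set of validated interactions.

## Junction windows (R regions)

For every exon, windows are anchored flush against its splice sites
(transcript sense): R1 = last 30 intronic nt of the upstream intron, R2 =
first 30 exonic nt, R3 = last 30 exonic nt, R4 = first 30 intronic nt of
the downstream intron. Window width 30 nt is the default because known
splicing-regulatory elements concentrate within a few tens of nucleotides
of the junction. Two boundary conventions deserve note:

* Interval notations like "−31:−1" describe 31 positions while the prose
  speaks of 30-nucleotide windows; this package implements exactly
  `window` nucleotides abutting the junction, so whether the
  junction-adjacent GT/AG dinucleotide falls inside depends only on the
  window side, never on an off-by-one.
* A first exon has no acceptor and a last exon no donor, so R1 and R4 are
  simply absent there; R2/R3 are kept for every exon (terminal exon ends
  are not splice sites, but exon-body elements are still scannable).
  Windows truncated by short exons or introns keep the available length
  and are flagged rather than dropped, so transcripts with small features
  remain in Ri-ratio denominators.

## Expression filtering, normalization, super-clusters

Differential expression uses the plain two-criterion filter: ≥ `fold`
(default 2) change between *any* two time points on replicate-averaged
abundances, and a two-sample Welch t-test p < `alpha` (default 0.001)
between some pair of *consecutive* time points on raw replicates. The
any-pair/consecutive asymmetry is intentional: a slow monotone drift can
satisfy the fold criterion across distant points while the statistical
test guards against replicate noise where the change happens. A
precomputed DE list (e.g. from limma) takes precedence when supplied —
the built-in filter is a self-contained approximation, not a moderated
statistic.

Profiles are replicate-averaged, z-scored across time points, and mapped
through the standard normal CDF Φ. This is the only parameter-free
reading of "z-score + CDF" normalization: outputs live in (0,1), ranks
are preserved, and the transform is invariant to affine rescaling, so
clustering compares *shapes*. Clustering is k-means with k-means++
seeding, `n_init` restarts and Lloyd refinement, keeping the lowest
within-cluster sum of squares; the default k = 50 suits transcriptome
scale, while the synthetic world (≈ 80 profiles) uses k = 12 — chosen
as roughly one cluster per planted archetype plus slack for decoys.

A cluster's developmental phases are read off its Φ-normalized centroid:
a phase is "on" when the centroid's mean over that phase's time points is
≥ 0.5, i.e. above the transcript's own temporal mean — a scale-free rule,
since no quantitative definition of "expressed during a phase" exists.
The on-phase set maps to one of six super-cluster labels (early; early +
middle; middle; middle + desiccation; desiccation; early + desiccation).
Degenerate sets are resolved deterministically and logged: an empty set
falls back to the maximal phase; the all-three set drops its weakest
phase to reach a listed pair.

## Co-expression edges

Edges use Spearman correlation — Pearson on ranks, midranks for ties —
so any strictly monotone distortion of either profile leaves the network
unchanged. With only n = 7 time points the t-approximation to the null is
unreliable exactly where the ρ > 0.95 threshold bites, so for n ≤ 9 the
two-sided p-value is exact: the fraction of all n! rank orderings whose
|ρ| reaches the observed value (at n = 7, only perfect rank agreement
survives ρ > 0.95 *and* p < 0.001 — a single adjacent swap gives
ρ ≈ 0.964 but p = 14/5040 ≈ 0.0028). Thresholds are strict inequalities
as printed, and only positive correlations form edges; negative-edge
retention is available as an option but off by default.

## ZOOPS motif discovery

The generative model: with probability λ a sequence carries exactly one
motif site at a uniformly chosen offset, site letters drawn column-wise
from a PWM, all other letters from a 0-order background; with probability
1 − λ it is pure background. EM alternates posterior site localization
with PWM/λ/background re-estimation (pseudocount 0.1 per cell).
Restarts are seeded deterministically from the `n_starts` = 20 most
over-represented exact k-mers (observed/expected under the background),
initialized at 0.7 match probability. A two-stage multistart — 8 EM
iterations for every seed, then the best start run to convergence
(relative log-likelihood change < 1e-6, cap 200 iterations) — gives the
same optimum as full multistart on all tested inputs at a fraction of the
cost. The log-likelihood trace is retained and is non-decreasing by
construction; tests assert it.

Significance is empirical: the fitted log-likelihood ratio (model vs
background-only) is compared with refits on `n_null` = 100
dinucleotide-shuffled copies of the input (random Eulerian-path shuffle,
exactly preserving dinucleotide counts and terminal letters);
significance = (1 + #{null ≥ observed})/(n_null + 1), gated at 0.01. This
replaces any internal E-value formula with a fully specified null that
preserves local sequence composition. With 100 nulls the smallest
achievable value is 1/101 ≈ 0.0099 — just under the gate, which is why
n_null < 19 (unable to resolve even 0.05) is rejected outright.

**Width selection.** One model is fitted per width 4–7 and the smallest
significance wins. Ties — common, because genuinely enriched widths all
hit the 1/101 floor — are broken by larger *total* information content
(bits summed over columns), then smaller width. Total rather than
per-column-mean IC is deliberate: a planted 7-mer's enriched 4-nt
sub-k-mer often has crisper columns, but a 4-nt motif cannot physically
reach the downstream p < 0.05 scan gate in a 30-nt window (27 positions ×
4⁻⁴ ≈ 0.1), so the per-column reading would systematically select motifs
that can never support an edge.

## Exact scan statistics

Scanning is sense-strand log-odds against the model background. Scores
are discretized to 1e-3-nat bins and the per-position null tail
P(score ≥ s) is computed *exactly* by dynamic programming over the score
distribution of background k-mers (the DP equals exhaustive enumeration
over all 4^w k-mers; tests verify this for w ≤ 6). The per-sequence hit
p-value applies a Šidák correction over the m scannable positions,
p = 1 − (1 − p_pos)^m, which is conservative for overlapping windows —
background calibration lands near 0.03 at the nominal 0.05 gate, and
tests accept 0.05 ± 0.02. Positions overlapping ambiguous letters are
skipped; a fully ambiguous sequence yields a no-hit sentinel.

## Network assembly and differential splicing

Per (RBP, region) with a significant motif, every co-expressed
transcript's windows are scanned; an edge forms when ≥ 1 exon hits at
p < 0.05, weighted by −log10 of the *minimum* exon hit p (strongest
site) — one number per edge is required and strongest-site is the
conservative standard choice. Each edge carries the Ri ratio with the
transcript's *total* exon count in the denominator. Co-splicing edges are
by construction a subset of co-expression pairs, and an RBP whose groups
yield no significant motif contributes nothing.

A gene is reported as differentially spliced when one splice variant has
an RBP edge and another variant either has edges only to disjoint RBPs
whose super-cluster labels are also disjoint (label inequality, not
profile distance — the definition is categorical), or has no RBP edge at
all; "stable" variants are catalog transcripts present in the expression
matrix but failing the DE filter.

## Protein-isoform diversity

The match-only global alignment (match 1, mismatch 0, gap 0) has the
longest common subsequence as its optimum, so the package computes LCS
directly by dynamic programming — only the score is used downstream, and
emulating a specific aligner's tie-breaking would add nothing.
`gaps_only` means score = length of the shorter isoform; comparing
against the shorter (not always the variant) length is a documented
deviation that avoids misclassification when the variant is longer than
the canonical form, and such cases are logged. Domain comparison pairs
hits per accession by start order: equal accession multisets with equal
interval lengths → identical; with ≥ 1 shortened interval → similar
(truncation tolerance 0 residues — hit intervals are integers); different
multisets → disparate; both empty → none. Requiring equal lengths for
"identical" is what separates it from "similar"; overlapping duplicate
hits of one accession are deduplicated preferring specific over
superfamily hits. The canonical isoform is the known variant with the
lowest isoform suffix (integer suffixes, then N-suffixes by number, then
lexicographic), so novel variants never serve as reference; ties among
equal numeric suffixes cannot occur in valid annotation and are not
handled specially.

## The synthetic world

`generate_world()` emulates the study design the pipeline targets: 7 time
points spanning three developmental phases (points 1–2 early maturation,
3–5 middle, 6–7 desiccation), 3 replicates, a handful of SF/SRP genes on
six phase archetypes, 12 targets per SF tied to their SF by a random
affine-plus-softplus monotone link (exercising rank invariance — Pearson
would differ), independent decoys, planted junction motifs
(`AGGTAAG`, per-position mutation rate 0.1, 90% of eligible junctions,
R1 by default), one motif-free RBP, alternative-acceptor splice-variant
pairs whose shifted junctions keep the two variants' windows disjoint,
stable (flat) variants, and peptide/domain pairs covering all diversity
classes. Replicate noise defaults to sd 0.005 on the unit template scale
with template values separated by ≥ 0.05: the ρ > 0.95, p < 0.001 gate at
n = 7 admits only perfect rank agreement, so this models transcripts
whose temporal ordering is measured essentially without error — the same
regime in which the thresholds are meaningful on real data.

What the generator does *not* model: read-level noise and isoform
quantification ambiguity, genome composition structure beyond a uniform
base distribution, correlated targets that are not SF-driven, motif
variants with indels, and overlapping genes. Passing the end-to-end tests
therefore demonstrates correctness of the machinery under its own
assumptions — not that real tissue data will yield comparable
precision/recall.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline on the
default world (≈ 85 transcripts, 21 samples, ≈ 100 kb genome; k = 12,
n_init = 50, n_null = 100), 100-trial significance calibration, 5000-draw
scan calibration, and full 5040-permutation Spearman enumeration —
minutes on one CPU, chosen so the whole suite iterates quickly while
every statistic still operates in its intended regime. All randomness
flows through R's RNG under explicit seeds (EM itself consumes none: its
restarts are deterministic k-mer seeds), so fixture bundles, cluster
assignments, motif models and exports are byte-reproducible.

## Known limitations

* The co-expression gate at n = 7 is all-or-nothing (perfect rank
  agreement); a single swapped time-point ordering removes a true target.
  More time points soften this.
* The empirical motif null cannot resolve significance below
  1/(n_null+1); ranking among significant motifs at the floor relies on
  the IC tie-break.
* The per-sequence scan p is conservative (Šidák over overlapping
  windows), slightly deflating edge counts at a fixed gate.
* Motifs are strand-pure PWMs; no secondary structure, no
  multiple-occurrence (OOPS/ANR) modes, no cross-database motif
  comparison.
* The protein-diversity module trusts supplied peptides and domain
  tables; in-silico translation is not performed unless explicitly
  requested, and coding labels are inputs, not predictions.
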