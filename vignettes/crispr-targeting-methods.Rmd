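---
title: "Methods: CRISPR targeting of prophages in bacterial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRISPR targeting of prophages in bacterial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the pipeline answers

Bacterial CRISPR arrays are molecular records: each spacer is a fragment of
a mobile genetic element (MGE) the lineage has encountered. If a species'
spacers match a prophage far more densely than they match the rest of the
genome carrying it (the *backbone*), that prophage is, or recently was, an
active target of CRISPR immunity — and every species whose spacers hit it
is a candidate host. `crisptarget` implements this chain of inference for
multi-species communities of bacterial genome assemblies:

1. find CRISPR arrays by seeding with known repeat sequences and extract
   spacers with provenance;
2. match spacers against all genomes at 100% identity over the full spacer
   length (zero mismatches, both strands), discarding matches that fall in
   CRISPR arrays themselves;
3. classify the surviving protospacers as prophage or backbone and test,
   per prophage, whether its targeting density exceeds the backbone's;
4. dereplicate and cluster MGE sequences by percent length aligned (PLA)
   so redundant predictions and plasmid look-alikes are handled;
5. build the directed species-to-species targeting network and infer
   additional host species for targeted prophages.

Prophage *prediction* is out of scope: prophage coordinates are an input
(BED-like TSV, 0-based half-open, as all coordinates in the package).

## The targeting-density statistic

For a prophage of length $L_p$ bp with $m_p$ surviving spacer matches, the
targeting density is $d_p = m_p / (L_p/1000)$ matches per kb. The backbone
of its genome has density $d_b = m_b / (L_b/1000)$, where $m_b$ counts
matches outside every annotated prophage and $L_b$ is the genome length
minus the summed lengths of all (merged) prophage intervals. The
definition is deliberately asymmetric: CRISPR array loci keep their length
in $L_b$, but matches inside arrays were already removed upstream — so
array content can only dilute, never inflate, backbone density.

Each kb of prophage and of backbone is one datapoint: bin vectors count
match starts per 1 kb bin (prophage bins over the prophage interval;
backbone bins over excised-and-concatenated coordinates that restart at
each contig, so no bin spans a contig junction). A one-sided Mann-Whitney
U test asks whether prophage bins are stochastically greater than backbone
bins. Raw p-values for all prophages tested in a run are adjusted with the
Holm-Sidak step-down correction,
$\tilde p_{(i)} = \max_{j \le i}\,[1 - (1 - p_{(j)})^{m - j + 1}]$,
and a prophage is called significantly targeted when $\tilde p \le \alpha$
(default 0.05).

### Numerical choices in the test

Per-kb count bins are extremely tie-rich (mostly 0 with a few 1s and 2s),
and this drives three choices:

* **Exact conditional p-values under ties.** The permutation distribution
  of U given the pooled multiset of bin values depends only on how many
  observations of each distinct value land in the smaller sample, so it
  can be enumerated exactly over value-count compositions with
  multivariate hypergeometric weights. We use this enumeration whenever
  the composition grid is small enough (budget 2e5 rows; with sparse count
  data it almost always is). Null-community simulation showed why this
  matters: the tie-corrected normal approximation with continuity
  correction — the usual fallback, which the package still uses when the
  enumeration budget is exceeded — is anticonservative in this regime
  (null fractions of raw $p \le 0.05$ up to ~0.07 in our simulations),
  enough to push the family-wise error rate above its nominal level.
  Tie-free samples use the classical exact distribution when the smaller
  side has at most 8 observations.
* **Partial bins.** A trailing bin of at least 100 bp is kept as its own
  datapoint; a smaller remnant is merged into the previous bin. This
  avoids manufacturing near-empty datapoints from slivers while keeping
  the bin count close to $\lceil L/1000 \rceil$. (A region shorter than
  one bin is always a single bin.)
* **One-sided alternative.** Only "prophage more targeted than backbone"
  is of interest for host inference; `alternative = "two.sided"` is
  available.

Degenerate inputs: a genome with no surviving matches at all is
untestable and reported with `p = NA` (never significant); two identical
constant bin vectors give `U = n_1 n_2 / 2`, `p = 1`; a density ratio with
zero backbone density and positive prophage density is reported as the
`Inf` sentinel, and `NA` when both densities are zero.

## Spacer discovery and matching

Array detection is repeat-seeded, not de novo: known repeat sequences
(~28-37 bp) are matched within a Hamming distance (default 2 mismatches,
no indels) on both strands, and maximal runs of at least 3 same-repeat
occurrences whose inter-repeat gaps fall in the spacer length range
(default 20-50 bp) are called as arrays. Spacers are the gap sequences, in
array orientation. De novo repeat discovery belongs to dedicated CRISPR
detectors; a k-mer tally helper (`bootstrap_repeat_seeds`) exists only to
bootstrap seeds on synthetic data.

Spacer uniqueness is computed on a canonical form — the lexicographic
minimum of the sequence and its reverse complement — because array
orientation is arbitrary; `canonicalize = FALSE` exposes the
strand-sensitive variant. Protospacer matching requires the full spacer at
zero mismatches on either strand (Aho-Corasick multi-pattern search);
`N` in a genomic window can never satisfy that rule. A palindromic spacer
matching one locus on both strands is reported once. A spacer carried by
genomes of several species contributes one match per donor species, since
donor attribution follows the species encoding the spacer. Matches
overlapping any array interval by at least 1 bp are removed (this is what
excludes a spacer's trivial match to its own array); matches overlapping a
prophage by at least 1 bp are prophage-compartment, with ties between
overlapping prophages resolved to the one containing the match start.
Intra-genome self-targeting outside arrays is deliberately retained.

## Dereplication and clustering by percent length aligned

PLA between two sequences is the fraction of a sequence covered by
high-identity local alignment footprints against the other. The aligner is
seed-and-extend without gaps: exact 21-mer seeds shared between the
sequences (both orientations) are chained on their diagonal when the
uncovered gap is at most 50 bp, extended outward under an X-drop of 20
(match +1, mismatch -2), and kept when segment identity is at least 90%.
Footprints are merged per sequence, and the default denominator is the
*shorter* sequence, so a fragment contained in a full-length element
scores PLA 1 — containment is redundancy for dereplication purposes. The
`longer` and `query` denominators are available. At the 95% threshold PLA
is dominated by long near-exact blocks, which is what makes the ungapped
engine adequate and keeps an independent oracle tractable in tests.

Clustering uses average linkage (UPGMA) on the distance `1 - PLA`,
implemented directly so that tied merges are deterministic (the pair whose
clusters contain the smallest original indices merges first); merge
heights are non-decreasing and agree with `stats::hclust` on tie-free
matrices. Dereplication cuts the dendrogram at distance `1 - threshold`
(default threshold 0.95) and keeps the longest member per cluster, ties to
the lexicographically smallest id. Dendrograms export to Newick with the
ultrametric convention (children of a node merged at height $h$ sit at
$h/2$). Predictions sharing a cut cluster with a plasmid or genetic-island
reference are flagged and excluded from host inference.

## Host inference and the species network

Host inference considers known phages plus predictions that are both
significantly targeted and not plasmid-flagged; known phages bypass the
significance gate. Any species with at least one spacer matching a
prophage is inferred as an additional host (the native species — the one
carrying the prophage — is never listed as additional); species supported
by more than one distinct spacer are marked. The species network has one
directed edge per (donor, target) pair with at least one surviving match;
edge counts are of *distinct spacers*, with prophage counts restricted to
eligible prophages and backbone counts taken from all backbone matches.
Self-loops are retained (a species targeting its own genomes is a real
signal); node totals count unique spacers encoded per species. Export is
GraphML plus a TSV edge list.

## The synthetic community generator

Because the real study conditions involve thousands of assemblies and
external prediction tools, every stage here is validated on synthetic
communities with complete ground truth. The generator plants, per genome:
non-overlapping prophage intervals and repeat-spacer CRISPR arrays (one
species-specific 32 bp repeat; spacers 30 bp random; at least 3 repeats
per array), then protospacers — exact copies or reverse complements of
spacers drawn from *other* genomes' arrays — at Poisson rates: a mean per
prophage per donor species (default 5) and a mean per Mb of backbone per
donor species (default 2). A species-pair rate matrix reproduces arbitrary
interspecies targeting structure. Defaults describe a small community: 4
species, 2 genomes each, 0.2 Mb single-contig genomes, two 15-30 kb
prophages and one 10-repeat array per genome. Placement is
rejection-sampled (cap 1000 retries) so planted elements never overlap,
protospacers never cross compartment boundaries and never fall inside
arrays; generation is byte-identical for a fixed seed.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: background composition (sequence outside
planted elements is i.i.d. uniform, no GC structure or repeats),
sequencing or assembly artifacts, phage biology (integration sites,
attachment sequences, gene content), spacer acquisition dynamics, and
mismatch-tolerant targeting (the zero-mismatch rule means near-matches
that a PAM-aware or mismatch-tolerant search would count are invisible by
design). Default rates are chosen for test power, not to mimic any
particular species' spacer-count distribution.

For the statistical properties of the significance pipeline, a
match-level simulator (`simulate_classified_matches`) draws classified
match positions directly at given per-kb densities, skipping sequence
generation. This is how the package's own calibration analyses are run:
family-wise error on 200 null communities (uniform placement over a
0.5 Mb genome with five 20 kb prophage annotations, backbone rate 0.1
matches/kb) and power on 100 communities with prophages planted at 10x
the backbone density (1 Mb genome, 20 kb prophages, backbone rate 0.12/kb,
so ~24 expected matches per hot prophage). Sequence-level end-to-end
replicates back the matcher, array-recovery and host-inference checks at
smaller sizes (0.05-0.12 Mb genomes). These problem sizes are the
package's validation conditions; all are exercised by the test suite and
`scripts/acceptance.R`.

## Known limitations

* Repeat matching is Hamming-only; repeats with indels relative to the
  seed are missed (a deliberate trade: exact brute-force oracles stay
  feasible, and ~32 bp repeats rarely differ by indels within a species).
* The PLA engine is ungapped; diverged homologs whose similarity is only
  detectable through gapped or protein-level alignment score near 0. At
  the 95% dereplication threshold this does not matter; at permissive
  thresholds it would.
* Whether the original spacer-uniqueness convention collapsed reverse
  complements, and whether its Mann-Whitney test was one- or two-sided,
  cannot be determined from the source material; both behaviours are
  exposed as flags with the defaults documented above.
* With zero planted backbone matches the density ratio is `Inf`; ordering
  prophages by ratio should treat those separately (the targeting results
  table keeps counts and densities so this is always possible).
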