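---
title: "kcvkit methods: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kcvkit methods: models, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcvkit)
```

`kcvkit` implements a diversity survey of chlorovirus *kcv* potassium-channel
genes and the single-channel analysis used to characterize the encoded Kcv
proteins. This vignette documents the models, the parameters that matter, the
synthetic stated world, and the numerical decisions — in enough detail that a
maintainer can judge what a green test does and does not establish.

## 1. Sequence survey

### Degenerate primers and in-silico PCR

Primers are IUPAC strings; a template position matches iff the (unambiguous)
template base lies in the primer base's ambiguity set. Reverse primers are
written 5'→3' on the minus strand — the standard bench convention — and
matched on the plus strand through `reverse_complement()`; this is the only
interpretation under which a product can form. Amplicon coordinates are
1-based inclusive on the plus strand, `product_length = rev_last − fwd_start + 1`.
Defaults are `max_mismatches = 0` and product bounds 200–2000 nt: the screen
this emulates produced clean single bands, and the bounds discard spurious
degenerate-site pairings. The annotated "position" column of the shipped
panel is documentation only and never used in matching, because its anchor
convention (relative to start vs stop codon) is not recoverable; similarly,
published GC% values are reproduced by `gc_content(mode = "unambiguous_only")`
for the fully determined rows (50 and 47), but not for all rows, whose
original formula is unstated — no attempt is made to force agreement.
`wallace_tm()` is the 2·(A+T) + 4·(G+C) rule of thumb over a concrete
realization (min/max/expected GC); it is informational, not thermodynamic.

### Alignment

`global_align()` is Needleman–Wunsch with affine gaps (Gotoh): a gap of
length *k* costs `gap_open + (k−1)·gap_extend`. Traceback is deterministic
with preference diagonal > up > left, so downstream column-difference counts
are reproducible run to run. Defaults: BLOSUM62 with open 10 / extend 0.5
for proteins; +2/−3 with open 5 / extend 2 for DNA. These are conventional
choices; the interactive aligner used for the original analysis does not
document its defaults, so small shifts in gap placement relative to the
original figures are expected for gapped comparisons (equal-length
comparisons are unaffected).

`progressive_msa()` orders merges by single-linkage clustering on 3-mer
Jaccard distances — cheap, deterministic, and adequate for ≤ ~100 short
sequences — and merges profiles by the same affine DP over expected
substitution scores (column frequency vectors against the substitution
matrix, gaps contributing zero), with "once a gap, always a gap". There is no
iterative refinement; the degap round-trip and column-count invariants are
tested properties.

### Diversity accounting

* `collapse_unique()` keys on exact case-insensitive nucleotide identity of
  the CDS *including* the stop codon, which is what makes a 249-nt gene
  correspond to an 82-residue protein.
* `pairwise_differences()` counts differing alignment columns
  (residue-vs-gap = one difference) and reports percent over the alignment
  length. The alignment-length denominator is deliberate: for strongly
  diverged pairs with indels it is the only denominator consistent with
  reporting both a difference count and a percentage larger than the count
  alone would give over the shorter sequence.
* `variable_sites()` on a family is computed over the modal-length CDS class
  stacked colinearly (no gaps): for an 82-aa-class family that is 249 columns.
  Indel-carrying outliers are excluded from this count rather than aligned in,
  the stated assumption of the analysis this mirrors; the exact inclusion set
  of the original count is not published, which is why the real-data value is
  not asserted by any offline test.
* Proteins deposited with an upstream start can optionally be trimmed to an
  internal Met that restores the family's modal length
  (`diversity_report(..., reannotate_internal_start = TRUE)`, backed by
  `reannotate_start()`). The default is off — sequences are analysed as
  deposited — because both readings are defensible and the choice should be
  explicit.
* The filter motif is the leftmost match of `T-T-x-G-[YF]-G-[DN]-x`, wide
  enough for the three observed classes (TTVGYGDL, TTTGYGDL, TTTGFGDV) while
  anchored on the invariant T-T…G…G scaffold. Absence is an explicit result,
  never a silent one.

### Domain annotation

The reference 82-residue architecture (`default_domain_annotation()`) uses
half-open 1-based intervals: TMD1 4–25, turret 26–39, pore helix 40–49,
filter 50–57, TMD2 58–78, C-tail 79–82, no slide helix (SAG-type Kcvs
essentially lack one). The turret/TMD boundaries follow the standard
two-TM channel topology for a subunit of this size; they are a package
convention, not measured data, and all per-domain statistics are relative to
them. `annotate_domains()` transfers intervals through a pairwise alignment;
insertions between TMD1 and the pore helix are assigned to the turret (that
is where the larger chlorovirus Kcv variants carry extra residues),
C-terminal insertions extend the tail, and the filter interval is re-anchored
on the query's own motif match.

### Phylogeny

The tree stage is deliberately a p-distance + neighbor-joining stand-in, not
maximum likelihood: published ML branch lengths are model- and
engine-dependent and are not reproducible from the data alone, so the
comparison surface is qualitative clade structure (`is_monophyletic()`), not
branch lengths. NJ uses the canonical Q-criterion with a deterministic
tie-break (lexicographically smallest cluster-id pair, cluster id = smallest
member leaf id) so Newick output is stable for snapshot comparisons. Negative
branch lengths are clamped to zero with the deficit moved to the sibling
branch, preserving the joined pair's mutual distance. On additive matrices NJ
is exact; the suite verifies recovery to 1e−9 against independently generated
random trees.

## 2. Synthetic stated world

`family_config()` defaults encode the surveyed family's structure: 103
isolates, 42 distinct DNA haplotypes with multiplicities
{20, 9, 3×12, 2×10, 1×18}, and 16 haplotypes that differ only synonymously
from another, giving 26 distinct proteins. Length variants: one lineage with
a 24-nt in-frame turret insertion and four/two lineages with 6/9-nt
C-terminal extensions. Two honest deviations from the real family:

* the 24-nt insertion yields a 90-aa protein (82 + 8), whereas the real
  Greenland isolate's protein is 89 aa — its full indel structure is not
  published, so the generator states the simple insertion;
* the real panel's single 87-aa protein arises from an upstream alternative
  start codon, a feature outside the generator's substitution/indel model; the
  synthetic 82-aa class therefore has 19 members rather than 18.

The ancestral CDS is drawn codon-uniformly from sense codons (no real
sequence is available to copy), with ATG start, TAA stop, and the filter
octapeptide overwritten to encode TTVGYGDL. Substitution pressure is
domain-structured (`filter 0.01 < turret = pore 0.03 < c_tail 0.04 < TMD 0.08`
per site), mirroring the observed conservation ranking; with
`preserve_motif = TRUE` filter codons admit only synonymous swaps, so all
synthetic proteins share one motif class — the generator does not emulate the
real family's three filter classes, and no test pretends it does. Mutations
are applied star-like from the ancestor, matching the duplicate-heavy
structure of the real panel; phylogeny recovery is instead exercised on
random additive trees. Flanks are random ACGT with one forward-primer site
(an expansion of the Kcv9 forward primer at the annotated −376 offset) and
one reverse site (Kcv6) planted per isolate, drawn independently from the
expansion sets so the standard pair amplifies every isolate while individual
binding sites vary. What a green ground-truth test establishes is internal
consistency of collapse/translation/counting — not agreement with GenBank
data, which the package never downloads.

## 3. Single-channel model and estimators

Gating is a two-state continuous-time Markov chain with rates
`k(V) = k₀·e^{sV}`; the open level is `γ·(V − V_rev)/1000` pA (γ in pS, V in
mV) and the closed level 0. Simulation draws exponential dwells (seeded),
samples at `fs`, adds white Gaussian noise, then applies an optional low-pass
filter of cascaded single-pole sections (default 4 poles at 1 kHz — a typical
bilayer recording bandwidth; the original recordings' settings are not
published). Defaults: 5 kHz sampling, 10 s sweeps, 1 pA noise.

`idealize()` estimates the two levels by deterministic two-class k-means
(initialized at the 5th/95th percentiles), thresholds at the midpoint
(half-amplitude criterion), merges events shorter than `min_event_samples`
(default 5 samples = 1 ms at 5 kHz) into their neighbours, and — when both
states survive — re-estimates levels as dwell means with 2 samples trimmed at
each boundary to avoid filter-rise bias. The open state is the level of
larger absolute amplitude, which works at both polarities. Known limitations:
with unresolved (flicker) gating the segmentation collapses and the cluster
centers become *apparent* levels — exactly the artifact the package
demonstrates — and there is no missed-event correction or hidden-Markov
refinement; dwell statistics are only trustworthy when mean dwells are ≥
several filter rise-times.

Reference kinetics (`flicker_reference_models()`): "slow" is
k_co = k_oc = 20 s⁻¹, fully resolved at 1 kHz, used for recovery tests; under
it the conductance estimate lands within ~0.5% of the generating γ (a small
systematic underestimate remains from filter edge effects at dwell
boundaries, well inside the 5% acceptance band). "Fast" keeps Po = 0.5 but
accelerates both rates e-fold per ~29 mV of hyperpolarization (20 s⁻¹ at
+80 mV → 5000 s⁻¹ at −80 mV), which makes negative-branch gating
unresolvable at 1 kHz: the apparent negative-branch conductance falls to
roughly one third of γ while the positive branch is unaffected. Because the
negative branch is an artifact by construction, `iv_and_conductance()` fits γ
through the origin over the positive voltages only, by default. Open
probability is the open-sample fraction of the idealization; tests compare it
to the stationary value k_co/(k_co+k_oc) within three binomial standard
errors using the event count as the effective sample size.

The voltage-dependent Po phenomena of individual channels (declining Po at
positive voltages in one channel, long closures at negative voltages in
another) are representable in the model via `s_open`/`s_close` but carry no
published rate constants, so they are properties, not numeric targets.

## 4. Determinism and tolerances

All stochastic paths take explicit integer seeds; the same seed reproduces
byte-identical generator output and pipeline bundles (manifests record
content, never timestamps). Alignment and NJ are deterministic by documented
tie-breaks. Numeric tolerances used by the suite: 1e−9 for additive-tree
recovery, three standard errors for stochastic recoveries (Po, dwell means,
binomial expectations), and 5% for conductance recovery — the band stated for
the acceptance protocol, not tuned to it.
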