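---
title: "Outcross linkage mapping and comparative placement: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outcross linkage mapping and comparative placement: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmap)
```

## The mapping problem

A full-sib family from two outbred parents (a CP cross) is the workhorse
design for species without inbred lines. Every marker where both parents
are heterozygous is informative, but in three distinct ways, named after
the parental genotype patterns:

* **ab×ab** — both parents carry the same two alleles; offspring segregate
  aa : ab : bb = 1 : 2 : 1. The heterozygote class pools both parental
  origins (an a from either parent looks the same), which is why only three
  classes are observable and why these markers carry the least linkage
  information.
* **ab×ac** — one shared allele; four observable classes, 1:1:1:1.
* **ab×cd** — no shared allele; four classes, 1:1:1:1, and every offspring
  reveals exactly which allele each parent transmitted. These markers are
  fully informative.

Because the parents are outbred, the *phase* of each parent — which alleles
sit together on one homologue — is unknown and must be estimated jointly
with linkage.

## Marker quality control

`filter_markers()` applies three retention rules, in a fixed order so every
dropped marker has a single attributed reason: presence (scored in at least
80% of offspring, a threshold argument), Mendelian segregation (Pearson
chi-square against the cross type's expected ratios, df = 2 for ab×ab and
df = 3 otherwise; discard at p < α, default α = 0.05), and informativeness
(both parents heterozygous). Presence is computed over offspring only;
parents are required to be non-missing. The order (presence, then
distortion, then informativeness) makes the reported reasons partition the
input, a bookkeeping invariant the tests enforce.

## Two-point estimation with phase

For a marker pair, condition on the parental genotypes and a phase
configuration (2 choices per parent, 4 in total). Each parent transmits one
of its two haplotypes with probability (1−r)/2 each, or one of the two
recombinants with probability r/2. Summing over the 2×2 gamete
combinations consistent with an offspring's observed joint genotype gives

P(class) = (c₀(1−r)² + c₁r(1−r) + c₂r²) / 4,

where the integer coefficients c count gamete combinations by how many
recombinant gametes they involve. The coefficients depend only on the two
cross types (after relabelling each marker's alleles to a canonical frame)
and on the phase pair, so they are enumerated once; the per-pair work is a
table lookup plus a one-dimensional likelihood maximisation. `estimate_rf()`
maximises over r ∈ [10⁻⁶, 0.4999] under each phase (golden-section, ties
toward smaller r), keeps the best phase, and reports
LOD = log₁₀ L(r̂) − log₁₀ L(0.5); at r = 0.5 the likelihood is
phase-independent, so the null needs no phase choice. `twopoint_scan()` runs
the same computation over all pairs in compiled code. Missing genotypes
contribute nothing to the likelihood; pairs with fewer than two jointly
scored offspring are refused.

Two properties worth knowing. First, on fully informative ab×cd pairs the
estimator reduces to the recombinant-count ratio, which the tests exploit
as a closed-form oracle. Second, maximising over four phases slightly
inflates the null LOD: for truly unlinked pairs at n = 94–100 we measure
LOD < 1 in ≈ 94% of replicates rather than the ≈ 97–98% a fixed phase
would give. This matters only for interpreting small LODs; grouping uses
thresholds far above this noise floor.

## Grouping, ordering, distances

Linkage groups are connected components of the relation
{LOD ≥ threshold and r̂ ≤ 0.4}. The default grouping LOD of 14 follows the
practice of dense single-family RAD maps, where the threshold is scanned
and chosen so the group count matches the karyotype while stranding few
markers; `scan_grouping_lod()` produces that profile, and no automatic
selection rule is imposed.

Within a group, markers are ordered by minimising the **sum of adjacent
recombination fractions** (SARF): the 6 most informative markers (priority
ab×cd > ab×ac > ab×ab, then most scored offspring, then marker id) are
ordered exhaustively; remaining markers are inserted greedily at the
SARF-minimising position; a final ripple pass permutes every sliding window
of 4 and accepts strict improvements until none remain. SARF was chosen
over a multipoint likelihood deliberately: it is deterministic, cheap, exact
on noiseless data, and its tie structure is transparent (reversal never
changes the criterion, so orientation is fixed arbitrarily by comparing the
end-marker ids). The cost is that a multipoint HMM would use flanking
information to rescue sparse regions; on dense RAD maps the difference is
confined to sub-resolution neighbourhoods. The `ordering_lod` parameter is
accepted for interface compatibility but the SARF criterion does not
consult it.

Positions are cumulative Kosambi distances of adjacent r̂,
d = 25·ln((1+2r)/(1−2r)) cM, with r ≥ 0.4999 capped with a warning. The
per-group summary reports size (last position), locus count, mean
inter-marker distance — size/(n−1) exactly — and the largest gap.

## What the simulator emulates, and what it does not

`simulate_family()` reproduces the study design the package targets: 94 F1
offspring of one female × one male; cross types drawn with probabilities
1896:1114:136 (the observed pattern counts, normalised); 5% missing calls
and 0.5% allele-call errors by default (magnitudes are configuration
choices — typical RAD values — not published facts); an optional fraction
of markers under viability selection of strength s against one parental
allele. Transmission is a Markov chain along each chromosome: the
transmitted haplotype switches between adjacent markers with probability
equal to the inverse Kosambi of their cM separation, independently across
intervals — i.e. **no crossover interference**. Using the Kosambi function
downstream while simulating without interference is mildly inconsistent
(Kosambi implies interference); it is the simplest process consistent with
the estimation machinery, and the recovery tolerances absorb the
discrepancy. Genotyping errors replace one allele of a call with another
allele segregating at the marker, constrained to keep the call producible
from the parents; this choice keeps the expected class ratios Mendelian, so
the error process does not masquerade as distortion. Physical positions are
~100 kb apart with jitter; only relative order matters downstream.

Real RAD data differ in ways the simulator does not model: read-depth
dependent genotype quality, allele dropout at restriction-site
polymorphisms (which produces *asymmetric*, distortion-like errors),
shared-stack paralogy, and interference. Passing recovery tests therefore
demonstrates correctness of the estimation chain under its own model, not
robustness to those artefacts — the QC stage is the guard against them.

Simulation sizes used in the tests and the acceptance script are scaled to
a 6-chromosome genome at the study's marker density (130 markers per
chromosome, 94 offspring); grouping recovery is insensitive to the number
of chromosomes because it is decided by the per-pair LOD distribution.
Ordering exactness is asserted on an evenly spaced noiseless group: under
uniformly drawn positions two markers can land closer than any 94-offspring
family can resolve (zero observed recombinants), and no ordering criterion
can be exact there — that is a property of the data, not the algorithm.

## Synteny and collinearity

Homology evidence enters as 12-column tabular hit files. `filter_hits()`
drops rows above the e-value cutoff (10⁻⁹ against genomes, 10⁻²⁰ against a
transcriptome), excludes queries with more than 10 surviving hits as
repetitive, and keeps the best hit per query (bit score, then e-value, then
subject id, then subject start — a total order, so filtering is
deterministic and idempotent). Subject coordinates follow the tabular
convention (1-based inclusive, start > end on minus strand) and are
normalised internally to 0-based half-open with a strand flag; a locus's
position is the midpoint of its best hit's subject interval. Markers with
no direct genome hit can inherit the genome position of their single best
transcriptome contig (`anchor_via_transcriptome()`), flagged as
transcriptome-anchored.

`build_synteny_table()` declares a linkage group homologous to every
chromosome holding a majority (> 0.5 by default) of its hits; when no
single chromosome reaches the majority, the top two are reported if each
holds at least 5 hits and they jointly exceed the majority — the signature
of a fused or split chromosome. Both thresholds are configurable; "most
loci" is not defined more precisely in the source practice, and published
tables show single dominant chromosomes per group, which the majority rule
reproduces. Ties between near-equal chromosomes are reported as both
rather than forced to one.

`detect_blocks()` finds runs of at least two anchors, consecutive along the
chromosome, whose map order agrees with their chromosome order in one
orientation. An order violation is tolerated when the two loci are
separated by less than 5% of the linkage group's cM length **or** 5% of the
chromosome's bp length — either side suffices, the reading that maximises
detection of informative synteny. Three refinements make the rule
operational: violations are judged (and the separation measured) against
the anchor holding the run's extreme map position, not the previous anchor
— otherwise a long inverted segment would be absorbed as a chain of small
pairwise mismatches; a violation is never tolerated as a run's first step
nor twice in a row, so reversed or drifting segments form their own blocks
instead of being nibbled from a neighbour's ends; and overlapping candidate
runs are resolved longest-first (ties: fewest mismatches, then smaller bp
start), with runs unable to bridge anchors already assigned to a block —
which keeps blocks disjoint in bp. A run is interrupted by any intervening
mapped locus from a *different* linkage group; an intervening anchor from
the same group does not break a block (whether the original practice broke
there is unstated; not breaking is the permissive choice), and unmapped
genes never do. Orientation is the sign of the Kendall correlation between
map and physical position over the run's members.

## Placement of unplaced transcripts

A transcript hitting a mapped marker directly inherits that marker's exact
position (zero-width interval). Otherwise, per reference species, the
transcript is used only if it has a single genome hit; the hit midpoint is
located inside a collinear block, and the nearest anchors left and right by
bp give a species interval spanning their map positions. Consensus across
species: keep the species voting for the modal linkage group; intersect
their intervals if they pairwise overlap, otherwise keep the single
smallest interval and flag the result partial (smallest-interval reading of
"smallest possible interval"; a union would grow with discordant evidence).
A tied vote between linkage groups is a conflict — reported with all
evidence, no consensus forced. A hit outside every block is ambiguous. A
hit coinciding with a block's terminal anchor yields the degenerate
one-sided case reported as edge. Placement adds no tolerance of its own:
all order-mismatch allowance lives in block construction. Consensus
intervals are never wider than any contributing species interval, and the
result is invariant to the order species are supplied in.

## Numerical and format choices

* rf optimisation on [10⁻⁶, 0.4999], golden-section to 10⁻⁶; LOD clamped
  at 0; ties toward smaller rf.
* cM serialised with 6 decimals, bp as integers; rows ordered (group,
  rank) so file diffs are meaningful. Circos linkage-group coordinates are
  cM × 10⁴ as integer units.
* Genotype files: TSV with header `marker_id, P1, P2, <offspring ids>`,
  cells `x/y` over alleles a–d, `-` missing; writers restore the original
  allele symbols so write∘read is the identity.
* Degenerate inputs are refused loudly: empty marker sets, single-anchor
  sets, pairs with fewer than two jointly scored offspring, rf outside
  [0, 0.5), fusing a chromosome with itself.

## Known limitations

Sex-averaged map only (no separate maternal/paternal recombination);
no multipoint likelihood; phase is estimated per pair and not reconciled
globally; no QTL machinery. The collinearity tolerance is a heuristic for
assembly/map noise, not a rearrangement test: inversions shorter than the
tolerance scale are deliberately absorbed. Placement accuracy is bounded by
anchor density — the consensus interval cannot be smaller than the local
inter-anchor spacing.
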