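---
title: "Methods: identity-based clade delimitation, chimera screening, OTU ecology and probe design for a 16S endosymbiont genus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identity-based clade delimitation, chimera screening, OTU ecology and probe design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`megascreen` implements a desk-scale survey pipeline for an intracellular
bacterial genus ("*Ca.* Megaira", an endosymbiont of ciliates, algae and
aquatic metazoa) observed only through its 16S rRNA gene: full-length
reference sequences on one side, and large collections of short,
environment-labelled amplicon reads on the other. This vignette explains the
models and procedures behind each stage, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the design
choices made where the methodology was genuinely open.

## Pairwise identity and species-level clades

All identity arithmetic rests on one explicit definition. Two sequences are
aligned by optimal global alignment with free terminal gaps (match +2,
mismatch −1, gap −2 per position; the dynamic programming is delegated to
`Biostrings::pairwiseAlignment(type = "overlap")`). Percent identity is
then

> 100 × (matching columns) / (aligned columns),

where terminal-gap columns are excluded (the compared genes have unequal
lengths, and overhangs carry no signal), internal gap columns count as
mismatches, and IUPAC-degenerate positions match iff their expansion sets
intersect. The definition is stated this explicitly because the numeric
identity of a given pair — and therefore where it falls relative to a
species threshold — depends on it. Identity values are conventionally
reported to one decimal; all clustering operates on unrounded values.

Species-level clades are the connected components of the graph whose edges
join sequence pairs at or above the species threshold, i.e. single-linkage
clustering. The default threshold is 98.7%, the upper bound of the
98.65–98.7% range conventionally used to discriminate bacterial species on
16S identity. Single linkage is a deliberate choice over complete linkage:
heterogeneous clades exist whose within-clade identity *minima* fall well
below the species cut (down to 96.5% in this genus) while every member is
chained to the clade through above-threshold links. Complete linkage would
shatter such clades; single linkage keeps them whole, which matches how the
genus is actually partitioned. The cost is the usual chaining risk, which
the threshold's conservative (high) default mitigates.

Clade labels (`A`, `B`, ...) are assigned by descending clade size with
ties broken by the lexicographically smallest member id, so the partition
is invariant to input order up to labelling.

## Chimera screening by split-and-compare

PCR and cloning can fuse fragments of two templates into a chimeric 16S
sequence. When the two parents belong to different clades of the same
genus, the chimera looks like a plausible novel lineage and is hard to spot.
The screen implements the split-and-compare logic: slide a candidate
breakpoint along the query, evaluate each side's best-matching reference
independently, and call a chimera when the two sides tell different
stories.

Concretely, for every breakpoint `b` in `[end_margin, L − end_margin]`
(step `scan_step`, defaults 100 and 10 nt), the prefix `query[1..b]` and
suffix `query[(b+1)..L]` are scored against every reference, and the `b`
maximizing (best prefix identity + best suffix identity) is examined. The
query is a chimera iff

1. *support*: each half matches its own parent at least as well as the full
   query matches that parent, minus `delta_support` (default 1%);
2. *conflict*: the two parents belong to different clades; and
3. each half matches the *other* half's parent worse by at least
   `delta_conflict` (default 3%).

The deltas quantify "similar to the whole sequence" and "significantly
different": 1% sits inside the within-clade identity regime (≥ 98.6%),
3% separates it from the between-clade regime (≤ 98.5%).

Two numerical points. First, the full query is aligned once against every
reference and half identities at every breakpoint are derived from
alignment-column prefix sums; for substitution-only divergence this equals
re-aligning each half, and for indel-containing queries it is a tight
approximation — it is what makes scanning hundreds of breakpoints
affordable. Second, the reported breakpoint is the smallest `b` attaining
the maximal score. When the two parents are identical across a conserved
stretch around the true cut, every breakpoint in that stretch yields
literally the same chimera; the true cut is unidentifiable within that
plateau and the reported position is its left edge. Accuracy should
therefore be judged against the equivalence interval, not the recorded
truth point, and the test suite does exactly that.

The detector's operating regime follows from condition 3: a chimera is
detectable only when its parents diverge by more than `delta_conflict` on
*each side* of the breakpoint. Chimeras between clades closer than that are
invisible to any split-and-compare screen — they differ from a clean
sequence by less than the method's own resolution. The generator therefore
offers `min_half_divergence`, which rejection-samples parent pairs and
breakpoints until both halves diverge by a stated margin; sensitivity
claims (and the acceptance checks) are made in that regime, using
`delta_conflict + 0.5%` where the extra half percent absorbs scan-grid
quantization at the breakpoint.

## Hypervariable regions and anchoring

Short amplicons cover different stretches of the gene and must be analysed
per region. A read is anchored to a user-chosen full-length reference
coordinate system (a real *E. coli* 16S or the synthetic ancestor) by the
same ends-free alignment; its mapped span is the reference interval covered
by the aligned part of the read, and mapping identity below 60% raises an
"unanchorable" error rather than returning a junk span. The default
windows, on canonical *E. coli* numbering, are V1–V2 = 8–338,
V4–V6 = 515–1064 and V7–V8 = 1115–1392, matching the common primer pairs
spanning those multi-region amplicons; they are configurable because no
universal boundary definition exists.

A read is assigned to the region whose window covers at least 80% of its
mapped span, and to `"other"` otherwise. With non-overlapping windows and a
threshold above 50% at most one region can qualify, so the rule yields
exactly one label per read and cannot double-assign straddling reads.

## The genus screen, OTUs and ecology indices

The screen retains reads strictly longer than 300 bp whose best identity
against any query reference reaches 95% — the conventional genus-level
similarity screen for mining public amplicon collections. An 8-mer
prefilter (fraction of read 8-mers present in the reference 8-mer pool,
cutoff 0.15) discards unrelated reads before any alignment: a read at 95%
identity keeps roughly two thirds of its 8-mers intact, an unrelated random
read essentially none, so the cutoff is far from the decision boundary and
only saves time.

Retained reads of one region are clustered into OTUs by the greedy centroid
algorithm at 99% identity: reads sorted by descending length (ties by id),
the first read seeds OTU 1, and each subsequent read joins the *first*
existing centroid it matches at or above the threshold, else seeds a new
OTU. The visit and centroid order are fully specified, which is the one
degree of freedom centroid-based tools usually leave to internal defaults;
fixing it makes runs reproducible bit for bit. The member–centroid
invariant (every member ≥ threshold to its centroid) is asserted in the
tests, together with a lower bound from exhaustive minimum clique cover on
tiny read sets — greedy clustering can never use fewer clusters than the
optimum.

Each OTU is attributed to an environment from the closed category
vocabulary (Freshwater; Seawater; Soil; Artificial/Anthropogenic; aquatic
animals; plants; terrestrial animals): a single environment if more than
50% of member reads share it; two environments (`"A+B"`) if exactly two
categories tie for the maximum; `"Unclassified"` otherwise. The third rule
is this package's reading of the open case (for example member fractions
45/35/20: no majority, no two-way tie); with it the three outcomes are
exhaustive and mutually exclusive.

Two ecology indices are computed per clade and category:

* **frequency of occurrence** — positive samples (≥ 1 retained read
  assigned to the clade; no minimum-read threshold) divided by samples in
  the category, as a percent; undefined (`NA`), never 0, for categories
  without samples;
* **relative abundance** — the mean over *positive samples only* of clade
  reads over total sample reads, as a percent; undefined when no sample is
  positive. Adding negative samples leaves it unchanged by construction.

## Region trees

Per-region trees are built by Saitou–Nei neighbor joining on the distance
`100 − identity`, with no evolutionary-model correction — a deliberate
desk-scale stand-in for likelihood inference, adequate for the short
distances involved (a few percent). The joining is `ape::nj()`; negative
branch lengths, which NJ produces on non-additive matrices, are clamped to
zero with the deficit moved to the sister branch so path lengths are
preserved as far as possible. On additive matrices NJ is exact, and the
tests hold it to that. Trees include the OTU centroids plus the full-length
references projected (sliced) into the region window, so reference clades
are visible next to the OTUs.

## Probe design and in-silico specificity

Hybridization (FISH) probes are stored antisense, 5'→3' as synthesized,
and matched against gene-sense sequences through their reverse complement.
A probe hit at a gene offset is counted by the IUPAC intersection rule per
position; specificity screening counts *sequences* (not match positions)
with at least one hit at 0 and at 1 allowed mismatches, in a target and a
non-target set — the counting convention of TestProbe-style database
screens.

Melting temperatures use the classical GC-content formula

> Tm = 69.3 + 0.41 · %GC − 650 / L,

with degenerate bases contributing their expected fractional GC (Y = 0.5,
B = 2/3, ...), rounded half-away-from-zero to 0.1 °C. The formula was fixed
by verifying, by linear solve over the five (L, %GC, Tm) triples of the
distributed "*Ca.* Megaira" probe set, that it reproduces every printed
value to 0.1 °C — notably both 21-mers with 12 G+C print the same Tm, which
a nearest-neighbor model would not produce. The formula's regime requires
≥ 14 nt; shorter input is an error, not an extrapolation.

Probe design enumerates all candidate sites of length 18–21 inside a target
window (default positions 66–95 of the reference numbering, the
hypervariable stretch where clade probes for this genus are conventionally
placed), builds the degenerate consensus of the targets at each site
(degeneracy only where targets vary, at most 2 degenerate positions), and
keeps candidates whose Tm falls in 52–64 °C, that hit *every* target and
*no* non-target at 0 mismatches. Survivors are ranked by non-target hits at
1 mismatch, then degeneracy, then closeness of Tm to the range midpoint.
When no site separates the sets — clades identical across the window — the
result is an empty list carrying a diagnostic, which is a finding, not a
failure: a clade without a private window sequence has no clade probe in
that window.

## The synthetic-data generator

Every stage is tested against generated data with complete ground truth.
The generator emulates, in order of importance:

* **clade structure** — one random ancestor (default 1400 nt, 50% GC); one
  root per clade whose divergence from the ancestor is drawn uniformly from
  1.0–1.75%, so pairwise between-clade divergence lands in roughly
  2.0–3.5%, the between-species band for this genus, while staying far
  enough from the 98.7% threshold that binomial noise at this gene length
  cannot merge clades; members mutated at half the within-clade divergence
  (default 1.0% pairwise) from their root;
* **conserved-vs-hypervariable architecture** — eight V-like blocks
  (about 38% of the gene) mutate 5× faster than the backbone, enough for
  region trees and window probes to separate clades while keeping the 95%
  genus screen passable;
* **chimeras** — exact prefix+suffix fusions of two parents from different
  clades, cut uniformly inside a margin, with the truth table recording
  parents and breakpoint (and optionally restricted to the detectable
  regime, above);
* **environment-labelled samples** — per-category sample counts, per-clade
  occupancy probabilities (defaults loosely shaped like the genus's
  reported habitat pattern: three freshwater-preferring clades, one
  marine-leaning clade, one rare clade), log-uniform relative abundance
  fractions (default 0.01–0.06%), nominal depths of 5000–20000 reads, and
  reads sliced from a region window of a random clade member with per-base
  substitution error 0.002. Read lengths are drawn so that at least 80% of
  each read lies inside its source window and reads exceed the 300 bp
  screen. Background reads are random sequence at 55% GC, which guarantees
  they fail the 95% screen; only a capped number per sample is physically
  emitted, the nominal depth serving as the abundance denominator.

Mutations are substitutions only (an indel-free model), so identity
arithmetic, breakpoint truth and slice coordinates stay exact. That is the
generator's main departure from real data, along with: no quality scores or
chimera-formation kinetics, no length heterogeneity beyond the window
policy, independence of samples, and a star topology within and between
clades (no nested substructure). Passing tests therefore demonstrate the
algorithms' correctness on clade-structured, substitution-diverged data —
not robustness to indels, alignment ambiguity, or database contamination.

## Problem sizes and determinism

All stochastic stages are seeded and byte-reproducible: the same spec and
seed give identical FASTA output. The test and acceptance runs use sizes
chosen to exercise every code path at desk scale: a 20-member, 5-clade
genus (1400 nt) for clade recovery and probe design; 50 constructed
chimeras against 10 references plus 100 clean members for the chimera
operating characteristics; 100 random 8-read sets against the exhaustive
clique-cover oracle; 200 single-category samples for occupancy recovery
(checked against the exact binomial 95% interval) and 20 replicate
15-sample runs for abundance recovery (checked against a 95% t-interval);
and a 10-sample three-category end-to-end run. The published full-scale
survey counts (thousands of samples and centroids) depend on reads that are
not redistributed and are not reproduction targets here.

## Known limitations

* Identity values are method-sensitive: a different aligner, gap model or
  identity definition shifts pairwise values by a few tenths of a percent,
  which matters near the species threshold. The definition used here is
  fixed and stated; comparisons with values computed elsewhere should
  allow for that.
* The chimera screen assumes two parents and one breakpoint; multi-parent
  chimeras and chimeras between clades closer than `delta_conflict` are out
  of reach by construction.
* Greedy OTU clustering is order-dependent by design (the order is fully
  specified); it approximates, not solves, the minimum-cluster problem.
* NJ trees are uncorrected-distance trees for visual clade separation, not
  model-based phylogenies; bootstrap support is out of scope.
* The sample generator's occupancy defaults are plausibility settings for
  testing recovery, not estimates of real habitat preferences.
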