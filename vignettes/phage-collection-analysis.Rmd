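---
title: "Methods: quantitative analysis of a phage collection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of a phage collection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagetools)
```

This vignette documents the models behind each stage of the package, the
parameters that matter, the conventions chosen where the underlying
definitions leave room, and what the synthetic-data validation does and
does not establish.

## Scoring the cross-infection matrix

The substrate is a phage × host grid in which each cell is either a
measured titer (PFU/ml, strictly positive) or one of three categorical
states: *resistant* (no clearing zone, no plaques), *impaired* (clearing
at high titer but no viable progeny — evidence of adsorption without
productive infection) and *not assessed*. Impaired cells are scored
exactly like resistant ones, because no viable phage is produced; the
state is kept in the data model for reporting.

The Paired Difference Index contrasts an entity's highest log10 infection
score with all its other scores:

$$\mathrm{PDI} = \frac{\sum_{i=2}^{N} (P_1 - P_i)}{N - 1},$$

with the $P_i$ sorted in decreasing order. Two conventions are explicit
in `scoring_policy()`:

* **Null handling.** `"floor"` (default) scores every non-titer cell at a
  detection-limit floor (`floor_value`, default 1 PFU/ml, log-score 0);
  `"drop"` removes those cells from both the sum and the denominator —
  the literal reading of treating null scores as non-assigned. Under
  `"drop"` a row can be left with fewer than two usable counterparts;
  such rows are flagged `insufficient_counterparts` rather than returning
  a silent `NaN`.
* **Normalization.** With `normalize = TRUE` (default) the log-scores are
  divided by the row maximum before differencing, which bounds the index
  in $[0, 1]$ and makes a fully uniform row score exactly 0. Without it
  the index is in raw log10 units and unbounded. Only the raw convention
  is invariant to multiplying all titers in a row by a common factor (the
  common log-shift cancels in the differences); the normalized ratio
  $(\ell_i + c)/(\ell_1 + c)$ is not scale-free, and the test suite
  asserts the invariance for the raw convention only.

Rows with no measured titer at all have an undefined log profile. They
are assigned PDI = 1 and flagged: this is the only assignment consistent
with the resistant host class, since the susceptibility score is
$1 - \mathrm{PDI}_{host}$ and fully resistant hosts must score exactly 0.
Host classes follow fixed thresholds: score 0 → resistant, (0, 0.5) →
slightly susceptible, ≥ 0.5 → susceptible (boundary inclusive).

One consequence of the default floor deserves note: a host reached by a
*single* phage scores exactly 0 (the floored cells contribute log-score
0, so its PDI is 1) and is classified resistant. If the floor is placed
at the assay's detection limit instead (e.g. `floor_value = 100` for a
plating series that cannot see below 10² PFU/ml), the same host scores
strictly between 0 and 0.5. Both behaviours are tested; which is
appropriate depends on how the assay's zeroes should be read, which is
why the floor is an explicit parameter rather than a constant.

## Phylogenetic neighborhood and class association

`patristic_distance_matrix()` sums branch lengths along leaf-to-leaf
paths (via `ape`); trees without branch lengths are refused rather than
silently defaulting to unit lengths. `neighborhood_profile()` takes, for
each strain, the `k = 6` closest other strains — ties at the k-th rank
broken by lexicographically smaller identifier, making the profile
deterministic and input-order invariant — and reports the mean distance
(*polymorphism*, branch-length units) and the fraction of neighbors
sharing the focal strain's trait value (*trait specificity*, in
$[0, 1]$). The fraction was chosen over a binary indicator or an entropy
because it degrades gracefully with mixed neighborhoods; the statistic is
a deliberate, documented operationalization, and the focal strain is
never counted in its own neighborhood.

Class differences are tested with the tie-corrected Kruskal–Wallis rank
test followed by all pairwise two-sided Mann–Whitney U tests, reported
raw and Benjamini–Hochberg adjusted (the adjustment choice is ours;
both columns are always present). Degenerate data with no rank variance
return H = 0, p = 1 by definition instead of the 0/0 the tie correction
would produce. The p-values use the standard χ² approximation, as the
field's tooling does; the test suite therefore validates the H statistic
against an independent rank-formula implementation and the U statistics
against exhaustive enumeration, rather than chasing exact permutation
tails at tiny group sizes.

## BBH families and the pangenome graph

All-vs-all protein similarity has two engines behind one interface.
`engine = "blast"` (default) shells out to NCBI BLAST+ — the standard
choice at proteome scale — and summarises the best HSP per ordered pair.
`engine = "pairwise"` is an exact Smith–Waterman via Biostrings
(BLOSUM62, gap open 11 / extend 1, `X` scored 0 against everything); it
is quadratic and intended for small inputs, and serves as the reference
implementation in the tests. Identity is defined as identical residues
over aligned columns and coverage relative to the *shorter* protein, the
two quantities the downstream cutoffs are phrased in. Precomputed hits
from an external search tool can be loaded with `read_similarity_hits()`
for exact replication of a particular search configuration.

BBH edges require mutual best hits (per ordered genome pair; ties broken
by score, then identity, then lexicographic target id) passing identity
> 20% and coverage > 50% strictly. Families are connected components over
the union of all genes, so genes with no edge become singleton families
and the families partition the gene set exactly; the persistence spectrum
reports the fraction of families present in > 80%, < 20% and
intermediate shares of the genomes.

The pangenome graph counts direct gene-order adjacencies: each genome
contributes one count per consecutive pair of genes (same-family tandem
pairs yield self-loops), strand ignored, genomes treated as linear by
default (`circular = TRUE` adds the wrap-around adjacency). For linear
genomes this gives the conservation law $\sum w = \sum_g (n_g - 1)$,
which the tests assert on every simulated genome set.

Rank classification applies single-linkage clustering (connected
components of the ≥ t graph) to a symmetric intergenomic similarity
matrix at the ICTV-style thresholds family ≥ 50%, genus ≥ 70%, species
≥ 95%. Because the thresholds increase, the partitions are nested by
construction.

Dollo parsimony places each family's single gain on the branch to the
most recent common ancestor of the genomes carrying it and a loss on each
maximal family-free subtree below the gain, which is the minimal-loss
completion; the tests verify minimality by exhaustive search over all
internal-state assignments on 6-leaf trees.

## Recombination, divergence and selection

Per-family divergence is the mean over unordered sequence pairs of
identical columns divided by mutually non-gap columns; pairs with no
shared column are excluded with a warning. A family is *divergent* when
this mean falls below 95% (the threshold is a parameter). The taxon
subset is explicit so an outgroup can be excluded from the comparison.

Recombination events arrive as a Gubbins-style GFF on the concatenated
core-gene alignment: 1-based inclusive coordinates in the file, converted
to the package's 0-based half-open convention on parse (the conversion is
bijective and round-trip tested), with affected taxa and branch kind
recovered from the attribute field when present. `map_events_to_genes()`
counts an event for every family whose interval shares at least one
column with it — no minimum-overlap fraction, since any overlap is
evidence of recombination at that locus — using untrimmed coordinates
(event prediction and dN/dS trimming are independent analyses).

The counting dN/dS is a Nei–Gojobori-style estimate: codon columns with
≥ 20% gapped sequences are trimmed; synonymous/nonsynonymous site counts
per codon average the fraction of the three single-nucleotide changes per
position that preserve the amino acid (changes creating stops counted as
nonsynonymous); observed differences average over all mutational pathways
with equal weight; proportions are Jukes–Cantor corrected. The ratio is
flagged undefined when dS = 0 or a proportion leaves the Jukes–Cantor
domain, never returned as Inf/NaN. This counting estimate is a
transparent, dependency-free statistic — it is *not* asserted to match a
codon-model fit, and model-based values computed externally are imported
with `read_dnds_table()` when exact replication is needed.

`divergence_association()` reports the Mann–Whitney comparison of event
counts between divergent and non-divergent families and Spearman
correlations of identity with event count and with dN/dS, raw and
BH-adjusted, degrading to a correlation-only report (with a warning) when
one divergence group is empty and flagging correlations against constant
vectors as undefined.

## Life-history estimation

Adsorption: free fractions are titers divided by the input titer; the
rate is the negated slope of the least-squares fit of ln(fraction) on
time over positive fractions, reported with R². Fractions above 1 are
retained with a warning — they are counting noise, and discarding them
would bias the fit.

One-step growth: replicates must share a time grid (averaging across
replicates happens *before* change-point detection; interpolation is
refused rather than silently applied). The rise index is the first point
exceeding `rise_factor` (default 2) times the running mean of all earlier
points; the baseline is the pre-rise mean (the infection-center level);
the first plateau is the earliest maximal run of ≥ 2 consecutive
post-rise points whose relative spread (max − min)/mean is within
`plateau_tol` (default 0.15). Burst size is plateau mean over baseline
mean — invariant to uniform rescaling of counts — and the latent period
is the last pre-rise time plus the adsorption duration. "First plateau"
and "initial increase" have no universal operational definition, so both
knobs are explicit parameters with the defaults above; a curve that never
exceeds the rise threshold raises "no burst observed" (interpretable as
burst ≤ rise_factor), and a rise with no stable plateau raises an error
carrying the post-rise counts as diagnostics.

## The synthetic-data generators

Each generator takes a single integer seed and is fully deterministic
given it; identical seeds give byte-identical outputs.

**Infection matrix** (`simulate_infection_matrix()`). Defaults mirror the
study design this package targets: 18 phages × 157 hosts, 3/18
specialists, log-titers clipped to the observable [10², 10⁸] PFU/ml
range, noise 0.3 log10 units. Host classes are drawn as 35% resistant /
30% slightly susceptible / 35% susceptible — a realistic three-way split
for a host panel spanning resistant clades and generalist targets, fixed
once and exposed as a parameter rather than a constant. Generalists
infect every susceptible host (log-mean 6), each slightly susceptible
host is reached by a 15–35% minority of generalists (log-mean 5), and
each specialist infects 2–4 "home" hosts at log-mean 8; a fraction of
resistant hosts' cells are recorded impaired. This construction makes the
true class recoverable from the scored matrix by design — which is
exactly what it is for: validating the scoring chain, not imitating every
correlation structure of a real assay (no phylogenetic autocorrelation
between hosts, no titer gradients within a clade, no plate effects).

**Genome collection** (`simulate_phage_genomes()`). A rooted random tree
(`ape::rtree`) carries core families (default 285, present everywhere,
fixed gene order), accessory families (default 258) assigned to island
positions, and recombination hotspots defaulting to two 5-gene blocks at
~45% and ~75% of the core order — the two-hotspot architecture of large
conserved phage genomes. Sequences evolve by per-site nucleotide
substitution (probability `subst_rate` × branch length per site,
stop-creating mutations rejected); gene lengths are uniform within ±60%
of 180 codons, matching typical phage gene sizes. Accessory gains are
scripted on random branches and losses below them are accepted only if
they keep the scripted history Dollo-canonical (the present set's MRCA
stays at the gain node and no accepted loss empties its sibling), so the
emitted presence/absence matrix reconstructs to exactly the scripted
gains and losses — making truth comparison exact rather than
approximate. Recombination injections replace a codon segment (30–70% of
the gene) in all genomes below a recipient branch with the donor
lineage's allele, additionally diverged by `donor_divergence = 0.15`
substitutions/site to emulate recombination with unsampled relatives;
without that extra divergence a within-collection segment swap at low
substitution rates barely moves identity, whereas observed recombined
loci are markedly more divergent than the core background. True event
coordinates on the concatenated core alignment are emitted as a
Gubbins-style GFF.

**Kinetics** (`simulate_kinetics()`). Defaults: burst 38, latent period
35 min, adsorption rate 0.5/min, four replicates on a 0–90 min grid
sampled every 10 min, multiplicative lognormal noise with sdlog 0.1.
Curves are piecewise: baseline until the end of the latent period, a
geometric-midpoint rise over one sampling interval, then an exact
plateau, so the zero-noise round trip through `one_step_growth()` is an
identity.

What the passing tests show: the estimators recover the truth their
inputs encode, at study scale, under the stated noise. What they do not
show: robustness to structure the generators deliberately omit — host
phylogenetic autocorrelation in the matrix, indels and rearrangements in
the genomes (alignments are gapless by construction), codon-usage bias,
or non-lognormal count error in the kinetics.

## Numerical conventions and problem sizes

Coordinates are 0-based half-open internally and 1-based inclusive on
GFF I/O. Gene identifiers must be globally unique across a genome set.
Best-hit and nearest-neighbor ties always break deterministically
(score, identity, then lexicographic id; distance then lexicographic id).
Matrix symmetry is enforced within 1e-6 where symmetric input is a
precondition. The validation suite runs PDI brute-force comparison on
1000 random rows (agreement within 1e-12), BBH recovery on 18 genomes ×
290 families at substitution rate 0.02, Dollo versus exhaustive search on
10 random 6-leaf trees × all presence patterns, recombination mapping on
10⁴ random events, and 200 seeded kinetic replicates at 10% noise
(median burst error observed ≈ 3%, well under the 10% design bound).
These sizes were chosen as the smallest that exercise each stage at the
scale of a real collection.

## Known limitations

* The BLAST engine inherits BLAST+'s heuristics; for borderline hits near
  the 20%/50% cutoffs the exact engine (or an external-search hit table)
  is the reference.
* The counting dN/dS saturates (Jukes–Cantor domain) on short or highly
  divergent alignments and is flagged undefined there; it is a screening
  statistic, not a substitute for codon-model inference.
* Dollo parsimony forbids convergent gain; families that were truly
  acquired twice (e.g. repeated horizontal transfer of an anti-defense
  island) will be reconstructed as one deep gain plus extra losses.
* The GenBank reader handles simple and complemented single-interval CDS
  locations with `/translation` qualifiers; compound (join) locations are
  refused explicitly rather than mis-parsed.
* PDI conventions beyond the two implemented (e.g. alternative
  normalizations of the underlying bipartite-network literature) are out
  of scope; the policy object is the extension point.
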