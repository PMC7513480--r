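---
title: "Evaluating a DNA barcode locus: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a DNA barcode locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

## The problem

A DNA barcode is a short, universally amplifiable locus whose sequence
variation separates species.  Whether a candidate locus — here the
nuclear ribosomal ITS2 spacer, a standard plant barcode — actually works
for a group such as the banana genus *Musa* is an empirical question
with several parts: do within-species (intra-specific) and
between-species (inter-specific) distances separate (the *barcoding
gap*)?  Can an unknown sample be assigned to the right species by its
nearest reference?  How much polymorphism does the locus carry per
taxonomic group, and is it compatible with neutral evolution?  Can
cheap PCR-RFLP assays (restriction digests of the amplicon) stand in
for sequencing?

`barcodeval` implements this whole evaluation over a species-labelled,
pre-aligned FASTA.  Alignment itself, marker trimming and wet-lab steps
are out of scope: the package consumes trimmed, aligned barcode
sequences.  A synthetic-data generator produces ITS2-like reference
sets with known truth, so every statistic can be validated against
constructions where the right answer is known.

## Distances: the Kimura 2-parameter model

For an aligned pair, sites where either residue is a gap or an IUPAC
ambiguity code are excluded (*pairwise deletion*; an ambiguity is never
partially matched, which keeps results deterministic).  Over the
remaining sites with transition proportion $P$ (A↔G, C↔T) and
transversion proportion $Q$,

$$ d = -\tfrac12 \ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right] $$

substitutions per site.  Two undefined cases are flagged rather than
coerced to a number: zero comparable sites (`no_sites`) and a
non-positive logarithm argument (`saturated`).  Saturated pairs are
excluded from every downstream mean with a reported count — clamping
them to an arbitrary large value would bias the divergence metrics.
Pairwise (not complete) deletion is used because the whole analysis is
pairwise; complete deletion would let one gappy sequence delete sites
for everyone.

## The six divergence metrics

The barcoding literature summarises a labelled distance matrix with six
metrics, which differ in their *weighting unit*.  The package makes the
unit explicit in its output because two of the metrics differ **only**
in weighting:

| metric | unit averaged | definition |
|---|---|---|
| `all_inter` | sample pair | mean over all between-species pairs |
| `theta_prime` | species pair | between-species distances averaged within each species pair first |
| `min_inter` | species | each species' nearest heterospecific distance |
| `all_intra` | sample pair | mean over all within-species pairs |
| `theta` | species | per-species mean intra distance (species with ≥ 2 samples) |
| `coalescent_depth` | species | per-species maximum intra distance (≥ 2 samples) |

The reported `±` value is the standard deviation over the averaged
units.  That is an interpretation choice — dispersion could also be a
standard error or a model-based variance — and it is stated here
because published tables rarely say which they use.  Species without
two samples are excluded from the intra-side species metrics and the
eligible counts are reported.

## Barcoding gap

`gap_histogram()` bins the two distance distributions into half-open
bins $[k\,w, (k+1)\,w)$ anchored at 0, with width $w = 0.008$ distance
units by default — a scale fine enough to resolve typical intra/inter
separations.  Anchored half-open bins make the binning bit-reproducible
(no data-driven break placement).  The single-number summary is the
`overlap_fraction`: the proportion of inter-specific distances that are
≤ the maximum intra-specific distance (0 for a perfect gap).
`proportion_below()` reports threshold proportions such as the fraction
of inter-specific distances below 0.135.

The two distributions are compared with a Wilcoxon rank-sum test.  The
exact two-sided p-value is used when both samples have ≤ 10
observations and no ties; otherwise the normal approximation with
midranks, tie-corrected variance and continuity correction.  A caution
documented deliberately: at very small sample sizes (roughly, either
sample below 5) the normal approximation can differ from the exact
p-value by more than 0.1 — this is a property of the approximation
itself, not of any implementation, so small-sample comparisons should
always use the exact path (as the default rule guarantees for
distance-class comparisons of that size).

## Species identification

Both identifiers run leave-one-out at the sample level: each sample is
queried against every remaining sample, with its conspecifics retained
in the database.  Outcomes follow the standard three rules: *correct*
when every top hit is the query's species, *ambiguous* when the top
hits span two or more species, *incorrect* when the single top-hit
species is wrong.  Queries whose distances are all undefined are
*unassignable*, reported separately so the four percentages still sum
to 100.  Tied hits that are all conspecific count as correct — the tie
conveys no conflicting information about the species.  Distance ties
use a tolerance of 1e−12 (distances are floating point); alignment
scores are integers, so their ties are exact.

The nearest-distance method reads the K2P matrix.  The
best-local-alignment-hit method ("BLAST1"-style) aligns the gap-stripped
query against each gap-stripped reference by Smith–Waterman local
alignment with megablast-like scoring: match +1, mismatch −2, and a gap
of length $k$ costing $5 + 2k$ (the gap-open penalty is charged once
per gap, plus the extension per base — stated explicitly because "open
−5, extend −2" is ambiguous between conventions).  Ambiguity codes
never score as matches.  The search is exhaustive rather than
k-mer-seeded; at reference-database scale (hundreds of sequences) the
quadratic cost is irrelevant and exactness simplifies tie handling.
Species from which only one sample exists can never be identified
correctly under leave-one-out; they are flagged in the per-species
table rather than silently depressing the rates.

## Polymorphism and neutrality

All statistics are computed over the *indel-free site set*: any column
containing a gap or ambiguity in any analysed sequence is excluded.
The exclusion is per analysed group, not global, so each group is
scored on its own maximal clean site set.  With $n$ sequences, $L$
included sites, $S$ segregating sites and $\bar k$ the mean pairwise
difference count:

* nucleotide diversity $\pi = \bar k / L$;
* Watterson's $\theta_W = S / (a_1 L)$, $a_1 = \sum_{i=1}^{n-1} 1/i$;
* haplotypes $H$ = distinct residue strings over included sites,
  numbered by first occurrence;
* Tajima's $D = (\bar k - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}$ with the
  standard constants $a_2, b_1, b_2, c_1, c_2, e_1, e_2$.

$D$ is undefined for $n < 4$ or $S = 0$ and is reported as `NA` with a
reason — never silently 0, because 0 is a meaningful value (neutrality).
ITS2 is non-coding, so the package computes total-site statistics only;
a silent/non-synonymous split would require inventing a reading frame
that the locus does not have, and no default pipeline should do that.

## In-silico restriction digestion (PCR-RFLP)

Recognition patterns are IUPAC-degenerate (AvaII's `GGWCC` matches
`GGACC` and `GGTCC`); scanning is exhaustive on the ungapped forward
strand, including overlapping matches — sufficient for the palindromic
built-ins MseI (`T^TAA`), PstI (`CTGCA^G`) and AvaII (`G^GWCC`), and
verified by a forward-plus-reverse-complement scan in the tests.  In
strict mode (default) an ambiguity code in the *sequence* never matches
any pattern letter; a permissive mode matches on IUPAC-set
intersection.  Molecules are linear (barcode amplicons are), cut
positions are de-duplicated, and a "cut" falling at either molecule end
is not a cut.  Every digest reports both the 1-based cut positions and
the sorted fragment lengths, which always sum to the ungapped length.

Discrimination power of an enzyme (or enzyme pair) is the number of
haplotype pairs whose fragment-length multisets differ; ties in the
ranking break toward fewer total cuts (cheaper assays), then name.

## Trees

Neighbor-joining (Saitou–Nei) over the K2P matrix provides the
clade-level sanity checks; likelihood tree inference is deliberately
out of scope, as it would dominate the package without adding to the
evaluation statistics.  Negative NJ branch lengths are clamped to zero
with a logged count (the common convention).  Bootstrap support
resamples alignment columns with replacement, recomputes K2P + NJ, and
reports the percentage of valid replicates containing each original
bipartition; replicates with undefined distances are dropped and
counted.  1000 replicates is the conventional default.

## The synthetic-data generator

`simulate_barcode_set()` emulates an ITS2-like reference set: alignment
length uniform on 325–375 bp, root GC 0.60, and species-structured
divergence under the K80 model with transition/transversion ratio
$\kappa = 2$ (a typical nuclear value; configurable).  Defaults for the
divergences are 0.19 between and 0.035 within species — the regime of a
usable plant barcode.

Design choices worth stating:

* **Star phylogeny among species (default).**  Every species ancestor
  descends independently from the root, so the expected inter-specific
  divergence is uniform across species pairs and analytically
  checkable.  A `bifurcating` mode substitutes a random species tree
  (returned in the truth table) for tree-reconstruction tests.
* **Branch lengths.**  Species ancestors sit at
  $(d_\text{inter} - d_\text{intra})/2$ from the root and samples at
  $d_\text{intra}/2$ from their ancestor.  With these lengths the
  expected pairwise path is exactly $d_\text{intra}$ within and
  $d_\text{inter}$ between species, so the K2P estimator's consistency
  can be tested against the nominal values directly.  (Putting species
  ancestors at $d_\text{inter}/2$ instead would make between-species
  pairs diverge by $d_\text{inter} + d_\text{intra}$ — a small but
  systematic bias that a 3-standard-error recovery test detects.)
* **No indels by default** (the alignment is trivially correct); an
  `indel_rate` option gaps short runs to exercise pairwise-deletion and
  indel-exclusion paths.
* **One seeded generator** drives everything; a fixed seed reproduces
  the FASTA byte for byte.

`simulate_coalescent()` draws a Kingman genealogy (merge rate
$k(k-1)/2$), adds Poisson mutations at rate $\theta/2$ per unit branch
length on distinct sites (infinite sites on $L$ positions, collisions
retried, error if the locus is too short), and emits binary variants on
an A background with derived allele G.  Under this model
$E[S] = \theta a_1$, $E[\bar k] = \theta$ and $E[D] \approx 0$, which
is exactly what the validation uses.

`plant_restriction_haplotypes()` builds haplotypes whose digestion
answer is known *by construction*: incidental recognition sites are
first mutated away, then each haplotype receives a distinct per-enzyme
count of planted sites (a mixed-radix code) in fixed windows, and the
realized site set is verified against the plan.  Two haplotypes are
separated by an enzyme exactly when their planted counts differ, giving
an independent truth table for the discrimination ranking.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: alignment error and trimming artifacts,
among-site rate heterogeneity and base-composition drift, unbalanced
sampling across species, paralogous ITS2 copies within a genome, and
(by default) indels.  Tests on synthetic data validate the statistics
and their implementations, not the biological claim that any particular
locus barcodes any particular genus.

## Numerical conventions and validation sizes

Positions reported to users (cut sites, segregating sites) are 1-based,
matching molecular-biology convention; internal storage is 0/1-based as
R dictates.  The gap character is `-` only; the `.` dialect is rejected
at parse time rather than silently mixed.  Distance ties use tolerance
1e−12; histogram bins are anchored at zero; haplotype ids are assigned
by first occurrence — all choices made for exact reproducibility.

The validation suite sizes were chosen to make 3-standard-error checks
meaningful while keeping the whole suite fast: 1000 random pairs for
the K2P oracle, 1000 neutral-coalescent replicates ($n = 20$,
$\theta = 5$), 50 replicate clear-gap reference sets (10 species × 5
samples, 350 bp), 1000 random 400-mers per enzyme for the digestion
oracle, and 100 random additive 6-taxon matrices for NJ consistency.
The bundled analysis scripts use a 46-species × 6-sample reference set
(≈ 277 sequences), the scale of a realistic barcode reference database
for a single genus.

## Known limitations

* The six divergence metrics are computed as defined above; published
  tables using different units or dispersion measures will not be
  numerically comparable without knowing their conventions.
* The local-alignment identifier is exhaustive; for reference databases
  beyond a few thousand sequences a seeded heuristic would be needed.
* Neutrality tests assume a panmictic constant-size population; the
  coalescent validator simulates exactly that, so departures seen on
  real data are inferences, not artifacts the tests can rule out.
* `wilcoxon_ranksum()`'s normal path should not be trusted below ~5
  observations per sample (see above); the exact path covers that
  regime.
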