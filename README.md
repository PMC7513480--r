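# barcodeval

Evaluation of DNA barcode markers over species-labelled reference sets:
barcoding-gap analysis, species identification, nucleotide diversity and
neutrality statistics, in-silico PCR-RFLP, and neighbor-joining trees.

## What it is for

Given a pre-aligned FASTA of barcode sequences (for example nuclear
ribosomal ITS2 across the cultivars, subspecies and wild species of the
banana genus *Musa*), `barcodeval` answers the questions a barcoding
study asks:

* **Do the distances separate?**  Pairwise Kimura 2-parameter (K2P)
  distances with pairwise deletion,
  `d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]` for transition and
  transversion proportions `P` and `Q`; the six standard divergence
  metrics (all inter, theta prime, minimum inter, all intra, theta,
  coalescent depth, each mean ± SD); the barcoding-gap histogram at
  0.008-unit bins with an overlap fraction; Wilcoxon rank-sum
  comparison of the two distributions.
* **Can samples be identified?**  Leave-one-out identification by the
  nearest-distance method and by a best-local-alignment-hit method
  (Smith–Waterman, megablast-style scoring), with correct / ambiguous /
  incorrect rates overall and per species.
* **How much variation does the locus carry?**  Segregating sites `S`,
  haplotypes `H`, nucleotide diversity `π = k̄/L`, Watterson's
  `θ_W = S/(a₁L)`, and Tajima's `D = (k̄ − S/a₁)/√(e₁S + e₂S(S−1))`
  per taxonomic or genome group, indels excluded.
* **Can a restriction digest discriminate haplotypes?**  IUPAC-aware
  in-silico digestion (built-ins MseI, PstI, AvaII; user-extensible via
  TSV), fragment predictions, and enzyme ranking by the number of
  haplotype pairs separated.
* **What does the tree look like?**  Neighbor joining on the K2P matrix
  with column bootstrap, exported as Newick.

A synthetic-data module generates ITS2-like reference sets under the
Kimura model (star or bifurcating species structure, controlled
intra/inter divergence, coalescent mode for the diversity statistics),
so every statistic is validated against data with a known answer.

## Worked example

```r
library(barcodeval)

set <- simulate_barcode_set(sim_config(n_species = 10,
                                       samples_per_species = 5,
                                       seed = 42))
aln <- set$aln
aln
#> aligned_set: 50 sequences x 373 sites; 10 species

d  <- k2p_matrix(aln, quiet = TRUE)
sp <- setNames(aln$meta$species, aln$meta$sample_id)
print(divergence_summary(d, sp), digits = 3)
#>             metric   mean      sd    n         unit
#> 1        all_inter 0.1985 0.03217 1125  sample pair
#> 2      theta_prime 0.1985 0.03033   45 species pair
#> 3        min_inter 0.1541 0.02259   10      species
#> 4        all_intra 0.0364 0.01097  100  sample pair
#> 5            theta 0.0364 0.00727   10      species
#> 6 coalescent_depth 0.0494 0.00976   10      species

gap_histogram(d, sp)
#> gap_histogram (bin width 0.008)
#>   intra: n=100 range [0.0108, 0.0616]
#>   inter: n=1125 range [0.1253, 0.3276]
#>   overlap fraction: 0.0000

evaluate_identification(aln, d = d)
#> identification_report (leave-one-out, 50 queries)
#>   DISTANCE correct 100.0%  ambiguous 0.0%  incorrect 0.0%
#>   BLAST1   correct 100.0%  ambiguous 0.0%  incorrect 0.0%
```

The generator was configured at its defaults — mean K2P divergence 0.19
between species and 0.035 within, ITS2-like lengths (325–375 bp) and GC
(0.60) — and the summary recovers those values: mean inter-specific
distance 0.199 against intra-specific 0.036, a clean gap (overlap
fraction 0, intra range ending at 0.062 well below the inter range
starting at 0.125), and perfect leave-one-out identification by both
methods, which is what a usable barcode locus looks like.  Real data
come in the same way via `read_fasta()` (headers
`species|sample_id|genome_code`, or a TSV sample sheet) followed by
`validate_alignment()`; `run_all()` executes every stage and writes a
TSV/Newick/JSON report bundle.

The numbered scripts under `analysis/` run the same stages as a
narrative pipeline over a 46-species × 6-sample synthetic reference set
(`01_simulate.R` … `06_tree.R`), writing tables under `results/`.

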