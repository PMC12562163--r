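# ssrpopgen

Microsatellite (SSR) marker development and population genetics for
codominant diploid data, in one tested R package. It covers the full desk
workflow used when SSR markers are mined from transcriptome sequence,
screened in silico for length polymorphism, and then applied to genotype
wild populations — the workflow behind marker panels for species such as the
freshwater snail *Angulyagra polyzonata*:

1. **SSR mining** — detection of perfect tandem repeats of 1–6 bp motifs
   with MISA-style per-size thresholds (≥10 copies for mononucleotide, ≥6
   for dinucleotide, ≥5 for tri- to hexanucleotide motifs), motif
   canonicalization under cyclic rotation and reverse complement (so GT, TG,
   CA and AC all count as the (AC/GT)n class), compound-SSR grouping at a
   100 bp maximum interval, and census tables (counts, occurrence
   frequencies, per-type and per-motif breakdowns, repeat-number bins).
2. **Polymorphism screen** — each SSR run is masked with a single
   placeholder `R`, candidates with flanks shorter than 20 bp are dropped,
   masked sequences are clustered greedily at 90 % identity / 70 % coverage
   (cd-hit style), and each cluster is scored by its *polymorphism value* —
   the number of distinct SSR lengths among its members. Clusters with a
   value > 2 whose representative admits a 100–400 bp amplicon are candidate
   markers.
3. **Diversity statistics** — allele frequencies; Na; Ne = 1/Σp²; Shannon's
   I = −Σp ln p; observed heterozygosity Ho; Nei gene diversity
   He = 1 − Σp² (so He = 1 − 1/Ne exactly); Botstein's
   PIC = 1 − Σp² − Σ_{i<j} 2p_i²p_j²; the inbreeding coefficient
   F = 1 − Ho/He; chi-square and Monte-Carlo Hardy–Weinberg tests.
4. **Differentiation** — multiallelic Weir–Cockerham θ (pairwise or global
   Fst), Wright's island-model gene flow Nm = 0.25(1 − Fst)/Fst, Nei (1972)
   standard genetic distance, UPGMA dendrograms (Newick output),
   allele-level AMOVA with Φ_PT and a permutation test, principal
   coordinates analysis, and Evanno ΔK post-processing of admixture run
   summaries.
5. **Simulation** — a Balding–Nichols genotype simulator (Dirichlet
   frequencies at a planted Fst, an inbreeding mixture at a planted F,
   missing-data erasure) and a planted-SSR sequence simulator with
   flank-sharing allele families, so every stage is testable without any
   external download.

Published summary tables from the *A. polyzonata* study (SSR census counts,
the nine-locus diversity table, the pairwise Fst/Nm matrix, the AMOVA table
and the Nei distance matrix) ship as plain CSVs and are available through
`snail_reference()`; the underlying reads and genotypes are not public, so
these tables serve as inputs for arithmetic identities and worked examples.

## Worked example

```r
library(ssrpopgen)

cfg <- sim_config(seed = 42, n_pops = 4, n_per_pop = 30, n_loci = 9,
                  planted_fst = 0.15, planted_f = 0.3)
gt  <- simulate_genotypes(simulate_allele_freqs(cfg), cfg)

round(attr(pooled_summary(gt), "means"), 3)
#>    Na     Ne      I     Ho     He    PIC      F mean_He_within
#> 8.333  4.854  1.719  0.453  0.779  0.750  0.421          0.658

wc_theta(gt)            # 0.179  (planted Fst 0.15 + Wahlund-free sampling noise)

amova(gt)
#> AMOVA (gene-copy level)
#>              source  df      SS       MS
#>   Among populations   3 130.796 43.59861
#>  Within populations 236 710.833  3.01201
#>               Total 239 841.629       NA
#> Variance components: among = 0.6764 (18.3%), within = 3.0120 (81.7%)
#> Phi_PT = 0.1834

write_newick(upgma(nei_distance_matrix(gt)))
#> (P04:0.379,(P03:0.282,(P01:0.239,P02:0.239):0.043):0.097);
```

The pooled F of 0.421 exceeds the planted within-population inbreeding of
0.3 because pooling across differentiated populations adds a Wahlund
deficit; per-population `population_summary(gt)` recovers the planted value.

For sequence work:

```r
cfg <- sim_config(seed = 7, n_families = 10, variants_per_family = 5)
sim  <- simulate_ssr_sequences(cfg)
loci <- group_compound(detect_ssrs_all(sim$seqs), max_interval = 100)
cl   <- cluster_candidates(mask_and_filter(sim$seqs, loci, min_flank = 20))
select_candidates(cl, min_poly = 3)    # 10 clusters, polymorphism value 5 each
```

A command-line front end with subcommands `mine`, `screen`, `stats`, `fst`,
`dist`, `tree`, `amova`, `pcoa`, `evanno` and `simulate` is installed at
`system.file("scripts", "ssrpopgen-cli.R", package = "ssrpopgen")`.

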