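---
title: "Methods: SSR mining, polymorphism screening and population genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR mining, polymorphism screening and population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpopgen)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, the numerical conventions,
and the choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

Microsatellites (SSRs) are perfect tandem repeats of 1–6 bp motifs. Because
their allele lengths mutate quickly and are scored codominantly, they remain
a workhorse for population genetics in non-model animals such as freshwater
snails. A typical marker-development campaign (i) mines a large
transcriptome-derived sequence set for SSR loci, (ii) screens loci in silico
for length polymorphism by clustering sequences that share flanks, (iii)
genotypes wild populations at the selected markers, and (iv) summarizes
diversity and differentiation. This package implements each desk stage and
a simulator that generates data with exactly the statistical structure the
analyses assume.

## SSR mining

`detect_ssrs()` reports every *maximal* perfect tandem run meeting its
size-class threshold. Defaults follow the MISA convention: at least 10
copies for mononucleotide motifs, 6 for dinucleotide, 5 for tri- to
hexanucleotide. Conventions, chosen once and used everywhere:

* **Coordinates** are 0-based, half-open, on the given (forward) strand.
* **Integer copies only.** Partial trailing copies are excluded, so the
  locus length is always `repeats * motif_length`. Runs are anchored at the
  start of the maximal periodic region.
* **Degenerate motifs** (tandems of a shorter unit, e.g. `ACAC`) are never
  reported; the run appears only under its shortest unit's class. This
  prevents double counting and matches the treatment of shifted permutations
  as one SSR type.
* **`N` is a hard break**: it never matches anything, including another `N`.
  This is the conservative choice for ambiguous bases; the convention is the
  package's own since scanner behaviour on `N` is rarely specified.
* **Canonical motifs.** `canonical_motif()` returns the lexicographically
  smallest string among all rotations of the motif and of its reverse
  complement, a true equivalence-class representative (`GT`, `TG`, `CA`,
  `AC` → `AC`).

The scanner works by comparing each position with the position one motif
length ahead and run-length-encoding the matches; the test suite holds it
equal to an exhaustive per-start extension oracle on random sequences, and
to planted ground truth from the simulator.

Compound SSRs chain transitively: consecutive loci separated by at most
`max_interval` (default 100 bp, boundary inclusive) form one compound, and
compound members still count in their motif-type rows of the census.

The census reports **both** occurrence frequencies under explicit names —
`pct_sequences_with_ssr` (sequences containing at least one SSR per 100
sequences examined) and `ssr_per_100_sequences` (loci per 100 sequences) —
because published tables sometimes label these two ratios ambiguously.

## The polymorphism screen

Allelic variants of one locus share flanks but differ in repeat count.
`mask_and_filter()` therefore replaces the SSR run with a **single** `R`
character: masked sequences of allelic variants become identical, so
clustering groups them regardless of allele length. (The alternative —
masking with a run of `R`s of the original length — would keep length
information in the mask and defeat the purpose; it is deliberately not
offered.) Candidates with either flank shorter than 20 bp are dropped, the
boundary being inclusive at exactly 20.

`cluster_candidates()` is a documented greedy reimplementation of
representative-based clustering, not a bit-compatible cd-hit: candidates are
sorted by masked length descending (ties broken by candidate id), and each
joins the first cluster whose representative aligns at ≥ 90 % identity and
≥ 70 % coverage, else founds a new cluster. Conventions:

* identity = matched positions / length of the shorter sequence (the
  convention of the clustering tools this mirrors);
* the alignment is ends-free (overlap) global with gap open 1 and gap
  extension 0, and coverage is the aligned span of the shorter sequence over
  its length. A strictly pattern-global alignment would pin the shorter
  sequence's coverage at 1 and make the coverage gate vacuous, which is why
  the ends-free form is used;
* `R` matches only `R` (it is heavily penalized against bases), so two
  candidates can only cluster through their flanks.

The per-cluster **polymorphism value** is the number of distinct SSR total
lengths among members: 1 if all lengths agree, 2 for two lengths, and so
on. It is monotone under cluster union. `select_candidates()` keeps
clusters with value > 2 (strict) whose representative's unmasked length
falls within the 100–400 bp amplicon window, and emits a report for
external primer design; thermodynamic primer design itself is out of scope.

## Diversity statistics

All indices are computed from allele frequencies with missing calls
excluded per locus. He is Nei's gene diversity `1 - sum(p^2)` **without**
the small-sample correction, which makes the identity `He = 1 - 1/Ne` exact
— the form consistent with published nine-locus tables where both columns
are printed (the corrected variant is available as `He_unbiased`). PIC is
Botstein's. F is `1 - Ho/He`, undefined (reported `NA` with a warning) at
monomorphic loci.

Scopes: the pooled per-locus table uses frequencies over all individuals —
the only scope consistent with a single row per locus spanning many
populations — while `population_summary()` uses within-population
frequencies. All across-locus means are unweighted arithmetic means of
per-locus values, not ratios of means; that averaging order is what
reproduces a printed Mean row from its column. The pooled table also
reports `mean_He_within`, the unweighted mean of within-population He per
locus. A published "Hs" column that *exceeds* pooled He cannot be this
quantity, so the package makes no claim to reproduce such columns and uses
its own explicit name instead.

The Hardy–Weinberg test is a chi-square goodness of fit of genotype counts
against expectations from observed allele frequencies with
`df = Na(Na-1)/2` (the convention of the standard spreadsheet tools for
codominant markers). With 200 diploids and three moderately frequent
alleles its type-I error sits inside [0.03, 0.07] at α = 0.05 (tested over
1000 simulated equilibrium datasets). For sparse genotype tables the
chi-square approximation degrades; a seeded Monte-Carlo variant (permuting
the allele pool among individuals, default 999 permutations) is available
via `hwe_test(method = "mc")`.

## Differentiation

**Fst.** The default estimator is Weir–Cockerham θ with variance components
summed over alleles and loci before the ratio; a "nei" alternative
((Ht − Hs)/Ht on the pooled pair) is provided. Negative estimates are
clamped to 0 with a warning. Published pairwise Fst tables whose estimator
flavour is unstated are treated as *inputs* (e.g. for the Nm identity), not
as reproduction targets. **Nm** uses Wright's island model,
`0.25 (1 - Fst) / Fst`, exact, rounded only for display; `Fst = 0` yields an
infinite-flow sentinel and negative input is a domain error.

**Nei (1972) distance** averages the gene identities J across loci before
the log (the convention of the marker-analysis tools whose trees this
mirrors); per-locus averaging is available by flag. Populations sharing no
allele give an infinite sentinel, and `upgma()` refuses non-finite input
rather than silently clamping — silent clamping would change tree topology
invisibly.

**UPGMA** is implemented directly because the required conventions (node
height = merge distance / 2; ties broken by the smallest (row, column) pair
in current label order; member-count-weighted average linkage) are not all
exposed by library routines. It is held equal, in tests, to a naive
reference that recomputes set-to-set means from the original matrix at every
step, and to average-linkage `hclust`. Newick serialization goes through
`ape`, and trees round-trip through an independent parser.

**AMOVA** operates at the gene-copy level — each typed diploid contributes
two units, forced by the published degrees of freedom (11/708/719 for
12 × 30 diploids ⇔ 720 gene copies). Sums of squares come from 0/1 allele
mismatch distances summed over loci; σ²_w = MS_within,
σ²_a = (MS_among − MS_within)/n₀ with the standard unequal-size n₀, and
Φ_PT = σ²_a/(σ²_a + σ²_w). The permutation test shuffles individuals among
populations with a required seed (default 999 permutations when enabled).

**PCoA** is classical scaling from the definition (double-centering of
−D²/2 followed by an eigendecomposition), returning axes for positive
eigenvalues with signs fixed by making each axis's largest-magnitude
loading positive; it is cross-checked against `stats::cmdscale` and by
Euclidean round-trips to 1e-9.

**Evanno ΔK** is the absolute second difference of mean log-likelihoods
over replicate admixture runs divided by the replicate standard deviation;
endpoints are undefined and zero standard deviation is an error. Running
the admixture MCMC itself is out of scope — the function post-processes
tabulated run summaries.

## The simulator

`simulate_allele_freqs()` draws, per locus, an ancestral frequency vector
from a uniform Dirichlet and population vectors from
`Dirichlet(p (1 - Fst)/Fst)` — the Balding–Nichols model, chosen as the
standard single-parameter Fst law (a finite-island alternative is out of
scope). `simulate_genotypes()` uses the inbreeding mixture: with
probability `planted_f` an individual's call is autozygous (one allele
duplicated), else two independent draws; missing data erases whole calls.
Allele codes are emitted as motif-spaced fragment sizes (steps of 3 or 4
bp within 100–400 bp) so simulated tables look like real capillary data.
Inbreeding is constant across loci and populations by default.

Defaults are the study conditions the analyses target: 12 populations × 30
diploids × 9 loci, planted Fst 0.175, planted F 0.390, 10 ancestral alleles
per locus. Sequence families default to 40 bp flanks (so a
flank–SSR–flank amplicon clears the 100 bp product minimum), 10 families ×
5 length variants, inter-family flank identity kept below 0.8 by rejection
sampling, and an SSR-free rejection-sampled background.

What the simulator deliberately does **not** emulate: stepwise mutation
through time, coalescent genealogies, null alleles, allele-calling error,
and linkage. Passing tests therefore demonstrate correctness of the
estimators under the stated generative models, not robustness to those
real-data complications.

## Study conditions used in the checks

Recovery checks run at the study scale: Weir–Cockerham θ against planted
Fst ∈ {0.05, 0.175, 0.409} with `planted_f = 0` (20 replicates each,
tolerance ±0.05), and `1 - Ho/He` against planted F = 0.390 on a single
panmictic population of 360 — a single population because pooling across
differentiated populations adds a Wahlund deficit on top of within-
population inbreeding, which would conflate the two parameters. Scanner
checks use 100 random 1–2 kb sequences against the exhaustive oracle plus
planted-truth FASTA; screen checks use 10 families × 5 variants. These
problem sizes keep the whole suite under a minute while leaving Monte-Carlo
standard errors well inside the stated tolerances.

## Known limitations

* The greedy clustering is order-dependent by design (the order rule is
  fixed and documented); it is not guaranteed to equal cd-hit's output.
* The chi-square HWE test is anti-conservative for loci with many rare
  alleles; use the Monte-Carlo variant there.
* AMOVA degrees of freedom follow the full individual count; with heavy
  missingness the within-population df overstates the typed gene copies.
* Infinite Nei distances (disjoint allele support) must be resolved by the
  user before UPGMA; the package refuses rather than guesses.
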