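---
title: "Locating crossovers from three-generation pedigree genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating crossovers from three-generation pedigree genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedrec)
```

## The problem

Meiotic crossovers shuffle the two homologous chromosomes a parent carries
into the gamete it transmits. With whole-genome SNP genotypes of a
three-generation pedigree — four grandparents, two parents, one or more
offspring — each crossover in a parental meiosis leaves a detectable
footprint: moving along the offspring's chromosome, the grandparent from
whom the transmitted allele descends switches. `pedrec` infers this
grandparent-of-origin (GoO) signal from unphased biallelic genotypes and
converts it into crossover positions in base pairs, each with a precision
estimate, without any haplotype phasing step.

The package is aimed at studies of recombination landscapes in species
with a pedigree and a (possibly scaffold-level) reference assembly:
genotypes come in as a plain 0/1/2 table, scaffolds are placed on
chromosomes by an ordering-and-orientation table, and results leave as
TSV tables and static plots.

## Grandparent-of-origin inference

At one SNP the seven genotypes form a 7-digit string over `{0,1,2}`
(0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternative),
ordered: paternal grandfather, paternal grandmother, maternal
grandfather, maternal grandmother, father, mother, offspring. There are
$3^7 = 2187$ such strings, so inference reduces to one exhaustive,
deterministic lookup table built by `build_goo_dictionary()`.

For each string the builder enumerates every Mendelian transmission
assignment: each grandparent passes one of its two alleles to its child
such that the child's genotype is realised, and each parent passes one of
its two alleles — tracked by which grandparent contributed it — such that
the offspring's genotype is realised. A string with no consistent
assignment is *impossible* (e.g. `0000002`: two homozygous-reference
parents cannot produce a homozygous-alternative offspring) and is left
out of the dictionary; at analysis time such SNPs are counted as
candidate genotyping errors and skipped. A parental side is *informative*
only when every consistent assignment routes the offspring's allele on
that side through the same grandparent; otherwise it is uninformative.
This invariance criterion is deliberately strict — a site where even one
consistent assignment disagrees about the source contributes no call —
so every emitted call is certain given the genotypes.

Of the 2187 strings, 435 are possible and 180 are informative per side
(the dictionary prints these counts). Two symmetries are built-in
consequences of the enumeration and are enforced by tests: swapping the
paternal and maternal halves of the string swaps the two sides'
inferences, and swapping the two grandparents within a side flips
GF and GM.

`infer_goo()` applies the dictionary to every SNP for one offspring and
chromosome. SNPs with a missing code in any of the seven individuals are
excluded outright — the dictionary is defined over complete strings, and
no imputation is attempted. Scaffold coordinates are lifted to
chromosome coordinates by concatenating scaffolds in their stated order
(`-`-oriented scaffolds are flipped; the inter-scaffold gap defaults to
0 bp and is configurable).

## Locating crossovers

Both locators work per parental side on the ordered sequence of
informative calls (GF/GM), not on bp windows, so their behaviour is
density-independent.

**Proportional difference (PD).** At a boundary between consecutive
calls, $D = |p_{GF}(\text{left}) - p_{GF}(\text{right})|$ over flanking
windows of `radius` calls (default 550). A coarse scan at stride `step`
(default 17 calls) finds local maxima with $D \ge$ `threshold` (default
0.9); each candidate is re-evaluated at stride `fine_step` (default 1)
within one coarse step, and the refined argmax is reported. On plateaus
of maximal $D$ — generic in clean data — the central boundary of the
plateau is taken. Boundaries within `radius` calls of either chromosome
end are not evaluable, so a larger radius trades noise robustness
against detection near chromosome ends.

**Cumulative continuity score (CCS).** The call sequence is segmented
into maximal same-origin runs; a run's CCS is its length in calls. Runs
shorter than the threshold (default 50) are treated as noise and
dropped; between consecutive kept runs of opposite origin one crossover
is called. Dropped noise runs are absorbed into the breakpoint interval.
CCS needs no full flanking window, so it can reach closer to chromosome
ends than PD, but genotyping errors fragment runs and make its reported
midpoint wander further (see *Numerical behaviour*).

Both algorithms report the floor of the midpoint between the two
informative calls flanking the inferred boundary. Raising either
threshold can only remove calls, never add them (tested as a
monotonicity property).

**Precision.** Each call carries the reverse local density of
informative calls: the number $n$ of same-side calls within a 100 kb
window centred on the call gives precision $= 100000 / n$ bp (rounded);
$n = 0$ yields `NA`. Smaller is better: it is the genomic span covered
by one informative SNP near the call, the natural resolution limit of
any marker-based locator. The window length is exposed as
`interval_bp`.

## The simulator and what it does (not) emulate

`simulate_pedigree()` generates the full seven-member genotype table
with known truth. Founder (grandparent) haplotypes are drawn per SNP
from an allele frequency uniform on $[0.05, 0.95]$; each grandparent
passes one whole, crossover-free gamete to its child, so the
grandparental origin of every parental allele is known by construction;
the offspring's two gametes recombine the parental haplotype pairs at
the planted crossover positions. Genotyping error (a code is replaced by
a uniformly chosen different code) is applied before missingness,
independently per SNP and individual; this one error model produces both
failure modes seen in real data — Mendelian-impossible strings (which
the analysis drops and counts) and origin-flip noise (which the
locators must absorb).

Defaults define the reference simulation conditions used throughout the
tests: a 25 Mb chromosome with 110,000 SNPs. With the default frequency
law about 23% of SNPs are informative per side, so this gives one
informative-capable SNP per kb per side; after the default corruption
levels used in the recovery experiments (0.5% genotype error, 1%
missingness) the realised informative-call density is ~0.94/kb.
Randomly placed crossovers keep a minimum separation (default 5 Mb)
from each other *and from the chromosome ends*: a crossover inside the
terminal PD window is undetectable by PD by construction, so terminal
placements are excluded from the reference conditions rather than
silently deflating recovery rates.

The simulator is deliberately simple where simplicity does not affect
the contract being tested: SNP positions are uniform (no hotspots or
assembly gaps), alleles are independent across SNPs (no LD), founders
are unrelated, crossovers show no interference beyond the minimum
separation, and error/missingness are homogeneous. Passing recovery
tests therefore demonstrate the correctness of the inference and
locating machinery under known truth — not robustness to clustered
errors, segmental misassembly, or genotyping artefacts that correlate
along the genome, which real data can contain.

## Numerical behaviour and edge cases

* Fewer than `2 * radius` informative calls: the PD profile is empty and
  the scan warns and returns no calls (the situation of a heavily
  thinned dataset; CCS still operates).
* Equal-$D$ plateaus in PD refinement: the central tied boundary is
  reported, which on clean data equals the exact planted boundary.
* Consecutive kept CCS runs of the *same* origin (possible when a noise
  run was dropped between them) emit no call.
* Missing precision (`NA`) marks calls in deserts with no informative
  call within the window — reported, never dropped.
* All table outputs are written with fixed formatting and Unix newlines;
  fixed-seed runs are byte-identical, and read/write round-trips are
  exact (tested).

Two properties of the precision estimate deserve emphasis. First, with
near-exponential spacing between informative calls, the distance from a
reported midpoint to the true crossover is bounded by half the local
gap, and the probability that this exceeds the 100 kb-window precision
is roughly $e^{-2} \approx 14\%$ even for a perfect locator on clean
data — precision is a typical-resolution estimate, not an error bound.
Second, with genotyping error, CCS's kept-run midpoint can wander by the
span of absorbed noise runs (tens of calls), so its distance to truth
exceeds the precision more often than PD's; the replicated recovery
experiments in the test suite quantify both effects.

## Problem sizes used in the shipped experiments

The replicated experiments run 100 seeded pedigrees at the reference
conditions above (with 1–3 crossovers per parental side), 25 of which
are additionally re-analysed after thinning the SNP table to 10% and 1%
to measure the precision degradation (~10x and ~50–100x). The unit-test
fixtures use 1–5 Mb chromosomes with proportionally fewer SNPs and a PD
radius of 100–150 calls so that every algorithmic path — including
two-crossover separation, noise absorption and threshold monotonicity —
is exercised on second-scale inputs.

## Limitations

Gene-conversion events (short double origin switches, typically well
below the inter-marker spacing) are out of scope: sub-threshold CCS runs
are treated as noise, and PD windows average over them. Sex chromosomes
are treated as autosomal diploid; hemizygosity is not modelled. There is
no genotype-likelihood weighting — a confidently wrong genotype counts
like any other — and no automatic parameter selection: `radius` and the
CCS threshold should be chosen against the dataset's informative-call
density, for which `informative_density()` provides the diagnostic
track.
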