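---
title: "Methods: crossover interference, recombination domains, and segregation distortion in Caenorhabditis crosses"
author: "wormcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormcross)
```

wormcross analyzes the genetics of a gonochoristic *Caenorhabditis*
mapping experiment built on an advanced-intercross design: two founder
strains (called A and B throughout; A is the recurrent, susceptible
reference strain) are crossed, intercrossed for several generations, and
backcrossed to founder A, producing lines whose chromosomes are mosaics
of founder ancestry. This vignette describes the models, the parameter
choices, and the numerical decisions, in the order the analyses run.

## 1. Meiosis under complete crossover interference

Each chromosome pair receives exactly one obligate crossover per meiosis
under complete interference, so a transmitted chromatid carries 0 or 1
crossovers, each with probability 1/2, and every chromosome is 50 cM
long regardless of physical size. `meiosis_gamete()` implements this,
plus a Poisson null (`mode = "poisson"`, count ~ Poisson(cM/100)) used
to contrast count variances: both modes give mean 0.5 crossovers per
gamete at 50 cM, with variance 0.25 (complete) versus 0.5 (Poisson).
Crossover positions are uniform in genetic distance and mapped to
physical coordinates linearly by default; a fitted Marey map can be
supplied instead, which changes positions but not counts — all the
calibration targets below are count statistics.

The X is hemizygous in males (X0 sex determination): male X meiosis
transmits the single X intact to half the sperm and no X (a nullosome)
to the other half, so X-bearing sperm make XX daughters and nullosomic
sperm make X0 sons. Autosomes recombine in both sexes.

## 2. The G4BC2 pedigree and its calibration surface

The default `cross_design()` is: founder cross A female x B male makes
the F1; three further generations of random mating produce G4; a G4
**male** is crossed to an A female (first backcross); the resulting BC1
female is crossed to an A male, and the final brood is pooled. Because
the whole brood is pooled and sequenced together, the non-recurrent
ancestry segments observed in the pool are those of the *BC1 parent's*
recombinant haplotype — the gamete the G4 male transmitted — so the
second backcross contributes no junctions to the counted mosaic.
`count_on = "final_gamete"` is available for the alternative convention
that follows a single final gamete through every backcross meiosis.

Expected junction counts on the counted haplotype can be derived by
accounting for junction creation per meiosis. A crossover at a uniform
point creates a visible junction only where the parent's two homologs
carry different founder ancestry, so each meiosis adds `0.5 * h`
expected junctions, where `h` is the parent's expected local
heterozygosity; a gamete inherits on average the mean of its two
parental haplotypes' junction counts. Within the intercross phase both
homologs are exchangeable pool gametes, so no dilution occurs and each
generation adds `0.5 * 0.5 = 0.25` junctions to the F1 gamete's 0.5:

* autosome, gamete of a G4 individual: 0.5 + 3(0.25) = **1.25**;
* X: males do not recombine and carry their mother's recombinant X, so
  the G4 male's X is the gamete of a G3 female. Tracking heterozygosity
  through the X's inheritance path (the F1 male's X is pure A) gives
  0.5 + 0 + 0.25 at the three female meioses = **0.75**.

These are the two calibration targets of the simulator; a G4 *female*
transmitting into the backcross would give 27/32 = 0.84375 on the X
instead, which is why the transmitting sex defaults to male. The
random-mating expectations assume unrelated parents; `pool_size` is Inf
by default (each line's ancestors are independent fresh draws, the limit
the derivation assumes), and `simulate_pool_pedigree()` simulates finite
pools explicitly when the effect of drift and inbreeding on the
calibration is of interest.

Monte-Carlo tests (`crossover_count_test()`, `xa_ratio_test()`) compare
observed per-line counts with the simulated null using the standard
bias-avoiding `(k+1)/(n+1)` tail estimator; the two-sided p is
`min(1, 2 min(tails))`. Simulations use one seeded R RNG stream; runs
are byte-reproducible given the seed.

## 3. Marey maps and recombination domains

A Marey map plots genetic against physical marker position; its slope is
the local recombination rate. *Caenorhabditis* chromosomes partition
into tip / arm / center domains, and the domain model is a continuous
three-segment linear regression. The pipeline follows the standard
recipe: rescale the chromosome to 50 cM (rescale-before-fit; the reverse
order is available by normalizing after), interpolate at 200 evenly
spaced physical positions, exclude 1 Mb from each end (tips have
suppressed recombination and poorly resolved boundaries), then fit.

`fit_segmented()` searches all ~19,900 ordered pairs of interior grid
points as candidate breakpoints and solves each candidate by least
squares in the hinge basis {1, x, (x-LC)+, (x-CR)+}, which enforces
continuity by construction. The search is exhaustive and deterministic —
immune to the local optima that iterative breakpoint estimators can hit
— at a cost that is trivial for n = 200. Ties in RSS (within a relative
tolerance of 1e-9) break toward the smallest LC, then the largest CR, so
degenerate inputs (straight lines, plateaus) are reproducible. All-equal
genetic positions return a zero-slope fit flagged `degenerate`. Slopes
are unconstrained in the fit; `domain_summary()` clamps small negative
slopes (numerical noise on monotone input) to zero when reporting rates.
Chromosomes are flagged as lacking domain structure when the fitted
center slope exceeds an arm slope or the fit is degenerate; the flag is
a report annotation, not an error. Breakpoint confidence intervals are
not computed: with a realistic number of crossovers they are of
megabase order, and no reported quantity depends on them.

## 4. Two-locus Medea segregation distortion

A *Medea* (maternal-effect dominant embryonic arrest) element carried by
a heterozygous mother damages offspring homozygous for the susceptible
(founder-A) allele at that locus with penetrance beta. Two unlinked loci
(chromosomes I and III) act independently, so survival is
multiplicative:

    P(affected) = 1 - (1 - bI hI)(1 - bIII hIII)

where `h` is the probability the offspring is homozygous susceptible:
0 unless the mother is heterozygous, 1/2 if the father is homozygous
susceptible, 1/4 if both parents are heterozygous. Homozygous mothers
produce no affected offspring — the reciprocal-cross asymmetry that
distinguishes Medea from zygotic lethality. `mode = "peel"` swaps the
parental roles for the paternal-effect analog. The sixteen-cross panel
(`all_cross_classes()`) crosses A, B and both reciprocal F1s in every
mother x father combination; the reciprocal F1s differ in mitochondrion
(females) and X (males), which the class bookkeeping records. A
mitochondrial or parent-of-origin interaction is not parameterized —
nothing in the estimation below quantifies one.

Estimation uses the difference D in affected proportions between the
susceptible-founder backcross classes (F1 mother x A father) and the F2
classes (F1 x F1), with an Agresti-Caffo 95% interval (add one success
and one failure per group, Wald on the adjusted proportions,
z = 1.959964). Two inversion formulas for the equal-penetrance solution
are exposed:

* `formula = "paper"` solves `16 D = 2 b + 3 b^2`, the published
  two-Medea expectation for this panel, and is the default because it is
  what produces the published penetrance solutions;
* `formula = "enumeration"` solves `16 D = 8 b - 3 b^2`, which is what
  direct enumeration of offspring genotypes under the multiplicative
  survival model yields for D.

The two agree only at b = 1. The discrepancy is inherited from the
source analysis and deliberately left visible rather than resolved:
simulation-based work (and the CI-coverage test) must use the matched
enumeration inversion, because inverting multiplicative-model data with
the other formula is biased by construction (at b = 0.8 the true D is
0.28, which the paper-formula inversion maps to 0.93). The
one-fully-penetrant solution solves `16 D = 1 + 4 b`. Both solvers are
monotone in D, so confidence intervals propagate by transforming the
interval endpoints, and solutions clamp to [0, 1].

Pooling counts into affected/total (`classify_and_pool()`) defaults to
affected = unhatched + deformed L1 + delayed L1-L3 larvae, denominator =
affected + wild-type adults and L4s, with the unaccounted "missing"
class excluded; both choices are toggles because pooled published counts
do not decompose them. Baseline (distortion-independent) mortality
cancels from D, and uniform missingness rescales both proportions
equally, so the estimator tolerates both nuisances.

## 5. Autosome-X cosegregation (skew)

In X0 male meiosis an autosomal insertion can cosegregate preferentially
with the nullosome. From a 2x2 offspring table (insertion x sex) the
preferred phase is insertion+ males plus insertion- females;
`tbr()` is the preferred:unpreferred ratio, association is tested with
the two-sided Fisher exact test (point-probability rule, the convention
of standard statistical environments), and `nullosome_distance()` treats
X-absence as a locus: recombination fraction = unpreferred/n, distance
in cM = 100 x fraction, normal-approximation binomial CI (z = 1.959964,
clipped to [0, 100]). `skew_analysis()` prints both phases' counts so
the phase convention cannot be silently inverted.

## 6. Genome composition

Windowed GC tiles non-overlapping windows from position 0 and drops the
trailing partial window — rescaling it would distort variance
comparisons across scales. N bases leave both numerator and denominator;
all-N windows report NA. Feature-class GC uses nested masking: exon
bases first, repeat bases next (minus exon overlap), introns = gene
spans minus both, intergenic = remainder. The four classes are disjoint
by construction and always partition the genome exactly — this is
asserted, not assumed. Composition is strand-agnostic except CDS
extraction, which concatenates each gene's CDS in genomic order and
reverse-complements minus-strand genes. Internally every coordinate is
0-based half-open; GFF3 (1-based inclusive) and BED convert only at the
I/O boundary.

RSCU is `count x family size / family total` over the standard nuclear
code, stops excluded, N-containing codons skipped, trailing partial
codons trimmed with a warning; single-codon families are 1 whenever
observed. Amino-acid usage reports residue percentages and deviations
from the unweighted cross-species mean (which therefore sum to zero per
amino acid), plus the mean G/C fraction of each amino acid's codons — a
property of the code. Telomere counting scans for maximal tandem runs of
the nematode unit TTAGGC at the right end and its reverse complement at
the left end, respecting the biological orientation of the G-rich
strand.

## 7. Synthetic data: what it emulates, and what it does not

Every input the analyses consume can be generated with recorded ground
truth (sidecar YAML when written to disk), so recovery is always tested
against stored truth, never truth re-derived from data:

* `make_marey_fixture()` samples markers from piecewise-linear
  domain-structured maps. Defaults: 120 markers/chromosome, 0.5 cM
  Gaussian marker noise (typical of an ~100-line mapping panel), tips of
  0.4 Mb, and per-chromosome domain geometry chosen so the symmetric arm
  rates implied by a 50 cM total reproduce the published *C. becei*
  domain figures (autosome arm mean 8.1 cM/Mb, centers 0.1-0.6 cM/Mb,
  chromosome V center 63% of its length). Noise is made monotone with a
  running maximum, a mild distortion relative to resampling.
* `make_g4bc2_lines()` runs the real pedigree simulator and emits
  haploid founder calls on a marker grid plus the aggregated map.
* `make_medea_table()` draws multinomial broods per cross class;
  defaults (60 embryos/brood, 12 replicates, 5% baseline mortality, 5%
  missingness) mirror a realistic bench experiment.
* `make_toy_genome()` builds GC-contrasted feature classes, coding CDS
  with a configurable codon profile, and optional telomeric ends.

What passing these tests shows is that the estimators recover the
parameters of their own generating models at realistic sizes. The
fixtures do not emulate marker ascertainment bias, genotyping error,
segregation distortion interacting with map construction, overlapping
isoform annotation, or assembly gaps; results on real data inherit none
of those guarantees.

## 8. Problem sizes and determinism

The simulation-heavy checks run at 2e5 lineages (calibration of the
1.25/0.75 expectations; Monte-Carlo s.e. ~0.002), 50 noise replicates
for breakpoint recovery, 200 simulated panels for CI coverage, and 1e4
random pedigrees for the tiling invariant — sizes at which every check
resolves its question comfortably on one CPU in minutes. All randomness
flows from explicit integer seeds through R's default RNG; identical
seeds give byte-identical outputs.

## 9. Known limitations

* Complete interference is modelled as exactly one obligate crossover at
  50 cM; partial interference (e.g. gamma models) is not implemented —
  the Poisson mode is the only alternative.
* The equal-penetrance inversion inherits the published expectation
  formula; see section 4 for the documented discrepancy with the
  multiplicative enumeration.
* Domain fitting assumes exactly three segments; chromosomes with
  genuinely different architecture are flagged, not refitted with a
  different segment count.
* The five-species comparative regression of arm rate on chromosome
  length is out of scope; `species_map_report()` only standardizes the
  per-species domain tables such a comparison would consume.
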