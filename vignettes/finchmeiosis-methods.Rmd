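---
title: "Models and methods behind finchmeiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind finchmeiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

finchmeiosis analyses germline point mutation and meiotic recombination
from whole-genome genotypes of multi-sibling, three-generation pedigrees,
with birds such as the zebra finch in mind: a highly polymorphic genome
(~1% heterozygosity), a karyotype split into a few macro-chromosomes and
many micro-chromosomes, an obligate crossover per chromosome pair, and no
PRDM9, so that recombination concentrates near hypomethylated CpG
islands. This vignette explains the models the package implements, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was open.

## De novo mutations from trios

A candidate de novo mutation (DNM) is a biallelic site where the proband
is heterozygous, both parents are homozygous reference, genotype quality
is at least 30 in all three, and no genotyped individual outside the
proband's nuclear family — descendants excepted, since they legitimately
inherit a true DNM — carries the alternate allele. Sites must fall in the
trio's callable mask: depth between 8 and twice each member's autosomal
mean, at least 5 bp from any indel called in the trio, outside the repeat
mask and inside the mappability mask. Read-level filters then require at
least two alternate reads in the proband, zero alternate reads in either
parent, and discard whole groups of candidates closer than 10 bp
(distance strictly less than 10 removes both members; the boundary is a
package decision, tested explicitly, since "within 10 bp" alone does not fix
inclusivity).

The per-generation rate is `n / (2 * sum(callable))` over trios, with an
exact (Garwood) Poisson interval on the count; per-year rates divide by
the mean parental age. Phasing uses two routes: transmission (informative
alleles within 200 kb that trace to exactly one grandparent, a 75%
majority over alleles, and the transmitted/untransmitted state of the
mutation in the next generation) and read tracing (fragments carrying the
mutant allele together with a parent-diagnostic allele within 300 bp).
Developmental timing looks for three distinct local haplotypes among the
proband's fragments — the signature of a post-zygotic, mosaic mutation —
requiring at least two fragments per haplotype so a single sequencing
error cannot fabricate a third haplotype; more than two haplotypes in a
parent marks a genotyping artifact and discards the record. Sex ratios
use Clopper–Pearson intervals transformed to ratio space; the spectrum
test is a chi-square goodness of fit over the seven collapsed-strand
substitution classes with CpG>TpG separated by trinucleotide context,
pooling classes whose expected count falls below one.

## Crossovers from phase switches

For each parent heterozygous at a site where the other parent is
homozygous, the allele each offspring received from that parent can be
read off the genotypes. Taking each offspring in turn as the template,
the other siblings are recoded to 1 (same focal-parent allele as the
template), 2 (the other allele) or 0 (missing); a change from 1 to 2 or
back is a phase switch. A phase change in the template's own meiosis is
called where the majority (strictly more than half of siblings with
defined states) switch across the same interval between adjacent
informative sites.

Runs of adjacent majority-supported gaps form one change group, and the
number of changes in a group is the modal per-sibling switch count: a
crossover whose position is blurred by missing data still counts once,
while an isolated conversion or genotype error in the template — every
sibling switching in and straight back out — counts twice. Change groups
within ten informative sites cluster together; odd totals are crossovers
(complex when above one), even totals are candidate non-crossovers.
Events within ten informative markers of a chromosome end are removed
after clustering (either ordering is defensible; applying it after keeps
partially clustered edge artifacts out). Crossover
intervals are refined on a relaxed track (depth 5, indel distance 5 bp)
only when the relaxed sites inside the original interval yield exactly
one change for the same template. Finally, within each meiosis,
crossovers within 2 Mb of each other (single linkage on interval
midpoints) in groups of three or more are treated as assembly artifacts:
the events are dropped, their span masked, and events of other meioses
inside the merged mask dropped too.

Map length in centimorgans is `100 * n_events / n_meioses`. The obligate
crossover test compares the number of meioses showing at least one event
on a chromosome against Binomial(n, 1/2), one-sided: under one crossover
per tetrad a gamete inherits it with probability one half, so falling
significantly below that indicates missed events. Normalized event
positions are interval midpoints divided by chromosome length, unfolded
(0 at one end, 1 at the other), matching cumulative-distribution
displays; a folded distance-to-nearest-end variant was considered and
rejected because the unfolded form is what the displays imply. The
genotype filters mask heterozygous calls with allelic imbalance (exact
two-sided binomial p <= 0.01 on allele depths) and, by default, any
genotype with GQ < 20; production pipelines achieve the same protection
by filtering low-quality calls at the caller level and cross-checking
several variant callers, which a single genotype set cannot do, and the
GQ mask is the equivalent guard — without it, miscalled heterozygotes
dominate the double-switch candidates.

## Non-crossovers

Non-crossovers appear as two phase changes in one meiosis across a short
tract. Calling is restricted to chromosomes with mean depth above 20 and
mean mapping quality above 40, and uses stricter genotypes: Mendelian
consistency, depth between half and twice the per-chromosome sample
mean, and imbalance masking at p <= 0.05. A candidate cluster with
exactly two changes becomes an event when no phase change of any other
meiosis overlaps the converted tract (any overlap suggests an assembly
problem rather than conversion) and at least ten congruent informative
sites flank it on each side. Converted sites are those where the
majority of the other siblings flip match/mismatch state relative to the
left flank — raw allele majority does not work, because at a true
conversion only the siblings sharing the background haplotype mismatch
the template.

Because a single-site conversion rests entirely on one genotype, the
caller optionally verifies converted sites at read level: a homozygous
call of the focal offspring, or of the homozygous parent that makes the
site informative, must carry zero reads of the discordant allele and
genotype quality of at least 50. Both thresholds target the same failure
mode — a true heterozygote whose sampled reads happened to show one
allele — which is by far the dominant source of false conversions on
simulated data (without the check, roughly four in five called events
are genotype errors, mirroring the large gap between raw double-switch
candidates and validated events in real pipelines). Post-filters remove
events within 1 kb of each other (tract midpoints, both members), events
whose flanking-site interval is less than half mappable, and events
whose converted site sits more than 10 kb from the nearest non-converted
informative site. Transmission validation tracks the converted allele
into the next generation where the genotype configuration allows it,
scoring only the first sequenced descendant so the Mendelian 50%
expectation holds per event.

## Gene-conversion parameters

**gBGC.** Among converted informative sites carrying one strong (G/C)
and one weak (A/T) allele, the bias is the fraction transmitting the
strong allele, with a Clopper–Pearson interval and a one-tailed exact
binomial test against 1/2. Sites, not events, are counted when tracts
carry several weak/strong heterozygotes.

**Tract length.** Tract lengths are modelled exponential, so two
informative sites d bp apart co-convert with probability
`exp(-d / mean)`. Every informative site within 5 kb of each converted
focal site contributes a Bernoulli term; the composite log-likelihood is
maximized over an integer grid of 1–1000 bp. Uncertainty comes from
1,000 bootstrap resamples of the converted focal sites; each focal site
carries its pair bundle, and resampling sites rather than events keeps
those bundles intact. Events whose converted sites span more than
4 kb are excluded as incompatible with the single-exponential model. A
2 kb pair window is the standard cross-check and gives the same point
estimate on simulation.

**Detection power and totals.** Power is Monte Carlo: exponential tracts
placed uniformly along each chromosome, counting the fraction that cover
at least one informative site of the focal founder; for Poisson sites of
density p the closed form is `p / (p + 1/mean)`, which the estimator
must match (a tested oracle). The total non-crossover count per meiosis
divides observed events by power, averaged across founders per
chromosome before dividing (the pool-then-divide alternative is exposed
as a flag because the two weightings genuinely differ when founder
panels differ in diversity). The per-site heteroduplex model of gBGC has
a consequence the coverage-only power misses: at a weak/strong
heterozygote, repair toward the background allele restores the original
sequence, so about half of single-site conversions at such sites are
silent. `estimate_power()` therefore accepts optional per-site
observability weights (1 for other heterozygotes, 1/2 for weak/strong
sites); the weighted form is what closes the detected/power loop against
simulated truth, while the unweighted, coverage-only form is the
conventional calculation.

## CpG islands and enrichment

The scanner averages 100 bp windows (1 bp step) over ten consecutive
windows and reports runs of at least 250 bp with GC above 0.5 and
observed:expected CpG above 0.6. The methylation-aware model is an
8-state hidden Markov model — island and non-island states for each
base — over six symbols (A, C, G, T, hypomethylated C and its
complementary-strand G, where hypomethylated means under half of
bisulfite reads support methylation). Transitions and emissions are
estimated by supervised counting on the scanner partition with
pseudocount 1 (no reference transition or emission probabilities exist
for these genomes, so island sets will differ in detail from any
particular published annotation); decoding is Viterbi, tested against exhaustive path
enumeration on short sequences. Island-state runs merge across gaps
under 50 bp and must end up between 150 bp and 2 kb.

Enrichment of recombination events at features uses the edge-gap
distance (overlap counts as zero): within 100 bp for islands, 500 bp for
TSSs. The null redistributes each event among equal-length windows
within 2.5 Mb, matching GC content of the surrounding 100 kb within
0.025 (absolute, a package reading of "within 2.5%") and mappable
fraction within 0.2, excluding overlap with the original interval.
Candidates are enumerated on a 100 bp stride (configurable to 1 for full
enumeration); 5,000 sampled placements per event form the null, the
empirical p-value is `(1 + #null >= observed) / (1 + n_sets)` so it can
never be zero, and fold enrichment is observed over the null mean.
Because the overlap fraction of a finite event set is discrete, ties
make the p-value conservative in the mid-range; calibration tests
therefore assert validity (rejection at or below the nominal level) and
near-nominal behaviour in the tail rather than exact uniformity, which a
discrete conservative statistic cannot attain. LD hotspots are 1 kb
windows whose mean population recombination rate exceeds five times the
mean of the flanking 20 kb per side (2 kb buffer), merged when adjacent;
the caller is scale-invariant in the rate units. The uniform-heat
thought experiment — every island carrying the mean hotspot heat h over
coverage c — expects a fraction `c h / (c h + 1 - c)` of crossovers at
islands.

## The synthetic pedigree generator

The generator exists so that every stage is testable without sequencing
data, and its defaults are the study conditions: founder heterozygosity
1% (segregating sites as a Poisson process with allele frequencies
uniform on 0.05–0.95, giving an informative-site density near 0.5%),
crossover intensity 2e-8 per bp per meiosis (about 20 events on a 1 Gb
genome) with an obligate minimum of one per chromosome per gamete and
telomere-weighted placement (Beta(0.5, 0.5)) on macro-chromosomes,
non-crossover initiation 9e-8 per bp (about 90 per 1 Gb), exponential
tracts with a 32 bp mean, strong-allele transmission probability 0.59 at
weak/strong heterozygotes inside tracts, point mutation rate 5e-9 per bp
per generation with a 1.7:1 paternal bias, a 15% post-zygotic fraction
with mosaic read fractions uniform on 0.1–0.4 (observed mosaic fractions
sit below one half; the uniform range is a modelling choice), and 25x
Poisson coverage with base error 1e-3 spread over the three alternative
bases. Genotypes are maximum-likelihood calls from the simulated read
counts, so realistic genotyping errors — the dominant adversary of
single-site conversion calling — arise naturally. Read-pair fragments
(300 bp span) are generated on demand around loci of interest for
phasing and timing analyses. One master seed determines everything;
per-meiosis child seeds keep subsets reproducible.

What the generator does not emulate: linkage disequilibrium among
founder alleles (sites are independent), sequence context beyond the
trinucleotide assigned to each mutation, indels, alignment and
mappability artifacts (masks are inputs), crossover interference (a
gamma renewal option exists but is off by default, as no interference
model is part of the estimators under test), and any joint placement of
crossovers and conversion tracts. Passing recovery tests therefore shows
that the estimators are correct under the stated sampling models, not
that real-data artifacts are handled; the stringent filters are
exercised by the generator's genotyping noise, which is the one artifact
class it does reproduce faithfully.

## Problem sizes used by the test suite

Unit fixtures run on 12 Mb toy genomes with elevated mutation or
conversion rates so each stage sees enough events. The parameter-recovery
suite simulates four five-sibling, three-generation families on a 100 Mb
toy genome (a 44 Mb macro-chromosome plus 30, 16 and 10 Mb
micro-chromosomes) at the default study conditions, processing one
chromosome at a time; chromosomes are independent given the pedigree, so
this is exactly one simulation of the full genome with bounded memory.
Tract-length recovery uses about 275 detected-style events over sites at
density 0.002 per bp on 50 Mb, the scale at which the composite
likelihood is actually applied; its sampling standard deviation there is
about 4 bp around the true 32 bp. Calibration checks use 200 replicates
with 200 shuffle sets. The acceptance script reruns the uniform-heat
expectation and the tract-length recovery from scratch at these same
sizes.

## Known limitations

The change-group parity rule can misclassify a genuine crossover
coinciding with an adjacent conversion in the same meiosis; both events
are rare enough that the joint case is negligible at realistic rates.
The read-level verification of converted sites trades a few percent of
true events (those whose homozygous genotypes carry an error read or sit
at modest depth) for an order-of-magnitude reduction in false calls; the
power correction does not model that loss, so power-corrected totals are
a slight underestimate. The composite likelihood treats focal sites as
independent although co-converted sites share a tract, which is why
uncertainty comes from the bootstrap rather than the curvature. The HMM
island set depends on the supervised training partition; counts of
islands are therefore not comparable across annotations built with other
parameterizations.
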