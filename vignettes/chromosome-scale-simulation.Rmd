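---
title: "Chromosome-scale coalescent simulation from a citable species catalog"
author: "chromsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-scale coalescent simulation from a citable species catalog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromsim)
```

## Motivation

Population-genomic analyses are routinely benchmarked against simulated
genomes, and chromosome-scale simulation matters because linkage —
haplotype structure, linkage disequilibrium, the spatial footprint of
recombination — cannot be reproduced by simulating unlinked loci.
`chromsim` packages the whole pipeline: a species *catalog* whose every
numeric parameter carries provenance citations, piecewise-constant
demographic models with per-model mutation-rate overrides, a
structured-coalescent engine with crossover and non-crossover
recombination, discrete-site Jukes–Cantor mutation, summary statistics,
and a quality-control procedure for independently re-specified models.

## The catalog and its conventions

A `Species` entry holds chromosomes (per-chromosome mutation and
recombination rates, optional gene-conversion parameters), a default
effective population size, a generation time, ploidy and citations. Two
conventions are central:

* **Never invent unpublished numbers.** The built-in entries embed only
  parameters with published point values: *Anopheles gambiae* (nuclear
  mutation rate 3.5e-9 per bp per generation — a *D. melanogaster*
  estimate adopted for this Dipteran — generation time 1/11 years,
  default Ne 1e6), *Bos taurus* (mutation rate 1.2e-8 everywhere,
  recombination rate 9.26e-9 on all chromosomes except the mitochondrial
  genome, default Ne 6.2e4, generation time 5 years), *D. melanogaster*
  (gene-conversion fraction 0.83 with mean tract 518 b on recombining
  chromosomes) and *E. coli* (haploid; non-crossover recombination
  initiating tracts at 8.9e-11 per bp per generation with mean tract
  542 b). Everything else — chromosome lengths in particular — is `NA`
  ("unknown, supply at simulation time") and comes from `chrom.sizes`
  or `.fai` files, `lengthOverride`, or explicit rate overrides. The
  catalog schema is versioned and unknown keys are *errors*, because a
  typo in a citable parameter name should never pass silently.
* **Provenance is an invariant.** `validateSpecies()` reports a
  violation whenever a non-missing parameter class has no citation with
  the matching reason tag. Citations of built-ins are descriptive
  provenance strings rather than full references; a production catalog
  would carry DOIs.

The *A. gambiae* default Ne documents its own derivation: with mean
nucleotide diversity θ ≈ 0.015 and μ = 3.5e-9, `deriveNeFromTheta()`
inverts θ = 4μNe to 1.07e6 (reported to three significant figures), and
the catalog default is that estimate rounded down to one million — the
derivation is exposed as a function precisely so the rounding is the
caller's visible, documented choice.

```{r}
signif(deriveNeFromTheta(0.015, 3.5e-9), 3)
```

### Pseudo-chromosomes

For genome builds made of unplaced contigs, `assemblePseudochromosomes()`
concatenates contigs into groups approximating a set of target chromosome
lengths, so simulations still carry realistic linkage blocks. The spec of
the grouping is deliberately simple and deterministic: first-fit-decreasing
bin packing against the target lengths, ties broken by input order,
overflow flagged rather than refused. On small instances this attains the
exhaustive-search optimum (the tests check one), and its determinism
matters more here than optimality: the same inputs must always produce the
same pseudo-chromosomes.

## Demographic models

A `DemographicModel` is a set of named populations with present-day sizes,
a time-ordered event list — instantaneous size changes, pastward splits
(a derived population merging into its ancestor), migration-rate changes —
and an optional **mutation-rate override**. Time is measured in
generations before the present, 0 = sampling time; epochs are half-open
pastward, so at an event time exactly the older size applies. Only
instantaneous size changes are supported (both worked catalog models are
step models); exponential-growth epochs are a declared non-goal.

The override exists because demographic models are inferred *under* an
assumed mutation rate. The cattle model is the worked example: the species
mutation rate (1.2e-8) is 28% higher than the 9.4e-9 assumed during the
runs-of-homozygosity inference, so simulating the model under the species
rate would inflate diversity; the model therefore carries
`mutationRateOverride = 9.4e-9`, and `effectiveMutationRate()` applies it.
No analogous recombination-rate override exists (models cannot carry one),
so the matching 8% recombination-rate discrepancy can only be *flagged*:
`auditRateConsistency()` emits both percent discrepancies, marking the
mutation one resolved when the override matches and the recombination one
always unresolved.

```{r}
bt <- builtinCatalog()[["BosTau"]]
m <- DemographicModel("holstein-like", "pop0", c(pop0 = 90),
  events = list(sizeChangeEvent(33000, "pop0", 62000)),
  mutationRateOverride = 9.4e-9)
auditRateConsistency(m, bt,
  list(mutation_rate = 9.4e-9, recombination_rate = 1e-8))[, 1:5]
```

Percent discrepancies round half-to-even to integer percent for the
human-readable form; the unrounded value is always available.

### Quality control by independent re-specification

New catalog models are accepted only after a second implementer recreates
them from the source documentation and `compareModels()` passes: it aligns
events by (time, type, populations) keys and compares all numeric fields
at a relative tolerance, flagging structural mismatches (missing
populations, unmatched events, override present vs absent)
unconditionally. The default tolerance is 1e-6: catalog constants are
transcribed, not computed, so two faithful transcriptions should agree to
the printed precision, and a tolerance much looser than that would defeat
the audit. Published descriptions of this review practice do not pin down a
tolerance; ours is a documented choice, configurable for derived
quantities.

## The ancestry engine

`simulateAncestry()` runs a Hudson-style structured coalescent backwards
in time over lineages carrying sorted lists of ancestral-material
segments. Competing exponential rates are:

* **Coalescence** within population *p* with *k* lineages at rate
  k(k−1)/2 × 1/(ploidy × N_p(t)). The ploidy convention is stated
  explicitly because sources often leave it implicit: diploids coalesce
  pairwise at 1/(2Ne) per generation, so E[pairwise diversity] = 4Neμ
  (matching θ = 4μNe); haploids (bacteria) at 1/Ne.
* **Migration** per lineage at the current matrix rates.
* **Crossover** per lineage at the rate-map mass over its *breakable
  span* — strictly between its leftmost and rightmost ancestral
  coordinates (Hudson's convention; breakpoints outside that span cannot
  change the genealogy).
* **Non-crossover (gene conversion) initiation** over the same span at a
  uniform per-link rate, the tract extending rightward from the
  initiation site by a geometric length and truncated at the span end.
  An alternative whole-contig initiation mode (`gcSpan = "contig"`) is
  available because the bacterial initiation-rate estimate does not say
  whether initiation is restricted to ancestral material; the default
  restricts to the span, which changes only the bookkeeping of
  drawn-but-ineffective events, not the genealogy distribution.

Piecewise-constant demography is handled by advancing to each epoch
boundary and redrawing waiting times, valid by memorylessness of the
exponential. Coordinates are 0-based half-open; breakpoints and
gene-conversion initiation sites are integers (discrete genome).
Simultaneous-event ties — probability zero, but conceivable with finite
precision — resolve by fixed type priority: coalescence, migration,
crossover, gene conversion.

Two parameterizations of non-crossover recombination mirror how the two
domains report it:

* **Eukaryotic gene conversion** is given as the *fraction f* of
  recombination events that are gene conversions. The initiation rate is
  then crossover-rate × f/(1−f) (`gcInitiationRate()`), so drawn events
  occur at a ratio f : (1−f) — 83:17 for the *D. melanogaster* value of
  0.83 — and the crossover rate itself is *not* reduced. With a
  non-uniform crossover map the gc initiation rate uses the map's mean
  rate, uniformly along the contig.
* **Bacterial mode** (`nonCrossoverOnly`) reinterprets the chromosome's
  recombination rate as the tract-initiation rate, zeroes the crossover
  map, and requires a mean tract length. Horizontal transfer of *novel*
  gene content (plasmids) is out of scope: only homologous replacement is
  modeled.

Tract lengths are geometric on {1, 2, ...} with success probability
1/mean — the memoryless discrete distribution with the requested
expectation; the sources specify only an *average* tract length, so the
canonical minimal-assumption choice is made and documented. Gene
conversion is **off by default** (it is expensive: the 0.83 fraction
multiplies the recombination event load by ~6) and must be enabled with
`makeContig(..., geneConversion = TRUE)`.

The engine logs every event with drawn/effective counts. Crossovers
within the breakable span always split material; gene-conversion tracts
falling entirely into gaps between ancestral segments are logged as drawn
but ineffective. The drawn-event ratio is therefore the end-to-end audit
of the competing-rates machinery: pooled over replicates,
gc_drawn/(gc_drawn + crossover_drawn) must recover the configured
fraction within binomial error, and the logged tract lengths must average
the configured mean.

The output `Genealogy` is a node table (times in generations) plus an
edge table (parent, child, genomic interval), the tabular encoding of all
marginal trees used across this field's simulators. Nodes are created
only where ancestral material actually overlaps at a common-ancestor
event, and intervals whose sample count reaches n are retired, so the
simulation stops exactly when every position has fully coalesced.
`marginalTree()` extracts any position's tree as an `ape::phylo`.

The engine core is compiled (Rcpp), as is standard for coalescent
simulators; it draws from R's RNG, so a single integer seed fixes the
run. One root seed drives independent derived substreams for ancestry and
mutation (`deriveSeeds()`), so mutation layering is reproducible
independent of the ancestry event interleaving.

## Discrete-site mutation

`throwMutations()` implements finite-sites Jukes–Cantor mutation: per
edge a Poisson count with mean μ × interval length × branch length, a
uniform integer site within the edge interval, a uniform time on the
branch, and a derived state uniform over the three non-current
nucleotides. Because sites are discrete, a site can be hit repeatedly —
on one lineage path (reversion, successive substitution) or on disjoint
branches — and can segregate **more than two alleles**; collisions are
retained, not rejected. Ancestral states are uniform over A,C,G,T (the
Jukes–Cantor stationary distribution); `fixedAncestral = TRUE` pins them
to "A" for deterministic fixtures and unfolded spectra. How the state
*above* a mutation is determined at multi-mutation sites is not pinned
down by the mutation model alone; we apply mutations root-to-tip in
decreasing age order along each site's marginal tree, which guarantees
derived ≠ parent state at every step, and document this as a choice.

## Summary statistics

`summaryStats()` computes segregating sites S, per-bp diversity π
(averaged over pairs, mismatches divided by the full contig length, not
per segregating site), Watterson's θ_w = S/(a_{n−1}L), and the site
frequency spectrum. Multi-allelic sites make the classical definitions
ambiguous in one place: the unfolded SFS counts *each derived allele* in
its own frequency class, while pairwise mismatches count any state
difference once. `branchDiversity()` is the variance-reduced companion
(2 × mean pairwise TMRCA × μ); site- and branch-mode π agree in
expectation *when per-site θ is small*. At high per-site rates the
discrete-site model saturates — recurrent hits mask differences — and
site π falls below branch π, approaching the Jukes–Cantor corrected
value θ/(1 + 4θ/3) for a pair; the property tests therefore run in the
low-θ regime, and the diversity calibration below tolerates the ~2%
saturation deficit at θ = 0.015.

## What the simulations do and do not establish

The test and calibration runs use the embedded study conditions — e.g.
500 replicates of a 100 kb contig with n = 10, Ne = 1e4, crossover rate
1e-8 and the fly gene-conversion parameters for the event-ratio audit;
1,000 replicates of a 10 kb, n = 2, zero-recombination contig at the
un-rounded *A. gambiae* Ne for the θ = 4μNe calibration (mean π = 0.015
to three decimals); 2,000 replicates for E[TMRCA] = 2·ploidy·Ne(1−1/n)
at n ∈ {2, 5, 10}; ≥5,000 tiny-instance replicates for the
uniform-first-coalescence topology check. These sizes are chosen so
Monte-Carlo error (3 standard errors; binomial for the ratio) is small
relative to the quantities checked. What passing shows: the engine's
rates, demography handling and mutation layering are internally
consistent and calibrated against closed forms. What it does not show:
realism of any particular species' genome — the generator emulates
neutral, uniformly mutating, panmictic-within-population sequences;
selection, rate heterogeneity along the genome, gene-content variation
and coordinate lift-over are explicitly out of scope.

## Numerical and degenerate-input choices

* Rates and lengths must be finite and non-negative; a gene-conversion
  fraction of exactly 1 is rejected (it implies an infinite initiation
  rate).
* Single-position lineages have an empty breakable span and never
  recombine; contigs of length 1 simulate (coalescence only).
* A model whose root populations are not connected by migration is
  rejected up front; the engine additionally detects stalls (no finite
  rate and no pending demographic event) rather than spinning.
* An event-count safety cap (default 5e7) aborts pathological
  configurations with an error rather than exhausting memory.
* VCF output converts the internal 0-based coordinates to 1-based in the
  writer only; nowhere else in the package do 1-based coordinates occur.

## Command-line use

`inst/scripts/chromsim-cli.R` is a thin optparse wrapper: `catalog
list|show|validate`, `simulate` (VCF + JSON stats + event TSV;
`--seed` is mandatory by construction) and `qc compare|audit` (JSON
report, non-zero exit on failure, CI-friendly). All logic lives in the
package functions documented above.
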