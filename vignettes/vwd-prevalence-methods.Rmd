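---
title: "Estimating von Willebrand disease prevalence from population allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating von Willebrand disease prevalence from population allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vwdprev)
```

## The estimation problem

Clinically ascertained prevalence figures for von Willebrand disease (VWD)
count symptomatic index cases and therefore miss mild and asymptomatic
genotypes. A genotype-first alternative starts from population sequencing
tallies: for each `VWF` variant and population we observe an alternate
allele count `AC`, a genotyped allele number `AN` and a homozygote count
`nhomalt`. The pipeline is then:

1. decide which variants are deleterious (the pathogenicity cascade);
2. sum their allele frequencies into a collective frequency `q` per
   population;
3. convert `q` into genotype frequencies under Hardy–Weinberg equilibrium
   (HWE).

## The Hardy–Weinberg layer

With `p = 1 − q`, HWE gives genotype proportions `p² : 2pq : q²`. The
package exposes each published summary as its own function:

- `carrier_frequency(q) = 2q` — the allele-counting approximation to the
  fraction of individuals carrying at least one deleterious allele. It is
  not a probability for `q > 0.5` (the function warns); at the observed
  `q ≈ 0.07` the error versus `1 − p²` is below one percentage point.
- `dominant_prevalence(q) = 2pq` — heterozygote frequency, the model for
  the dominantly inherited types (1, 2A, 2B, 2M).
- `recessive_prevalence(q) = q²` — homozygote/compound frequency.
- `compound_recessive_prevalence(q, q_null) = q² + 2·q·q_null` — the type
  2N model: affected individuals are 2N/2N homozygotes or 2N/null compound
  heterozygotes, with the null class the collective frequency of type 1
  and type 3 alleles.
- `pooled_recessive_prevalence(c(q1, q3)) = (q1 + q3)²` — the type 3
  model: type 1 and type 3 alleles pooled into a single recessive class.

**Assumptions.** Random mating within each population, independence
between variants (no linkage or haplotype structure), complete penetrance
of the modelled genotypes, and that every allele in the summed set is
causal. These are strong; the output should be read as an upper bound on
genetic prevalence rather than clinical prevalence.

**Denominator conventions.** The collective frequency uses a fixed
reference denominator `AN_ref = 2 × n_individuals` per population, so that
`q` values are comparable across variant subsets; per-variant MAF uses the
variant's own genotyped `AC/AN`, which differs where coverage varies.
Type-specific frequencies are sums of per-variant MAFs rather than a
single `AC/AN` ratio; the returned `collective_q` object then carries `NA`
counts and the summed value.

## The pathogenicity cascade

`classify_cohort()` applies five rules in strict priority order; the first
match assigns the rule label:

1. **known_db** — the variant appears in the merged HGMD/LOVD knowledge
   base with a clear VWD association. Database membership overrides
   in-silico predictors (and is the only rule that can admit a synonymous
   variant).
2. **truncating** — frameshift, stop-gained, and (by default) stop-lost.
   Stop-loss removes the natural terminator rather than truncating, but it
   is treated as a loss-of-function class here; `classification_options(
   include_stop_lost = FALSE)` reverses that choice.
3. **splice_core** — canonical splice positions (intronic offset ±1–2).
4. **splice_consensus** — intronic/splice-region variants where all three
   splice predictors (Varseak, ESEfinder, BDGP) call the site deleterious
   *and* CADD ≥ 20. A tool calls deleterious when the site is abolished or
   the variant score falls strictly below half the wild-type score. The
   CADD requirement makes the rule 4-of-4; `classification_options(
   splice_require_cadd = FALSE)` gives the 3-tool variant.
5. **missense_consensus** — all six categorical tools (SIFT, PolyPhen-2,
   LRT, MutationTaster, MutationAssessor, FATHMM) unanimous *and* CADD ≥
   20 (7-of-7).

Missing predictor values fail closed: a variant cannot become deleterious
through absent evidence. Thresholds are strict where the convention is
ambiguous (`< 0.5 × wild-type`, MAF `> cutoff`), chosen so that boundary
values never flip a verdict silently; tests pin these boundaries.

## Exclusions and cutoffs as data

Three recurrent `VWF` changes (p.Arg2185Gln, p.Met740Ile, p.His817Gln) are
common polymorphisms in the African/African American population and are
excluded from the carrier summary by default; the two with an assigned
VWD type are also excluded from the per-type grid. These are study
choices, not algorithm, so they live in `default_exclusions()` /
`prevalence_config()` and can be replaced wholesale. Recessive per-type
models additionally drop variants with population MAF strictly above 1%
by default (`maf_cutoff_recessive`), the usual guard against benign
polymorphisms inflating `q²`-scale estimates. Every variant dropped by
name or cutoff is recorded in the report's audit trail.

## The synthetic cohort generator

`simulate_cohort()` emulates a gnomAD-style aggregation with known ground
truth. Per variant, a true allele frequency is drawn; per population,
genotype counts are drawn under HWE at that frequency and tallied into
`AC`/`AN`/`nhomalt`. Defaults encode the reference cohort's observed
conditions rather than convenient values:

- population sizes: the eight gnomAD v2.1 populations (12,487 afr …
  64,603 nfe);
- 4,313 variants of which 505 pathogenic, 218 of those reported;
- mutation-class mix 355 missense / 53 frameshift / 40 stop-gained /
  1 stop-loss / 41 splice / 14 inframe / 1 synonymous (the 41 splice
  variants are split 28 canonical-site / 13 splice-region, an internal
  modelling choice — the source tally does not separate them);
- VWD-type mix 78 / 23 / 12 / 21 / 15 / 54 / 15 over types 1, 2A, 2B,
  2M, 2N, 3, UC;
- `singleton_fraction = 0.48`: about half of pathogenic variants observed
  as a single allele;
- per-tool `concordance = 0.3^(1/7)` (≈ 0.842), anchored so that a truly
  pathogenic missense variant passes all seven tools with probability
  ≈ 0.30 — the observed rate at which candidate deleterious missense
  variants survive a unanimous-consensus filter;
- a rare-frequency tail `10^U(−5, −2.5)` for non-singletons, spanning
  singleton-adjacent to just-below-common frequencies.

When `keep_genotypes = TRUE` the generator draws one dosage per
individual and returns the genotype matrices, so aggregation can be
verified against brute-force per-individual summation; the default draws
one multinomial per variant–population, which has the identical joint
distribution of counts and scales to gnomAD-sized cohorts. Both paths are
deterministic under the spec's seed.

**What it does not emulate:** linkage/haplotype structure between
variants, sequencing or genotyping error, coverage variation between
variants (`AN` is constant at `AN_ref`), population substructure within a
population, and ascertainment of the variant list itself.

## Numerical choices

All estimators are closed-form in `q`; no optimization or iteration is
involved, so numerical concerns reduce to exact count bookkeeping
(integers until the final division), strict-versus-inclusive thresholds
(documented and tested at the boundary), and TSV round-trips of doubles
written with 17 significant digits so that files reproduce byte-for-byte.
`q` values are validated into `[0,1]` at every model entry, and
`compound`/`pooled` models reject component sums above 1 rather than
returning a value outside `[0,1]`.

## Limitations

- Prevalence here is *genetic* prevalence under full penetrance; type 1
  VWD in particular shows incomplete penetrance and variable
  expressivity, so `2pq`-scale figures exceed clinically observed rates
  by an order of magnitude.
- The cascade inherits the blind spots of its predictors: a pathogenic
  missense variant missed by any one of seven tools is classified benign
  unless reported, and inframe indels and synonymous variants are only
  reachable through the knowledge base.
- Collective frequencies treat all deleterious alleles as exchangeable
  within an inheritance class; allele-specific severity is out of scope.
- The shipped VWF domain map (`inst/extdata/vwf_domains.tsv`, 16 domains
  over 2,813 residues) approximates published annotations; boundaries are
  configuration data and can be replaced via `domain_map()`.
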