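# vwdprev

Population prevalence of von Willebrand disease (VWD) from large-scale
allele-frequency data.

VWD is the most common inherited bleeding disorder, caused by quantitative
(types 1 and 3) or qualitative (types 2A, 2B, 2M, 2N) defects of von
Willebrand factor (VWF). Clinically ascertained prevalence estimates are
biased toward symptomatic index cases; an alternative is to start from
population sequencing databases (gnomAD-style per-population `AC`/`AN`/
`nhomalt` tallies), decide which `VWF` variants are deleterious, and convert
the collective frequency of deleterious alleles into genotype frequencies
under Hardy–Weinberg equilibrium (HWE). `vwdprev` implements that pipeline
end to end:

- **Cohort I/O** — a wide per-variant table (annotations, predictor scores,
  per-population counts) read and written as TSV or as an annotated VCF
  dialect, with structural validation (`ac <= an`, `2*nhom <= ac`, …) and
  multi-allelic sites split into biallelic records.
- **Knowledge base** — merge HGMD- and LOVD-style tables of reported VWD
  variants, resolving type disagreements (literature override, otherwise
  "UC"/unclassified), with cDNA-HGVS-first, genomic-fallback lookup.
- **Pathogenicity cascade** — five prioritized rules: known database
  variant; truncating (frameshift / stop gained / stop lost); canonical
  splice-site (±1–2); splice-prediction consensus (Varseak, ESEfinder, BDGP
  score halving or site abolition, plus CADD ≥ 20); missense consensus
  (six categorical tools unanimous and CADD ≥ 20). Missing predictors fail
  closed.
- **Aggregation** — affected-allele tables split by novel vs reported,
  recurrent-variant rankings, common-variant flags (MAF strictly > 1% in
  any population), homozygote census.
- **Prevalence models** — collective frequency `q = AC_total / AN_ref`;
  carrier frequency `2q`; dominant prevalence `2pq`; recessive `q²`;
  compound-recessive `q² + 2·q·q_null` for type 2N against type-1/3 null
  alleles; pooled recessive `(q1+q3)²` for type 3 — each with an audit
  trail of every variant dropped by an exclusion list or MAF cutoff.
- **Synthetic cohorts** — a seeded generator drawing HWE genotypes at known
  true allele frequencies with a configurable predictor-concordance model,
  so every stage can be tested against ground truth, plus small named
  fixtures whose aggregate counts reproduce published tallies.

## The model

With `q` the collective frequency of deleterious alleles in a population
and `p = 1 − q`, HWE gives genotype frequencies `p²`, `2pq`, `q²`. The
package reports:

| quantity | formula | interpretation |
|---|---|---|
| carrier frequency | `2q` | allele-counting approximation of carriers |
| dominant prevalence | `2pq` | heterozygote frequency (types 1, 2A, 2B, 2M) |
| recessive prevalence | `q²` | homozygote/compound frequency (type 3, pooled with type 1) |
| compound recessive | `q² + 2·q·q_null` | type 2N homozygotes plus 2N/null compounds |

The denominator convention is fixed: `AN_ref = 2 × n_individuals` per
population for collective frequencies, while per-variant MAF uses the
variant's own genotyped `AC/AN`.

## Worked example

Collective frequency and the three HWE figures from published-scale counts
(19,693 deleterious alleles over 282,912 reference alleles):

```r
library(vwdprev)
q <- collective_q(19693, 282912, population = "all")
print(q)
#> Collective allele frequency q = 0.0696082 (19,693 / 282,912) [all]
carrier_frequency(q)            # 0.1392164  (~1 in 7 carries an allele)
dominant_prevalence(q) * 100    # 12.95258   per 100
recessive_prevalence(q) * 100   # 0.484530   per 100
```

A full synthetic run — simulate a gnomAD-sized cohort, classify it against
its own knowledge-base fixture, and estimate prevalence:

```r
sim <- simulate_cohort(cohort_spec(n_variants = 600, seed = 42))
cls <- classify_cohort(sim$records, sim$db)
print(cls)
#> Pathogenicity classification: 53 of 600 variant(s) deleterious (30 reported, 23 novel)

prev <- prevalence_report(sim$records, cls, sim$populations)
prev$carrier[1, c("population", "q_all", "carrier_2q", "dominant_all")]
#>   population     q_all carrier_2q dominant_all
#> 1        all 0.0192498  0.0384996     3.775849
```

Named fixtures reproduce published aggregate tallies exactly; for example
the per-population count fixture yields the Latino/Admixed American
dominant prevalence of 18.6 per 100:

```r
fx <- end_to_end_fixture("table4_populations")
cls <- classify_cohort(fx$records, fx$db)
prev <- prevalence_report(fx$records, cls, fx$populations,
  prevalence_config(exclusions_carrier = character(0),
                    exclusions_types = character(0)))
round(prev$carrier[prev$carrier$population == "amr", "dominant_all"], 1)
#> [1] 18.6
```

The batch pipeline (`run_pipeline()` on a `run_config()`) writes
classification, affected-allele, recurrent-variant, common-variant and
prevalence tables plus a JSON summary and a run log; a thin CLI wrapper
lives at `inst/cli/vwdprev.R` (`run`, `simulate`, `fixture` subcommands).

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "vwdprev", load_package = "installed")'
```

The suite covers unit oracles (exhaustive predictor truth tables,
brute-force per-individual allele summation, closed-form prevalence
oracles), property-based checks (HWE identity, model ordering, evidence
monotonicity, determinism) and fixture-level acceptance tests at printed
precision.

## License

MIT (see `LICENSE`).
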