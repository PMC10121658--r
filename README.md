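# mfscreen

Chromosome-quotient screening for male-determining factor candidates in
mosquito transcriptomes.

## The problem

In culicine mosquitoes, sex is decided by a dominant male-determining
factor (M factor) at a hemizygous M locus: one copy in males, none in
females. That hemizygosity leaves a genomic footprint — male whole-genome
reads align to M-linked sequence, female reads essentially do not — and an
M factor additionally has a diagnostic expression signature: transcription
starting at zygotic genome activation (~6–7 h post-oviposition, the
syncytial blastoderm stage), no maternal deposition, and no expression in
adult females.

`mfscreen` turns this reasoning into a tested, reusable pipeline for
anyone hunting sex-determining loci in a de novo transcriptome with
male/female DNA resequencing and staged RNA-seq in hand. For each
reference transcript with male/female alignment counts $M, F$ and library
totals $N_M, N_F$ it computes the chromosome quotient

$$\mathrm{CQ} = \frac{F/N_F}{M/N_M}$$

(≈ 0 for male-specific, ≈ 1 for autosomal, ≈ 2 for female-dosage-biased
sequence) and applies the two-gate candidate screen:

1. **CQ gate** — CQ < 0.2 and male count > 20 and female count < 20, all
   strict;
2. **expression gate** — on TMM-normalized abundances: 4–8 h embryos > 0,
   8–12 h embryos > 0, 0–1 h embryos = 0, adult females = 0;

followed by exclusion of transposase/reverse-transcriptase-derived
contigs. TMM (trimmed mean of M-values) normalization is implemented from
its definition with exact zero preservation, and a synthetic-data module
plants M-linked, autosomal and female-biased contigs with known truth so
the whole screen is testable end to end without any downloads. Candidate
characterization (longest-ORF finding, translation, in-silico PCR) and
knockout-phenotype statistics (per-tissue feminization percentages,
injection/hatch/sex-ratio tables, 2^-ddCt fold changes) round out the
workflow.

## Worked example

```r
library(mfscreen)
library(dplyr)

params   <- sim_params(seed = 1)       # 10 M-linked, 200 autosomal, 20 female-biased
scenario <- simulate_scenario(params)  # truth table + DNA counts + expression
report   <- run_screen(scenario)      # TMM -> CQ gate -> expression gate
report
#> M-factor candidate screen: 230 references; CQ gate 10; both gates 10; TE-excluded 0; final candidates 10
#> # A tibble: 230 × 10
#>   id     male_count female_count    cq cq_pass expr_pass te_excluded ...
#> 1 M_0001         58            0     0 TRUE    TRUE      FALSE
#> 2 M_0002         54            0     0 TRUE    TRUE      FALSE
#> 3 M_0003         39            0     0 TRUE    TRUE      FALSE

glance(report)
#> # A tibble: 1 × 6
#>   n_references n_cq_pass n_expr_pass n_both_gates n_te_excluded n_final
#> 1          230        10          10           10             0      10
```

All 10 planted M-linked contigs — and only those — survive both gates:
hemizygous contigs draw zero female reads (CQ = 0) and carry the
zygotic-male-limited expression signature, autosomal contigs sit at CQ ≈ 1
and fail the CQ clause, female-biased contigs at CQ ≈ 2. `tidy(report)`
exposes the full per-reference filter trail (which clause failed, TE
exclusion, final verdict), `autoplot(report)` draws the gate funnel, and
`write_report()` serialises it with a summary header.

Phenotype summaries reproduce published-style tables from raw
per-individual scores:

```r
pheno <- read_phenotypes(system.file("extdata",
          "mosaic_phenotypes_synthetic.csv", package = "mfscreen"))
summarize_phenotypes(pheno, group = "mosaic") |> select(tissue, label)
#>   tissue             label
#> 1 antennae           54% (21/39)
#> 2 maxillary_palps    90% (35/39)
#> 3 external_genitalia 92% (36/39)
#> 4 gonads             85% (33/39)

fold_change_ddct(24, 20, 26.5, 20)
#> [1] 5.656854
```

The feminization labels read "x % of the 39 mosaic knockout males show a
feminized score in this tissue"; the fold change is the 2^-ddCt relative
expression of a target against a reference gene in case vs control
samples.

See `vignettes/mfscreen-methods.Rmd` for the model, the TMM definition,
the simulator's assumptions, and the package's numerical conventions.

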