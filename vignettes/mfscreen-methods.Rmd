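---
title: "Screening for male-determining factor candidates with mfscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for male-determining factor candidates with mfscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfscreen)
library(dplyr)
```

## The problem

In culicine mosquitoes, maleness is imposed by a dominant male-determining
factor (M factor) residing at an M locus on one homolog of an otherwise
homomorphic chromosome pair. Because the locus is hemizygous — one copy in
males, none in females — its sequence leaves a characteristic footprint in
whole-genome sequencing of the two sexes: male reads align to it, female
reads essentially do not. An M factor additionally has a characteristic
developmental expression signature: it must switch on at zygotic genome
activation (the syncytial blastoderm stage, around 6–7 h post-oviposition
in these species), cannot be maternally deposited, and is never expressed
in adult females.

`mfscreen` implements this two-gate screen over a de novo transcriptome:

1. **Chromosome-quotient (CQ) gate.** For each reference transcript, with
   male and female genomic alignment counts $M$ and $F$ and library totals
   $N_M$, $N_F$,
   $$\mathrm{CQ} = \frac{F / N_F}{M / N_M},$$
   i.e. the female-to-male ratio of depth-scaled coverage. Hemizygous
   male-specific sequences concentrate near 0, autosomal sequences near 1,
   and sequences with female-biased dosage near 2. A transcript passes the
   gate iff CQ < 0.2 **and** male count > 20 **and** female count < 20,
   all strictly: boundary values fail. A transcript with no male coverage
   has an undefined CQ and can never pass.

2. **Expression gate.** On TMM-scale abundances across the developmental
   design, a candidate must satisfy: 4–8 h embryos > 0, 8–12 h embryos
   > 0, 0–1 h embryos = 0, adult females = 0.

Transcripts whose annotation marks them as transposase- or reverse-
transcriptase-derived are excluded from the final candidate list; such
repeat-derived sequences pass sex-specificity filters for reasons unrelated
to sex determination.

## Design choices in the CQ statistic

The screen's published description fixes the thresholds but not the
orientation or the normalization of the quotient, so the package takes a
position and documents it:

* **Orientation** is female-over-male, the convention of the CQ method
  itself, so that male-specific sequences score near 0 and the threshold
  "CQ < 0.2" reads naturally.
* **Depth normalization** is on by default. With near-equal male and
  female library sizes it is immaterial, but it makes the statistic
  invariant to sequencing depth (scaling every female count and the female
  total by the same constant leaves CQ unchanged to floating precision),
  which is the property a screen should have. `normalize = FALSE` gives
  the raw ratio for libraries known to be exactly balanced.
* **Strictness**: all three comparisons are strict, exactly as printed. A
  CQ of exactly 0.2, a male count of exactly 20 or a female count of
  exactly 20 fails, and the verdict records which clause failed.
* **No male coverage** yields an undefined CQ (`NA`), not infinity; such
  records also necessarily fail the male-count clause.

## TMM normalization

`tmm_factors()` implements trimmed-mean-of-M-values normalization from its
definition rather than wrapping an existing implementation, because the
zero-preservation property the expression gate relies on is part of this
package's contract. For a library $j$ against a reference library $r$,
every gene $g$ with nonzero counts in both contributes a log-ratio and an
average log-abundance of the depth-scaled proportions:
$$M_g = \log_2 \frac{y_{gj}/N_j}{y_{gr}/N_r}, \qquad
  A_g = \tfrac12\left(\log_2 \tfrac{y_{gj}}{N_j} + \log_2 \tfrac{y_{gr}}{N_r}\right).$$
The most extreme 30 % of $M_g$ on each side and 5 % of $A_g$ on each side
are discarded (rank-based double trim), and the scaling factor is
$2^{\bar M}$ with $\bar M$ the weighted mean of the surviving $M_g$ under
inverse-variance weights from the binomial delta-method approximation
$\operatorname{var}(M_g) \approx \frac{N_j - y_{gj}}{N_j y_{gj}} +
\frac{N_r - y_{gr}}{N_r y_{gr}}$. Factors are rescaled to geometric mean 1.
The reference library is chosen as the one whose 75th percentile of
$y/N$ (over genes expressed somewhere) is closest to the across-library
mean of those percentiles. The test suite checks this implementation
against both an independently written brute-force trimmed weighted mean
and `edgeR::calcNormFactors()` to relative error below $10^{-9}$.

`normalize_tmm()` then rescales to counts-per-million of the *effective*
library size, `raw / (lib_size * factor) * 1e6`. Zeros map to zeros
exactly — no pseudocounts — so the presence/absence pattern the expression
gate tests is identical on raw and normalized values. "TMM > 0" is
therefore interpreted as exact positivity with no epsilon floor.

## The expression gate and replicate aggregation

The published filter is phrased per stage, not per replicate, so the
default aggregation is the stage **mean**: an `eq_zero` rule requires the
replicate mean to be 0 (equivalently every replicate 0, values being
non-negative) and a `gt_zero` rule requires the mean to be positive
(equivalently any replicate positive). The stricter `all_replicates` mode —
the condition must hold in each replicate individually — is provided for
sensitivity analyses; the two modes differ exactly on references detected
in some but not all replicates of a stage. References missing from the
expression matrix are treated as unexpressed (all-zero) with a warning
rather than as errors, mirroring quantifiers that drop contigs with no
assigned reads.

## What the simulator emulates

`sim_params()` / `simulate_scenario()` generate a complete synthetic study:
contigs of three linkage classes with the copy numbers a hemizygous M
locus implies — M-linked (1 male copy, 0 female), autosomal (2, 2) and
female-dosage-biased (1, 2) — plus equal-depth male/female DNA counts and
a stage × replicate expression matrix.

* **DNA counts** are Poisson with mean
  $\text{depth} \times \text{copy}/2 \times \ell/\bar\ell$, where $\ell$
  is contig length. Poisson (rather than negative binomial) coverage is
  adequate here because the screen consumes hard thresholds, not variance
  estimates. A sex with zero copies draws from mean
  $\varepsilon \times \text{depth}$, the mismapping *leakage*; the default
  $\varepsilon = 0$ gives exact zeros. Library totals are column sums plus
  a constant off-target mass (reads aligning nowhere in the transcript
  set), so totals always exceed tabulated counts.
* **Expression** gives every contig a log-normal baseline (meanlog
  $\log 50$, sdlog 1) with log-normal replicate noise (sdlog 0.3).
  M-linked contigs are exactly zero in every sample collected before
  zygotic activation and in adult females, and positive otherwise;
  autosomal contigs are positive everywhere (maternal deposition covers
  0–1 h embryos); female-biased contigs are elevated (default 4-fold) in
  adult females. A stage counts as pre-activation when its collection
  window *closes* before `activation_hour`: with the default 6.5 h, the
  4–8 h pool spans activation and already contains zygotic transcripts,
  while 0–1 h and 2–4 h pools do not.
* **Default scale.** 10 M-linked, 200 autosomal and 20 female-biased
  contigs of 1500–2000 nt at depth 100 per autosomal contig per sex, seven
  stages × 3 replicates. The near-uniform mRNA-scale length range keeps
  per-contig coverage close to the nominal depth, so hemizygous contigs
  have expected male coverage of roughly 50 alignments — comfortably clear
  of the "> 20 male reads" clause — which is the regime in which exact
  recovery of the planted set is the correct expectation. These sizes run
  the full screen in seconds on one CPU.
* **Determinism.** Each component (per-class sequences, male counts,
  female counts, expression baseline, replicate noise) draws from its own
  seed-derived substream, so changing one class's size does not perturb
  another's draws, and a scenario regenerates byte-identically from its
  manifest.

What the simulator does **not** emulate: real mismapping structure
(paralogy, repeats), GC- or mappability-dependent coverage, overdispersed
biological replicates, transcript-vs-gene multiplicity, or partially
male-specific sequences. Passing the recovery tests therefore shows the
screen's logic is correct under its own model, not that real data will be
as clean; on real assemblies the TE-annotation exclusion and downstream
amplification checks do the work the simulator cannot.

## Candidate characterization

`find_longest_orf()` scans the three forward frames (inputs are
mRNA-oriented, so the reverse strand is not searched) for ATG-initiated
ORFs terminating at an in-frame stop within the sequence; the longest
wins, ties break to the 5'-most start, and ORFs lacking a stop are not
reported — a transcript whose frame runs off the end encodes no complete
protein here. Coordinates are 0-based half-open with the stop codon inside
the span; `peptide_length = (end - start)/3 - 1` excludes the stop.
`translate_dna()` uses the standard genetic code, renders stops as `*`,
drops trailing partial codons, maps any codon containing an ambiguity code
to `X` and errors on non-IUPAC characters. `insilico_pcr()` is
exact-match: every occurrence of the forward primer, every downstream
non-overlapping occurrence of the reverse primer's reverse complement, and
every resulting product up to `max_product`; degenerate-base expansion is
out of scope.

## Phenotype and qPCR summaries

`summarize_phenotypes()` tallies normal/feminized/malformed scores per
sexually dimorphic tissue (antennae, maxillary palps, external genitalia,
gonads) over a group and formats percentages as integers over the whole
group; `summarize_injection()` reports hatch rates to one decimal and
adult sex shares to two decimals. All percentage rounding is half-up (base
R's `round()` is half-to-even), matching how such tables are printed.
`fold_change_ddct()` computes $2^{-\Delta\Delta C_T}$; its reciprocal
symmetry (swapping case and control inverts the fold change exactly) is a
test invariant. The bundled per-individual phenotype table is a clearly
marked synthetic reconstruction: only its per-tissue marginal counts are
meaningful, individual-level co-occurrence of phenotypes is arbitrary.

## A worked run

```{r screen}
params <- sim_params(seed = 1)
scenario <- simulate_scenario(params)
report <- run_screen(scenario)
report
glance(report)
tidy(report) |> filter(final_candidate) |> select(id, male_count, female_count, cq, class)
```

The CQ landscape and the gate funnel:

```{r plots, fig.width = 6, fig.height = 4}
autoplot(apply_cq_filter(compute_cq(scenario$counts)))
autoplot(report)
```

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open everywhere.
* CQ depth-invariance holds to $10^{-12}$; TMM factors carry geometric
  mean 1 to $10^{-12}$.
* An empty count table screens to an empty report, not an error; an empty
  phenotype group and a zero injected count are hard errors.
* A library sharing no expressed gene with the TMM reference gets factor 1
  with a warning rather than failing the whole normalization.
* One SAM alignment line counts as one alignment; read pairs are not
  collapsed, secondary/supplementary lines are skipped by default and
  unmapped lines always. This is a documented convention — alignment-level
  counting policies are rarely stated in screen descriptions, and any
  consistent choice leaves CQ's separation of linkage classes intact.

## Known limitations

The screen operates at transcript granularity; collapsing isoforms to
genes is left to the caller. The CQ gate assumes roughly equal-quality
male and female libraries — severe female-specific mappability loss would
mimic male-specificity. The expression gate is presence/absence only; it
cannot distinguish a male-limited activator from any other
zygotic-male-limited transcript, which is why candidate characterization
(ORF, amplification) and functional follow-up remain necessary.
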