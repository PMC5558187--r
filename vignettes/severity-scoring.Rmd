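---
title: "Scoring cystinuria mutation severity from variant effect predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cystinuria mutation severity from variant effect predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystsev)
```

## The problem

Cystinuria is an inherited stone-forming disorder caused by mutations in two
genes encoding the renal dibasic amino-acid transporter: *SLC3A1* (the heavy
subunit rBAT) and *SLC7A9* (the light subunit b(0+)AT). Clinical course
varies widely between patients, and a natural question for precision
management is whether the *predicted* molecular severity of a patient's
mutations tracks their phenotype — urinary cystine, ornithine, arginine and
lysine levels, age at presentation, and stone episodes and interventions
over a three-year window.

This package implements that analysis as a reusable pipeline:

1. **Per-mutation severity.** Each missense mutation is dichotomised into
   mild (1) or severe (2) from the score of one variant effect predictor
   (SIFT, PolyPhen2, MutationAssessor, FATHMM, Condel or CADD).
   Frameshift, deletion, splice-site and nonsense mutations are assigned
   severity 2 outright, since they typically ablate protein function.
2. **Per-patient severity.** Mutation severities are aggregated under the
   gene's inheritance model (below).
3. **Group comparison.** Patients are grouped by score and phenotype
   distributions compared between groups with a two-sided Wilcoxon rank-sum
   test, Bonferroni-corrected over the whole family of tests.
4. **Variant-set contrast.** Disease-associated variants are contrasted
   with population-only variants of the same genes on allele frequency,
   ConSurf conservation grade (1–9) and predicted folding stability change
   ΔΔG (kcal/mol, negative = destabilising).

## Severity thresholds and the stabilisation search

Deleterious-vs-neutral predictors are designed to flag even mildly
deleterious variants as damaging, so their standard thresholds cannot
separate *mild* disease mutations from *severe* ones. The pipeline
therefore uses a second, more stringent threshold per method:

| method            | scale direction  | standard deleterious | severe (score 2)  |
|-------------------|------------------|----------------------|-------------------|
| SIFT              | lower is worse   | < 0.05               | ≤ 0.025           |
| PolyPhen2         | higher is worse  | ≥ 0.5                | ≥ 0.80            |
| MutationAssessor  | higher is worse  | > 1.9                | ≥ 2.7             |
| FATHMM            | lower is worse   | ≤ −1.5               | < −8.5            |
| Condel            | higher is worse  | > 0.522              | > 0.672           |
| CADD              | higher is worse  | ≥ 15                 | ≥ 27.5            |

The inequalities deliberately differ in strictness between methods and are
encoded literally (`method_spec()`), because boundary scores do occur.
Scores on the *neutral* side of the standard threshold still map to
severity 1 — the mild side is unbounded — but trigger a warning, since such
mutations are predicted not deleterious at all.

`threshold_scan()` + `select_stable_threshold()` implement the selection
procedure behind these severe thresholds: candidate thresholds are swept
from the standard threshold toward higher stringency, all mutations are
re-scored and all patients re-aggregated at each grid point, and the
chosen threshold is the most stringent point of the longest run of
consecutive grid points with *identical* patient-to-group assignment.
Design choices that the procedure description leaves open, fixed here once:

* grid step 0.05 for the probability-scaled methods (SIFT, PolyPhen2,
  Condel), 0.5 for MutationAssessor and FATHMM, 2.5 for CADD — the
  finest granularity at which stable ranges have been reported;
* a run must span at least `min_run = 3` grid points, otherwise the
  grid is declared too coarse and an error advises refining it;
* stability is judged on the full patient→group assignment, not merely on
  group sizes. Identical assignment implies identical sizes, so this is
  the stricter and unambiguous reading of "group numbers stabilised";
* ties between equally long runs resolve toward the more stringent run.

## Inheritance-aware patient scores

*SLC7A9* behaves as autosomal dominant with incomplete penetrance: one
mutated allele suffices. The patient score is the **sum** of per-allele
severities, giving 1 (one mild mutation) through 4 (two severe mutations,
one per allele). *SLC3A1* is autosomal recessive: both alleles must be
mutated, and the allele carrying the worst mutation is modelled as not
expressed, so the patient score is the **minimum** of the two allele
severities — 1 or 2.

Two deliberate simplifications are preserved rather than "fixed": a
patient with two mild mutations scores the same as logic might assign a
single moderate one (the additive scale treats mutations independently),
and the recessive minimum rule is a strong expression assumption. Both are
properties of the scoring system under study, and the package reproduces
them exactly. Edge cases: a dominant allele carrying several mutations
(not observed in practice) scores as its worst mutation with a warning,
keeping the 1–4 range; patients with no identified mutation, or recessive
patients with a single mutated allele, are excluded with a notice; a
patient with mutations in both genes is an error — such patients must be
removed before scoring, as their gene-specific score is undefined.

## Rank statistics

All comparisons use an internally implemented Wilcoxon rank-sum test
(`wilcoxon_rank_sum()`). The reported statistic is the rank-sum of the
first sample with mid-ranks for ties. Conventions, stated because they
differ between implementations:

* **Two-sided p** is the total null probability of rank-sums at least as
  far from the null mean as observed, accumulated in both tails directly —
  *not* one tail doubled. For tie-free data the null distribution is
  symmetric and the two conventions agree; under ties they need not.
* **Exact mode** builds the full null distribution over all
  `choose(n1+n2, n1)` assignments of the pooled mid-ranks via a
  subset-sum recursion on doubled ranks (doubling makes mid-ranks
  integers), so ties are handled exactly rather than by approximation.
* **Approximate mode** uses the tie-corrected normal approximation with a
  0.5 continuity correction.
* `mode = "auto"` selects exact enumeration for `n1 + n2 ≤ 20` — the
  recursion is O(n · n1 · Σ2r), a few milliseconds at n = 20 — and the
  approximation beyond.

The exact path is validated against two independent oracles in the test
suite: full subset enumeration for small tied inputs, and R's null
Wilcoxon distribution (`dwilcox`) exhaustively for every tie-free
configuration with `n1 + n2 ≤ 8`. Its finite-sample level is checked by
simulation at n = 10 + 10; note the test is conservative there (the
attainable level just below 0.05 is about 0.043) because the null
distribution is discrete.

Bonferroni correction multiplies each raw p by the family size, capped at
1 (delegated to `stats::p.adjust`). The family for one analysis run is
every (group pair × phenotype) test performed; `family_size` can be
overridden when batches are corrected jointly. Rank correlation
(`spearman_correlation()`) is Pearson on mid-ranks with a t-approximation
p-value — chosen over the product-moment correlation because conservation
grades are ordinal and heavily tied.

## Group comparison design

All unordered pairs of severity groups are tested, with a minimum group
size of 2 (both overridable). Missing phenotype values are dropped
pairwise per comparison. Group summaries report n, mean, standard
deviation *and* median for each group × phenotype: "average" levels can be
read either way, so both are emitted and downstream consumers choose.
Urinary levels are compared exactly as supplied, without creatinine
normalisation.

## The variant-set contrast

`contrast_sets()` compares disease-associated and population-only variant
sets on one annotation at a time, reporting per-set medians, histograms
and the rank test. Conventions:

* an allele frequency of exactly 0 — the variant is absent from the
  population panel — is a real observation, kept as a literal zero, never
  recoded as missing. `frequency_spectrum()` therefore has a dedicated
  zero bin ahead of its half-open log-spaced bins;
* ΔΔG is signed so that negative values destabilise;
* ConSurf histograms use the nine integer grades; frequency and ΔΔG bin
  edges are configurable arguments with documented defaults, since no
  canonical binning exists;
* `sequence_clustering_runs()` groups mutated positions into maximal runs
  with spacing ≤ `max_gap` (default 1); reported stretches in the
  literature sometimes span small gaps, hence the knob.

## What the synthetic generator emulates — and what it does not

`sim_config()` / `simulate_variants()` / `simulate_cohort()` generate data
with the statistical structure the analysis assumes, so the whole pipeline
is testable without any external download. Defaults encode the study
conditions: 94 *SLC3A1* and 58 *SLC7A9* disease mutations against 318 and
144 population-only nsSNVs; disease variants mostly absent from the panel
or rarer than 0.01% (with a 3% chance of a common outlier, up to 31%);
about 80% of disease variants at ConSurf grades 6–9 versus about 40% of
population variants; stability changes centred at −1.122 kcal/mol
(disease) versus −0.668 (population); and a cohort of 41 recessive plus 32
dominant patients. Baseline urinary levels (cystine 300, ornithine 150,
arginine 100, lysine 500 µmol/mmol creatinine, log-normal with sdlog 0.5)
are round clinical magnitudes; their absolute values do not affect any
rank-based result.

Predictor scores are drawn from severity-conditional truncated normal
distributions on each method's native scale and direction, placed so that
each method recovers the latent severity for roughly 95–97% of mutations
at the default noise; `noise_scale = 0` collapses the emissions to
noiseless point masses, which underpins the end-to-end oracle: with no
noise, pipeline patient scores must equal the latent truth exactly, for
every method.

Phenotypes follow the simplest models consistent with the assumed
directionality: log-normal urinary levels with a multiplicative shift per
severity unit, normal age with a negative shift (−3 years/unit, truncated
at 1), and Poisson episode/intervention counts with a log-rate increase
(0.2/unit). The planted log-scale effects (arginine 0.45 per unit,
ornithine and lysine 0.12, cystine 0.06) were power-calibrated once so
that, in a balanced dominant cohort of 40 patients per score group, the
top-vs-bottom arginine comparison is reliably detected after Bonferroni
correction and is typically the smallest adjusted p of the whole family;
arginine deliberately carries the dominant planted signal, mirroring the
amino acid with the most consistent observed group differences. These
problem sizes (160-patient dominant cohorts, 200 replicate seeds,
60-vs-300 variant contrasts, 2000 null draws) are the package's standard
validation conditions throughout the tests and the acceptance script.

Three RNG streams (variants, predictor scores, cohort) are derived from
the master seed, so enlarging the cohort never perturbs the variant draws,
and identical (config, seed) pairs reproduce outputs bit-identically.

The generator deliberately does **not** emulate: population stratification
or realistic site-frequency spectra; linkage between annotations (ConSurf,
ΔΔG and frequency are drawn independently per set, although the real
quantities are correlated through selection); recurrent mutation at the
same position (simulated positions are sampled without replacement, so
multi-variant positions — which the real data do contain — are exercised
through `distinct_positions()` directly rather than through the
generator); splice-site variants (which have no faithful protein-level
notation); or any protein-structural signal. Passing tests on synthetic
data therefore demonstrate that the pipeline's logic and statistics behave
as designed under the assumed generative model — not that the biological
associations will replicate in a clinical cohort.

## Amino-acid classes

The four physicochemical classes used in the substitution cross-tabs are
hydrophobic {G, A, V, L, I, P, F, M, W, C, Y}, polar {S, T, N, Q},
positive {K, R, H} and negative {D, E}. Grouping G, C and Y with the
hydrophobics and H with the positives matches the groupings implied by the
published per-mutation examples; because reasonable schemes differ (H is
often called polar), the mapping is a plain named vector that every
classification entry point accepts as an argument. The published
b(0+)AT table also contains one negative→negative substitution that no
listed D↔E mutation accounts for (a likely typographical slip in the
source table); fixtures encode the printed cell values rather than a
guessed mutation list.

## Numerical and degenerate-input choices

* Exact rank-test tail membership uses a 1e-9 slack when comparing
  distances from the null mean, guarding mid-rank floating-point noise.
* A rank test on two identical samples returns p = 1; a constant sample
  pair in the approximation (zero variance) also returns 1.
* Rank correlation of constant input is undefined: `NA` with a warning.
* `select_stable_threshold()` errors rather than guessing when no run
  reaches `min_run`.
* Table writes are atomic (write-to-temporary, then rename) and the run
  manifest is written last, so an output directory containing
  `manifest.json` always holds a complete, self-consistent run;
  re-running on the same inputs is byte-identical for all tables.

## Known limitations

* The pipeline starts from predictor *scores*; it never runs the
  predictors, ConSurf or stability predictors themselves.
* Everything is protein-level: no DNA coordinates, no VCF, no transcript
  mapping, no phasing inference — allele assignment is taken as given.
* The dominant/recessive aggregation rules are the scoring system under
  study, with the simplifications noted above.
* Only Bonferroni correction is provided, matching the analysis design
  the pipeline reproduces.
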