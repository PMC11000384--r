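---
title: "Models and methods behind mendelburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mendelburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelburden)
```

`mendelburden` quantifies the burden of Mendelian disease variation in a
biobank cohort with genetic substructure and consanguinity. This vignette
is the package's account of the statistics it implements, the conventions
it fixes where the field leaves room, and what its synthetic-data tests do
and do not demonstrate about real cohorts.

## The data model

A cohort is a subjects-by-variants genotype matrix (codes 0/1/2, `NA` for
missing calls) plus four tables: variant annotations, subject covariates,
quantitative traits and panel genes. Two loading conventions matter
downstream and are fixed at the door:

* **Multi-allelic sites** are decomposed into one biallelic entry per
  alternate allele. A genotype is recoded against each alternate
  separately, with other alternates counted as reference — so a `1/2` call
  becomes heterozygous in both decomposed entries. This makes `AC`/`AN`
  unambiguous.
* **Missing genotypes are excluded from allele numbers** (the gnomAD
  convention): `AN = 2 × n_called`, `AC = n_het + 2 × n_hom`. A variant
  absent from every external database is treated as frequency zero for
  rarity filters, and flagged as database-absent where that is itself
  informative (founder screen).

Coordinates are 1-based VCF positions, preserved as-is.

## The known-P/LP catalogue

Classification intersects two curated databases rather than re-deriving
evidence: a variant must be disease-causing in HGMD (`DM`/`DM?`) *and*
carry ClinVar support, with the current ClinVar status assigning one of
four categories (P/LP ≥ 2 stars; P/LP < 2 stars; conflicting/VUS;
benign-but-previously-P/LP). Review status is consumed as an integer star
count; `clinvar_star_table()` documents the mapping from status strings.
Burden summaries default to categories 1–2 — the variants currently
supported as P/LP — while categories 3–4 stay in the catalogue because
reclassified variants remain informative (several founder alleles are
category 3).

Gene-level counts are adjusted for gene length as **P/LP variants per kb of
coding sequence** (`n_plp / (coding_length_bp / 1000)`). Length adjustment
is required because long genes accumulate more variants by target size
alone; the per-kb rate is the simplest statistic with interpretable units.

## Carrier burden and enrichment

Per subject we count distinct P/LP variants carried (a homozygote counts
once), homozygous genotypes in recessive-condition genes and heterozygous
genotypes in dominant-condition genes; genes with inheritance "both"
contribute to both tallies. In subpopulation summaries the homozygote and
dominant-heterozygote percentages use the **carrier count as denominator**,
and fold enrichments compare those per-carrier rates against a reference
(admixed-like) group. This denominator choice is deliberate and recorded
prominently: it is the only reading under which the percentage, count and
fold columns of a published-style burden table are mutually consistent
(e.g. 25 homozygote carriers of 794 = 3.15%, against 4/739 = 0.54%,
giving a 5.8-fold enrichment). Rounding happens only at presentation;
internals keep full precision.

Homozygote enrichment between groups is tested with a two-sided Wilcoxon
rank-sum test on per-subject homozygote counts: exact when both groups have
≤ 12 observations and no ties, otherwise the normal approximation with tie
and continuity correction (count data are heavily tied, so the exact path
is essentially a small-sample safeguard). Both "one subpopulation vs
another" and "one vs rest" comparisons are exposed, since either may be the
scientifically relevant contrast.

## Gene carrier frequency

The per-variant carrier frequency is `(AC − Hom)/(0.5 × AN)` with `Hom`
the number of homozygous *individuals*; algebraically this equals
`(n_het + n_hom)/n_called`, the fraction of called subjects carrying at
least one allele — which is what "carrier frequency" means in screening
practice, and the reason the formula is parenthesised this way. The gene
carrier frequency (GCF) is the sum over the gene's P/LP variants, computed
per subpopulation in unrelated subjects (relatedness is consumed as an
input flag; kinship inference is out of scope). Screening tiers use strict
lower bounds (cat1 > 1/50, cat2 > 1/100, cat3 > 1/150, cat4 > 1/200) with
each upper endpoint belonging to the lower tier, so exactly 1/50 is cat2.
Sums can exceed 1 in pathological configurations (many common variants in
one gene); values are reported uncapped with a warning, because the
definition is a sum of frequencies, not a probability. Subpopulations below
a configurable size (default 100 unrelated subjects) are flagged
low-confidence: small denominators overestimate GCF.

## Population screens

* **Founder alleles**: subpopulation AF > 1% while the maximum global
  database AF is < 1%; database-absent variants are additionally flagged.
* **Exceedingly common P/LP**: maximum subpopulation AF ≥ 2%; above 5% the
  variant is flagged as a candidate for benign reclassification.
* **Homozygosity depletion**: for globally rare variants, expected
  homozygotes are `n_called × q²` with `q` the pooled-cohort frequency —
  deliberately a *random-mating* expectation even though the cohort is
  consanguineous, so that a deficit is conservative evidence of selection
  against the homozygous state. A per-subpopulation variant of the
  expectation is available behind a flag. A hit requires expected ≥ 3 and
  zero observed homozygotes; the zero-observed rule is strict (one
  homozygote disqualifies).
* **Knockouts**: rare loss-of-function variants (nonsense, frameshift,
  canonical splice-site as annotated upstream; global AF < 1%) counted per
  subject overall and within panel genes, plus every LoF variant with a
  homozygous carrier.

Under random mating the depletion screen's false-fire probability for a
variant with expectation λ is `P(0 hom) ≈ e^{-λ}` — about 5% at the λ = 3
boundary, decaying quickly; across a realistic spread of eligible variants
the aggregate rate sits well below 1%, which the test suite verifies on
F = 0 fixtures (5000 subjects × 2000 variants).

## Extreme-trait screens

Novel candidates (global AF < 1%, CADD > 20, GERP > 3, ≥ 3 cohort
homozygotes, no benign class, not already catalogued) are screened for
extreme trait values among their homozygotes. Percentile thresholds are
**nearest-rank order statistics** (quantile type 1) over all non-missing
cohort values — fixed and documented because flags near the boundary depend
on the interpolation rule. The default decision rule requires *all*
non-missing homozygotes in the same tail; a majority rule is available.
Traits are used raw (no inverse-normal transform) so percentiles refer to
the measured scale; the transform option exists only in the burden module.

The all-homozygotes rule is intentionally stringent, and its power is easy
to state in closed form: a recessive effect of δ residual SDs leaves a
homozygote beyond the cohort 5th percentile with probability
`Φ(δ − 1.645)`, so all five homozygotes of a −2 SD variant are
simultaneously extreme only `Φ(0.355)⁵ ≈ 0.11` of the time (the suite
confirms the simulation agrees with this arithmetic). The screen is
therefore a high-specificity filter for *large* effects — the validated
hits it is designed around shift biomarkers by several SDs — not a
high-sensitivity test for moderate ones; at −4 SD the all-five recovery
probability exceeds 0.95, and the majority rule trades specificity for
sensitivity in between.

## The rare-variant burden scan

QC is applied per call, then per variant. The heterozygote allele-balance
criterion is implemented as the retention band 0.2 < AB < 0.8 (a literal
"AB > 0.2 or AB < 0.8" would retain everything; the band is the only
sensible reading). Homozygous-alternate calls need AB > 0.8, all calls
GQ > 10; failing calls — and calls lacking AD/GQ, which fail closed — are
set missing. Variants then need post-filter call rate > 90%, an exact
Hardy–Weinberg p ≥ 1e−6, and cohort plus external AF < 1%. Singletons
(AC = 1) are dropped; doubletons (AC = 2) are kept only when every carrier
call has depth ≥ 10 — the reading under which depth rescues a doubleton;
the opposite literal reading (dropping exactly the well-supported
doubletons) is implausible but preserved behind a switch. "Doubleton"
counts alleles, not carrier pairs.

The Hardy–Weinberg test is the exact conditional test: given the sample
size and allele counts, heterozygote counts of the correct parity have
probability proportional to `n! 2^h / (n_AA! h! n_aa!)`, and the p-value
sums the probabilities not exceeding the observed count's. The
implementation works in log-space and the suite checks the distribution is
proper for every configuration up to 30 diploid subjects and matches a
random allele-pairing simulation.

Collapsing is the unweighted sum of genotype codes over a gene's qualifying
variants (missing contributes 0), with genotype-class counts aggregated as
`RR|RA|AA`. Association is **ordinary least squares** of the trait on the
burden plus age, sex and PC1–PC4 over complete cases, with a 1-df Wald
chi-square on the burden coefficient. This is a fixed-effects stand-in for
a mixed model: close relatives are assumed removed or flagged, and the PCs
absorb population structure at this scale. The trade-off is explicit —
betas are comparable, not identical, to what a kinship-aware model gives —
and the regression interface accepts any covariate data frame, so a
precomputed kinship projection can be added by the caller. No
multiple-testing correction is applied beyond the fixed 1e−8 genome-wide
threshold.

Power is again worth stating plainly: with `m` effective allele copies and
a per-allele effect of β residual SDs, the expected Wald z is `β√m`. Thirty
carriers at β = 1 give z ≈ 5.5 and reliable detection at stringent
thresholds (the suite recovers such a spike as the top hit); thirty
carriers at β = 0.5 give z ≈ 2.7, which is nominally significant but far
below genome-wide thresholds — detecting half-SD effects needs on the order
of 120 allele copies. The suite also verifies type-I error at α = 0.05
stays nominal over 1000 null gene–trait pairs.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analyses assume,
so that every stage is testable without access-controlled data:

* **Genotypes** follow the single-parameter inbreeding model
  `P(hom-alt) = q² + Fq(1−q)`, `P(het) = 2q(1−q)(1−F)`, independent across
  subjects and variants. One F per subpopulation reproduces the key
  observable (homozygote enrichment) without explicit pedigrees.
* **Defaults are the cohort composition the package targets**: six
  subpopulations in proportions 2311/1372/1180/1052/92/38 (scaled to the
  requested size), F averaging ≈ 0.018 — consistent with ~29% parental
  consanguinity at F = 0.0625 per first-cousin union — with the
  Peninsular-Arab-like group highest (0.035). These are illustrative
  choices, not estimates; subpopulation-level F is not published.
* **Allele frequencies**: rare panel variants draw base frequencies
  log-uniformly from 2×10⁻⁴–8×10⁻³, with per-subpopulation log-normal
  divergence multipliers (founder-style drift) and optional explicit
  founder spikes. Designated novel candidates draw from 1.5–5% (matching
  validated founder-inflated novel alleles at ~4.6% with several
  homozygotes), benign-common variants from 2–10%.
* **Annotations** honour the designations by construction: known-P/LP
  variants get ClinVar/HGMD intersection evidence (spanning all four
  categories) and global AFs capped below 1%; novel candidates get
  CADD > 20, GERP > 3 and no benign class; a slice of variants is absent
  from every database.
* **Traits** are `β_age(age−40) + β_sex·male + Σγ_k PC_k + spikes +
  N(0, σ²)` with effects in residual-SD units (β_age = 0.015/yr,
  β_sex = 0.4, γ = 0.3/0.2/0.1/0.1); recessive spikes add to
  homozygotes, additive spikes per allele copy. Trait missingness defaults
  to 2% at random.
* **Call noise**: depth Poisson(35); alternate reads binomial with success
  0.5/0.98/0.002 for het/hom-alt/hom-ref; GQ normal(60, 18) truncated to
  0–99; 0.5% of genotypes missing — enough to give every QC filter
  non-trivial work.

All randomness flows from one seed (`set.seed` at entry; identical config
and seed give bit-identical cohorts). What the generator does **not**
emulate: linkage disequilibrium and haplotype structure, explicit
pedigrees/IBD segments, runs of homozygosity, sequence context,
annotation errors correlated with sequence class, and trait correlations
between biomarkers. Passing tests therefore demonstrate correctness of the
statistics under the stated sampling laws, not robustness to every real
data pathology.

## Numerical conventions and degenerate inputs

* Tier and threshold comparisons are strict (`>`), with boundaries assigned
  to the lower tier; filters use strict inequalities matching their
  definitions (GQ > 10, call rate > 0.9, AF < 0.01).
* `AN = 0` (no called genotypes) is an error for carrier frequency; zero
  variance in a burden vector yields a null result row rather than an
  error; collinear covariates abort naming the offending columns.
* Constant traits produce equal percentile thresholds and no extreme flags.
* Empty selections propagate as empty tibbles with stable schemas; the
  pipeline completes with warnings on an empty catalogue and aborts, naming
  the stage, when a required input is absent.
* Fold enrichment against a reference group with zero homozygotes is
  undefined and reported as `NA` with a warning.

## Problem sizes in the test suite

The suite exercises the law-level checks at the sizes where their
tolerances are sharp — 50,000 draws for the inbreeding law (3 binomial SEs),
1000 variants × 2000 subjects for exact-HWE calibration, 1000 null
gene–trait pairs for scan type-I error, 5000 × 2000 for the depletion
screen — and the end-to-end pipeline at a few hundred subjects, which is
ample for contract checks. These sizes are the package's own choice of
where statistical claims become testable without being wasteful.

## Known limitations

Compound heterozygosity is not phased, so GCF aggregates carrier risk
without distinguishing cis/trans; the burden scan has no
variance-component (SKAT-style) alternative and no binary-trait path;
kinship is consumed, never estimated; consequence annotation is trusted
from the input table; and the homozygosity-depletion expectation ignores
the cohort's actual inbreeding, which makes it conservative in exactly the
cohorts the package targets.
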