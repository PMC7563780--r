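---
title: "Methods: panel TMB, genomic subtypes and ICI resistance prediction in melanoma cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel TMB, genomic subtypes and ICI resistance prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melcohort)
```

## The data model

`melcohort` analyses targeted-panel somatic sequencing cohorts at the gene
level. A cohort is four tables: clinical annotation (histopathological
subtype, ICI regimen, RECIST best response, BRAF/MEKi pretreatment flag),
somatic small variants (one row per SNV/INDEL with a driver and a hotspot
flag), gene-level copy number events (amplification/deletion with a driver
flag), and a panel definition (gene universe, target size in Mb, the
known-tumor-gene subset, genome size in Mb). Genomic coordinates are
deliberately not modelled: every analysis here operates on gene symbols
and alteration classes, so nothing downstream depends on assembly or
annotation versions. Driver status is an input — it originates from an
external annotation step — and is trusted, not recomputed.

The boolean patient-by-gene `alteration_matrix()` is the substrate for
counting, enrichment and prediction. A patient with both an SNV and a CNV
in the same gene counts once; synonymous variants can never qualify as
drivers; every clinical patient contributes a row even if alteration-free.

## Adjusted TMB

Panel TMB is usually the somatic coding variant count divided by the panel
target size. Cancer panels, however, are enriched for known tumor
suppressors and oncogenes, where somatic hits cluster; extrapolating those
hits at the per-panel-megabase rate inflates the estimate. The adjustment
splits the count: with $S$ somatic coding SNVs/INDELs, $K$ of them in the
known-tumor-gene subset, target size $T$ and genome size $G$ (Mb),

$$\mathrm{TMB} = \frac{S - K}{T} + \frac{K}{G}.$$

Variants outside the known tumor genes extrapolate as usual; variants
inside them are counted at the rate they would contribute to a
whole-genome TMB, i.e. essentially not extrapolated at all. Both addends
are reported (`panel_term`, `genome_term`) so the normalisation can be
audited or an alternative grouping swapped in one place. The
known-tumor-gene term counts *variants*, symmetrically with the first
term. Design choices: synonymous variants count toward $S$ (the measure is
"all somatic coding alterations", not driver load); CNVs never count; the
genome size defaults to 3101.79 Mb (the GRCh37 total) and is configurable;
TMB is rounded only at presentation, never in computation.

Useful consequences, all tested as properties: adding a non-tumor-gene
variant raises TMB by exactly $1/T$ and a tumor-gene variant by exactly
$1/G$; with an empty tumor-gene set the formula reduces to the naive
$S/T$; doubling $T$ halves the first addend exactly.

## Genomic subtype classification

Melanomas are classified BRAF, RAS (NRAS/HRAS/KRAS), NF1 or triple
wild-type (TWT) from driver small variants only — amplification of a
RAS-pathway gene does not change the class. Co-mutated tumors exist (e.g.
simultaneous BRAF V600E and NRAS Q61 hotspots), so a deterministic
precedence BRAF > RAS > NF1 is applied, following the established
TCGA-style convention; it is also the unique tie-break under which the
reference cohort's published class counts (23 + 21 + 2 + 36 = 82)
reconcile with its per-gene carrier counts and overlaps. The NF1 class
accepts any driver NF1 variant class, since loss of function is not
verifiable from the symbol alone. Every patient receives exactly one
label; TWT if and only if the evidence list is empty.

## Enrichment and burden comparisons

For each (gene, subtype) pair the 2×2 table altered/unaltered ×
in-subtype/rest is tested with Fisher's exact test. Sidedness was a
genuinely open choice: the one-sided enrichment tail matches how
oncoplot-style subtype reports are conventionally read (and is what makes
the uveal MYC table (8, 0, 12, 62) give $p = 3.5\times10^{-6}$), so the
`significant` flag follows the raw one-sided p at `alpha = 0.05`; the
two-sided p and a Benjamini–Hochberg column are emitted alongside but do
not drive the flag, because this style of report conventionally flags raw
p < 0.05. Genes altered in nobody (or everybody) yield p = 1 and are never
flagged.

Burden metrics (adjusted TMB, SNV count, CNV count) are compared between
each subtype and the cutaneous reference with two-sided Mann–Whitney U
tests. When both groups have at most 12 patients the p-value comes from
exact enumeration of the rank-sum permutation distribution, implemented as
a dynamic program over doubled midranks so it remains exact under ties
(the classical exact tables do not cover ties); larger comparisons use the
normal approximation with tie correction and no continuity correction.
The exact two-sided p is defined as $\min(1, 2\min(P(W \le w), P(W \ge
w)))$, which gives 0.1 for complete separation of two triples and 1 for
identical samples. Both exact tests are verified in the suite against
brute-force enumeration (all margin-fixed tables; all
$\binom{n}{n_1}$ labelings) for sizes up to 30.

## The resistance predictor

A `resistance_rule(gene_set, combination_k, require_pretreatment)` fires
for a patient when at least `combination_k` distinct genes of the set
carry a driver alteration (SNV or CNV — the relevant resistance lesions
span PTEN deletions, EGFR amplifications and TP53 point mutations), OR
when the pretreatment clause is enabled and the patient received BRAF/MEK
inhibition before ICI. `evaluate_rule()` restricts to ICI-treated patients
and scores against RECIST progressive disease versus disease control
(SD+PR): sensitivity $a/(a+c)$, specificity $d/(b+d)$, PPV, NPV, relative
risk $[a/(a+b)]/[c/(c+d)]$ and Fisher's exact p (two-sided reported first,
one-sided alongside; sidedness of the original analysis is not
documented). The relative risk is explicitly flagged undefined — never a
silent NaN — when a rule stratum is empty or no rule-negative patient
progressed.

The four shipped rule variants (`default_rules()`) are: the EGFR/PTEN/TP53
union; the union OR pretreatment; the union extended by CDKN2A (with
pretreatment); and "any combination" of the four genes. The last is
implemented as `combination_k = 2` — at least two distinct altered genes —
which is the reading under which all nine rule-positive patients progress
and the relative risk works out to 1.83; plain union semantics remain
available via `combination_k = 1`. Percentages are presented
round-half-up to 1 decimal and relative risks to 2 decimals; internal
computation is never rounded.

## The reference cohort

`make_paper_fixture()` builds a deterministic 82-patient cohort whose
published summary counts are pinned exactly: subtypes 42 cutaneous / 14
acral / 9 mucosal / 8 uveal / 9 occult; 75 ICI-treated splitting PD 45 /
SD 12 / PR 18; driver small-variant carriers BRAF 23 (21 of them V600
hotspots), NRAS 20, HRAS 1, KRAS 2, NF1 5, with 2 BRAF∩NRAS double-hotspot
patients and 3 NF1 patients carrying a BRAF/NRAS hotspot; MYC
amplification in all 8 uveal patients plus 12 others (20/82 = 24%);
mutually exclusive GNAQ/GNA11 drivers with SF3B1/BAP1 in uveal; and every
predictor contingency count: EGFR 6/0, TP53 6/1, PTEN 11/3 (PD vs SD+PR),
union 19/4, union+pretreatment 28/6, +CDKN2A 33/10, two-gene combination
9/0, and the BRAF-mutated pretreatment split 16/18 in PD and 2/4 in SD+PR.

Most of the assignment is forced by overlap arithmetic: among PD patients
the union and pretreatment clauses must overlap in exactly 19 + 16 − 28 =
7 patients (0 = 4 + 2 − 6 among SD+PR); the 23 single-gene memberships
across 19 union-positive PD patients force exactly 4 two-gene patients;
and the 9 combination-positive PD patients force exactly 5 CDKN2A
co-alterations among single-gene union patients. Where several assignments
remained admissible (which single-gene patients carry the CDKN2A
co-deletion; the identity of plain-PD patients) one was chosen and is now
pinned: the assignment is committed as constructor code, a change in any
count is a breaking change, and an internal checker re-verifies every
constraint on each build. Deterministic passenger variants and CNVs (fixed
per-subtype loads cycling through non-tumor panel genes) give the fixture
realistic nonzero burdens without randomness.

Two published figures are internally inconsistent with their own counts
and are resolved in favour of the counts: a quoted 84.4% PD rate where
28/34 = 82.4%, and a PTEN PD frequency of 24.5% where 11/45 = 24.4%. The
reduced rule's rule-positive disease-control count is not printed anywhere;
4 is the unique integer consistent with its relative risk of 1.65.

## The simulator

`simulate_cohort()` draws cohorts with the statistical structure the
analyses assume, for parameter-recovery testing: subtype proportions
(42/14/9/8/9 over 82 by default); per-subtype driver alteration
frequencies mirroring the reference cohort's oncoplot (GNAQ/GNA11 drawn
mutually exclusively within uveal); BRAF/MEKi pretreatment with
probability 18/23 given a BRAF driver; ICI with probability 75/82; and
RECIST response drawn conditionally on the union+pretreatment rule status
with P(PD | positive) = 28/34 and P(PD | negative) = 17/41, non-PD
responses splitting SD:PR as 12:18.

Burden families are package choices, since only medians, IQRs and ranges
are published: TMB is log-normal parameterised by its per-subtype median
(9.4 / 1.5 / 3.2 / 2.8 / 7.5 mut/Mb) with `sdlog = 0.65`, the value
implied by the cutaneous IQR 6–14.6; CNV counts are negative binomial
(dispersion `size = 2.5`, a realistic overdispersion for per-sample CNV
counts) with the mean matched numerically so the distribution median hits
the configured 8 / 12.5 / 33 / 8 / 16. Passenger variants are added per
patient so that the *computed* adjusted TMB equals the drawn target up to
integer rounding of the variant count (at a 1.3 Mb panel the rounding
error is below 0.4 mut/Mb and symmetric). The seed is mandatory and the
output is byte-identical for identical seeds.

What the simulator does not emulate — per-base reads, allele frequencies,
FFPE artifacts, within-gene mutation multiplicity, correlated alteration
structure beyond GNAQ/GNA11 exclusivity, and survival follow-up — bounds
what passing recovery tests show: they demonstrate that the analysis
stages are unbiased estimators of the generating parameters under this
structure, not that the pipeline is robust to real-data artifacts.

## Numerical choices and problem sizes

Exact Mann–Whitney enumeration is used up to 12 patients per group
(covering every subtype-vs-cutaneous comparison except the reference group
itself, which always exceeds it and uses the tie-corrected normal
approximation — the published comparisons were run in standard statistics
software, which does the same at these sizes). Fisher p-values use the
standard convention that the two-sided p sums all tables with probability
at most that of the observed table (within a $1+10^{-7}$ relative
tolerance). The test suite verifies exact-test equivalence on tables and
labelings up to n = 30, simulator recovery on cohorts of 4,000 (unit) and
10,000 (acceptance) patients within three binomial standard errors, and
the mucosal-vs-cutaneous CNV excess on 40 simulated 82-patient replicates;
these sizes keep the full suite around ten seconds on one core while
leaving Monte Carlo margins comfortably wide.

## Limitations

Gene-level modelling cannot distinguish multiple distinct variants of a
gene in one patient in presence/absence analyses; driver annotation is
trusted as given; the predictor is evaluated on the cohort it was defined
on (no cross-validation — an independent cohort would be needed for an
honest estimate of its precision and recall); and survival endpoints are
out of scope.
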