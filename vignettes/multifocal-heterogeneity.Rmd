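---
title: "Methods: quantifying genomic heterogeneity between multifocal breast cancer lesions"
author: "mfhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying genomic heterogeneity between multifocal breast cancer lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfhet)
```

## The scientific question

Multifocal breast cancer (MFBC) presents as two or more synchronous invasive
lesions in the same breast, separated by benign tissue. Even when those
lesions look identical under the microscope — same histological grade, same
ER and HER2 status — they need not be genetically identical. `mfhet`
implements a pipeline for deciding, patient by patient, whether the lesions
share their somatic mutations (and hence a clonal origin) or carry disjoint,
privately acquired driver events, together with the orthogonal-platform
validation logic, the oncogenicity annotation, and the genome-wide
(copy-number and rearrangement) comparisons that support that decision.

The pipeline consumes per-sample somatic variant tables from two sequencing
platforms (a discovery capture screen at moderate depth and a deep targeted
validation assay), a sample-to-lesion-to-patient hierarchy with
clinico-pathological covariates, a COSMIC-like recurrence snapshot and a
gene-role table, and optionally per-lesion segmented absolute copy-number
profiles and rearrangement breakpoint lists. Alignment, primary variant
calling, segmentation and purity estimation are out of scope: the package
starts from calls and segments.

## Cross-platform confirmation

Every mutation identified in at least one sample of a patient is
re-interrogated in *all* samples of that patient on the validation platform.
The decision rule, applied per (variant, sample) pair:

* validation allele fraction (AF) at least 5% (inclusive): accepted;
* AF at least 1% but below 5%: accepted only when another sample of the same
  patient carries the same variant at 5% or more (the *rescue rule*; the
  supporting sample is recorded, and a sample can never support itself);
* otherwise: not detected;
* a failed or missing assay makes no claim (`ASSAY_FAILED`).

Accepted calls that the discovery platform also called are `CONFIRMED`;
accepted calls the discovery platform missed are `PRESENT` — the deep assay
routinely recovers mutations in samples where the discovery screen saw
nothing. AFs are compared as real numbers, without rounding, and both
boundaries are inclusive.

Concordance between the platforms is summarised by Spearman's rho over
paired AFs and by an ROC analysis. The ROC construction is a design choice
the protocol leaves open; we fix the positive label as validation status
`CONFIRMED`/`PRESENT` versus `NOT_DETECTED` (assay failures excluded) and
the score as the discovery AF, zero when the discovery platform made no
call. The AUC confidence interval is DeLong's asymptotic interval. A flag
(`confirmed_only`) restricts the correlation to accepted pairs, since the
protocol does not state which set the published correlation used.

## Rule-based oncogenicity

Each unique non-silent variant — variant identity is the left-normalised
genomic key (chrom, pos, ref, alt); the protein change is annotation only —
is assigned one of four tiers by a fixed cascade. Tiers are evaluated in
order; the first tier that fires wins, and within a tier the lowest-numbered
rule is recorded.

* **Oncogenic** — R1: non-synonymous substitutions or in-frame indels in a
  canonical oncogene at a recurrent hotspot; R2: non-synonymous
  substitutions with two or more confirmed catalogue samples; R3: variants
  recurrent in two or more *patients* of the analysed cohort; R4: nonsense
  or frameshifting indels in a known tumour suppressor.
* **Putative oncogenic** — R5: previously unreported non-synonymous
  substitutions in a known cancer gene within ±3 amino acids of a
  catalogue-recurrent mutation; R6: membership in a cohort mutation cluster.
* **Possible oncogenic** — R7: substitutions confirmed somatic in exactly
  one catalogue sample; R8: proximity to a catalogue mutation cluster.
* **Unknown significance** — everything else.

Downstream, the three oncogenic tiers are collapsed into a single binary
"oncogenic" flag.

Design choices where the written protocol is open, fixed here and testable:

* "Recurrent hotspot" (R1) is operationalised as an exact protein change
  with at least two confirmed catalogue samples in an oncogene; the protocol
  does not define hotspots separately from catalogue recurrence.
* R3 counts distinct *patients*, not samples, so multi-sample patients do
  not self-inflate.
* R6 requires at least three distinct substituted residues of one gene
  within a window of span ≤ 3 residues, pooling substitutions across the
  cohort; distinct residues (not distinct genomic variants) are counted.
* R5 applies to any gene with a role other than `not_cancer_gene` (the
  protocol says "a known cancer gene" without restricting to oncogenes).
* R8 needs a cluster annotation column (`in_cluster`) in the recurrence
  table; the catalogue we abstract over gives no cluster definition, so
  without that column R8 is inert.
* An unparseable protein change disables the residue-position rules for that
  variant (with a warning) but not the truncation rule R4, which needs only
  the variant class.

## Heterogeneity grouping

For each patient a presence matrix is built: rows are validated variants
(at least one accepted call), columns are the patient's assayed samples
grouped by lesion; cells are present, absent, or non-informative. Patients
are grouped as:

* `HOMOGENEOUS` — every variant present in every sample of every lesion;
* `HETEROGENEOUS` — no variant is *lesion-common* (present in at least one
  sample of every lesion);
* `INTERMEDIATE` — otherwise (both common and private mutations).

Two readings of "homogeneous" are defensible because multi-sample lesions
can carry a mutation in some samples only: the strict reading above
(default) and a lesion-level reading where lesion-commonness of every
variant suffices. The `strict_homogeneous` flag switches between them; under
the strict default, a patient whose every variant is lesion-common but not
sample-complete is `INTERMEDIATE`.

Assay-failed cells are handled asymmetrically, which matters for recovery
accuracy under realistic failure patterns:

* For *commonness*, a failed cell falls back to the discovery screen:
  present where the discovery platform called the mutation, absent where the
  sample was discovery-sequenced but reported no call (the discovery screen
  is perfectly specific for absence in this setting, though it misses some
  true carriers), non-informative only for samples that entered at the
  validation phase.
* The *strict* sample-completeness criterion counts validated cells only;
  fallback evidence cannot veto homogeneity, because discovery misses would
  otherwise masquerade as private mutations.
* A lesion with no informative cell for a variant does not block that
  variant's commonness (an uninvestigated lesion is not evidence of
  absence).

Patients with zero accepted variants cannot be grouped and are excluded with
a warning.

Two comparisons accompany the grouping. First, in intermediate patients —
the only group with both sets — the per-patient median AF of private
variants is paired with that of common variants and tested by Wilcoxon's
signed-rank test; pooled medians are reported alongside. Private mutations
sit at lower AF when they are subclonal. Second, covariates are tested
against the grouping: continuous covariates by Kruskal–Wallis across the
three groups and by rank-sum tests for the homogeneous-versus-heterogeneous
and shared-versus-private-oncogenic contrasts (patients with no oncogenic
variant are excluded from the latter, mirroring the study design);
categorical covariates by Fisher's exact test. Because the published
analysis does not state whether the inter-lesion-distance association came
from the three-group or the two-group comparison, both are emitted. Raw
two-tailed p-values are reported with no multiplicity correction (as in the
protocol); a Benjamini–Hochberg column is available behind a flag.

## Copy-number and rearrangement comparison

Rearrangements (breakpoint pairs with orientations) match across lesions
when class, chromosome pair and strands agree and both breakpoints lie
within a tolerance (default 500 bp — the protocol validated breakpoints by
capillary sequencing but states no tolerance, so this is an explicit,
configurable stand-in). Within each lesion pair a deterministic greedy
one-to-one matching is used (sorted by summed breakpoint distance, ties by
genomic order); matches are clustered across lesions and a cluster present
in every lesion is *common*. Clustering makes the result invariant to
lesion order.

Copy-number profiles arrive segmented with absolute total copy numbers. An
aberration is a maximal run of segments departing from the lesion's baseline
— the rounded ploidy, so a tetraploid lesion is not called whole-genome
gained — in one direction; collapsing to direction runs makes the comparison
invariant to re-segmentation. An aberration is common when every other
lesion has an overlapping same-direction aberration with reciprocal overlap
at least 0.5 (configurable). A focal-region table adds per-gene gain / loss /
neutral calls per lesion.

The inter-lesion distance is a minimum-event metric: the smallest number of
events transforming one profile into the other, where an event adds +1 or −1
to one contiguous run of segments on one chromosome. Segments at copy
number 0 are fixed — they can never regain copies nor participate in any
event, so they split runs, and a target requiring a zero segment to gain is
unreachable (reported as `NA` with a warning). On the union breakpoint grid
the distance is computed per chromosome by a linear scan over the positive
and negative parts of the difference profile, with zero segments as
barriers, and summed; the test suite proves it equal to breadth-first search
over the event graph on thousands of random instances.

## Statistical machinery

All tests return a uniform record (statistic, two-tailed p, n, method).
Exact small-sample branches are used where the cohort sizes here live:
Spearman's p is exact for n ≤ 9 without ties (the exact-distribution
algorithm is available only below n = 10; above that a t-approximation is
used), Wilcoxon tests are exact up to n = 25 without ties (normal
approximation with continuity correction beyond), Fisher's test is always
exact, Kruskal–Wallis uses the chi-squared approximation with tie
correction. Zero differences are dropped for the signed-rank test
(Wilcoxon's original treatment). The suite checks the exact branches
against full enumeration (all 8! rank permutations; all 2^n sign patterns;
the hypergeometric closed form) and the size of every test against
[0.03, 0.07] at nominal 0.05 over 1000 null replicates. For the Fisher
size check the null uses two binomial samples of 50: with smaller counts
the test's discreteness makes it markedly conservative, which would test
the discreteness, not the implementation.

## The synthetic cohort generator

There is no public per-sample mutation table for the study cohort (the
sequencing data are controlled-access), so the package ships a generator
that emulates the cohort's statistical structure with recorded ground truth
for every stage. Defaults are the study conditions:

* 36 patients; 2 lesions with probability 22/36, else 3 (10/36) or 4 (4/36)
  — the published table only splits 2 versus more-than-2; the 3/4 split is
  our choice, fixed once; 1–3 samples per lesion.
* Group proportions 11:13:12, allocated by largest-remainder rounding and
  shuffled, so the planted composition matches the proportions exactly at
  any cohort size (the study cohort is a fixed design, not a multinomial
  draw).
* Mutations per patient: 1 + Geometric(0.25), capped at 27 (median 3,
  range 1–27). Homogeneous patients carry only truncal mutations (cancer
  cell fraction 1 in every sample); intermediate patients add private
  subclones at CCF 0.5 in a proper subset of lesions; heterogeneous patients
  carry disjoint per-lesion mutation sets at CCF 1, with distinct planted
  driver mutations per lesion (emulating convergent evolution, e.g.
  different TP53 hotspots in different lesions).
* Observed AF for variant v in sample s has expectation
  purity_s × CCF_{v,s} / 2 (diploid heterozygous model; copy-number-aware
  AF is out of scope). Purity is uniform on 0.4–0.9 (the study required
  >40% cellularity). Reads are Poisson-depth samples at 178× (discovery)
  and 1344× (validation) with beta-binomial noise, overdispersion 0.01, to
  mimic FFPE dispersion; binomial and noise-free modes exist.
* Each mutation is a catalogue driver with probability 0.44 (the observed
  oncogenic fraction of unique validated mutations); the built-in catalogue
  carries 61 entries with known planted rules (oncogene hotspots,
  catalogue-recurrent substitutions, truncating tumour-suppressor events,
  near-hotspot novelties, single-sample entries), plus an optional planted
  dataset-recurrent substitution and a three-residue cohort cluster. When
  sampling puts the same driver into two or more patients, the recorded
  truth rule is adjusted to the dataset-recurrence rule where that outranks
  the planted one — exactly what the cascade semantics imply. Because
  drivers recur across patients while passengers are unique, the
  cohort-level fraction of *unique* variants that are oncogenic falls
  somewhat below the per-mutation rate, and shrinks further in very large
  cohorts as the catalogue saturates.
* Validation assays fail through the study's two channels: variant-level
  design failures (19/474 of patient-variants) and sample-level DNA
  exhaustion (4/171 of samples), together about 7% of pairs. The discovery
  caller reports a variant in a sample only with at least 3 supporting reads
  and an observed AF of 5% or more, so subclonal variants are missed at the
  detection limit — the main source of validation-only `PRESENT` calls — and
  an additional 2% of present pairs drop out to FFPE/library artifacts.
  Every variant is guaranteed discovered in at least one sample, since
  otherwise it would never have entered the validation assay.
* The group-defining mutation slots (first truncal, first private) are
  never silent: silent variants are excluded from grouping, so a planted
  intermediate patient whose only private variant were silent would be
  observationally homogeneous and its label unrecoverable by any correct
  pipeline.
* Inter-lesion distances are Normal with group means 1.5 / 2.5 / 4 cm
  (sd 1, truncated at 0.2) — heterogeneous lesions lie further apart —
  missing with probability 10/36; other covariates follow the published
  marginal distributions.
* Eight patients (2 homogeneous, 3 intermediate, 3 heterogeneous, as in the
  frozen-tissue subset) receive genome-wide data: non-overlapping planted
  copy-number events and rearrangements, common or lesion-private, with more
  private events in heterogeneous patients; common rearrangements are
  jittered by ±100 bp across lesions.

What the generator does **not** emulate — and hence what passing recovery
tests do and do not show: no sequence-level reads, no alignment or calling
artefacts, no copy-number-driven AF distortion, no discovery-platform false
positives, no spatial correlation between samples of a lesion, no germline
contamination. Recovery results on this generator validate the *logic* of
the pipeline under the study's sampling design; they do not certify caller
performance on real FFPE data.

A scoring helper compares every pipeline stage with the planted truth:
confirmation sensitivity and specificity, oncogenicity category and rule
accuracy, the patient-group confusion matrix, and common/private accuracy
for rearrangements and copy-number events.

## Numerical and reproducibility choices

* Thresholds (5%, 1%, ±3 aa, recurrence ≥ 2, cluster ≥ 3, α = 0.05) live in
  a single validated configuration object that round-trips through YAML.
* All generator randomness flows from one integer seed through R's default
  generator in a single sequential path; equal seed and configuration give
  byte-identical output files.
* Variant identity uses left-normalised alleles (shared suffix trimmed, then
  shared prefix, position adjusted) so the same indel reported with
  different padding by the two platforms compares equal; the protocol does
  not state how indel notations were reconciled, so normalisation by
  genomic key is our documented resolution.
* Greedy rearrangement matching breaks ties deterministically by genomic
  order; reported tables are sorted; reports are byte-reproducible.

## Problem sizes used by the checks

The shipped checks run the full pipeline on generated cohorts of 36 patients
(the study scale) and 200 patients (for stable recovery-rate estimates),
enumerate all presence matrices up to 3 variants × 2 lesions × 2
samples/lesion against a set-logic oracle, compare the event distance with
breadth-first search on 1000 random profiles of up to 6 segments with copies
0–4, and calibrate each statistical test on 1000 null replicates. These
sizes give stable answers while keeping a full run in the minutes range.

## Known limitations

* The heterogeneity grouping is descriptive set logic, as in the study; no
  clonal-fraction deconvolution or phylogenetic inference is performed, so
  a private mutation at low AF and one lost by copy-number deletion are not
  distinguished.
* R8 (catalogue cluster proximity) is inert without a cluster annotation,
  since no catalogue cluster definition is available.
* The minimum-event distance is computed on total copy number; allele-
  specific events are out of scope.
* With few lesions and samples, "no mutation in common" cannot exclude
  deeper clonal relatedness — the genome-wide comparison exists precisely
  because targeted panels underestimate shared ancestry.

## A worked run

```{r example, eval = FALSE}
cohort <- generate_cohort(generator_config(seed = 1))
fit <- mfhet(cohort$discovery, cohort$validation, cohort$hierarchy,
             cohort$recurrence, cohort$roles,
             rearrangements = cohort$rearrangements,
             cn_profiles = cohort$cn_profiles)
print(fit)
plot(fit, patient_id = fit$heterogeneity$patients$patient_id[1])
truth_vs_pipeline_report(cohort, fit$confirmation, fit$oncogenicity,
                         fit$heterogeneity, fit$cn)
```
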