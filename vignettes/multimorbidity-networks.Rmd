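---
title: "Multimorbidity networks from inpatient ICD-10 records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity networks from inpatient ICD-10 records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

## The problem

Multimorbidity — two or more diseases in the same person — is usually
studied one disease pair at a time. A network view treats each 3-character
ICD-10 disease category as a node and each statistically supported
co-occurrence ("comorbidity pattern") as an edge, so that the structure of
disease co-occurrence in a whole inpatient population can be summarized,
compared between populations, and mined for *hub diseases*: the few
conditions involved in a disproportionate share of all comorbidity.

`comorbnet` implements this pipeline end to end for baseline inpatient
records: cohort filtering, exhaustive pairwise odds-ratio screening with
Bonferroni control and a prevalence floor, network construction with seven
node centralities (including maximal clique centrality), hub identification
and coverage statistics, and two-population comparison reports. Because the
hospital registries this kind of analysis is run on are access-restricted,
the package ships a synthetic-cohort generator with *planted* pairwise odds
ratios, so every stage can be validated by parameter recovery.

## Cohort definition

The unit of analysis is the **baseline record**: each patient's earliest
admission. When a patient has several admissions on that earliest date,
their code sets are merged into one record; we treat the baseline as a
snapshot of diagnoses, and merging makes the result independent of input
row order. (Registries rarely document how same-day admissions should be
resolved; this is the package's choice, and it is flagged in the cohort
report.) All diagnosis positions are treated equally — no primary/secondary
distinction.

Raw codes are normalized to 3-character ICD-10 categories (uppercase, dots
and subcategory digits removed): `"e78.5"` becomes `E78`. Chapters are
assigned from the standard WHO ranges (chapter 1 `A00–B99` through chapter
22 `U00–U99`); codes in classification gaps (e.g. `D49`) map to no chapter
and are dropped by the filters. The analysis scope is chapters 1–14:
pregnancy, perinatal, congenital, symptom/sign, injury, external-cause and
contact codes (chapters 15–22) are removed from every record, records left
with no in-scope code are excluded, and ages are restricted to the
inclusive middle-age window [40, 59].

## Pattern screening

Every unordered pair of diseases co-occurring in at least one record is a
candidate edge. For each pair the patient-level 2×2 table is
(`n11` both, `n10`/`n01` exactly one, `n00` neither); patients with no
disease at all count in `n00`. The association measure is the odds ratio
from an unadjusted logistic regression of one indicator on the other. With
a single binary covariate the exponentiated slope *equals* the contingency
cross-product ratio `(n11·n00)/(n10·n01)`, so the package computes the
closed form — exact and fast across tens of thousands of patterns — and the
test suite keeps an actual `glm()` fit as an independent oracle. The
p-value is the two-sided Wald test of the log odds ratio with
`SE = sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00)`.

If any cell is zero the Haldane–Anscombe correction (+0.5 to all four
cells) keeps the estimate finite; such patterns carry a `zero_cell` flag so
the sensitivity of downstream results to this choice can be audited.

An edge enters the network iff (all inequalities strict):

1. odds ratio > 1;
2. p-value < `alpha / N`, where `N` is the number of patterns with OR > 1
   in the same cohort or stratum (Bonferroni over the positively associated
   family, recomputed per stratum, never shared);
3. pattern prevalence (`n11 / n_inpatients`) > 1/10,000, with the
   denominator taken from the cohort or stratum being screened.

Under global independence, criterion 2 bounds the family-wise probability
of any selected edge near `alpha`: each of the ~`2N` candidate patterns is
selected with probability about `alpha/(2N)` (the OR > 1 requirement keeps
one tail). The test suite measures this on fully null synthetic cohorts.

## Network metrics

The selected patterns form a simple undirected graph; odds ratios and
frequencies are edge *annotations*, not weights — all metrics below are
computed on the unweighted graph. Seven per-node metrics are reported:

- **degree** — incident edge count;
- **MCC (maximal clique centrality)** — the sum over maximal cliques `C`
  (size ≥ 2) containing the node of `(|C|−1)!`. Cliques come from igraph's
  pivoting Bron–Kerbosch enumeration; factorials stay exact in double
  precision because clique sizes in these networks are far below 18.
  When a node's neighborhood has no internal edges every maximal clique
  through it is a single edge and MCC equals degree; by the same rule an
  isolated node has MCC 0 (we resolve the boundary case toward the
  degree-consistent convention rather than counting the singleton clique).
- **closeness** — per connected component, with the Wasserman–Faust
  scaling `(nc−1)/Σd × (nc−1)/(n−1)` so values from different components
  are comparable; isolated nodes get 0.
- **local clustering coefficient** — share of realized edges among
  neighbors; 0 when degree < 2.
- **betweenness** — unnormalized, on the full graph (pairs in different
  components contribute nothing).
- **PageRank** — damping 0.85, uniform personalization (igraph's exact
  PRPACK solver; the stated 1e-9 tolerance is conservative).
- **eigencentrality** — principal adjacency eigenvector of the largest
  component (ties between equal-sized components broken toward the one
  containing the lexicographically smallest code), 0 elsewhere,
  max-normalized.

These disconnected-graph conventions match common network-tool defaults;
they are documented here because published analyses rarely state them, and
alternative conventions would change closeness and eigencentrality values
(not orderings within the main component).

## Hub diseases and coverage

Hubs are the top `k = 10` nodes by degree; ties are broken by higher
disease prevalence, residual ties lexicographically so runs are
reproducible. The *hub-associated network* keeps every edge incident to at
least one hub plus the endpoints. Three coverage statistics situate the
hubs: the shares of the complete network's edges, of its total pattern
frequency, and of its nodes captured by the hub-associated network. All
three are plain ratios recomputable from the exported edge tables — the
test suite does exactly that recount.

## The synthetic-cohort generator

The generator defines the package's study conditions. Given marginal
prevalences and a set of *vertex-disjoint* planted pairs with target odds
ratios ψ, the joint probability of each planted pair is the admissible root
of the Plackett quadratic
`(ψ−1)p11² − S·p11 + ψ·p_i·p_j = 0`, `S = 1 + (p_i+p_j)(ψ−1)`,
which always lies within the Fréchet bounds; every non-planted disease is
sampled independently. Vertex-disjointness is what makes the joint law
exactly specified without a full multivariate dependence model — each
patient's record is a product of independent bivariate-Bernoulli and
Bernoulli draws. Ages are uniform integers over [40, 59] and sex is a
Bernoulli split (defaults 50/50); empirical age/sex profiles of real
registries are irrelevant to method validation. The random stream order is
fixed (sex, age, planted pairs in config order, remaining diseases in
catalog order), so a cohort is a pure function of its config and seed, and
generation leaves the caller's RNG state untouched.

Patients for whom no disease is sampled are **kept** in the cohort: the 2×2
screening tables need them in `n00`, and dropping them would bias every
recovered odds ratio. (The record-reading path, by contrast, excludes
zero-code records, as the inclusion flow for real data requires — the two
paths deliberately differ here.)

An optional latent-factor mode (one shared Gaussian factor thresholded per
disease) produces diffuse positive dependence among *all* pairs for
realism; its pairwise odds ratios are not specified exactly, so it is
excluded from exact recovery checks.

What the generator does *not* emulate: real registries' long-tailed
disease-frequency profiles, within-chapter correlation structure, age- and
sex-dependent prevalences, and repeated admissions. Passing recovery tests
therefore demonstrates that the screening recovers planted pairwise
structure at realistic sample sizes — not that any particular published
network is correct.

## Validation design and problem sizes

Three layers, all run by the test suite and the acceptance script:

1. **Printed-count arithmetic.** Every percentage and ratio the pipeline
   reports (multimorbidity share, hub coverage, complexity ratio) is pure
   arithmetic on counts; tests feed published two-population inpatient
   counts through the same operations and compare at 2-decimal precision.
2. **Oracle equivalence.** The closed-form OR/Wald test against an
   independently converged logistic fit on random all-positive tables;
   clique enumeration and MCC against exhaustive subset search on random
   graphs of up to 12 nodes; MCC = degree on random bipartite (hence
   triangle-free) graphs; PageRank and betweenness against hand-written
   power-iteration and path-enumeration oracles.
3. **Parameter recovery and error control.** With n = 20,000 patients, 20
   diseases at 5% prevalence and one pair planted at ψ = 5, the full
   screen-and-select chain recovers the planted edge (and nothing else) in
   well over 90% of 50 seeds; on fully null cohorts (20 diseases at 10%,
   n = 10,000) the family-wise probability of selecting any edge stays at
   the nominal Bonferroni level over 200 seeds. These sizes keep the whole
   suite at a couple of minutes while leaving the binomial noise on each
   estimate well inside the asserted bounds.

## Worked example

```{r example}
dis <- c(I10 = 0.25, E78 = 0.15, E11 = 0.10, K29 = 0.12,
         I63 = 0.08, N39 = 0.05, J45 = 0.03, M54 = 0.06)
pairs <- data.frame(code_i = c("I10", "E78"),
                    code_j = c("I63", "E11"),
                    psi = c(6, 5))
gen <- generateCohort(syntheticCohortConfig(10000, dis, pairs, seed = 7))
gen$truth

pat <- screenPatterns(gen$cohort)
subset(pat, selected,
       select = c(code_i, code_j, n11, odds_ratio, p_value))

rep <- hubPipeline(gen$cohort, k = 3)
rep$hubs
round(rep$coverage, 2)
```

The planted I10–I63 and E78–E11 pairs are selected with odds-ratio
estimates near 6 and 5; with only two edges the hub list is led by the
higher-degree/higher-prevalence endpoints and the hub-associated network
covers 100% of patterns.

## Known limitations

- Associations are unadjusted marginal odds ratios: no age/sex covariates,
  no regularization, no FDR alternative — by design, to mirror the
  screening rule the pipeline implements. Confounding by demography is
  therefore *in* the estimates.
- Undirected, baseline-only: no temporal ordering of disease onset.
- Bonferroni over the OR > 1 family is conservative when many true
  positive associations exist (N inflates, the threshold tightens).
- The prevalence floor makes selection denominator-dependent: the same
  pair can pass in a large stratum and fail in a small one.
- MCC grows factorially with clique size; on graphs far denser than
  disease networks (cliques above ~18 nodes) the exact-integer contract of
  double precision would break.
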