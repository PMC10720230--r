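# comorbnet

Multimorbidity network analysis of baseline inpatient ICD-10 records.

Hospital registries record, for each patient, a set of diagnoses coded in
ICD-10. `comorbnet` turns such records into **multimorbidity networks** —
undirected graphs whose nodes are 3-character disease categories and whose
edges are statistically supported comorbidity patterns — and computes the
population-level statistics used to compare disease profiles across
populations: multimorbidity proportions, per-capita diagnoses by age and
chapter, node centralities, hub diseases, hub coverage, and network
complexity ratios. It is aimed at epidemiologists working with inpatient
registries or biobank hospital-episode data.

## Method

For every unordered pair of diseases *(i, j)* co-occurring in at least one
baseline record, the patient-level 2×2 table (n₁₁, n₁₀, n₀₁, n₀₀) yields
the odds ratio of an unadjusted logistic regression of one indicator on the
other, which with a single binary covariate equals the cross-product ratio

    OR = (n₁₁ · n₀₀) / (n₁₀ · n₀₁),

with the two-sided Wald p-value from SE = √(1/n₁₁ + 1/n₁₀ + 1/n₀₁ + 1/n₀₀)
(Haldane–Anscombe +0.5 correction when a cell is zero, flagged). A pattern
becomes an edge iff **OR > 1**, **p < α/N** where N is the number of
patterns with OR > 1 in the same cohort or stratum (Bonferroni, α = 0.05),
and **pattern prevalence n₁₁/n > 1/10,000**.

On the resulting graph the package computes degree, **maximal clique
centrality** (MCC(v) = Σ over maximal cliques C ∋ v of (|C|−1)!, via
Bron–Kerbosch enumeration), closeness (Wasserman–Faust scaling for
disconnected graphs), local clustering coefficient, betweenness, PageRank
(damping 0.85) and max-normalized eigencentrality. **Hub diseases** are the
top 10 nodes by degree (ties → higher prevalence → code order); the
hub-associated subnetwork and its edge/frequency/node coverage of the
complete network quantify how concentrated comorbidity is.

A synthetic-cohort generator plants vertex-disjoint disease pairs at exact
target odds ratios (bivariate-Bernoulli cells solved from the Plackett
quadratic) inside an otherwise independent catalog, so the whole pipeline
is validated by parameter recovery and by family-wise error measurement on
null cohorts. See the methods vignette
(`vignettes/multimorbidity-networks.Rmd`) for conventions and design
rationale.

## Worked example

```r
library(comorbnet)

dis <- c(I10 = 0.25, E78 = 0.15, E11 = 0.10, K29 = 0.12,
         I63 = 0.08, N39 = 0.05, J45 = 0.03, M54 = 0.06)
pairs <- data.frame(code_i = c("I10", "E78"),
                    code_j = c("I63", "E11"),
                    psi = c(6, 5))
gen <- generateCohort(syntheticCohortConfig(10000, dis, pairs, seed = 7))

pat <- screenPatterns(gen$cohort)
subset(pat, selected, select = c(code_i, code_j, n11, odds_ratio, p_value))
#>    code_i code_j n11 odds_ratio       p_value
#> 1     E11    E78 415   5.244932 2.435336e-117
#> 14    I10    I63 539   6.427437 1.063059e-132

hubPipeline(gen$cohort, k = 3)
#> HubReport 'synthetic'
#>   complete network: 4 nodes, 2 edges
#>   hubs: I10, E78, E11
#>   hub-associated coverage: 100% of patterns, 100% of frequency, 100% of nodes
```

Of the 28 candidate patterns enumerated in this 10,000-patient cohort, the
screening selects exactly the two planted pairs, with odds-ratio estimates
(6.43, 5.24) close to the planted values (6, 5); every other pair fails the
Bonferroni-adjusted threshold. The three hubs are the highest-degree nodes
with ties broken by prevalence, and because every edge touches a hub, the
hub-associated network covers 100% of patterns, frequency and nodes.

For real data, start from `readRecords()` → `selectBaseline()` →
`applyFilters()` → `stratifyBySex()`, then `hubPipeline()` per stratum or
`runFullComparison()` for two populations. A thin CLI over the same
functions is in `inst/scripts/comorbnet-cli.R`.

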