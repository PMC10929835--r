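# cupscore

Discovery and per-sample quantification of **cuproptosis regulation
patterns** in bulk tumour expression cohorts, built for the glioblastoma
setting but agnostic to the disease. Cuproptosis — copper-dependent cell
death triggered by copper binding to lipoylated TCA-cycle proteins — is
governed by a 13-gene regulator panel (FDX1, LIPT1, LIAS, DLD, DLAT,
PDHA1, PDHB, DBT, GCSH, DLST, SLC31A1, ATP7A, ATP7B). The package takes a
cohort from raw expression to a prognostic per-sample score:

1. **Preprocessing** — FPKM→TPM (`fpkm_to_tpm`), empirical-Bayes batch
   correction (`batch_correct`), readers/writers for expression TSV, GMT,
   clinical TSV, MAF, CNV calls and PPI edge lists.
2. **Pattern discovery** — resampling consensus clustering on the
   regulator panel (`consensus_cluster`), k selected by minimal PAC
   (proportion of ambiguous clustering), labels ordered by regulator
   activity.
3. **Microenvironment** — single-sample gene-set enrichment with unity
   normalisation (`ssgsea`), composite immune/stromal scores
   (`composite_score`), hypergeometric over-representation (`ora`).
4. **Pattern DEGs** — empirical-Bayes moderated t (`moderated_t`),
   pairwise discovery at |log2FC| > 0.7 & p < 0.05 (`pattern_degs`),
   cross-pattern overlap pool at adjusted p < 0.001 (`overlap_degs`).
5. **CupScore** — univariate-Cox prognostic filter
   (`prognostic_filter`), LASSO-Cox sparsification (`lasso_select`), PCA
   model (`fit_cupscore`) and the score

   CupScore_s = Σ_i (w1_i + w2_i) · z_si,

   the sum of the sample's projections on the first two principal axes of
   the z-scored signature pool; samples split at a maximally selected
   survival cutpoint (`best_cutpoint`) into low/high groups.
6. **Genomic landscape** — mutation/CNV summaries (`mutation_summary`,
   `cnv_frequency`), pairwise mutual exclusivity (`mutual_exclusivity`),
   PPI classification of direct/indirect regulator neighbours
   (`ppi_classify`).

A seeded synthetic-cohort generator (`synthetic_config`,
`generate_cohort`) plants three regulator-driven subtypes, DEG blocks,
subtype-dependent survival and toy mutation/CNV tables, and is the ground
truth every stage is validated against. See the methods vignette
(`vignettes/cuproptosis-patterns.Rmd`) for the models, parameters and
design decisions.

## Worked example

The numbered drivers under `analysis/` run the whole study on the default
synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_cluster_patterns.R
Rscript analysis/03_tme_enrichment.R
Rscript analysis/04_pattern_degs.R
Rscript analysis/05_cupscore_survival.R
Rscript analysis/06_genomic_landscape.R
```

Selected output (seed 1):

```
ConsensusResult: chosen k = 3 (k range 2-6, 1000 resamples)
PAC: 2=9.9e-05, 3=0, 4=0.00705, 5=0.0102, 6=0.0197
ARI vs planted truth: 1
cluster sizes 68/213/169 (total 450); log-rank chisq 38.9, p 3.62e-09

immune score is highest in cluster A | stromal score is highest in cluster C

overlap pool (adj p < 0.001 in every pair): 81 genes
prognostic filter: 77 of 81 overlap genes at Cox p < 0.05
LASSO support: 8 genes
CupScoreResult: 221 low / 229 high at cutoff -0.0543 (total 450)
low vs high survival: log-rank chisq 40.6, p 1.92e-10
AUC(365 d) = 0.653
median CupScore by planted cluster: A=-2.62, B=-0.61, C=1.82

worked fixture: 9/390 samples carry a panel mutation (2.31%, 9 events)
most mutated regulator: ATP7A
```

Reading this: consensus clustering recovers the three planted regulation
patterns exactly (adjusted Rand index 1 against the generator's truth);
the immune-activated pattern A and stromal/metabolic pattern C fall out of
the enrichment scores; the CupScore built from the cross-pattern DEG pool
orders the clusters by their planted hazard (A lowest, C highest), and the
high-score group has significantly worse survival. The fixed 390-sample
mutation fixture reproduces the printed 2.31% panel alteration frequency
with ATP7A the most frequently mutated regulator.

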