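# mirhcc

Integrative analysis of a microRNA's role in disease from heterogeneous
evidence: expression meta-analysis, literature mining, consensus target
prediction, pathway enrichment, and interaction-network topology,
intersected into one report. The package grew out of the question of which
genes miR-34a acts through in hepatocellular carcinoma, but every stage is
generic: it consumes plain-text tables (study summaries, document-gene
mention tables, prediction matrices, GMT gene sets, typed edge lists) and
a synthetic-data module generates all of them with planted ground truth,
so the full pipeline runs and is testable without any external downloads.

It is aimed at computational biologists who have per-study two-group
summary statistics (e.g. extracted from public expression series), target
predictions from multiple tools, and a tagged literature corpus, and who
want the combination analysed with explicit, tested statistics instead of
a chain of web tools.

## The statistics at the core

* **Meta-analysis.** Per-study Hedges' g (control minus case, so a
  transcript downregulated in disease scores positive),
  `g = J * (m_ctl - m_case)/s_p` with `J = 1 - 3/(4 df - 1)` and variance
  `(n1+n2)/(n1 n2) + g^2/(2(n1+n2))`; DerSimonian-Laird random-effects
  pooling with Cochran's Q, I^2, tau^2, normal-quantile CIs, leave-one-out
  sensitivity, and subgroup pooling. Two decisions are reported side by
  side: the conventional zero-crossing p and the unit-interval rule (the
  95% CI must overlap neither +1 nor -1).
* **Co-citation.** For a gene mentioned in m of N documents, n of them
  disease-relevant and k co-mentions, the score is the hypergeometric
  upper tail `P[X >= k]`, computed in log-gamma space and verified against
  exact enumeration.
* **Consensus targets.** A gene is called when at least `threshold` of the
  prediction tools support it (default 4 of 11).
* **Enrichment.** Hypergeometric upper tail per gene set, equal to a
  one-sided Fisher exact test; the universe is explicit and overridable.
* **Hubs.** Node degree standardised against the empirical degree
  distribution, `z = (k - mean)/sd`, one-sided upper-tail p.

## Worked example

```r
library(mirhcc)

# eleven simulated two-group studies at true SMD 0.63, moderate heterogeneity
studies <- simulate_meta_studies(meta_sim_config(seed = 101))
pooled  <- pool_random_effects(study_effects(studies))
pooled
#> random-effects pooled SMD over 11 studies
#>   SMD = 0.580, 95% CI [0.330, 0.831], z = 4.543, p = 5.54e-06
#>   Q = 23.504 (df = 10, p_het = 0.00903), I2 = 57.5%, tau2 = 0.0981
#>   heterogeneity: present; unit-interval rule: significant
```

The pooled SMD of 0.58 (true value 0.63) with CI [0.33, 0.83] clears both
unit boundaries, so the unit-interval rule calls the expression difference
significant; this particular draw is more heterogeneous than average
(I^2 = 57.5%).

```r
# full pipeline on the default synthetic configuration (planted truth:
# 40 true targets, 30 disease genes, 20 in both)
b <- run_pipeline(default_pipeline_config(seed = 101), quiet = TRUE)
cat(b$cocite$n_disease_genes, b$consensus$n_called,
    b$overlap$counts$overlap, b$overlap$planted_recall)
#> 32 43 21 1
```

The literature stage recovers 32 disease genes at alpha = 0.01, consensus
voting calls 43 targets at threshold 4, and their overlap of 21 genes
contains all 20 planted disease-targets (recall 1). Per-stage tables and
a JSON report bundle are written when `out_dir` is given; reruns under the
same seed are byte-identical.

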