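---
title: "Methods: integrative miRNA-disease evidence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative miRNA-disease evidence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirhcc)
```

mirhcc asks a single question of heterogeneous evidence: which genes does a
microRNA plausibly act through in a disease? It answers by combining five
independent evidence streams — expression meta-analysis, literature
co-citation, multi-tool target prediction, gene-set enrichment, and
interaction-network topology — and intersecting the results. This vignette
documents the statistical model behind each stage, the tunable parameters
and their defaults, what the synthetic generators do and do not emulate,
and the numerical and design choices that were genuinely open.

## Expression meta-analysis

Each study contributes two-group summary statistics (per-arm $n$, mean,
SD of the miRNA's expression on an arbitrary platform scale). The effect
size is Hedges' $g$, the standardized mean difference with small-sample
correction:

$$d = \frac{\bar x_{\mathrm{control}} - \bar x_{\mathrm{case}}}{s_p},
\qquad
s_p^2 = \frac{(n_1 - 1)s_1^2 + (n_2 - 1)s_2^2}{n_1 + n_2 - 2},
\qquad
g = \left(1 - \frac{3}{4(n_1 + n_2 - 2) - 1}\right) d,$$

with sampling variance
$v = \frac{n_1 + n_2}{n_1 n_2} + \frac{g^2}{2(n_1 + n_2)}$. The sign
convention is control minus case: a transcript downregulated in diseased
tissue yields a *positive* SMD, the convention used by the standard
meta-analysis tools for expression screens.

Pooling is the DerSimonian–Laird random-effects model. Fixed weights
$w_i = 1/v_i$ give Cochran's $Q$; the method-of-moments between-study
variance is $\hat\tau^2 = \max\!\big(0, (Q - \mathrm{df})/C\big)$ with
$C = \sum w_i - \sum w_i^2 / \sum w_i$; random weights $1/(v_i +
\hat\tau^2)$ give the pooled SMD, its normal-quantile 95% CI, $z$ and
two-sided $p$. Heterogeneity is summarised by
$I^2 = \max(0, (Q-\mathrm{df})/Q)\cdot 100$ and the $\chi^2$ upper tail of
$Q$; the heterogeneity flag fires when $p_{\mathrm{het}} < 0.05$ or
$I^2 > 50$. We deliberately use normal quantiles rather than
Knapp–Hartung so results are comparable with the widely used clinical
meta-analysis software whose defaults this engine mirrors; `metafor`
serves as an independent cross-check in the test suite, never as the
implementation.

Two significance summaries are reported side by side and must not be
conflated:

* the conventional zero-crossing $p$-value, and
* the **unit-interval rule**: the pooled effect is declared significant
  only when its 95% CI overlaps neither $+1$ nor $-1$ (closed intervals —
  touching a boundary counts as overlap).

The unit-interval rule asks whether the CI stays clear of effects of a
full pooled SD, a screen used in SMD analyses of expression data. Its
behaviour at the null deserves a caveat: a tight CI around zero also
avoids both boundaries, so the rule alone cannot distinguish "confidently
null" from "confidently moderate". That is why both summaries are
exposed; a defensible call of association requires the zero-crossing test
as well, and the package leaves the decision to the analyst.

Degenerate inputs are handled explicitly: a single study has
$\mathrm{df} = 0$, where $p_{\mathrm{het}}$ is defined as 1 and
$I^2 = 0$; $\hat\tau^2$ and $I^2$ are floored at zero; a zero pooled SD
with unequal means is an error rather than an infinite effect.
Leave-one-out sensitivity analysis re-pools with each study omitted;
subgroup pooling restricts to one clinicopathological stratum (tissue
comparison, vascular invasion, cirrhosis, metastasis).

## Literature co-citation

With $N$ eligible documents, $n$ disease-relevant ones, $m$ mentioning a
gene and $k$ doing both, the association score is the hypergeometric
upper tail

$$p = 1 - \sum_{i=0}^{k-1} \frac{\binom{m}{i}\binom{N-m}{n-i}}{\binom{N}{n}}
    = P[X \ge k],$$

the probability of at least $k$ co-citations under random assortment.
Counting is document-level: a gene counts once per document no matter how
often it is named. The literal factorial formula overflows at realistic
corpus sizes, so the implementation works in log-gamma space with
log-sum-exp accumulation; exactness is guarded by an enumeration oracle
(every valid $(k, n, m, N)$ tuple with $N \le 40$ agrees to $10^{-12}$).
$k = 0$ returns exactly 1 (empty sum). No multiple-testing correction is
applied by default — the score is a ranking statistic, and the
co-citation literature reports raw tails — but Benjamini–Hochberg is
available behind a flag. The significance cut-off `alpha` is a required
user choice; there is no defensible universal default for corpus mining,
and results should be reported together with the alpha used. A
case-insensitive whole-word dictionary matcher is included as plumbing
for raw-text fixtures; it performs no entity recognition and no synonym
resolution.

## Consensus target calling

Target predictions from independent tools arrive as a genes-by-tools
boolean matrix. A gene is a consensus target when its row sum reaches the
support threshold; the default of 4 (of 11 tools) reflects the common
reliability convention for combining independent prediction algorithms.
Consensus set size is non-increasing in the threshold (property-tested),
with threshold 1 the union and threshold $T$ the intersection of the
tools' calls. Running the tools themselves is out of scope: web
predictors are versioned and unreproducible, so the matrix is the
interface.

## Gene-set enrichment

For a query of $n$ genes inside a universe of $N$, a set of size $K$
overlapping the query in $k$ genes scores $P[X \ge k]$ under the
hypergeometric — identical to a one-sided Fisher exact test, which the
test suite uses as an oracle on 500 random instances. Two choices matter
and are explicit:

* **Universe.** Defaults to the union of all collection members, and can
  be overridden. Enrichment $p$-values move with the background, which is
  why printed pathway $p$-values from other tools are not comparable
  without knowing theirs.
* **Out-of-universe query genes** are dropped (with a warning) rather
  than counted in $n$; counting them would inflate significance.

The significance flag uses $p \le \alpha$ (inclusive, matching the
convention of pathway tables that admit boundary rows). GO annotation is
grouped by namespace without graph propagation; a gene annotated in
several namespaces appears in each.

## Network analysis

Typed edges (enzyme–enzyme relation, protein–protein interaction,
gene-expression interaction, co-citation) with polarity labels
(association / inhibition / activation) build an **undirected simple
graph**: self-loops are dropped, and parallel edges across evidence types
merge into one edge carrying the set of types. Polarity is kept as
annotation only; the evidence sources do not supply reliable direction.
Connectivity is plain degree. The hub statistic standardises a node's
degree against the empirical degree distribution,
$z_i = (k_i - \bar k)/s_k$ with the sample SD, and reports the one-sided
upper tail $1 - \Phi(z_i)$. This is a screening heuristic, not a
calibrated test — degree distributions of biological networks are
right-skewed, so the normal tail is conservative at the top and the
ranking, not the absolute $p$, is the useful output. A regular graph has
zero degree variance; all $z$ are then defined as 0 with $p = 0.5$ and
the result is flagged degenerate. An alternative definition via a
permutation null was considered and rejected: it requires a generative
edge model the input does not supply, and degree standardisation is the
interpretation consistent with reporting a single $z$-test $p$ per node.

## Integration

The final report intersects consensus targets with literature-derived
disease genes after case normalisation and optional alias mapping
(symbol styles in the wild mix `Bcl-2` with `BCL2`; alias resolution
beyond a user-supplied table is out of scope). The overlap is annotated
with the enriched pathways that pass `alpha` and contain at least one
overlap gene. `run_pipeline()` chains all stages, writes per-stage TSVs
plus one JSON bundle, and logs timings to the console only — the bundle
contains no timestamps or absolute paths, so reruns under one seed are
byte-identical.

## Synthetic data: what it emulates and what it does not

Every stage input can be generated with planted ground truth:

* **Studies** are simulated at the *observation* level: study $i$ draws a
  true effect $\delta_i \sim N(\delta, \tau^2)$, then per-arm Gaussian
  observations (cases at 0, controls at $\delta_i$, SD `within_sd`),
  which are then summarised. Summaries therefore carry realistic SD
  sampling noise, exercising the small-$n$ bias that the Hedges
  correction addresses. Defaults: 11 studies, $\delta = 0.63$, per-arm
  sizes uniform on 4–96 (the range spanned by public HCC miRNA series),
  and $\tau = 0.23$. The $\tau$ default was calibrated by simulation so
  the mean $I^2$ across replicate meta-analyses sits near 40%, i.e. the
  moderate-heterogeneity regime the pipeline is intended for; at these
  settings 1000-replicate runs give CI coverage ≈ 0.93 and absolute bias
  < 0.005.
* **Corpora** flag each document disease-relevant with rate 0.3 and
  mention each gene with rate 0.05 (defaults chosen to put per-gene
  document counts in the tens-to-hundreds at $N = 2000$, the regime where
  the hypergeometric tail is discriminative but not saturated); enriched
  genes have their mention *odds* multiplied (default 20) inside disease
  documents.
* **Prediction matrices** are per-cell Bernoulli: true targets hit with
  0.8 per tool, others with 0.1. At 11 tools and threshold 4 the binomial
  tail puts per-gene recall above 0.999, so consensus recall failures in
  tests indicate bugs, not noise.
* **Gene sets and edges** are uniform draws (no planted structure).

Each generator consumes one master seed; per-record randomness runs on
deterministically derived sub-stream seeds, and the caller's RNG state is
restored afterwards.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: platform- and probe-level artefacts,
non-Gaussian and correlated expression, publication bias across studies,
burstiness and topic correlation of real literature (documents here are
independent), correlated errors among prediction tools trained on shared
features, and the skewed degree distributions of real interactomes. The
suite demonstrates that the statistics are computed correctly and recover
planted truth under their own model, not that the model is true of any
particular public dataset.

## Problem sizes and determinism

The shipped tests and the acceptance script use 200 replicate
meta-analyses of 11 studies, the full $N \le 40$ co-citation oracle sweep
(≈ 259,000 tuples), 500 Fisher-oracle enrichment instances, 100 random
consensus matrices, and a 150-gene / 2000-document end-to-end pipeline —
sizes at which every stage's sampling error is far below the tolerances
asserted, while a full run stays under a minute. All randomness is
seed-derived; the end-to-end bundle is byte-identical across reruns under
one seed.

## Known limitations

* The unit-interval rule's null behaviour (above) means its flag must be
  read together with the zero-crossing $p$.
* Co-citation treats documents as exchangeable; review articles and
  highly cited genes violate this in real corpora.
* The hub $p$-value is a ranking device; no multiplicity control is
  applied across nodes.
* Symbol matching is exact after normalisation; unresolved aliases leak
  genes out of the overlap.
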