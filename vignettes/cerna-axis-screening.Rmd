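---
title: "Methods: screening a ceRNA axis from pull-down to prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening a ceRNA axis from pull-down to prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernascreen)
```

## The model

A 3'-UTR acting as a competing endogenous RNA (ceRNA) sponges miRNAs
through seed-match binding sites; genes sharing those miRNAs' sites are
de-repressed when the UTR is overexpressed. The package nominates the
(miRNA, gene) axis behind such a network by chaining independent screens,
each of which is a self-contained, testable statistic. None of the stages
fits a joint model: the cascade is a deterministic pipeline of set
operations over ranked lists, which is what makes its behavior auditable
stage by stage.

### Enrichment (pull-down libraries)

Raw mature-miRNA tag counts are normalized to tags per million aligned
(TPA), so `sum(TPA) = 1e6` for every library, and each miRNA is scored as
`log2((TPA_pd + c) / (TPA_ctrl + c))` with pseudocount `c = 1` TPA. The
pseudocount bounds scores when the control count is zero; it is the only
regularization applied. Enrichment here is a *ranking* statistic, not a
test — no p-values are attached, mirroring the screening practice the
pipeline reproduces. The selection thresholds (`min_log2 = 1`,
`min_tpa = 10`) are analyst knobs: the original screen's "highly
enriched" criterion is not stated anywhere, so its published per-line
counts cannot anchor a default and are treated as non-reproducible.
Ties in the ranking are broken by pull-down TPA then id, making `top_k`
order-invariant and reproducible across platforms.

### Differential expression

Expression is RPKM, `1e9 * count / (depth * length)`; fold change is
`log2((mean_case + 1) / (mean_ctrl + 1))` with means over replicates. The
DEG filter is the raw two-threshold rule `|log2FC| > 1` and `P < 0.05`,
with no multiple-testing correction by default (a Benjamini-Hochberg
option exists behind `p_adjust = "BH"`). The identity of the DE test is
the largest fidelity gap in the pipeline: the source analysis names no
test. The default is the classic exact binomial test for unreplicated
libraries (the gene's pooled case count against the proportion implied by
pooled depths, two-sided by summing all outcome probabilities not above
the observed one); `welch_replicated` offers an unequal-variance t-test on
`log2(RPKM + 1)` when replicates exist. The exact mode is checked against
explicit enumeration for all pooled counts up to 30.

### Seed-match target prediction

The canonical seed taxonomy stands in for database predictors, because it
is the minimal transparent mechanism those predictors share. With the
seed at miRNA positions 2–8, a UTR position matches as `8mer` (reverse
complement of 2–8 followed by A), `7mer-m8` (reverse complement of 2–8),
`7mer-A1` (reverse complement of 2–7 followed by A) or `6mer` (reverse
complement of 2–7); each match is reported once under its best class, and
intervals are 0-based half-open spanning 8/7/7/6 nt. No context scoring
(AU content, position within the UTR, conservation) is applied — the
point of the stand-in is transparency, not accuracy, and database-derived
target counts are declared non-reproducible. Dual-predictor combination
defaults to union, maximizing sensitivity to match a deliberately large
candidate pool; an intersection mode exists.

### Survival and association statistics

Kaplan-Meier, log-rank, Cox and Spearman are implemented from scratch so
the pipeline has no runtime dependency on a survival stack; the
`survival` package appears only in the test suite as an independent
oracle (agreement to ~1e-6 on random fixtures with ties). Choices worth
stating:

* **Cox ties** use the Efron approximation, the standard modern default.
  Newton steps are damped by halving until the partial likelihood
  improves; convergence requires a gradient max-norm below 1e-8, and a
  coefficient passing |beta| > 15 triggers a separation warning with
  `converged = FALSE`.
* **Dichotomization** of cohort expression defaults to the median split,
  with values equal to the median assigned to "low" (deterministic);
  fixed-cutoff and Youden alternatives are provided. The original
  cohorts' cutoff rule is unstated, so the median is a choice, not a
  reproduction.
* **Direction check.** The prognostic filter keeps a gene only if the
  log-rank p-value clears alpha *and* the high-expression group has the
  lower survival at the horizon (60 months). "Associated with poor
  prognosis" implies the direction but never defines the test
  orientation; making it explicit halves the null retention rate to
  alpha/2, and the calibration tests assert 2.5%, not 5%.
* **Spearman** uses midranks and the t approximation for p-values,
  two-sided, matching `cor.test(exact = FALSE)` to 1e-12 under ties.

### ISH composite scoring

Intensity (0–3) times proportion-of-positive-cells category (0 for none,
1 for ≤10%, 2 for ≤50%, 3 for ≤75%, 4 above) gives composites in 0–12,
banded negative (0), weak (1–4), moderate (5–8), strong (9–12), with the
low/high split between 4 and 5. Note the attainable composites are only
the factor products {0,1,2,3,4,6,8,9,12}; the banding is nevertheless
defined on all of 0–12 because the printed scheme is, and because the
smallest *nominal* high-group score (5) is itself unattainable. The
Youden cutoff maximizes `sensitivity + specificity − 1` over thresholds
1–12 classifying "high" as `score >= c` (higher score = worse), resolves
ties to the smallest cutoff, and — because mathematically tied J values
can differ by float rounding when reached via different fractions —
treats values within 1e-9 as tied. The outcome used for cutoff estimation
is death within the 60-month horizon, with subjects censored before the
horizon excluded; the original endpoint is unstated, and this is the
package's choice.

### The cascade

`run_screen()` flows: per-line enrichment → selection → intersection
(common set) → per-line top-k → union (candidates) and intersection (core
miRNAs) → seed targets of the candidate set ∩ up-DEGs → prognostic filter
→ ∩ targets of core miRNAs → Spearman ranking against the core gene. The
top gene plus its strongest-enriched core miRNA form the axis. Target
prediction feeds on the top-k union (configurable to the full common
set), and the final selection is by correlation alone — the original
judgment also weighed cross-cohort prognosis qualitatively, a step
reduced here to the documented ranking. Empty stages warn and propagate
empty sets; the report always completes.

## The synthetic world

`simulate_bundle()` states one coherent world per seed, with defaults
chosen once for desk-scale testability (a real study would be an order of
magnitude larger in genes and depth):

| Parameter | Default | Why |
|---|---|---|
| miRNA universe / planted | 500 / 20 | enough decoys for rank-based recovery to be non-trivial |
| enrichment fold | 8 (axis ×4) | "strong" capture enrichment; the axis boost (~3 SD of ratio noise) realizes the design intent that the axis tops both lines |
| library depth | 1e6 tags | typical small-RNA library scale |
| genes, up/down, lfc | 2000, 30/30, ±2 | clears the |log2FC|>1 filter with margin |
| dispersion | 0.1 (counts: NB, `var = mu + phi mu^2`) | sequencing-realistic overdispersion; 0 gives Poisson |
| replicates | 3 per condition | minimal replicated design |
| UTR length | 300 nt | hosts 20 planted sites with room for clean background |
| cohort n, beta | 500, 0.8 per SD | log-rank/Cox power without being trivial |
| censoring | 30%, independent exponential | calibrated at beta = 0 |
| baseline survival | exponential, 36-month median | simplest hazard satisfying proportional hazards |

Specific generator mechanics that matter for interpreting green tests:

* Counts are negative binomial around expected proportions; the pull-down
  library's depth *inflates* with captured material rather than being
  renormalized, so the planted raw-count ratio equals the fold exactly in
  expectation. TPA renormalization then compresses scores slightly;
  rankings are unaffected.
* UTR backgrounds are **rejection-sampled to be site-free** for the
  planted miRNA set, and plants are verified by a full re-scan (drafts
  creating junction artifacts are discarded). Planted miRNA sets are
  chosen seed-compatible — no planted miRNA's core may occur inside
  another's site — since otherwise a clean background cannot exist.
  Consequently, target-prediction recovery tests establish scanner
  correctness, *not* robustness to near-miss sites, which real UTRs have.
* Sequences are emitted in the DNA alphabet (U→T), per FASTA convention;
  the scanner normalizes on input.
* The cohort's hazard depends only on core-gene expression; target genes
  acquire prognostic signal through correlation (0.7 for the axis gene,
  0.25 for decoys). This satisfies proportional hazards by construction —
  a green Cox recovery says nothing about misspecified hazards.
* Each generator draws from its own RNG stream derived from the master
  seed by fixed offsets, so regenerating one dataset never perturbs
  another and identical configurations are byte-identical.

What the synthetic world does **not** emulate: read-level artifacts (UMIs,
alignment, isomiRs), batch structure, non-canonical or context-scored
binding, informative censoring, competing risks, and the covariate
structure of real multivariate prognostic models. Published real-data
stage counts therefore cannot be, and are not, reproduced; the tests
assert the analytic identities those numbers force (e.g. 241 + 82 = 323;
a 4-shared top-10 merge gives 16 and 4; the composite scheme tops at 12
with the high group from 5) plus calibration and recovery in the stated
world.

## Numerical choices and degenerate inputs

* Exact binomial two-sidedness uses the "sum of probabilities not above
  the observed" rule with a 1e-7 relative guard against float ties;
  pooled count 0 gives p = 1.
* Log-rank variance terms skip event times with a risk set of 1 (the
  hypergeometric variance is 0/0 there); a zero total variance yields
  chi-square 0, p = 1.
* `dichotomize` errors on constant values; the prognostic filter treats
  per-gene split failures as "not retained" rather than aborting a whole
  screen.
* Youden requires both outcome classes and errors otherwise.
* The exporter writes edges TSV + report JSON with canonical ordering so
  write → read → write is byte-identical.

## Known limitations

The DE-test identity, the "highly enriched" thresholds, the
dichotomization cutoff and the Youden endpoint are all choices where the
reproduced analysis is silent; each is a visible knob with its default
argued above, and none is calibrated against published counts. The
seed-match predictor deliberately omits context scoring, so its
specificity is below database predictors on real sequence. The final
axis choice uses a single cohort's correlation; with several cohorts,
run the ranking per cohort and reconcile externally.
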