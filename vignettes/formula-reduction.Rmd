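---
title: "Deciding whether formula components are dispensable: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding whether formula components are dispensable: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formulanet)
```

## The problem

Traditional multi-herb medicines — here the Uyghur Yimusake formula used
against erectile dysfunction (ED) — sometimes contain ingredients from rare
or endangered animals. Because such mixtures act through many weak
compound–target interactions at once, the dispensability of a component set
cannot be judged one compound at a time. formulanet operationalizes a
network-level argument: enumerate the plausible bioactive compounds of each
formula variant, predict their protein targets, and compare the *target
coverage* of the variant with and without the questioned components. If
nearly all targets are preserved and nothing lost is disease-relevant, the
components are candidates for removal.

This vignette explains each stage's model and assumptions, the tunable
parameters, the synthetic-data design, and the numerical choices. It states
no empirical result beyond what the package's tests and acceptance script
themselves compute.

## Herb–disease association from literature counts

Herbs are pre-screened by literature co-occurrence. With `N` papers in the
corpus, `K` linked to the disease, `n` about the herb and `k` about both, the
association score is the upper tail of the hypergeometric distribution,
`P(X >= k)`. The test conditions on both margins, which compensates for the
very different research volumes behind individual herbs. The decision rule is
strict: `P < alpha` with `alpha = 0.01` by default, uncorrected — the stage
is a pre-screen, not a formal inference, and herbs additionally enter on
empirical grounds.

Numerics: the pmf terms are computed as `exp(lchoose(K,i) + lchoose(N-K,n-i)
- lchoose(N,n))` and combined by log-sum-exp; whichever tail (upper, or one
minus lower) has fewer support terms is summed, so corpora up to about 1e7
documents are handled without overflow and with relative error on the order
of the `lgamma` rounding (~1e-8 at that scale). Out-of-support terms are
zero by convention, which makes `k = 0` return exactly 1. An exhaustive sweep
against a direct pmf-summation oracle for all instances with `N <= 60`
agrees to 1e-12 in the test suite.

## ADME screening

Compounds are retained when oral bioavailability `OB >= 30` (percent) and
drug-likeness `DL >= 0.18`. OB is a *consumed* attribute — the regression
model that predicts it from structure is not part of this package — while DL
can either be consumed or recomputed as the continuous Tanimoto similarity
between a compound's descriptor vector and the mean vector of a reference
drug collection (0.18 is the DrugBank mean, hence the threshold: it asks for
at-least-average drug-likeness). When a tabulated DL and descriptors are both
available the tabulated value wins, because the descriptor set behind the
published values is not public.

Two boundary decisions matter:

* **Inclusive thresholds.** The published screen retains compounds sitting
  exactly at DL = 0.18 (methyllinolenate, pinocembrin, and others), so the
  comparison is `>=`, switchable to strict via `screen_config(inclusive =
  FALSE)`.
* **Explicit rescues.** The published per-herb counts include compounds that
  fail the numeric filter but are retained for documented pharmacological
  activity (brucine at OB = 7.6 %, safranal and picrocrocin with DL = 0.04,
  myristicin, and so on). These are editorial judgments, so the package takes
  the whitelist as an explicit input rather than inferring it; the Table-1
  fixture ships the ten published rescues as its `rescued` column. The screen
  result keeps `strict_pass`, `rescued` and `rejected` disjoint so the two
  retention routes are never conflated.

## Target consensus

Compound–target interactions arrive as random-forest and support-vector-
machine scores from a chemogenomic model whose training is out of scope here;
only its published decision rule is implemented. The two stated principles —
membership in both positive prediction lists (score > 0.5) and final cutoffs
RF > 0.7, SVM > 0.8 — are composed conjunctively, with all comparisons strict
per their "greater than" wording. The 0.5 rule is dominated by the defaults
but is kept as independent configuration, since a user may lower the final
cutoffs below 0.5. The filter is row-local and order-stable, which the suite
checks against a per-row oracle scan.

## Network statistics

Networks are bipartite: compound nodes (with herb/component group sets) and
target nodes. Only degree-based statistics and set-algebra partitions are
computed, because those are what the coverage argument needs — no
centralities, no layout. Conventions:

* A compound attributed to several herbs contributes its targets to every
  such group (the published multi-herb rows feed several sub-networks).
* "Shared" across more than two groups means hit by *every* group;
  group-specific means hit by exactly one. Everything else (partial overlap,
  or targets reached only by compounds outside the compared groups) is
  reported as `other`, so the partition always covers the target side.
* Percentages and mean degrees round half *up* (away from zero), not to even:
  67/132 must report as 50.76. `round_half_up()` is exported because R's
  banker's rounding would silently disagree with published figures.

## The removability rule

The comparison of two formula variants partitions the target union into
shared, A-specific and B-specific sets (B is the removed component set);
`shared_fraction` uses the union as denominator, matching the published
"97 %" = 135 shared of 139 total. The verdict rule had to be formalized here,
since the source argument is narrative:

* **Coverage rule** — `shared_fraction >= 0.90` by default. The threshold was
  fixed at 0.90, below the 0.97 observed in the motivating case, so that the
  rule tolerates moderate coverage loss while still demanding near-complete
  preservation; it is fully configurable.
* **Disease-link rule** — no B-specific target may be disease-associated.
  Removal is a safety-relevant claim, so a B-specific target with *unknown*
  annotation makes the verdict `indeterminate` rather than passing silently;
  a failed coverage or disease-link rule still yields a definite
  "not removable".

Only set membership matters: how many compounds hit each shared target is
ignored, which is the main known limitation — a target covered by one weak
binder in the reduced formula counts the same as one covered by ten.

## Pathway mapping

Pathway membership is a caller-supplied curated table (pathway name → target
ids); no live database is queried, because curated pathway snapshots are the
only reproducible input. Mapping is plain set intersection per pathway, and
compound participation counts deduplicate by compound id. The tripartite
compound–target–pathway export tags node and edge roles for downstream
visualization tools.

## Synthetic data: what it emulates and what it does not

The generators exist because no edge lists were published for the real
networks; they are the only way to exercise the consensus, network and
comparison stages end-to-end. Defaults were fixed once to mirror the
headline scenario: 66 compounds allocated over the seven herbs with weights
proportional to their published candidate counts, 139 targets in the
comparison union, 135 shared, 4 specific to the removed components, none
disease-linked.

* **OB/DL** are drawn from two-component mixtures of uniform ranges on
  either side of the filter thresholds (low: OB 2–28, DL 0.01–0.17; high:
  OB 32–95, DL 0.19–0.95; `p_high = 0.85` each). Uniform components were
  chosen because no distributional shape is published and they make the
  design strict-pass rate available in closed form for binomial checks. A
  component with zero spread sitting exactly on a threshold is rejected at
  configuration time, since its planted pass/fail label would be undefined.
* **Scores**: planted true interactions clear both consensus cutoffs by at
  least `score_noise` (default 0.02) and decoys miss at least one by the
  same margin, so the filter recovers the truth set exactly by construction
  — the corresponding tests validate the plumbing, not the discriminative
  power of any model.
* **Formula pairs**: targets are assigned to shared/A-specific/B-specific
  classes by a seeded permutation and each target is linked to 1–3 random
  compounds of its side. In noise-free mode (default) the measured shared
  fraction equals the planted one exactly; `noise_targets > 0` drops that
  many shared targets from one random side to perturb it.

Everything is deterministic given the configured seed (each generator
re-seeds with a fixed offset). What the synthetic data does *not* emulate:
chemistry (descriptors are arbitrary non-negative vectors), realistic degree
distributions, correlated RF/SVM errors, or literature corpora. Passing
tests therefore demonstrate correctness of the set algebra, thresholds and
bookkeeping on data of the right shape — not predictive validity on real
compound libraries.

## Problem sizes and degenerate inputs

The test suite runs at deliberately modest sizes — the exhaustive
hypergeometric sweep stops at `N = 60` (about a million instances), the
consensus oracle scan uses 10,000 rows, simulated libraries up to 10,000
compounds — which keeps the whole suite under a minute while still covering
every code path. Degenerate inputs are defined, not patched around: empty
libraries screen to empty partitions, an empty interaction list builds an
empty network (whose mean degree is an error, not NaN), a comparison of two
empty target sets is a domain error, and duplicate ids anywhere are
validation errors naming the offender.

## Known limitations

* OB and the RF/SVM scores are inputs; nothing here validates their quality.
* The fixture layer reproduces two published inconsistencies rather than
  resolving them: the conclusion's "140 target proteins" versus the 139-
  target comparison union (139 is used as the denominator throughout), and a
  CNS-network overlap percentage whose printed denominator cannot be
  reconstructed (it is therefore not asserted anywhere).
* Removability is a target-coverage statement only — no dosing, no efficacy,
  no pharmacokinetic equivalence.
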